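test_that("negative-control statistics use mean and sample SD, rejecting degenerates", {
    w <- data.frame(plate_id = "p1", replicate = 1L, well = c("A1", "A2", "B1"),
                    content_id = c("nc", "nc", "m1"),
                    role = c("neg_control", "neg_control", "mimic"),
                    treatment = "drug", luminescence = c(90, 110, 80))
    st <- negControlStats(screenExperiment(w))
    expect_equal(st$mu, 100)
    expect_equal(st$sigma, sqrt((10^2 + 10^2) / 1), tolerance = 1e-6)  # 14.142
    expect_equal(st$n, 2L)

    w$luminescence <- c(100, 100, 80)
    expect_error(negControlStats(screenExperiment(w)), "zero")
    w1 <- w[-2L, ]
    expect_error(negControlStats(screenExperiment(w1)), "fewer than 2")
})

test_that("percent viability and Z-score implement the plate formulas", {
    expect_equal(percentControlViability(100, 100), 100)
    expect_equal(percentControlViability(0, 100), 0)
    expect_equal(percentControlViability(75, 100), 75)
    expect_error(percentControlViability(10, 0), "zero")
    expect_equal(zScore(100, 100, 10), 0)
    expect_equal(zScore(80, 100, 10), -2)
    expect_error(zScore(80, 100, 0), "sigma")
})

test_that("plate normalisation makes negative-control Z mean 0 / SD 1 and is affine-invariant", {
    sim <- simulateScreen(nMimics = 60, nPlantedHits = 2, seed = 9, nReplicates = 1)
    w <- as.data.frame(wells(sim$screen))
    st <- as.data.frame(negControlStats(sim$screen))
    for (i in seq_len(nrow(st))) {
        sel <- w$role == "neg_control" & w$plate_id == st$plate_id[i] &
            w$treatment == st$treatment[i] & w$replicate == st$replicate[i]
        z <- zScore(w$luminescence[sel], st$mu[i], st$sigma[i])
        expect_equal(mean(z), 0, tolerance = 1e-10)
        expect_equal(sd(z), 1, tolerance = 1e-10)
    }
    # scaling a whole plate/arm leaves every z unchanged
    res0 <- screenResults(sim$screen)
    w2 <- w
    w2$luminescence <- w2$luminescence * 3.7
    res1 <- screenResults(screenExperiment(w2))
    expect_equal(res1$z, res0$z, tolerance = 1e-10)
    expect_equal(res1$pct_viability_drug, res0$pct_viability_drug, tolerance = 1e-10)
})

test_that("simulated negative controls match the generative moments", {
    sim <- simulateScreen(nMimics = 4, nPlantedHits = 0, nToxic = 0,
                          wellsPerPlate = 1100, negPerPlate = 1000,
                          brca2PerPlate = 4, nReplicates = 1, plateScaleSD = 0,
                          noiseCV = 0.10, baseLum = 1000, seed = 2)
    w <- as.data.frame(wells(sim$screen))
    nc <- w$luminescence[w$role == "neg_control" & w$treatment == "drug"]
    expect_equal(mean(nc), 1000, tolerance = 0.02)        # MC error ~ 1000*0.1/sqrt(1000)
    expect_equal(sd(nc) / mean(nc), 0.10, tolerance = 0.15)
})

test_that("toxicity is called against the BRCA2-siRNA vehicle comparator, boundary inclusive", {
    mkWells <- function(mimicVehicle) {
        rows <- list()
        for (arm in c("drug", "vehicle")) {
            lum <- c(rep(c(95, 105), 2),          # 4 neg controls, mean 100
                     if (arm == "vehicle") 60 else 30,  # BRCA2
                     if (arm == "vehicle") mimicVehicle else 50)
            rows[[arm]] <- data.frame(
                plate_id = "p1", replicate = 1L,
                well = sprintf("W%d", seq_along(lum)),
                content_id = c(rep("nc", 4), "BRCA2_siRNA", "m1"),
                role = c(rep("neg_control", 4), "pos_control_brca2", "mimic"),
                treatment = arm, luminescence = lum)
        }
        screenExperiment(do.call(rbind, rows))
    }
    expect_true(screenResults(mkWells(50))$toxic)    # clearly below BRCA2
    expect_false(screenResults(mkWells(95))$toxic)   # clearly above
    expect_true(screenResults(mkWells(60))$toxic)    # equal counts as toxic
})

test_that("hit calling applies both thresholds and ranks by viability", {
    res <- S4Vectors::DataFrame(
        mimic = c("a", "b", "c", "d", "e"),
        plate_id = "p1",
        pct_viability_drug = c(50, 50, 74, 80, 40),
        pct_viability_vehicle = c(100, 100, 95, 90, 50),
        z = c(-3, -4, -2.5, -3, -6),
        toxic = c(FALSE, FALSE, FALSE, FALSE, TRUE))
    res$hit <- !res$toxic & res$z < -2 & res$pct_viability_drug < 75
    res$rank <- NA_integer_
    h <- which(res$hit)
    o <- order(res$pct_viability_drug[h], res$z[h], res$mimic[h])
    res$rank[h[o]] <- seq_along(h)
    hits <- callHits(res)
    # d fails viability, e is toxic; b beats a on z at equal viability
    expect_equal(hits$mimic, c("b", "a", "c"))
    expect_equal(hits$rank, 1:3)
    expect_length(callHits(res[0, ]), 8L)  # empty in, empty out (same columns)
    expect_equal(nrow(callHits(res[0, ])), 0L)
})

test_that("fold enrichment is the double ratio and is scale-invariant", {
    expect_equal(foldEnrichment(2, 2, 2, 2), 1)
    expect_equal(foldEnrichment(8, 2, 2, 2), 4)
    expect_error(foldEnrichment(1, 0, 1, 1), "> 0")
    set.seed(5)
    for (i in 1:25) {
        v <- runif(4, 0.1, 10)
        c1 <- runif(1, 0.1, 10)
        expect_equal(foldEnrichment(v[1] * c1, v[2] * c1, v[3], v[4]),
                     foldEnrichment(v[1], v[2], v[3], v[4]), tolerance = 1e-12)
    }
})

test_that("loosening the Z cutoff never removes a hit", {
    sim <- simulateScreen(nMimics = 200, nPlantedHits = 6, nToxic = 2, seed = 21)
    strict <- callHits(sim$screen, analysisParams(zCutoff = -3))
    loose <- callHits(sim$screen, analysisParams(zCutoff = -2))
    expect_true(all(strict$mimic %in% loose$mimic))
    res <- screenResults(sim$screen)
    expect_true(all(!res$toxic[res$hit]))  # hits are a subset of non-toxic mimics
})
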