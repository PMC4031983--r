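locus <- makeGR("chr4", 36427988, 36428050)

test_that("segment-rule locus status reads the midpoint segment with closed band edges", {
    seg <- function(l2) makeGR("chr4", 36e6, 37e6, log2_ratio = l2)
    expect_equal(locusStatusAcgh(seg(-0.5), locus), "deletion")
    expect_equal(locusStatusAcgh(seg(0.0), locus), "neutral")
    expect_equal(locusStatusAcgh(seg(-0.2), locus), "neutral")   # band is closed
    expect_equal(locusStatusAcgh(seg(0.2), locus), "neutral")
    expect_equal(locusStatusAcgh(seg(0.21), locus), "amplification")
    away <- makeGR("chr4", 1, 100, log2_ratio = -1)
    expect_equal(locusStatusAcgh(away, locus), "unknown")
    # narrower overlapping segment wins at the midpoint
    both <- c(makeGR("chr4", 30e6, 40e6, log2_ratio = 0),
              makeGR("chr4", 36.3e6, 36.5e6, log2_ratio = -0.8))
    expect_equal(locusStatusAcgh(both, locus), "deletion")
})

test_that("marker-rule locus status uses the nearest marker, ties to the lower position", {
    mk <- function(pos, cn) makeGR("chr4", pos, pos, allelic_cn = cn)
    expect_equal(locusStatusSnp(mk(36427000, 1.2), locus), "deletion")
    expect_equal(locusStatusSnp(mk(36427000, 2.0), locus), "neutral")
    expect_equal(locusStatusSnp(mk(36427000, 2.3), locus), "amplification")
    expect_equal(locusStatusSnp(makeGR("chr9", 1, 1, allelic_cn = 1), locus),
                 "unknown")
    # equidistant on both sides: lower position wins
    two <- c(mk(36427988 - 1000, 1.0), mk(36428050 + 1000, 2.0))
    expect_equal(locusStatusSnp(two, locus), "deletion")
    set.seed(13)
    for (i in 1:50) {
        pos <- sort(sample.int(8e7, sample(2:40, 1)))
        cn <- round(runif(length(pos), 0.5, 3), 3)
        got <- locusStatusSnp(makeGR("chr4", pos, pos, allelic_cn = cn), locus)
        cnNear <- bruteNearestCn(pos, cn, start(locus), end(locus))
        want <- if (cnNear < 1.9) "deletion" else if (cnNear <= 2.1) "neutral"
                else "amplification"
        expect_equal(got, want)
    }
})

test_that("the two miR-1255b loci combine with deletion dominance and unknown propagation", {
    expect_equal(combineMir1255b("deletion", "neutral"), "deletion")
    expect_equal(combineMir1255b("neutral", "deletion"), "deletion")
    expect_equal(combineMir1255b("deletion", "unknown"), "deletion")
    expect_equal(combineMir1255b("neutral", "neutral"), "neutral")
    expect_equal(combineMir1255b("amplification", "neutral"), "amplification")
    expect_equal(combineMir1255b("unknown", "neutral"), "unknown")
    expect_equal(combineMir1255b("neutral", "unknown"), "unknown")
})

test_that("group assignment implements the WT definition and exclusions", {
    gt <- S4Vectors::DataFrame(
        sample = sprintf("S%d", 1:5),
        status = I(matrix(c("neutral", "neutral", "neutral",
                            "deletion", "neutral", "neutral",
                            "neutral", "amplification", "neutral",
                            "unknown", "neutral", "neutral",
                            "deletion", "deletion", "neutral"),
                          nrow = 5, byrow = TRUE,
                          dimnames = list(NULL, c("miR-1255b", "miR-148b*",
                                                  "miR-193b*")))))
    out <- assignGroups(gt)
    expect_equal(out$group,
                 c("WT", "del-miR-1255b", "excluded", "excluded",
                   "del-miR-1255b,del-miR-148b*"))
    grp <- sampleGroups(out)
    expect_equal(grp$WT, "S1")
    expect_equal(grp$`del-miR-1255b`, c("S2", "S5"))
    expect_length(intersect(grp$WT, unlist(grp[-1])), 0L)
})

test_that("cohort genotyping recovers planted groups and ignores sample order", {
    sim <- simulateCohort(nWT = 5, nDel = c("miR-1255b" = 2, "miR-148b*" = 2),
                          seed = 8)
    for (m in c("acgh", "snp")) {
        gt <- genotypeCohort(sim$cohort, method = m)
        expect_equal(gt$group, unname(sim$truth$groupOf[gt$sample]))
    }
    # permuting the stored layers changes nothing
    co <- sim$cohort
    perm <- rev(seq_along(cnSegments(co)))
    co2 <- tumorCohort(lohEvents = lohEvents(co), cnSegments = cnSegments(co)[perm],
                       snpMarkers = snpMarkers(co), expression = exprTable(co),
                       samples = rev(sampleIDs(co)))
    gt2 <- genotypeCohort(co2, method = "acgh")
    gt1 <- genotypeCohort(co, method = "acgh")
    expect_equal(setNames(gt2$group, gt2$sample)[gt1$sample],
                 setNames(gt1$group, gt1$sample))
})
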