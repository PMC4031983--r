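test_that("covered fraction uses union semantics and matches a per-base oracle", {
    ev <- makeGR("chr1", 1001, 2000)               # length 1000
    expect_equal(coveredFraction(ev, GenomicRanges::GRanges()), 0)
    expect_equal(coveredFraction(ev, makeGR("chr1", 500, 3000)), 1)
    seg <- makeGR("chr1", c(1001, 1401), c(1500, 1900))  # union covers 900
    expect_equal(coveredFraction(ev, seg), 0.9)

    set.seed(42)
    for (i in 1:300) {
        L <- sample.int(10000, 1)
        ns <- sample.int(6, 1) - 1L
        s0 <- sample.int(L + 200, ns, replace = TRUE) - 100L
        e0 <- pmax(s0 + sample.int(500, ns, replace = TRUE), 0L)
        got <- coveredFraction(makeGR("chrX", 1, L), makeGR("chrX", pmax(1L, s0), e0))
        expect_equal(got, bruteCoveredFraction(L, s0, e0), tolerance = 1e-12)
    }
})

test_that("cross-sample mixing in coverage computation is rejected", {
    ev <- makeGR("chr1", 1, 1000, sample = "S1")
    seg <- makeGR("chr1", 1, 500)
    expect_error(coveredFraction(ev, seg), "cross-sample")
    seg2 <- makeGR("chr1", 1, 500, sample = "S2")
    expect_equal(coveredFraction(ev, seg2), 0)  # same chrom, other sample
})

test_that("segment-rule classification follows the printed inequalities", {
    s <- "T1"
    st0 <- c(1e7, 4e7, 7e7)
    ev <- makeGR("chr1", st0, st0 + c(2e6, 2e6, 5e5) - 1, sample = s)
    seg <- makeGR("chr1", 1e7, 1e7 + 1.7e6 - 1, sample = s, log2_ratio = -0.5)
    cls <- classifyLOH(ev, "acgh", segments = seg)
    expect_equal(as.character(cls$label),
                 c("deletion_mediated", "copy_neutral", "copy_neutral"))
    expect_equal(cls$retained, c(FALSE, TRUE, FALSE))
})

test_that("boundary fixtures pin the strict/non-strict rule edges", {
    fx <- boundaryFixtures()
    cls <- classifyLOH(fx$events, "acgh", segments = fx$segments)
    expect_equal(as.character(cls$label[1]), fx$expect$ev1)          # 0.80 coverage
    expect_equal(cls$covered_fraction[1], 0.8, tolerance = 1e-12)
    expect_equal(as.character(cls$label[2]), fx$expect$ev2)          # log2 == -0.20
    expect_equal(cls$retained[2], fx$expect$ev2_retained)            # width == 1 Mb
    expect_equal(cls$retained[3], fx$expect$ev3_retained)
    mcls <- classifyLOH(fx$markerEvent, "snp", markers = fx$markers)
    expect_equal(mcls$n_markers, 10L)
    expect_equal(mcls$n_low, 8L)
    expect_equal(as.character(mcls$label), fx$expect$markerEvent)    # 0.8 >= 0.8
})

test_that("marker-rule labels agree with an independent per-event recount", {
    set.seed(2)
    n <- 100L
    st <- sort(sample.int(9e6, n)) * 10L
    ev <- makeGR("chr2", st, st + sample(2e4:2e5, n, TRUE), sample = "S1")
    pos <- sort(sample.int(1e8, 5000))
    mk <- makeGR("chr2", pos, pos, sample = "S1",
                 allelic_cn = sample(c(1.2, 1.5, 2.0, 2.05), 5000, TRUE))
    cls <- suppressWarnings(classifyLOH(ev, "snp", markers = mk))
    for (i in seq_len(n)) {
        inside <- pos >= start(ev)[i] & pos <= end(ev)[i]
        N <- sum(inside); nlow <- sum(inside & mk$allelic_cn < 1.9)
        expect_equal(cls$n_markers[i], N)
        want <- if (N == 0L) "unlabelled"
                else if (nlow / N >= 0.8) "deletion_mediated" else "copy_neutral"
        expect_equal(as.character(cls$label[i]), want)
    }
    # N = 10, n = 8 boundary and N = 10, n = 7 just below
    mkB <- makeGR("chr3", (1:10) * 100, (1:10) * 100, sample = "S1",
                  allelic_cn = c(rep(1, 8), 2, 2))
    evB <- makeGR("chr3", 50, 50 + 2e4, sample = "S1")
    expect_equal(as.character(classifyLOH(evB, "snp", markers = mkB)$label),
                 "deletion_mediated")
    mkB$allelic_cn[8] <- 2
    expect_equal(as.character(classifyLOH(evB, "snp", markers = mkB)$label),
                 "copy_neutral")
})

test_that("marker-rule edge handling: size filter, empty events, unsorted input", {
    mk <- makeGR("chr1", c(100, 200), c(100, 200), sample = "S1",
                 allelic_cn = c(1, 1))
    evSmall <- makeGR("chr1", 1, 1e4, sample = "S1")       # width == 10 kb: dropped
    cls <- classifyLOH(evSmall, "snp", markers = mk)
    expect_false(cls$size_pass)
    expect_equal(as.character(cls$label), "unlabelled")
    evEmpty <- makeGR("chr1", 5e6, 5e6 + 2e4, sample = "S1")
    expect_warning(cls2 <- classifyLOH(evEmpty, "snp", markers = mk), "N = 0")
    expect_equal(as.character(cls2$label), "unlabelled")
    mkU <- makeGR("chr1", c(200, 100), c(200, 100), sample = "S1",
                  allelic_cn = c(1, 1))
    expect_error(classifyLOH(evEmpty, "snp", markers = mkU), "sorted")
})

test_that("every event lands in exactly one class and thresholds act monotonically", {
    sim <- simulateCohort(nWT = 4, nDel = c("miR-193b*" = 2), seed = 6,
                          layers = c("loh", "cn"))
    cls <- classifyLOH(sim$cohort, "acgh")
    lab <- as.character(cls$label)
    expect_true(all(lab %in% c("deletion_mediated", "copy_neutral")))
    expect_equal(sum(lab == "deletion_mediated") + sum(lab == "copy_neutral"),
                 length(cls))
    # raising the deletion threshold toward 0 can only add deletion calls
    clsLoose <- classifyLOH(sim$cohort, "acgh",
                            params = analysisParams(delLog2Threshold = -0.05))
    wasDel <- lab == "deletion_mediated"
    isDel <- as.character(clsLoose$label) == "deletion_mediated"
    expect_true(all(isDel[wasDel]))
})

test_that("per-sample cnLOH counts include zero-count samples and match truth", {
    cls <- classifyLOH(makeGR("chr1", 1, 2, sample = "S1")[0], "acgh",
                       segments = GenomicRanges::GRanges())
    expect_equal(cnlohCountPerSample(cls, c("A", "B")), c(A = 0L, B = 0L))
    sim <- simulateCohort(nWT = 5, nDel = c("miR-148b*" = 2), seed = 3,
                          layers = c("loh", "cn"))
    cls <- classifyLOH(sim$cohort, "acgh")
    cnt <- cnlohCountPerSample(cls, sampleIDs(sim$cohort))
    expect_equal(cnt, sim$truth$cnlohCount[names(cnt)])
})

test_that("SCNA events merge same-sign neighbours within a chromosome", {
    seg <- makeGR("chr1", c(1, 101, 201, 301), c(100, 200, 300, 400),
                  sample = "S1",
                  log2_ratio = c(-0.5, -0.4, 0.5, 0.0))
    expect_equal(unname(scnaCountPerSample(seg)), 2L)   # del-run + amp
    segN <- seg; segN$log2_ratio <- c(0, 0.1, -0.1, 0.2)
    expect_equal(unname(scnaCountPerSample(segN)), 0L)
    seg1 <- makeGR("chr1", 1, 100, sample = "S1", log2_ratio = 0.6)
    expect_equal(unname(scnaCountPerSample(seg1)), 1L)
    # random segmentations agree with an independent walk
    set.seed(8)
    for (i in 1:20) {
        k <- sample(3:30, 1)
        st <- cumsum(sample.int(100, k))
        df <- data.frame(sample = sample(c("S1", "S2"), k, TRUE),
                         chrom = sample(c("chr1", "chr2"), k, TRUE),
                         start = st, end = st + 50,
                         log2 = round(runif(k, -0.6, 0.6), 2))
        gr <- makeGR(df$chrom, df$start, df$end, sample = df$sample,
                     log2_ratio = df$log2)
        expect_equal(sum(scnaCountPerSample(gr)), bruteScnaCount(df))
    }
})
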