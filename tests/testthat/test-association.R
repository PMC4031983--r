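test_that("the one-tailed U test reproduces the exact textbook case", {
    res <- mannWhitneyOneTailed(c(4, 5, 6), c(1, 2, 3))
    expect_equal(res$U, 9)
    expect_equal(res$p, 0.05)         # 1 of C(6,3) = 20 assignments
    expect_equal(res$method, "exact")
    same <- mannWhitneyOneTailed(c(1, 2, 3), c(1, 2, 3))
    expect_gte(same$p, 0.5)
    expect_error(mannWhitneyOneTailed(numeric(), 1:3), "non-empty")
    expect_warning(mannWhitneyOneTailed(c(2, 2), c(2, 2, 2)), "identical")
})

test_that("U keeps the complement identity and direction reversal is consistent", {
    set.seed(31)
    for (i in 1:30) {
        a <- sample.int(10, sample(2:8, 1), replace = TRUE)
        b <- sample.int(10, sample(2:8, 1), replace = TRUE)
        f <- mannWhitneyOneTailed(a, b, "a_greater")
        r <- mannWhitneyOneTailed(a, b, "b_greater")
        expect_equal(f$U, bruteU(a, b))
        expect_equal(f$U + bruteU(b, a), length(a) * length(b))
        expect_equal(r$U, f$U)
    }
})

test_that("small-sample p-values match full permutation enumeration, ties included", {
    set.seed(17)
    for (i in 1:40) {
        na <- sample(2:6, 1); nb <- sample(2:6, 1)
        vals <- if (i %% 2) sample.int(4, na + nb, replace = TRUE)  # heavy ties
                else sample.int(1000, na + nb)
        if (length(unique(vals)) == 1L) vals[1L] <- vals[1L] + 1L
        a <- vals[seq_len(na)]; b <- vals[-seq_len(na)]
        got <- mannWhitneyOneTailed(a, b)$p
        expect_equal(got, brutePermPvalue(a, b), tolerance = 1e-12)
    }
})

test_that("untied exact p agrees with wilcox.test", {
    set.seed(23)
    for (i in 1:20) {
        a <- runif(sample(3:12, 1)); b <- runif(sample(3:12, 1))
        got <- mannWhitneyOneTailed(a, b)
        ref <- wilcox.test(a, b, alternative = "greater", exact = TRUE)
        expect_equal(got$U, unname(ref$statistic))
        expect_equal(got$p, ref$p.value, tolerance = 1e-12)
    }
})

test_that("the large-sample approximation tracks the tie-corrected normal reference", {
    set.seed(27)
    a <- sample.int(30, 60, replace = TRUE)
    b <- sample.int(30, 45, replace = TRUE)
    got <- mannWhitneyOneTailed(a, b)
    ref <- suppressWarnings(wilcox.test(a, b, alternative = "greater",
                                        exact = FALSE, correct = TRUE))
    expect_equal(got$method, "normal")
    expect_equal(got$p, ref$p.value, tolerance = 1e-10)
})

test_that("group comparison reports medians, flags significance, and survives empty groups", {
    metric <- setNames(c(1, 2, 3, 4, 10, 11, 12), sprintf("S%d", 1:7))
    groups <- list(WT = sprintf("S%d", 1:4), `del-miR-148b*` = sprintf("S%d", 5:7),
                   `del-miR-193b*` = character())
    out <- compareGroups(metric, groups, "cnLOH_count")
    r1 <- out[out$group == "del-miR-148b*", ]
    expect_equal(r1$n_wt, 4L); expect_equal(r1$n_del, 3L)
    expect_equal(r1$median_wt, 2.5); expect_equal(r1$median_del, 11)
    expect_equal(r1$U, 12)            # complete separation
    expect_true(r1$significant)       # p = 1/35 < 0.05
    r2 <- out[out$group == "del-miR-193b*", ]
    expect_false(r2$testable)
    expect_true(is.na(r2$p_one_tailed))
    # identical distributions: not significant
    null <- compareGroups(setNames(rep(1:4, 2), sprintf("S%d", 1:8)),
                          list(WT = sprintf("S%d", 1:4),
                               `del-miR-148b*` = sprintf("S%d", 5:8)))
    expect_false(null$significant)
})

test_that("a planted cohort effect reaches significance and matches the oracle", {
    sim <- simulateCohort(nWT = 40, nDel = c("miR-148b*" = 10), seed = 4,
                          layers = c("loh", "cn"))
    res <- runPipeline(sim$cohort, method = "acgh", verbose = FALSE)
    p <- res$association$p_one_tailed[res$association$metric == "cnLOH_count" &
                                      res$association$group == "del-miR-148b*"]
    expect_lt(p, 0.05)
    # single-instance cross-check against a Monte-Carlo permutation p
    cnt <- res$cnlohCount
    grp <- sampleGroups(res$genotypes)
    a <- cnt[grp$`del-miR-148b*`]; b <- cnt[grp$WT]
    uObs <- bruteU(a, b)
    set.seed(99)
    pooled <- c(a, b)
    perm <- replicate(4000, {
        idx <- sample.int(length(pooled), length(a))
        bruteU(pooled[idx], pooled[-idx])
    })
    pMC <- mean(perm >= uObs - 1e-9)
    expect_lt(abs(p - pMC), 0.02)
})
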