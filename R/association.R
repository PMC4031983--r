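#' One-tailed Mann-Whitney U test
#'
#' Rank-sum test of whether values in `a` tend to be larger than values in
#' `b`. `U` is computed from midranks, so ties are handled; `U` counts the
#' pairs `(i, j)` with `a_i > b_j` plus half the tied pairs. The p-value is
#' `P(U >= u_obs)` under the null, computed by: the exact distribution when
#' there are no ties and `n_a * n_b <= 400`; full enumeration of all group
#' assignments when there are ties and `n_a + n_b <= 12`; and otherwise a
#' normal approximation with continuity and tie correction.
#'
#' @param a,b Numeric vectors (non-empty).
#' @param alternative `"a_greater"` (the planted direction of every cohort
#'   comparison) or `"b_greater"`.
#' @return A list with `U` (for the `a`-greater orientation), `p`, `n_a`,
#'   `n_b` and `method` (`"exact"`, `"enumeration"` or `"normal"`). When
#'   every value in both groups is identical the test is uninformative and
#'   `p = 0.5` is returned with a warning.
#' @examples
#' mannWhitneyOneTailed(c(4, 5, 6), c(1, 2, 3))  # U = 9, p = 0.05
#' @export
mannWhitneyOneTailed <- function(a, b, alternative = c("a_greater", "b_greater")) {
    alternative <- match.arg(alternative)
    if (!length(a) || !length(b))
        stop("both groups must be non-empty", call. = FALSE)
    if (anyNA(a) || anyNA(b))
        stop("missing values not allowed", call. = FALSE)
    if (alternative == "b_greater") {
        res <- mannWhitneyOneTailed(b, a, "a_greater")
        res$U <- length(a) * length(b) - res$U
        res$n_a <- length(a); res$n_b <- length(b)
        return(res)
    }
    na <- length(a); nb <- length(b); N <- na + nb
    pooled <- c(a, b)
    if (length(unique(pooled)) == 1L) {
        warning("all values identical across both groups; p = 0.5", call. = FALSE)
        return(list(U = na * nb / 2, p = 0.5, n_a = na, n_b = nb,
                    method = "degenerate"))
    }
    r <- rank(pooled)
    U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
    ties <- anyDuplicated(pooled) > 0L
    if (!ties && na * nb <= 400) {
        # U is an integer without ties; exact null distribution
        p <- stats::pwilcox(U - 1, na, nb, lower.tail = FALSE)
        return(list(U = U, p = p, n_a = na, n_b = nb, method = "exact"))
    }
    if (ties && N <= 12) {
        idx <- utils::combn(N, na)
        eps <- 1e-9
        Us <- apply(idx, 2L, function(i) sum(r[i])) - na * (na + 1) / 2
        p <- mean(Us >= U - eps)
        return(list(U = U, p = p, n_a = na, n_b = nb, method = "enumeration"))
    }
    mu <- na * nb / 2
    tj <- table(pooled)
    tieTerm <- sum(tj^3 - tj) / (N * (N - 1))
    sigma <- sqrt(na * nb / 12 * ((N + 1) - tieTerm))
    z <- (U - mu - 0.5) / sigma
    list(U = U, p = stats::pnorm(z, lower.tail = FALSE),
         n_a = na, n_b = nb, method = "normal")
}

#' Compare deletion groups against WT
#'
#' Runs the one-tailed Mann-Whitney test (deletion greater than WT, the
#' planted direction: loss of the miRNA is expected to increase LOH
#' burden, copy-number aberration burden and target-gene expression) for
#' one per-sample metric and every deletion group.
#'
#' @param metric Named numeric vector, one value per sample.
#' @param groups Named list of sample vectors from [sampleGroups()]
#'   (must contain `WT`).
#' @param metricName Label stored in the result.
#' @param params An \linkS4class{AnalysisParams} (significance level).
#' @param bonferroni Apply a Bonferroni correction across the deletion
#'   groups (off by default; no correction is applied in the reference
#'   analysis).
#' @return A `DataFrame` with one row per deletion group: `metric`,
#'   `group`, `n_wt`, `n_del`, `median_wt`, `median_del`, `U`,
#'   `p_one_tailed`, `significant`, `testable`.
#' @export
compareGroups <- function(metric, groups, metricName = "metric",
                          params = analysisParams(), bonferroni = FALSE) {
    stopifnot("WT" %in% names(groups))
    wt <- metric[names(metric) %in% groups$WT]
    delGroups <- setdiff(names(groups), "WT")
    rows <- lapply(delGroups, function(g) {
        dl <- metric[names(metric) %in% groups[[g]]]
        if (!length(dl) || !length(wt))
            return(DataFrame(metric = metricName, group = g,
                             n_wt = length(wt), n_del = length(dl),
                             median_wt = if (length(wt)) median(wt) else NA_real_,
                             median_del = if (length(dl)) median(dl) else NA_real_,
                             U = NA_real_, p_one_tailed = NA_real_,
                             significant = NA, testable = FALSE))
        tst <- mannWhitneyOneTailed(dl, wt, "a_greater")
        DataFrame(metric = metricName, group = g,
                  n_wt = length(wt), n_del = length(dl),
                  median_wt = median(wt), median_del = median(dl),
                  U = tst$U, p_one_tailed = tst$p,
                  significant = tst$p < params@alpha, testable = TRUE)
    })
    out <- do.call(rbind, rows)
    if (bonferroni) {
        out$p_one_tailed <- pmin(1, out$p_one_tailed * length(delGroups))
        out$significant <- ifelse(out$testable,
                                  out$p_one_tailed < params@alpha, NA)
    }
    out
}

#' Full cohort association table
#'
#' Builds the three per-sample metrics (retained copy-neutral LOH count,
#' somatic copy-number event count, and expression of each gene in the
#' expression layer) and compares every deletion group against WT for each.
#'
#' @param x A \linkS4class{TumorCohort}.
#' @param classified Output of [classifyLOH()].
#' @param genotypes Output of [genotypeCohort()].
#' @param params An \linkS4class{AnalysisParams}.
#' @return A `DataFrame` of [compareGroups()] rows stacked over metrics.
#' @export
associateCohort <- function(x, classified, genotypes,
                            params = analysisParams()) {
    samples <- sampleIDs(x)
    groups <- sampleGroups(genotypes)
    tabs <- list(compareGroups(cnlohCountPerSample(classified, samples),
                               groups, "cnLOH_count", params))
    if (length(cnSegments(x)))
        tabs <- c(tabs, list(compareGroups(
            scnaCountPerSample(cnSegments(x), params, samples),
            groups, "scna_count", params)))
    ex <- exprTable(x)
    if (nrow(ex))
        for (g in unique(ex$gene)) {
            v <- setNames(as.numeric(ex$value[ex$gene == g]),
                          as.character(ex$sample[ex$gene == g]))
            tabs <- c(tabs, list(compareGroups(
                v, groups, paste0("expression:", g), params)))
        }
    do.call(rbind, tabs)
}
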