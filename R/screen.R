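#' Negative-control plate statistics
#'
#' Luminescence on a screen plate is normalised against the negative-control
#' mimic wells of that plate and treatment arm: `mu` is their arithmetic
#' mean and `sigma` their sample (n-1) standard deviation. Z-scores and
#' percent-control viability are both defined relative to these.
#'
#' @param x A \linkS4class{ScreenExperiment}.
#' @return A `DataFrame` with one row per (`plate_id`, `replicate`,
#'   `treatment`) normalisation unit and columns `mu`, `sigma`, `n`.
#'   Units with fewer than 2 negative-control wells, or with zero spread
#'   (Z undefined), are an error.
#' @examples
#' scr <- simulateScreen(nMimics = 40, seed = 1)
#' negControlStats(scr)
#' @export
negControlStats <- function(x) {
    w <- wells(x)
    nc <- w[w$role == "neg_control", , drop = FALSE]
    if (!nrow(nc))
        stop("no negative-control wells", call. = FALSE)
    key <- paste(nc$plate_id, nc$replicate, nc$treatment, sep = "\r")
    sp <- split(nc$luminescence, key)
    n <- vapply(sp, length, 0L)
    if (any(n < 2L))
        stop("fewer than 2 negative-control wells on plate/arm: ",
             gsub("\r", "/", names(sp)[which(n < 2L)[1L]]), call. = FALSE)
    mu <- vapply(sp, mean, 0)
    sigma <- vapply(sp, stats::sd, 0)
    if (any(sigma == 0))
        stop("negative-control standard deviation is zero (Z undefined) on plate/arm: ",
             gsub("\r", "/", names(sp)[which(sigma == 0)[1L]]), call. = FALSE)
    parts <- do.call(rbind, strsplit(names(sp), "\r", fixed = TRUE))
    DataFrame(plate_id = parts[, 1L], replicate = parts[, 2L],
              treatment = parts[, 3L], mu = unname(mu),
              sigma = unname(sigma), n = unname(n))
}

#' Percent-control viability
#'
#' Viability of a well as a percentage of the negative-control mean of its
#' plate and arm: `100 * x / mu`.
#'
#' @param x Luminescence value(s).
#' @param mu Negative-control mean (recycled against `x`).
#' @return Numeric percent value(s).
#' @export
percentControlViability <- function(x, mu) {
    if (any(mu == 0))
        stop("negative-control mean is zero", call. = FALSE)
    100 * x / mu
}

#' Plate Z-score
#'
#' `z = (x - mu) / sigma` with `mu`/`sigma` the negative-control mean and
#' sample standard deviation of the well's plate and treatment arm.
#'
#' @param x Luminescence value(s).
#' @param mu,sigma Negative-control statistics (recycled against `x`).
#' @return Numeric Z value(s).
#' @export
zScore <- function(x, mu, sigma) {
    if (any(sigma <= 0))
        stop("sigma must be > 0", call. = FALSE)
    (x - mu) / sigma
}

#' Fold enrichment of a pulled-down target
#'
#' Enrichment of a transcript in a biotinylated-miRNA pull-down over a
#' control pull-down, normalised to input abundances:
#' `(pdMirna / pdControl) / (inputMirna / inputControl)`.
#'
#' @param pdMirna,pdControl Pull-down abundances (miRNA vs control pull-down).
#' @param inputMirna,inputControl Input abundances.
#' @return Unitless fold enrichment.
#' @examples
#' foldEnrichment(8, 2, 2, 2)  # 4-fold
#' @export
foldEnrichment <- function(pdMirna, pdControl, inputMirna, inputControl) {
    v <- c(pdMirna, pdControl, inputMirna, inputControl)
    if (any(!is.finite(v)) || any(v <= 0))
        stop("all four abundances must be finite and > 0", call. = FALSE)
    (pdMirna / pdControl) / (inputMirna / inputControl)
}

# per-well normalised table: pct viability and z against the well's own
# (plate, replicate, arm) negative-control stats
.normalizeWells <- function(x) {
    w <- as.data.frame(wells(x))
    st <- as.data.frame(negControlStats(x))
    key <- paste(w$plate_id, w$replicate, w$treatment, sep = "\r")
    skey <- paste(st$plate_id, st$replicate, st$treatment, sep = "\r")
    idx <- match(key, skey)
    if (anyNA(idx))
        stop("no negative-control statistics for plate/arm: ",
             gsub("\r", "/", key[which(is.na(idx))[1L]]), call. = FALSE)
    w$pct <- percentControlViability(w$luminescence, st$mu[idx])
    w$z <- zScore(w$luminescence, st$mu[idx], st$sigma[idx])
    w
}

#' Per-mimic screen results
#'
#' Normalises every well against its plate/arm negative controls, averages
#' replicate measurements per mimic within each arm, applies the toxicity
#' rule (a mimic is toxic when its vehicle-arm percent viability is less
#' than or equal to that of the BRCA2-siRNA positive control of its plate;
#' such mimics kill cells without the drug and are not considered), and
#' flags sensitizer hits: non-toxic, drug-arm Z below the Z cutoff and
#' drug-arm percent viability below the viability cutoff. Hits are ranked
#' by ascending drug-arm percent viability (ties: ascending Z, then mimic
#' identifier).
#'
#' @param x A \linkS4class{ScreenExperiment}.
#' @param params An \linkS4class{AnalysisParams}.
#' @param zMode `"constant"` uses `zCutoff(params)` (default); `"brca2"`
#'   instead uses the per-plate mean drug-arm Z of the BRCA2-siRNA wells as
#'   the cutoff.
#' @param replicates `"average"` (default) averages replicate wells per
#'   mimic before thresholding; `"raw"` keeps one row per replicate and
#'   leaves `hit`/`rank` unset.
#' @return A `DataFrame` with one row per mimic: `mimic`, `plate_id`,
#'   `pct_viability_drug`, `pct_viability_vehicle`, `z`, `toxic`, `hit`,
#'   `rank` (NA for non-hits).
#' @seealso [callHits()]
#' @export
screenResults <- function(x, params = analysisParams(),
                          zMode = c("constant", "brca2"),
                          replicates = c("average", "raw")) {
    zMode <- match.arg(zMode)
    replicates <- match.arg(replicates)
    w <- .normalizeWells(x)
    mim <- w[w$role == "mimic", , drop = FALSE]
    if (!nrow(mim))
        stop("no mimic wells", call. = FALSE)
    if (!any(mim$treatment == "vehicle"))
        stop("vehicle arm missing: toxicity filter undefined", call. = FALSE)
    if (replicates == "raw") {
        out <- DataFrame(mimic = mim$content_id, plate_id = mim$plate_id,
                         replicate = mim$replicate, treatment = mim$treatment,
                         pct_viability = mim$pct, z = mim$z)
        return(out[order(out$mimic, out$replicate, out$treatment), ])
    }
    aggBy <- function(df, val) {
        k <- paste(df$content_id, df$plate_id, sep = "\r")
        vapply(split(df[[val]], k), mean, 0)
    }
    dr <- mim[mim$treatment == "drug", , drop = FALSE]
    ve <- mim[mim$treatment == "vehicle", , drop = FALSE]
    pctD <- aggBy(dr, "pct"); zD <- aggBy(dr, "z"); pctV <- aggBy(ve, "pct")
    ids <- sort(unique(c(names(pctD), names(pctV))))
    parts <- do.call(rbind, strsplit(ids, "\r", fixed = TRUE))
    res <- DataFrame(mimic = parts[, 1L], plate_id = parts[, 2L],
                     pct_viability_drug = unname(pctD[ids]),
                     pct_viability_vehicle = unname(pctV[ids]),
                     z = unname(zD[ids]))
    if (anyNA(res$pct_viability_vehicle) || anyNA(res$pct_viability_drug))
        stop("mimic measured in only one treatment arm: ",
             res$mimic[which(is.na(res$pct_viability_vehicle) |
                             is.na(res$pct_viability_drug))[1L]], call. = FALSE)
    brca <- w[w$role == "pos_control_brca2" & w$treatment == "vehicle", , drop = FALSE]
    if (!nrow(brca))
        stop("no BRCA2-siRNA vehicle wells: toxicity comparator undefined", call. = FALSE)
    brcaPct <- vapply(split(brca$pct, brca$plate_id), mean, 0)
    if (anyNA(match(res$plate_id, names(brcaPct))))
        stop("plate without BRCA2-siRNA vehicle wells", call. = FALSE)
    res$toxic <- res$pct_viability_vehicle <= brcaPct[res$plate_id]
    zcut <- rep(params@zCutoff, nrow(res))
    if (zMode == "brca2") {
        bd <- w[w$role == "pos_control_brca2" & w$treatment == "drug", , drop = FALSE]
        if (!nrow(bd))
            stop("no BRCA2-siRNA drug wells for zMode = 'brca2'", call. = FALSE)
        bz <- vapply(split(bd$z, bd$plate_id), mean, 0)
        zcut <- unname(bz[res$plate_id])
    }
    res$hit <- !res$toxic & res$z < zcut &
        res$pct_viability_drug < params@viabilityCutoffPct
    res$rank <- NA_integer_
    if (any(res$hit)) {
        h <- which(res$hit)
        o <- order(res$pct_viability_drug[h], res$z[h], res$mimic[h])
        res$rank[h[o]] <- seq_along(h)
    }
    res[order(!res$hit, ifelse(is.na(res$rank), Inf, res$rank), res$mimic), ]
}

#' Ranked hit list
#'
#' Subsets a [screenResults()] table to the called hits, in rank order.
#'
#' @param results A `DataFrame` from [screenResults()], or a
#'   \linkS4class{ScreenExperiment} (then results are computed first).
#' @param params,zMode Passed to [screenResults()] when `results` is a
#'   \linkS4class{ScreenExperiment}.
#' @return The hit rows, ordered by `rank`.
#' @export
callHits <- function(results, params = analysisParams(),
                     zMode = c("constant", "brca2")) {
    if (is(results, "ScreenExperiment"))
        results <- screenResults(results, params, zMode = match.arg(zMode))
    h <- results[!is.na(results$rank) & results$hit, , drop = FALSE]
    h[order(h$rank), , drop = FALSE]
}
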