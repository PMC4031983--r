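#' @importFrom stats setNames
NULL

.statusLevels <- c("deletion", "neutral", "amplification", "unknown")

.bandStatus <- function(value, lo, hi) {
    ifelse(is.na(value), "unknown",
    ifelse(value < lo, "deletion",
    ifelse(value <= hi, "neutral", "amplification")))
}

#' Locus copy-number status from an aCGH segmentation
#'
#' The representative log2 ratio of a locus is the value of the segment
#' overlapping the locus midpoint (loci are tens of bases, so they almost
#' always sit inside one segment; should several segments overlap the
#' midpoint, the narrowest is taken, ties to the lowest start). Status is
#' deletion below the neutral band, neutral inside the closed band,
#' amplification above it, and unknown when no segment overlaps.
#'
#' @param segments `GRanges` copy-number segments of one sample (or with a
#'   `sample` mcol, in which case one status per sample is returned).
#' @param locus A length-1 `GRanges` locus interval.
#' @param params An \linkS4class{AnalysisParams}.
#' @param samples Samples to report when `segments` carries a sample column.
#' @return Character status (named by sample when per-sample).
#' @export
locusStatusAcgh <- function(segments, locus, params = analysisParams(),
                            samples = NULL) {
    stopifnot(length(locus) == 1L)
    mid <- GRanges(seqnames(locus),
                   IRanges(floor((start(locus) + end(locus)) / 2), width = 1L))
    hit <- segments[IRanges::overlapsAny(segments, mid)]
    sampleCol <- mcols(segments)$sample
    if (is.null(sampleCol)) {
        if (!length(hit)) return("unknown")
        pick <- order(GenomicRanges::width(hit), start(hit))[1L]
        return(.bandStatus(mcols(hit)$log2_ratio[pick],
                           params@neutralBand[1L], params@neutralBand[2L]))
    }
    if (is.null(samples)) samples <- unique(sampleCol)
    out <- setNames(rep("unknown", length(samples)), samples)
    if (length(hit)) {
        o <- order(GenomicRanges::width(hit), start(hit))
        hit <- hit[o]
        first <- !duplicated(mcols(hit)$sample)
        v <- mcols(hit)$log2_ratio[first]
        s <- mcols(hit)$sample[first]
        keep <- s %in% samples
        out[s[keep]] <- .bandStatus(v[keep], params@neutralBand[1L],
                                    params@neutralBand[2L])
    }
    out
}

#' Locus copy-number status from SNP markers
#'
#' Status is inferred from the marker nearest to the locus on the locus
#' chromosome (distance 0 when inside; equidistant ties break to the
#' lower genomic position): deletion when its allelic copy number is
#' strictly below the lower edge of the neutral copy-number band, neutral
#' inside the closed band, amplification above it, unknown when the
#' chromosome carries no marker.
#'
#' @param markers Width-1 `GRanges` markers with mcols `allelic_cn` (and
#'   optionally `sample` for per-sample calls).
#' @param locus A length-1 `GRanges` locus interval.
#' @param params An \linkS4class{AnalysisParams}.
#' @param samples Samples to report when `markers` carries a sample column.
#' @return Character status (named by sample when per-sample).
#' @export
locusStatusSnp <- function(markers, locus, params = analysisParams(),
                           samples = NULL) {
    stopifnot(length(locus) == 1L)
    onChr <- markers[as.character(seqnames(markers)) ==
                     as.character(seqnames(locus))]
    sampleCol <- mcols(onChr)$sample
    band <- params@neutralCnBand
    pickStatus <- function(gr) {
        if (!length(gr)) return("unknown")
        d <- pmax(start(locus) - start(gr), start(gr) - end(locus), 0L)
        pick <- order(d, start(gr))[1L]
        .bandStatus(mcols(gr)$allelic_cn[pick], band[1L], band[2L])
    }
    if (is.null(sampleCol))
        return(pickStatus(onChr))
    if (is.null(samples)) samples <- unique(mcols(markers)$sample)
    out <- setNames(rep("unknown", length(samples)), samples)
    if (length(onChr)) {
        d <- pmax(start(locus) - start(onChr), start(onChr) - end(locus), 0L)
        o <- order(d, start(onChr))
        onChr <- onChr[o]
        first <- !duplicated(mcols(onChr)$sample)
        s <- mcols(onChr)$sample[first]
        v <- mcols(onChr)$allelic_cn[first]
        keep <- s %in% samples
        out[s[keep]] <- .bandStatus(v[keep], band[1L], band[2L])
    }
    out
}

#' Combine the two miR-1255b locus statuses
#'
#' Mature miR-1255b is encoded at two genomic loci; a sample counts as
#' deleted when either locus is deleted. Otherwise the combined status is
#' amplification when either locus is amplified, neutral when both are
#' neutral, and unknown in every remaining case (unknowns propagate
#' conservatively).
#'
#' @param status1,status2 Character statuses (vectorised).
#' @return Character combined status.
#' @examples
#' combineMir1255b("deletion", "neutral")   # deletion
#' combineMir1255b("unknown", "neutral")    # unknown
#' @export
combineMir1255b <- function(status1, status2) {
    stopifnot(length(status1) == length(status2),
              all(c(status1, status2) %in% .statusLevels))
    ifelse(status1 == "deletion" | status2 == "deletion", "deletion",
    ifelse(status1 == "amplification" | status2 == "amplification", "amplification",
    ifelse(status1 == "neutral" & status2 == "neutral", "neutral", "unknown")))
}

#' Genotype miRNA loci across a cohort
#'
#' Calls per-interval locus status for every sample and miRNA (segment or
#' marker rule), combines multi-locus miRNAs (see [combineMir1255b()]), and
#' assigns cohort groups with [assignGroups()].
#'
#' @param x A \linkS4class{TumorCohort}.
#' @param loci Named `GRangesList` from [mirnaLoci()].
#' @param method `"acgh"` or `"snp"`.
#' @param params An \linkS4class{AnalysisParams}.
#' @return A `DataFrame`: `sample`, one combined-status column per miRNA
#'   (`status.<miRNA>`), `group` (comma-joined memberships) and `is_wt`.
#' @export
genotypeCohort <- function(x, loci = syntheticMirnaLoci(),
                           method = c("acgh", "snp"),
                           params = analysisParams()) {
    method <- match.arg(method)
    samples <- sampleIDs(x)
    statusFun <- if (method == "acgh") {
        layer <- cnSegments(x)
        function(locus) locusStatusAcgh(layer, locus, params, samples)
    } else {
        layer <- snpMarkers(x)
        function(locus) locusStatusSnp(layer, locus, params, samples)
    }
    comb <- sapply(names(loci), function(mir) {
        iv <- loci[[mir]]
        st <- vapply(seq_along(iv), function(i) statusFun(iv[i]),
                     setNames(character(length(samples)), samples))
        st <- matrix(st, nrow = length(samples),
                     dimnames = list(samples, NULL))
        if (ncol(st) == 1L) st[, 1L] else combineMir1255b(st[, 1L], st[, 2L])
    })
    comb <- matrix(comb, nrow = length(samples),
                   dimnames = list(samples, names(loci)))
    assignGroups(DataFrame(sample = samples,
                           status = I(comb), check.names = FALSE))
}

#' Assign WT / deletion-group membership
#'
#' A sample is WT when its combined status is neutral at all miRNAs
#' (no amplification, deletion or unknown anywhere). It enters the
#' deletion group of each miRNA whose combined status is deletion (the
#' deletion groups are not mutually exclusive). Samples that are neither
#' WT nor deleted anywhere (amplification-only, or any unknown without a
#' deletion) are excluded.
#'
#' @param genotypes A `DataFrame` with `sample` and a `status` matrix
#'   column (samples x miRNAs), as built by [genotypeCohort()].
#' @return The input with `group` (comma-joined `del-<miRNA>` memberships,
#'   `"WT"`, or `"excluded"`) and `is_wt` columns added.
#' @export
assignGroups <- function(genotypes) {
    st <- genotypes$status
    isWt <- apply(st == "neutral", 1L, all)
    delAt <- st == "deletion"
    grp <- vapply(seq_len(nrow(st)), function(i) {
        if (isWt[i]) return("WT")
        d <- colnames(st)[delAt[i, ]]
        if (length(d)) paste(paste0("del-", d), collapse = ",") else "excluded"
    }, "")
    genotypes$group <- grp
    genotypes$is_wt <- isWt
    genotypes
}

#' Samples per comparison group
#'
#' @param genotypes Output of [genotypeCohort()].
#' @return Named list of sample identifier vectors: `WT` plus one
#'   `del-<miRNA>` element per miRNA with at least the groups present.
#' @export
sampleGroups <- function(genotypes) {
    mirs <- colnames(genotypes$status)
    out <- list(WT = genotypes$sample[genotypes$is_wt])
    for (m in mirs)
        out[[paste0("del-", m)]] <-
            genotypes$sample[genotypes$status[, m] == "deletion"]
    out
}
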