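#' @importFrom GenomicRanges findOverlaps pintersect reduce
#' @importFrom S4Vectors queryHits subjectHits mcols mcols<-
NULL

# remap seqnames of two layers to sample\rchrom on a shared level set, so
# that ranges of different samples can never overlap and one findOverlaps
# serves the whole cohort
.pairBySample <- function(gr1, gr2) {
    k1 <- paste(mcols(gr1)$sample, as.character(seqnames(gr1)), sep = "\r")
    k2 <- paste(mcols(gr2)$sample, as.character(seqnames(gr2)), sep = "\r")
    lev <- unique(c(k1, k2))
    list(GRanges(factor(k1, levels = lev), IRanges(start(gr1), end(gr1))),
         GRanges(factor(k2, levels = lev), IRanges(start(gr2), end(gr2))))
}

#' Fraction of an LOH event covered by deletion segments
#'
#' Computes, per event, the fraction of its bases lying under the union of
#' the supplied segments (overlapping segments are not double-counted).
#' When both inputs carry a `sample` metadata column, coverage is computed
#' within sample; otherwise both inputs must be single-sample, and mixing
#' samples on one side only is an error.
#'
#' @param events `GRanges` of LOH events.
#' @param segments `GRanges` of (deletion) segments.
#' @return Numeric vector in `[0, 1]`, parallel to `events`.
#' @examples
#' ev <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1000))
#' seg <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 401), c(500, 900)))
#' coveredFraction(ev, seg)  # union covers 900/1000
#' @export
coveredFraction <- function(events, segments) {
    if (!length(events)) return(numeric())
    if (!length(segments))
        return(numeric(length(events)))
    evS <- mcols(events)$sample
    segS <- mcols(segments)$sample
    if (is.null(evS) != is.null(segS))
        stop("cross-sample mixing: both or neither of events/segments must carry a sample column",
             call. = FALSE)
    if (is.null(evS)) {
        ev <- granges(events)
        seg <- granges(segments)
    } else {
        pr <- .pairBySample(events, segments)
        ev <- pr[[1L]]
        seg <- pr[[2L]]
    }
    out <- numeric(length(ev))
    if (length(seg)) {
        segU <- reduce(seg)
        ov <- findOverlaps(ev, segU)
        if (length(ov)) {
            w <- GenomicRanges::width(pintersect(ev[queryHits(ov)], segU[subjectHits(ov)]))
            cov <- tapply(w, queryHits(ov), sum)
            out[as.integer(names(cov))] <- as.numeric(cov)
        }
    }
    out / GenomicRanges::width(ev)
}

.lohLabels <- c("unlabelled", "deletion_mediated", "copy_neutral")

#' Classify LOH events as deletion-mediated or copy-neutral
#'
#' Two rules are implemented. The segment (aCGH) rule: deletion segments
#' are copy-number segments with log2 ratio strictly below the deletion
#' threshold; an event is deletion-mediated when they cover at least the
#' coverage cutoff of its length (union across segments), the remaining
#' events are copy-neutral, and a copy-neutral event is retained when
#' strictly longer than the copy-neutral minimum size. The marker (SNP)
#' rule: events at or below the marker-rule size are dropped before
#' counting; for each remaining event, `N` is the number of markers inside
#' it and `n` the number of those with allelic copy number strictly below
#' the copy-number threshold; the event is deletion-mediated when
#' `n/N >= cutoff` (non-strict) and copy-neutral otherwise; events with
#' `N = 0` stay unlabelled and are excluded with a warning.
#'
#' @param x A \linkS4class{TumorCohort}, or a `GRanges` of LOH events (with
#'   a `sample` mcol) if `segments`/`markers` are passed directly.
#' @param method `"acgh"` (segment rule) or `"snp"` (marker rule).
#' @param params An \linkS4class{AnalysisParams}.
#' @param segments,markers Optional explicit layers overriding the cohort's.
#' @return The events `GRanges` with added mcols: `label` (one of
#'   `unlabelled`, `deletion_mediated`, `copy_neutral`), `retained`
#'   (logical), `size_pass` (logical) and the rule's evidence
#'   (`covered_fraction`, or `n_markers`/`n_low`/`frac_low`).
#' @seealso [coveredFraction()], [cnlohCountPerSample()]
#' @examples
#' sim <- simulateCohort(nWT = 4, nDel = c("miR-148b*" = 2), seed = 1,
#'                       layers = c("loh", "cn"))
#' cls <- classifyLOH(sim$cohort, method = "acgh")
#' table(cls$label, cls$retained)
#' @export
classifyLOH <- function(x, method = c("acgh", "snp"),
                        params = analysisParams(),
                        segments = NULL, markers = NULL) {
    method <- match.arg(method)
    if (is(x, "TumorCohort")) {
        events <- lohEvents(x)
        if (is.null(segments)) segments <- cnSegments(x)
        if (is.null(markers)) markers <- snpMarkers(x)
    } else events <- x
    out <- granges(events)
    mcols(out) <- mcols(events)
    if (method == "acgh") {
        if (length(events) && (is.null(segments) || !length(segments)))
            stop("segment rule needs copy-number segments", call. = FALSE)
        if (is.null(segments)) segments <- GRanges()
        dels <- segments[mcols(segments)$log2_ratio < params@delLog2Threshold]
        cf <- coveredFraction(events, dels)
        lab <- ifelse(cf >= params@overlapFractionCutoff,
                      "deletion_mediated", "copy_neutral")
        mcols(out)$covered_fraction <- cf
        mcols(out)$label <- factor(lab, levels = .lohLabels)
        mcols(out)$size_pass <- GenomicRanges::width(out) > params@minCnlohSizeAcgh
        mcols(out)$retained <- lab == "copy_neutral" & mcols(out)$size_pass
    } else {
        if (is.null(markers))
            stop("marker rule needs SNP markers", call. = FALSE)
        if (length(markers)) {
            ms <- split(start(markers),
                        paste(mcols(markers)$sample, seqnames(markers)))
            if (any(vapply(ms, is.unsorted, TRUE)))
                stop("SNP markers must be sorted by position within chromosome",
                     call. = FALSE)
        }
        sizePass <- GenomicRanges::width(out) > params@minLohSizeSnp
        N <- n <- integer(length(out))
        if (length(markers)) {
            pr <- .pairBySample(events, markers)
            ev <- pr[[1L]]
            mk <- pr[[2L]]
            ov <- findOverlaps(mk, ev)
            q <- subjectHits(ov)
            low <- mcols(markers)$allelic_cn[queryHits(ov)] < params@snpCnThreshold
            N <- as.integer(tabulate(q, length(out)))
            n <- as.integer(tabulate(q[low], length(out)))
        }
        frac <- ifelse(N > 0L, n / N, NA_real_)
        lab <- rep("unlabelled", length(out))
        lab[sizePass & N > 0L] <-
            ifelse(frac[sizePass & N > 0L] >= params@snpFracCutoff,
                   "deletion_mediated", "copy_neutral")
        nEmpty <- sum(sizePass & N == 0L)
        if (nEmpty)
            warning(sprintf("%d LOH event(s) contain no markers (N = 0); left unlabelled and excluded",
                            nEmpty), call. = FALSE)
        mcols(out)$n_markers <- N
        mcols(out)$n_low <- n
        mcols(out)$frac_low <- frac
        mcols(out)$label <- factor(lab, levels = .lohLabels)
        mcols(out)$size_pass <- sizePass
        mcols(out)$retained <- lab == "copy_neutral"
    }
    out
}

#' Retained copy-neutral LOH events per sample
#'
#' Counts retained copy-neutral events per sample from a [classifyLOH()]
#' result. Samples with zero retained events are reported with count 0,
#' which is why the full cohort sample list should be supplied.
#'
#' @param classified `GRanges` from [classifyLOH()].
#' @param samples Character vector of all cohort samples; defaults to the
#'   samples seen in `classified`.
#' @return Named integer vector, one count per sample.
#' @export
cnlohCountPerSample <- function(classified, samples = NULL) {
    if (is.null(samples))
        samples <- unique(mcols(classified)$sample)
    keep <- mcols(classified)$retained &
        mcols(classified)$label == "copy_neutral"
    tab <- table(factor(mcols(classified)$sample[keep], levels = samples))
    out <- as.integer(tab)
    names(out) <- samples
    out
}

#' Somatic copy-number event count per sample
#'
#' Counts somatic copy-number amplification/deletion events per sample from
#' a copy-number segmentation: segments outside the copy-neutral log2 band
#' (below its lower edge: deletion; above its upper edge: amplification)
#' are events, and consecutive same-sign out-of-band segments of one
#' chromosome's segmentation are merged and counted once.
#'
#' @param segments `GRanges` with mcols `sample`, `log2_ratio`.
#' @param params An \linkS4class{AnalysisParams} (supplies the band).
#' @param samples All cohort samples (zero counts included).
#' @return Named integer vector, one count per sample.
#' @export
scnaCountPerSample <- function(segments, params = analysisParams(),
                               samples = NULL) {
    if (is.null(samples))
        samples <- unique(mcols(segments)$sample)
    out <- setNames(integer(length(samples)), samples)
    if (!length(segments)) return(out)
    o <- order(mcols(segments)$sample, as.factor(seqnames(segments)),
               start(segments))
    seg <- segments[o]
    sgn <- ifelse(mcols(seg)$log2_ratio < params@neutralBand[1L], -1L,
                  ifelse(mcols(seg)$log2_ratio > params@neutralBand[2L], 1L, 0L))
    key <- paste(mcols(seg)$sample, seqnames(seg))
    for (sc in split(data.frame(sgn = sgn, sample = mcols(seg)$sample), key)) {
        r <- rle(sc$sgn)
        cnt <- sum(r$values != 0L)
        if (cnt) {
            s <- sc$sample[1L]
            if (s %in% names(out)) out[s] <- out[s] + cnt
        }
    }
    out
}
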