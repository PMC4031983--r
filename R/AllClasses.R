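#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom GenomicRanges GRanges granges seqnames start end width
#' @importFrom IRanges IRanges
NULL

#' Analysis parameters
#'
#' Container for every numeric threshold the pipeline applies, with the
#' published defaults: a copy-number segment is a deletion when its aCGH log2
#' ratio falls strictly below \code{delLog2Threshold}; an LOH event is
#' deletion-mediated under the segment rule when deletion segments cover at
#' least \code{overlapFractionCutoff} of its length; copy-neutral events are
#' retained when strictly longer than \code{minCnlohSizeAcgh} (segment rule)
#' or \code{minLohSizeSnp} (marker rule, applied before counting); under the
#' marker rule an event is deletion-mediated when the fraction of its markers
#' with allelic copy number strictly below \code{snpCnThreshold} is at least
#' \code{snpFracCutoff}; loci are copy-neutral inside the closed
#' \code{neutralBand} (log2) or \code{neutralCnBand} (allelic copy number);
#' screen hits require percent-control viability strictly below
#' \code{viabilityCutoffPct} and Z strictly below \code{zCutoff}; group
#' comparisons are significant at \code{alpha}.
#'
#' @slot delLog2Threshold numeric, log2-ratio deletion threshold (strict `<`).
#' @slot overlapFractionCutoff numeric in (0, 1], coverage cutoff (non-strict).
#' @slot minCnlohSizeAcgh numeric, bp; copy-neutral retention size (strict `>`).
#' @slot minLohSizeSnp numeric, bp; marker-rule size filter (strict `>`).
#' @slot snpCnThreshold numeric, allelic copy number threshold (strict `<`).
#' @slot snpFracCutoff numeric in (0, 1], n/N cutoff (non-strict `>=`).
#' @slot neutralBand numeric length 2, closed log2 copy-neutral band.
#' @slot neutralCnBand numeric length 2, closed allelic-copy-number band.
#' @slot viabilityCutoffPct numeric, percent-control viability hit cutoff.
#' @slot zCutoff numeric, Z-score hit cutoff.
#' @slot alpha numeric in (0, 1), significance level.
#' @seealso [analysisParams()]
#' @export
setClass("AnalysisParams", representation(
    delLog2Threshold      = "numeric",
    overlapFractionCutoff = "numeric",
    minCnlohSizeAcgh      = "numeric",
    minLohSizeSnp         = "numeric",
    snpCnThreshold        = "numeric",
    snpFracCutoff         = "numeric",
    neutralBand           = "numeric",
    neutralCnBand         = "numeric",
    viabilityCutoffPct    = "numeric",
    zCutoff               = "numeric",
    alpha                 = "numeric"
))

setValidity("AnalysisParams", function(object) {
    msg <- character()
    sc1 <- function(x, nm) if (length(x) != 1L || !is.finite(x))
        sprintf("%s must be a single finite number", nm) else NULL
    for (nm in c("delLog2Threshold", "overlapFractionCutoff", "minCnlohSizeAcgh",
                 "minLohSizeSnp", "snpCnThreshold", "snpFracCutoff",
                 "viabilityCutoffPct", "zCutoff", "alpha"))
        msg <- c(msg, sc1(slot(object, nm), nm))
    if (length(msg))
        return(msg)
    if (object@overlapFractionCutoff <= 0 || object@overlapFractionCutoff > 1)
        msg <- c(msg, "overlapFractionCutoff must be in (0, 1]")
    if (object@snpFracCutoff <= 0 || object@snpFracCutoff > 1)
        msg <- c(msg, "snpFracCutoff must be in (0, 1]")
    if (object@minCnlohSizeAcgh <= 0 || object@minLohSizeSnp <= 0)
        msg <- c(msg, "size thresholds must be > 0")
    if (object@snpCnThreshold <= 0)
        msg <- c(msg, "snpCnThreshold must be > 0")
    for (nm in c("neutralBand", "neutralCnBand")) {
        b <- slot(object, nm)
        if (length(b) != 2L || any(!is.finite(b)) || b[1L] > b[2L])
            msg <- c(msg, sprintf("%s must be a non-empty closed interval c(lo, hi)", nm))
    }
    if (object@alpha <= 0 || object@alpha >= 1)
        msg <- c(msg, "alpha must be in (0, 1)")
    if (length(msg)) msg else TRUE
})

#' Construct analysis parameters
#'
#' @param delLog2Threshold,overlapFractionCutoff,minCnlohSizeAcgh,minLohSizeSnp
#'   Segment-rule thresholds; see [AnalysisParams-class].
#' @param snpCnThreshold,snpFracCutoff Marker-rule thresholds. The published
#'   sensitivity rerun uses \code{snpFracCutoff = 0.75}.
#' @param neutralBand,neutralCnBand Closed copy-neutral bands (log2 and
#'   allelic copy number).
#' @param viabilityCutoffPct,zCutoff Screen hit thresholds.
#' @param alpha Significance level for group comparisons.
#' @return A validated \linkS4class{AnalysisParams} object.
#' @examples
#' p <- analysisParams()
#' p
#' analysisParams(snpFracCutoff = 0.75)
#' @export
analysisParams <- function(delLog2Threshold = -0.20,
                           overlapFractionCutoff = 0.80,
                           minCnlohSizeAcgh = 1e6,
                           minLohSizeSnp = 1e4,
                           snpCnThreshold = 1.9,
                           snpFracCutoff = 0.80,
                           neutralBand = c(-0.2, 0.2),
                           neutralCnBand = c(1.9, 2.1),
                           viabilityCutoffPct = 75,
                           zCutoff = -2,
                           alpha = 0.05) {
    new("AnalysisParams",
        delLog2Threshold = delLog2Threshold,
        overlapFractionCutoff = overlapFractionCutoff,
        minCnlohSizeAcgh = minCnlohSizeAcgh,
        minLohSizeSnp = minLohSizeSnp,
        snpCnThreshold = snpCnThreshold,
        snpFracCutoff = snpFracCutoff,
        neutralBand = neutralBand,
        neutralCnBand = neutralCnBand,
        viabilityCutoffPct = viabilityCutoffPct,
        zCutoff = zCutoff,
        alpha = alpha)
}

setMethod("show", "AnalysisParams", function(object) {
    cat("AnalysisParams\n")
    cat(sprintf("  deletion log2 < %g; coverage >= %g; cnLOH size > %g bp (segment rule)\n",
                object@delLog2Threshold, object@overlapFractionCutoff,
                object@minCnlohSizeAcgh))
    cat(sprintf("  LOH size > %g bp; allelic CN < %g; n/N >= %g (marker rule)\n",
                object@minLohSizeSnp, object@snpCnThreshold, object@snpFracCutoff))
    cat(sprintf("  neutral log2 band [%g, %g]; neutral CN band [%g, %g]\n",
                object@neutralBand[1L], object@neutralBand[2L],
                object@neutralCnBand[1L], object@neutralCnBand[2L]))
    cat(sprintf("  screen: viability < %g%% and Z < %g; alpha = %g\n",
                object@viabilityCutoffPct, object@zCutoff, object@alpha))
    invisible(object)
})

#' Tumor cohort container
#'
#' Holds the four per-sample data layers the cohort pipeline consumes: LOH
#' event segments, copy-number segments with log2 ratios, SNP markers with
#' allelic copy numbers, and per-sample gene expression values. Coordinates
#' are 1-based closed (\code{GRanges} convention); each range carries its
#' sample in \code{mcols()$sample}.
#'
#' @slot samples character, the cohort sample identifiers (unique).
#' @slot lohEvents GRanges, mcols \code{sample}.
#' @slot cnSegments GRanges, mcols \code{sample}, \code{log2_ratio}.
#' @slot snpMarkers GRanges (width 1), mcols \code{sample}, \code{allelic_cn}.
#' @slot expression DataFrame with columns \code{sample}, \code{gene},
#'   \code{value}; may have zero rows.
#' @seealso [tumorCohort()], [simulateCohort()], [classifyLOH()]
#' @export
setClass("TumorCohort", representation(
    samples    = "character",
    lohEvents  = "GRanges",
    cnSegments = "GRanges",
    snpMarkers = "GRanges",
    expression = "DataFrame"
))

.checkLayer <- function(gr, nm, extraCols = character()) {
    if (!length(gr)) return(character())
    msg <- character()
    need <- c("sample", extraCols)
    miss <- setdiff(need, colnames(S4Vectors::mcols(gr)))
    if (length(miss))
        msg <- c(msg, sprintf("%s lacks mcols: %s", nm, paste(miss, collapse = ", ")))
    msg
}

setValidity("TumorCohort", function(object) {
    msg <- character()
    if (anyDuplicated(object@samples))
        msg <- c(msg, "duplicate sample identifiers")
    msg <- c(msg,
             .checkLayer(object@lohEvents, "lohEvents"),
             .checkLayer(object@cnSegments, "cnSegments", "log2_ratio"),
             .checkLayer(object@snpMarkers, "snpMarkers", "allelic_cn"))
    if (length(msg))
        return(msg)
    if (length(object@snpMarkers) && any(GenomicRanges::width(object@snpMarkers) != 1L))
        msg <- c(msg, "snpMarkers must have width 1")
    if (length(object@cnSegments)) {
        l2 <- S4Vectors::mcols(object@cnSegments)$log2_ratio
        if (any(!is.finite(l2)))
            msg <- c(msg, "cnSegments log2_ratio must be finite")
    }
    if (length(object@snpMarkers)) {
        cn <- S4Vectors::mcols(object@snpMarkers)$allelic_cn
        if (any(!is.finite(cn)) || any(cn < 0))
            msg <- c(msg, "snpMarkers allelic_cn must be finite and >= 0")
    }
    ref <- unique(c(
        as.character(S4Vectors::mcols(object@lohEvents)$sample),
        as.character(S4Vectors::mcols(object@cnSegments)$sample),
        as.character(S4Vectors::mcols(object@snpMarkers)$sample),
        if (nrow(object@expression)) as.character(object@expression$sample)))
    unk <- setdiff(ref, object@samples)
    if (length(unk))
        msg <- c(msg, sprintf("samples referenced in data layers but absent from sample list: %s",
                              paste(utils::head(unk, 5L), collapse = ", ")))
    if (nrow(object@expression) &&
        !all(c("sample", "gene", "value") %in% colnames(object@expression)))
        msg <- c(msg, "expression must have columns sample, gene, value")
    if (length(msg)) msg else TRUE
})

#' Construct a tumor cohort
#'
#' @param lohEvents,cnSegments,snpMarkers `GRanges` layers; see
#'   \linkS4class{TumorCohort}. Missing layers default to empty.
#' @param expression A `DataFrame`/`data.frame` with columns `sample`,
#'   `gene`, `value`.
#' @param samples Sample identifiers. Defaults to the union of samples seen
#'   in the supplied layers.
#' @return A validated \linkS4class{TumorCohort}.
#' @export
tumorCohort <- function(lohEvents = GRanges(), cnSegments = GRanges(),
                        snpMarkers = GRanges(), expression = DataFrame(),
                        samples = NULL) {
    expression <- as(expression, "DataFrame")
    if (is.null(samples))
        samples <- unique(c(
            as.character(S4Vectors::mcols(lohEvents)$sample),
            as.character(S4Vectors::mcols(cnSegments)$sample),
            as.character(S4Vectors::mcols(snpMarkers)$sample),
            if (nrow(expression)) as.character(expression$sample)))
    new("TumorCohort", samples = as.character(samples),
        lohEvents = lohEvents, cnSegments = cnSegments,
        snpMarkers = snpMarkers, expression = expression)
}

setMethod("show", "TumorCohort", function(object) {
    cat(sprintf("TumorCohort with %d samples\n", length(object@samples)))
    cat(sprintf("  lohEvents:  %d segments\n", length(object@lohEvents)))
    cat(sprintf("  cnSegments: %d segments\n", length(object@cnSegments)))
    cat(sprintf("  snpMarkers: %d markers\n", length(object@snpMarkers)))
    cat(sprintf("  expression: %d values (%d genes)\n", nrow(object@expression),
                length(unique(object@expression$gene))))
    invisible(object)
})

#' Screen experiment container
#'
#' Raw well-level luminescence observations of a mimic screen. One row per
#' well measurement; a mimic occupies a fixed plate position measured in one
#' or more replicates and in two treatment arms (drug / vehicle).
#'
#' @slot wells DataFrame with columns \code{plate_id}, \code{replicate},
#'   \code{well}, \code{content_id}, \code{role} (one of \code{mimic},
#'   \code{neg_control}, \code{pos_control_brca2}, \code{empty}),
#'   \code{treatment} (\code{drug} or \code{vehicle}), \code{luminescence}.
#' @seealso [screenExperiment()], [simulateScreen()], [screenResults()]
#' @export
setClass("ScreenExperiment", representation(wells = "DataFrame"))

.screenRoles <- c("mimic", "neg_control", "pos_control_brca2", "empty")
.screenArms  <- c("drug", "vehicle")

setValidity("ScreenExperiment", function(object) {
    msg <- character()
    need <- c("plate_id", "replicate", "well", "content_id", "role",
              "treatment", "luminescence")
    miss <- setdiff(need, colnames(object@wells))
    if (length(miss))
        return(sprintf("wells lacks columns: %s", paste(miss, collapse = ", ")))
    w <- object@wells
    if (nrow(w)) {
        if (!all(w$role %in% .screenRoles))
            msg <- c(msg, "role must be mimic/neg_control/pos_control_brca2/empty")
        if (!all(w$treatment %in% .screenArms))
            msg <- c(msg, "treatment must be drug or vehicle")
        if (any(!is.finite(w$luminescence)) || any(w$luminescence < 0))
            msg <- c(msg, "luminescence must be finite and >= 0")
        bad <- w$role == "mimic" & (is.na(w$content_id) | w$content_id == "")
        if (any(bad))
            msg <- c(msg, "mimic wells must carry a content_id")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a screen experiment
#'
#' @param wells A `data.frame`/`DataFrame` of well observations; see
#'   \linkS4class{ScreenExperiment} for the required columns. A missing
#'   `replicate` column defaults to 1.
#' @return A validated \linkS4class{ScreenExperiment}.
#' @export
screenExperiment <- function(wells) {
    wells <- as(as.data.frame(wells), "DataFrame")
    if (!"replicate" %in% colnames(wells))
        wells$replicate <- 1L
    for (col in c("plate_id", "well", "content_id", "role", "treatment"))
        if (col %in% colnames(wells)) wells[[col]] <- as.character(wells[[col]])
    new("ScreenExperiment", wells = wells)
}

setMethod("show", "ScreenExperiment", function(object) {
    w <- object@wells
    cat(sprintf("ScreenExperiment: %d well measurements\n", nrow(w)))
    if (nrow(w)) {
        cat(sprintf("  plates: %d; replicates: %d; mimics: %d\n",
                    length(unique(w$plate_id)), length(unique(w$replicate)),
                    length(unique(w$content_id[w$role == "mimic"]))))
        cat(sprintf("  neg-control wells: %d; BRCA2-siRNA wells: %d\n",
                    sum(w$role == "neg_control"), sum(w$role == "pos_control_brca2")))
    }
    invisible(object)
})

#' Wells accessor
#' @param x A \linkS4class{ScreenExperiment}.
#' @return The well-level `DataFrame`.
#' @export
wells <- function(x) {
    stopifnot(is(x, "ScreenExperiment"))
    x@wells
}

#' Accessors for cohort layers
#'
#' @param x A \linkS4class{TumorCohort}.
#' @return `lohEvents`, `cnSegments`, `snpMarkers` return the corresponding
#'   `GRanges` layer; `exprTable` the expression `DataFrame`; `sampleIDs`
#'   the character vector of sample identifiers.
#' @name cohort-accessors
NULL

#' @rdname cohort-accessors
#' @export
lohEvents <- function(x) { stopifnot(is(x, "TumorCohort")); x@lohEvents }

#' @rdname cohort-accessors
#' @export
cnSegments <- function(x) { stopifnot(is(x, "TumorCohort")); x@cnSegments }

#' @rdname cohort-accessors
#' @export
snpMarkers <- function(x) { stopifnot(is(x, "TumorCohort")); x@snpMarkers }

#' @rdname cohort-accessors
#' @export
exprTable <- function(x) { stopifnot(is(x, "TumorCohort")); x@expression }

#' @rdname cohort-accessors
#' @export
sampleIDs <- function(x) { stopifnot(is(x, "TumorCohort")); x@samples }
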