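#' miRNA locus sets
#'
#' A miRNA locus set is a named `GRangesList`: one element per mature miRNA,
#' each holding one or more genomic intervals. miR-1255b is encoded at two
#' distinct loci (miR-1255b-1 and miR-1255b-2) and must carry exactly two
#' intervals; its combined status is a deletion when either locus is deleted.
#'
#' `mirnaLoci()` builds a locus set from a data.frame; `printedMirnaLoci()`
#' returns the two miR-1255b loci at their published coordinates;
#' `syntheticMirnaLoci()` extends that with package-chosen stand-in intervals
#' for miR-148b* and miR-193b* (whose genomic coordinates must normally be
#' supplied by the user from an annotation) so the cohort simulator has a
#' complete three-miRNA locus set.
#'
#' @param df data.frame with columns `mirna`, `chrom`, `start`, `end`
#'   (1-based closed coordinates).
#' @return A named `GRangesList`, one element per miRNA.
#' @examples
#' syntheticMirnaLoci()
#' @export
mirnaLoci <- function(df) {
    need <- c("mirna", "chrom", "start", "end")
    miss <- setdiff(need, colnames(df))
    if (length(miss))
        stop("mirnaLoci: missing columns: ", paste(miss, collapse = ", "))
    gr <- GRanges(df$chrom, IRanges(df$start, df$end))
    ll <- S4Vectors::split(gr, factor(df$mirna, levels = unique(df$mirna)))
    n1255 <- sum(df$mirna == "miR-1255b")
    if (n1255 > 0L && n1255 != 2L)
        stop("mirnaLoci: miR-1255b must have exactly 2 intervals, got ", n1255)
    ll
}

#' @rdname mirnaLoci
#' @export
printedMirnaLoci <- function() {
    mirnaLoci(data.frame(
        mirna = c("miR-1255b", "miR-1255b"),
        chrom = c("chr4", "chr1"),
        start = c(36427988, 167967898),
        end   = c(36428050, 167967964)))
}

#' @rdname mirnaLoci
#' @export
syntheticMirnaLoci <- function() {
    # miR-148b*/miR-193b* intervals below are synthetic stand-ins for the
    # simulator's model genome, not published coordinates.
    mirnaLoci(data.frame(
        mirna = c("miR-1255b", "miR-1255b", "miR-148b*", "miR-193b*"),
        chrom = c("chr4", "chr1", "chr12", "chr16"),
        start = c(36427988, 167967898, 54731036, 14397824),
        end   = c(36428050, 167967964, 54731105, 14397906)))
}

#' Model genome for the cohort simulator
#'
#' Named vector of chromosome lengths (bp) covering the four chromosomes that
#' carry the three miRNA loci of [syntheticMirnaLoci()].
#' @return Named numeric vector of chromosome lengths.
#' @export
syntheticGenome <- function() {
    c(chr1 = 249e6, chr4 = 191e6, chr12 = 134e6, chr16 = 90e6)
}
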