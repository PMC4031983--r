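#' @importFrom utils read.delim write.table read.csv write.csv head
NULL

.requireCols <- function(df, need, path) {
    miss <- setdiff(need, colnames(df))
    if (length(miss))
        stop(sprintf("format error in '%s': missing column(s) %s",
                     path, paste(miss, collapse = ", ")), call. = FALSE)
}

.asNum <- function(x, col, path) {
    out <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(out) & !is.na(x))
    if (length(bad))
        stop(sprintf("parse error in '%s': non-numeric '%s' in column %s at line %d",
                     path, x[bad[1L]], col, bad[1L] + 1L), call. = FALSE)
    out
}

#' Read and write segment files
#'
#' Segment layers come in two on-disk flavours. SEG-like TSV has columns
#' `sample`, `chrom`, `start`, `end` (1-based closed) and, for copy-number
#' segments, `log2_ratio`. BED has `chrom`, `start`, `end`, `name` with the
#' sample identifier in the name column and, for copy-number segments, the
#' log2 ratio in the score column; BED's 0-based half-open coordinates are
#' converted on import. Internally all segments are `GRanges` (1-based
#' closed). Rows describing an empty interval (`end <= start` in the file's
#' own columns) are rejected with their line number.
#'
#' @param path File path.
#' @param kind `"loh"` or `"cn"`. Copy-number segments carry a `log2_ratio`
#'   metadata column.
#' @param format `"auto"` (by extension), `"tsv"` or `"bed"`.
#' @param gr `GRanges` with mcols `sample` (and `log2_ratio` for `kind = "cn"`).
#' @return `readSegments`: a `GRanges` with mcols `sample` (and
#'   `log2_ratio`). `writeSegments`: the path, invisibly.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1e6, 3e6),
#'                              sample = "S1")
#' f <- tempfile(fileext = ".tsv")
#' writeSegments(gr, f, kind = "loh")
#' readSegments(f, kind = "loh")
#' @export
readSegments <- function(path, kind = c("loh", "cn"), format = c("auto", "tsv", "bed")) {
    kind <- match.arg(kind)
    format <- match.arg(format)
    if (!file.exists(path))
        stop(sprintf("file not found: '%s'", path), call. = FALSE)
    if (format == "auto")
        format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "tsv"
    if (format == "bed") {
        gr <- rtracklayer::import(path, format = "BED")
        if (is.null(gr$name))
            stop(sprintf("format error in '%s': BED name column (sample) required", path),
                 call. = FALSE)
        empty <- which(GenomicRanges::width(gr) <= 0L)
        if (length(empty))
            stop(sprintf("empty interval (end <= start) in '%s' at line %d",
                         path, empty[1L]), call. = FALSE)
        out <- granges(gr)
        S4Vectors::mcols(out)$sample <- as.character(gr$name)
        if (kind == "cn") {
            if (is.null(gr$score))
                stop(sprintf("format error in '%s': BED score column (log2 ratio) required",
                             path), call. = FALSE)
            S4Vectors::mcols(out)$log2_ratio <- as.numeric(gr$score)
        }
        return(out)
    }
    df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
    need <- c("sample", "chrom", "start", "end")
    if (kind == "cn") need <- c(need, "log2_ratio")
    .requireCols(df, need, path)
    start <- .asNum(df$start, "start", path)
    end <- .asNum(df$end, "end", path)
    empty <- which(end <= start)
    if (length(empty))
        stop(sprintf("empty interval (end <= start) in '%s' at line %d",
                     path, empty[1L] + 1L), call. = FALSE)
    out <- GRanges(df$chrom, IRanges(start, end), sample = df$sample)
    if (kind == "cn")
        S4Vectors::mcols(out)$log2_ratio <- .asNum(df$log2_ratio, "log2_ratio", path)
    out
}

#' @rdname readSegments
#' @export
writeSegments <- function(gr, path, kind = c("loh", "cn"), format = c("auto", "tsv", "bed")) {
    kind <- match.arg(kind)
    format <- match.arg(format)
    if (format == "auto")
        format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "tsv"
    if (format == "bed") {
        out <- granges(gr)
        S4Vectors::mcols(out)$name <- as.character(S4Vectors::mcols(gr)$sample)
        if (kind == "cn")
            S4Vectors::mcols(out)$score <- S4Vectors::mcols(gr)$log2_ratio
        rtracklayer::export(out, path, format = "BED")
        return(invisible(path))
    }
    df <- data.frame(sample = as.character(S4Vectors::mcols(gr)$sample),
                     chrom = as.character(seqnames(gr)),
                     start = start(gr), end = end(gr))
    if (kind == "cn")
        df$log2_ratio <- S4Vectors::mcols(gr)$log2_ratio
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read and write SNP marker tables
#'
#' TSV with columns `sample`, `chrom`, `pos` (1-based) and `allelic_cn`, the
#' allelic copy number estimate at the marker.
#'
#' @param path File path.
#' @param gr Width-1 `GRanges` with mcols `sample`, `allelic_cn`.
#' @return `readSnpMarkers`: width-1 `GRanges` with mcols `sample`,
#'   `allelic_cn`. `writeSnpMarkers`: the path, invisibly.
#' @export
readSnpMarkers <- function(path) {
    if (!file.exists(path))
        stop(sprintf("file not found: '%s'", path), call. = FALSE)
    df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
    .requireCols(df, c("sample", "chrom", "pos", "allelic_cn"), path)
    pos <- .asNum(df$pos, "pos", path)
    GRanges(df$chrom, IRanges(pos, width = 1L), sample = df$sample,
            allelic_cn = .asNum(df$allelic_cn, "allelic_cn", path))
}

#' @rdname readSnpMarkers
#' @export
writeSnpMarkers <- function(gr, path) {
    df <- data.frame(sample = as.character(S4Vectors::mcols(gr)$sample),
                     chrom = as.character(seqnames(gr)),
                     pos = start(gr),
                     allelic_cn = S4Vectors::mcols(gr)$allelic_cn)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read and write expression tables
#'
#' TSV with columns `sample`, `gene`, `value` (one expression value per
#' sample and gene, on whatever scale the upstream platform produced).
#'
#' @param path File path.
#' @param df `DataFrame`/`data.frame` with columns `sample`, `gene`, `value`.
#' @return `readExpression`: a `DataFrame`. `writeExpression`: the path,
#'   invisibly.
#' @export
readExpression <- function(path) {
    if (!file.exists(path))
        stop(sprintf("file not found: '%s'", path), call. = FALSE)
    df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
    .requireCols(df, c("sample", "gene", "value"), path)
    DataFrame(sample = df$sample, gene = df$gene,
              value = .asNum(df$value, "value", path))
}

#' @rdname readExpression
#' @export
writeExpression <- function(df, path) {
    write.table(as.data.frame(df), path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read and write screen plate tables
#'
#' CSV with columns `plate_id`, `well`, `content_id`, `role` (`mimic`,
#' `neg_control`, `pos_control_brca2`, `empty`), `treatment` (`drug`,
#' `vehicle`), `luminescence`, and optionally `replicate`.
#'
#' @param path File path.
#' @param x A \linkS4class{ScreenExperiment}.
#' @return `readPlateCsv`: a \linkS4class{ScreenExperiment}.
#'   `writePlateCsv`: the path, invisibly.
#' @export
readPlateCsv <- function(path) {
    if (!file.exists(path))
        stop(sprintf("file not found: '%s'", path), call. = FALSE)
    df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
    .requireCols(df, c("plate_id", "well", "content_id", "role", "treatment",
                       "luminescence"), path)
    df$luminescence <- .asNum(df$luminescence, "luminescence", path)
    if ("replicate" %in% colnames(df))
        df$replicate <- as.integer(.asNum(df$replicate, "replicate", path))
    screenExperiment(df)
}

#' @rdname readPlateCsv
#' @export
writePlateCsv <- function(x, path) {
    write.csv(as.data.frame(wells(x)), path, quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read and write a cohort directory
#'
#' A cohort directory holds one file per data layer: `loh.tsv`, `cn.tsv`,
#' `snp.tsv`, `expr.tsv` (any layer file may be absent, giving an empty
#' layer).
#'
#' @param dir Directory path.
#' @param cohort A \linkS4class{TumorCohort}.
#' @return `readCohort`: a \linkS4class{TumorCohort}. `writeCohort`: the
#'   directory, invisibly.
#' @export
readCohort <- function(dir) {
    p <- function(f) file.path(dir, f)
    loh <- if (file.exists(p("loh.tsv"))) readSegments(p("loh.tsv"), "loh") else GRanges()
    cn  <- if (file.exists(p("cn.tsv")))  readSegments(p("cn.tsv"), "cn")  else GRanges()
    snp <- if (file.exists(p("snp.tsv"))) readSnpMarkers(p("snp.tsv"))     else GRanges()
    ex  <- if (file.exists(p("expr.tsv"))) readExpression(p("expr.tsv"))   else DataFrame()
    if (length(loh) == 0L) S4Vectors::mcols(loh)$sample <- character()
    if (length(cn) == 0L) {
        S4Vectors::mcols(cn)$sample <- character()
        S4Vectors::mcols(cn)$log2_ratio <- numeric()
    }
    if (length(snp) == 0L) {
        S4Vectors::mcols(snp)$sample <- character()
        S4Vectors::mcols(snp)$allelic_cn <- numeric()
    }
    tumorCohort(lohEvents = loh, cnSegments = cn, snpMarkers = snp, expression = ex)
}

#' @rdname readCohort
#' @export
writeCohort <- function(cohort, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    if (length(lohEvents(cohort)))
        writeSegments(lohEvents(cohort), file.path(dir, "loh.tsv"), "loh")
    if (length(cnSegments(cohort)))
        writeSegments(cnSegments(cohort), file.path(dir, "cn.tsv"), "cn")
    if (length(snpMarkers(cohort)))
        writeSnpMarkers(snpMarkers(cohort), file.path(dir, "snp.tsv"))
    if (nrow(exprTable(cohort)))
        writeExpression(exprTable(cohort), file.path(dir, "expr.tsv"))
    invisible(dir)
}
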