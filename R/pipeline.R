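#' Run the cohort pipeline end to end
#'
#' Classifies LOH events, genotypes the miRNA loci, assigns groups and
#' builds the association table, keeping a structured run log of
#' input/retained/removed counts at every filtering stage. The run is a
#' pure function of its inputs: repeated runs on the same cohort and
#' parameters are identical. When `outDir` is given, all output tables are
#' written only after every stage has succeeded, so a failing stage leaves
#' no partial outputs.
#'
#' @param x A \linkS4class{TumorCohort} or a cohort directory path (read
#'   with [readCohort()]).
#' @param loci Named `GRangesList` of miRNA loci.
#' @param method `"acgh"` (segment rule) or `"snp"` (marker rule).
#' @param params An \linkS4class{AnalysisParams}; validated before any
#'   work.
#' @param outDir Optional output directory for `classified_loh.tsv`,
#'   `genotypes.tsv`, `association.tsv` and `run_log.tsv`.
#' @param verbose Log each stage to stderr via [message()].
#' @return A list: `classified` (`GRanges`), `genotypes` (`DataFrame`),
#'   `association` (`DataFrame`), `cnlohCount` (named vector), `log`
#'   (`data.frame` of stage counts) and `params`.
#' @examples
#' sim <- simulateCohort(nWT = 6, nDel = c("miR-148b*" = 2), seed = 2,
#'                       layers = c("loh", "cn", "expr"))
#' res <- runPipeline(sim$cohort, method = "acgh", verbose = FALSE)
#' res$log
#' @export
runPipeline <- function(x, loci = syntheticMirnaLoci(),
                        method = c("acgh", "snp"),
                        params = analysisParams(), outDir = NULL,
                        verbose = TRUE) {
    method <- match.arg(method)
    validObject(params)
    if (is.character(x)) x <- readCohort(x)
    stopifnot(is(x, "TumorCohort"))
    logRows <- list()
    note <- function(stage, nIn, nOut, detail = "") {
        logRows[[length(logRows) + 1L]] <<- data.frame(
            stage = stage, n_in = nIn, n_out = nOut,
            n_removed = nIn - nOut, detail = detail)
        if (verbose)
            message(sprintf("[%s] in=%d out=%d removed=%d %s",
                            stage, nIn, nOut, nIn - nOut, detail))
    }
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
                 call. = FALSE))
    }
    nEv <- length(lohEvents(x))
    classified <- stage("classify", classifyLOH(x, method, params))
    lab <- as.character(classified$label)
    note("classify/label", nEv, sum(lab != "unlabelled"),
         sprintf("method=%s deletion_mediated=%d copy_neutral=%d dropped=%d",
                 method, sum(lab == "deletion_mediated"),
                 sum(lab == "copy_neutral"), sum(lab == "unlabelled")))
    note("classify/retain", sum(lab == "copy_neutral"),
         sum(classified$retained), "retained copy-neutral events")
    genotypes <- stage("genotype", genotypeCohort(x, loci, method, params))
    grp <- sampleGroups(genotypes)
    note("genotype", length(sampleIDs(x)),
         sum(genotypes$group != "excluded"),
         sprintf("WT=%d %s", length(grp$WT),
                 paste(sprintf("%s=%d", setdiff(names(grp), "WT"),
                               lengths(grp[setdiff(names(grp), "WT")])),
                       collapse = " ")))
    association <- stage("associate",
                         associateCohort(x, classified, genotypes, params))
    note("associate", nrow(association), sum(association$testable),
         "testable comparisons")
    runLog <- do.call(rbind, logRows)
    res <- list(classified = classified, genotypes = genotypes,
                association = association,
                cnlohCount = cnlohCountPerSample(classified, sampleIDs(x)),
                log = runLog, params = params)
    if (!is.null(outDir)) {
        if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
        cls <- data.frame(sample = classified$sample,
                          chrom = as.character(seqnames(classified)),
                          start = start(classified), end = end(classified),
                          label = as.character(classified$label),
                          retained = classified$retained)
        if (method == "acgh") cls$covered_fraction <- classified$covered_fraction
        else { cls$n_markers <- classified$n_markers; cls$frac_low <- classified$frac_low }
        gt <- data.frame(sample = genotypes$sample,
                         as.data.frame(unclass(genotypes$status)),
                         group = genotypes$group, check.names = FALSE)
        utils::write.table(cls, file.path(outDir, "classified_loh.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(gt, file.path(outDir, "genotypes.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(as.data.frame(association),
                           file.path(outDir, "association.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(runLog, file.path(outDir, "run_log.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    }
    res
}
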