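#' @importFrom stats rnorm rpois rlnorm runif median sd pnorm pwilcox
NULL

# deterministic child seeds from one root seed, one per generation stage
.childSeeds <- function(seed, n) {
    set.seed(seed)
    sample.int(2^31 - 2L, n)
}

# log-uniform sizes in (lo, hi]
.rlogunif <- function(n, lo, hi) {
    pmax(1, round(exp(runif(n, log(lo), log(hi)))))
}

# --- plain-numeric interval helpers (placement is the simulator's hot
# path, so it avoids GRanges construction until the very end) ---

.emptyIv <- function() data.frame(chr = character(), start = numeric(),
                                  end = numeric())

# merge possibly-overlapping intervals into disjoint sorted ones
.mergeIv <- function(start, end) {
    if (!length(start)) return(cbind(start = numeric(), end = numeric()))
    o <- order(start)
    s <- start[o]; e <- end[o]
    top <- cummax(e)
    grp <- cumsum(c(TRUE, s[-1L] > top[-length(e)]))
    cbind(start = as.numeric(tapply(s, grp, min)),
          end = as.numeric(tapply(e, grp, max)))
}

# per-chromosome merged-interval index for fast overlap rejection
.forbidIndex <- function(df) {
    lapply(split(df[c("start", "end")], df$chr),
           function(d) .mergeIv(d$start, d$end))
}

# place intervals of the given widths uniformly on the genome, redrawing
# any that overlap the forbidden index; widths must fit every chromosome
.placeNum <- function(widths, genome, forb = list()) {
    n <- length(widths)
    if (!n) return(.emptyIv())
    lv <- names(genome)
    chromp <- genome / sum(genome)
    chr <- character(n); st <- numeric(n)
    todo <- seq_len(n)
    for (iter in seq_len(200L)) {
        k <- length(todo)
        c2 <- sample(lv, k, replace = TRUE, prob = chromp)
        s2 <- floor(runif(k, 1, genome[c2] - widths[todo] + 1))
        e2 <- s2 + widths[todo] - 1
        bad <- logical(k)
        for (ch in unique(c2)) {
            m <- forb[[ch]]
            if (is.null(m) || !nrow(m)) next
            sel <- which(c2 == ch)
            idx <- findInterval(e2[sel], m[, 1L])
            bad[sel] <- idx >= 1L & m[pmax(idx, 1L), 2L] >= s2[sel]
        }
        chr[todo[!bad]] <- c2[!bad]
        st[todo[!bad]] <- s2[!bad]
        todo <- todo[bad]
        if (!length(todo)) break
    }
    if (length(todo))
        stop("could not place intervals outside forbidden regions; genome too crowded",
             call. = FALSE)
    data.frame(chr = chr, start = st, end = st + widths - 1)
}

#' Simulate a mimic screen with planted sensitizer hits
#'
#' Generates well-level luminescence for a multi-plate, two-arm
#' (drug/vehicle), replicated mimic screen. Each plate carries negative
#' control wells, BRCA2-siRNA positive-control wells and mimic wells. Well
#' luminescence is `base x plateScale(plate, replicate, arm) x effect x
#' noise`, with multiplicative log-normal noise of coefficient of variation
#' `noiseCV` (mean 1, so expected values equal the planted effects).
#' Planted hits lose viability only under drug (`hitEffect` fractional
#' viability); planted toxic mimics lose viability in both arms
#' (`toxicEffect`, at or below the BRCA2-siRNA vehicle effect so the
#' toxicity filter catches them); BRCA2-siRNA wells lose viability in both
#' arms, more under drug.
#'
#' @param nMimics Number of distinct mimics.
#' @param nPlantedHits Number of planted sensitizer hits.
#' @param nToxic Number of planted drug-independent toxic mimics (disjoint
#'   from the planted hits).
#' @param hitEffect Fractional drug-arm viability of planted hits (0.5 =
#'   half of control).
#' @param toxicEffect Fractional viability of toxic mimics in both arms.
#' @param brca2VehicleEffect,brca2DrugEffect Fractional viability of the
#'   BRCA2-siRNA control in vehicle / drug arm.
#' @param noiseCV Coefficient of variation of well noise (must be > 0:
#'   a zero-spread plate makes the Z-score undefined).
#' @param wellsPerPlate,negPerPlate,brca2PerPlate Plate layout.
#' @param nReplicates Replicate measurements per well position.
#' @param baseLum Baseline luminescence scale (arbitrary units).
#' @param plateScaleSD SD of the log-normal per-(plate, replicate, arm)
#'   scale factor.
#' @param seed Root seed; all randomness derives from it.
#' @return A list with `screen` (a \linkS4class{ScreenExperiment}) and
#'   `truth` (seed, planted hit / toxic identifiers and planted effects).
#' @examples
#' sim <- simulateScreen(nMimics = 100, nPlantedHits = 3, seed = 7)
#' sim$truth$plantedHitIds
#' @export
simulateScreen <- function(nMimics = 880, nPlantedHits = 20, nToxic = 8,
                           hitEffect = 0.5, toxicEffect = 0.5,
                           brca2VehicleEffect = 0.6, brca2DrugEffect = 0.25,
                           noiseCV = 0.10, wellsPerPlate = 384,
                           negPerPlate = 16, brca2PerPlate = 4,
                           nReplicates = 3, baseLum = 1000,
                           plateScaleSD = 0.15, seed = 1) {
    if (noiseCV <= 0)
        stop("noiseCV must be > 0: with zero noise the negative-control sigma degenerates and Z is undefined",
             call. = FALSE)
    mimPerPlate <- wellsPerPlate - negPerPlate - brca2PerPlate
    if (mimPerPlate < 1L)
        stop("wellsPerPlate must exceed the control wells per plate", call. = FALSE)
    if (nPlantedHits + nToxic > nMimics)
        stop("more planted hits + toxics than mimics", call. = FALSE)
    seeds <- .childSeeds(seed, 2L)

    set.seed(seeds[1L])
    mimics <- sprintf("mimic_%04d", seq_len(nMimics))
    hitIds <- sort(sample(mimics, nPlantedHits))
    toxIds <- sort(sample(setdiff(mimics, hitIds), nToxic))
    nPlates <- ceiling(nMimics / mimPerPlate)
    plateOf <- rep(seq_len(nPlates), each = mimPerPlate)[seq_len(nMimics)]

    # one row per well position per plate
    layout <- do.call(rbind, lapply(seq_len(nPlates), function(p) {
        ids <- mimics[plateOf == p]
        data.frame(
            plate_id = sprintf("plate_%02d", p),
            well = sprintf("W%03d", seq_len(negPerPlate + brca2PerPlate + length(ids))),
            content_id = c(rep("neg_ctrl", negPerPlate),
                           rep("BRCA2_siRNA", brca2PerPlate), ids),
            role = c(rep("neg_control", negPerPlate),
                     rep("pos_control_brca2", brca2PerPlate),
                     rep("mimic", length(ids))))
    }))

    set.seed(seeds[2L])
    grid <- expand.grid(replicate = seq_len(nReplicates),
                        treatment = c("drug", "vehicle"),
                        stringsAsFactors = FALSE)
    sdlog <- sqrt(log(1 + noiseCV^2))
    eff <- function(role, id, arm) {
        e <- rep(1, length(role))
        e[role == "pos_control_brca2"] <-
            ifelse(arm[role == "pos_control_brca2"] == "drug",
                   brca2DrugEffect, brca2VehicleEffect)
        isHit <- id %in% hitIds
        e[isHit & arm == "drug"] <- hitEffect
        e[id %in% toxIds] <- toxicEffect
        e
    }
    tabs <- lapply(seq_len(nrow(grid)), function(i) {
        w <- layout
        w$replicate <- grid$replicate[i]
        w$treatment <- grid$treatment[i]
        scale <- rlnorm(nPlates, 0, plateScaleSD)
        names(scale) <- sprintf("plate_%02d", seq_len(nPlates))
        mu <- baseLum * scale[w$plate_id] *
            eff(w$role, w$content_id, w$treatment)
        w$luminescence <- mu * rlnorm(nrow(w), -sdlog^2 / 2, sdlog)
        w
    })
    scr <- screenExperiment(do.call(rbind, tabs))
    truth <- list(seed = seed, plantedHitIds = hitIds, toxicIds = toxIds,
                  hitEffect = hitEffect, toxicEffect = toxicEffect,
                  brca2VehicleEffect = brca2VehicleEffect,
                  brca2DrugEffect = brca2DrugEffect, noiseCV = noiseCV,
                  mimics = mimics)
    list(screen = scr, truth = truth)
}

#' Simulate a tumor cohort with planted miRNA-locus deletions
#'
#' Generates the four cohort data layers with known ground truth. Samples
#' fall into a WT group and one deletion group per miRNA. Per sample the
#' generator plants:
#' \itemize{
#' \item copy-neutral LOH events: a Poisson number of events longer than
#'   the copy-neutral reporting size (rate `lohRateWT`, or `lohRateDel` in
#'   deletion groups, the planted group effect) plus a Poisson number
#'   (`subThresholdRate`, all groups) of sub-threshold events down to 1 kb,
#'   so both size filters are exercised on both sides; no deletion segment
#'   overlaps them and the SNP markers beneath them stay in the neutral
#'   copy-number band;
#' \item deletion-mediated LOH events (rate `delMediatedRate`, all groups):
#'   each co-located with one or two aCGH deletion segments (log2 about
#'   -0.5) covering a fraction of its length drawn well above the coverage
#'   cutoff, with all markers inside the event drawn below the
#'   allelic-copy-number threshold;
#' \item extra somatic copy-number events (rate `scnaRateWT` /
#'   `scnaRateDel`), amplified or deleted, placed away from LOH events and
#'   miRNA loci;
#' \item for deletion-group samples, a focal deletion segment covering the
#'   sample's miRNA locus (for miR-1255b one of its two loci, chosen at
#'   random), with low markers beneath it;
#' \item a regular SNP marker grid (`markerSpacing`) and per-sample BRCA1
#'   expression, shifted upward by `exprShift` in deletion groups.
#' }
#' Copy-number segments form a non-overlapping per-chromosome segmentation:
#' gaps between planted out-of-band segments are filled with copy-neutral
#' baseline segments. Nothing random is drawn outside the root seed.
#'
#' @param nWT WT group size.
#' @param nDel Named integer vector of deletion-group sizes; names must be
#'   miRNA names present in `loci`.
#' @param genome Named vector of chromosome lengths (bp).
#' @param loci Named `GRangesList` of miRNA loci (see [mirnaLoci()]).
#' @param lohRateWT,lohRateDel Expected reportable (above-size) copy-neutral
#'   LOH events per WT / deletion-group sample.
#' @param subThresholdRate Expected sub-size copy-neutral events per sample.
#' @param delMediatedRate Expected deletion-mediated LOH events per sample.
#' @param scnaRateWT,scnaRateDel Expected extra somatic copy-number events.
#' @param exprShift Additive BRCA1 expression shift in deletion groups.
#' @param markerSpacing SNP marker grid spacing (bp).
#' @param coverageRange Range the deletion-segment coverage fraction of a
#'   deletion-mediated event is drawn from (kept away from the cutoff so
#'   planted labels are non-borderline).
#' @param layers Which data layers to generate; dropping `"snp"` / `"expr"`
#'   makes large replicate sweeps cheap.
#' @param params An \linkS4class{AnalysisParams} (size thresholds used by
#'   the generator).
#' @param seed Root seed.
#' @return A list with `cohort` (a \linkS4class{TumorCohort}) and `truth`:
#'   `groupOf` (named sample -> group), `lohTruth` (`data.frame` parallel
#'   to `lohEvents(cohort)` with the generated label and an above-size
#'   flag), `cnlohCount` (planted reportable copy-neutral events per
#'   sample), `lociDeleted` (sample -> deleted miRNA), and the rates used.
#' @examples
#' sim <- simulateCohort(nWT = 6, nDel = c("miR-148b*" = 2), seed = 1,
#'                       layers = c("loh", "cn"))
#' table(sim$truth$groupOf)
#' @export
simulateCohort <- function(nWT = 40,
                           nDel = c("miR-1255b" = 10, "miR-148b*" = 10,
                                    "miR-193b*" = 10),
                           genome = syntheticGenome(),
                           loci = syntheticMirnaLoci(),
                           lohRateWT = 60, lohRateDel = 80,
                           subThresholdRate = 15, delMediatedRate = 20,
                           scnaRateWT = 30, scnaRateDel = 40,
                           exprShift = 1, markerSpacing = 25e3,
                           coverageRange = c(0.85, 1),
                           layers = c("loh", "cn", "snp", "expr"),
                           params = analysisParams(), seed = 1) {
    stopifnot(lohRateWT > 0, lohRateDel > 0, markerSpacing > 0)
    layers <- match.arg(layers, several.ok = TRUE)
    if (is.null(names(nDel)) || !all(names(nDel) %in% names(loci)))
        stop("names(nDel) must be miRNA names present in `loci`", call. = FALSE)
    lociGr <- unlist(loci, use.names = FALSE)
    names(lociGr) <- rep(names(loci), lengths(loci))
    if (!all(as.character(seqnames(lociGr)) %in% names(genome)) ||
        any(end(lociGr) > genome[as.character(seqnames(lociGr))]))
        stop("genome model does not accommodate the miRNA loci", call. = FALSE)

    seeds <- .childSeeds(seed, 4L)
    samples <- sprintf("S%03d", seq_len(nWT + sum(nDel)))
    groupOf <- c(rep("WT", nWT),
                 rep(paste0("del-", names(nDel)), nDel))
    names(groupOf) <- samples
    isDel <- groupOf != "WT"
    lociZone <- GenomicRanges::reduce(lociGr + 1e5)

    ## which locus is deleted per deletion sample (miR-1255b: pick one of two)
    set.seed(seeds[1L])
    lociDeleted <- character(0)
    locusDelIdx <- integer(0)   # index into lociGr per deletion sample
    for (s in samples[isDel]) {
        mir <- sub("^del-", "", groupOf[[s]])
        cand <- which(names(lociGr) == mir)
        locusDelIdx[s] <- if (length(cand) > 1L) sample(cand, 1L) else cand
        lociDeleted[s] <- mir
    }

    ## --- LOH events + their covering deletion segments ---
    set.seed(seeds[2L])
    evList <- list(); cnList <- list()
    minBig <- params@minCnlohSizeAcgh
    lociZoneDf <- data.frame(chr = as.character(seqnames(lociZone)),
                             start = start(lociZone), end = end(lociZone))
    fzLoci <- .forbidIndex(lociZoneDf)
    for (s in samples) {
        rate <- if (isDel[[match(s, samples)]]) lohRateDel else lohRateWT
        scnaRate <- if (isDel[[match(s, samples)]]) scnaRateDel else scnaRateWT
        nBig <- rpois(1L, rate)
        nSmall <- rpois(1L, subThresholdRate)
        nDm <- rpois(1L, delMediatedRate)

        dm <- .placeNum(.rlogunif(nDm, 1e3, 1e7), genome, fzLoci)
        dmW <- dm$end - dm$start + 1
        # covering deletion segments: fraction f of the event, one or two pieces
        f <- runif(nDm, coverageRange[1L], coverageRange[2L])
        covW <- pmax(1, round(dmW * f))
        split2 <- runif(nDm) < 0.5 & covW >= 4 & dmW > covW + 1
        covs <- .emptyIv()
        if (nDm) {
            one <- dm[!split2, , drop = FALSE]
            covs <- data.frame(chr = one$chr, start = one$start,
                               end = one$start + covW[!split2] - 1)
            if (any(split2)) {
                two <- dm[split2, , drop = FALSE]
                w1 <- floor(covW[split2] / 2)
                w2 <- covW[split2] - w1
                gap <- dmW[split2] - covW[split2]
                covs <- rbind(covs,
                    data.frame(chr = two$chr, start = two$start,
                               end = two$start + w1 - 1),
                    data.frame(chr = two$chr, start = two$start + w1 + gap,
                               end = two$start + w1 + gap + w2 - 1))
            }
        }
        covs$log2_ratio <- rnorm(nrow(covs), -0.5, 0.05)

        locusDel <- .emptyIv(); locusDel$log2_ratio <- numeric()
        if (s %in% names(locusDelIdx)) {
            loc <- lociGr[locusDelIdx[[s]]]
            segW <- round(runif(1L, 2e5, 2e6))
            margin <- floor(runif(1L, 5e4, segW - GenomicRanges::width(loc) - 5e4))
            st <- max(1, start(loc) - margin)
            locusDel <- data.frame(chr = as.character(seqnames(loc)),
                                   start = st, end = st + segW - 1,
                                   log2_ratio = rnorm(1L, -0.6, 0.05))
        }

        ## copy-neutral events avoid all deletion-type territory
        delTerr <- rbind(lociZoneDf, dm,
                         locusDel[c("chr", "start", "end")])
        fzCn <- .forbidIndex(delTerr)
        big <- .placeNum(.rlogunif(nBig, minBig + 1, 1e7), genome, fzCn)
        small <- .placeNum(.rlogunif(nSmall, 1e3, minBig - 1), genome, fzCn)

        ## extra somatic CN events avoid LOH events and loci
        nScna <- rpois(1L, scnaRate)
        scna <- .placeNum(.rlogunif(nScna, 1e5, 5e6), genome,
                          .forbidIndex(rbind(delTerr, big, small)))
        amp <- runif(nScna) < 0.5
        scna$log2_ratio <- ifelse(amp, rnorm(nScna, 0.5, 0.05),
                                  rnorm(nScna, -0.5, 0.05))

        ev <- rbind(dm, big, small)
        ev$sample <- s
        ev$truth_label <- rep(c("deletion_mediated", "copy_neutral", "copy_neutral"),
                              c(nDm, nBig, nSmall))
        evList[[s]] <- ev

        seg <- rbind(covs, locusDel, scna)
        seg$sample <- if (nrow(seg)) s else character(0)
        cnList[[s]] <- seg
    }
    evDf <- do.call(rbind, unname(evList))
    cnDf <- do.call(rbind, unname(cnList))
    events <- GRanges(factor(evDf$chr, levels = names(genome)),
                      IRanges(evDf$start, evDf$end),
                      sample = evDf$sample, truth_label = evDf$truth_label)
    S4Vectors::mcols(events)$truth_big <- GenomicRanges::width(events) > minBig
    planted <- GRanges(factor(cnDf$chr, levels = names(genome)),
                       IRanges(cnDf$start, cnDf$end),
                       sample = cnDf$sample, log2_ratio = cnDf$log2_ratio)

    ## --- baseline copy-neutral fill to a full per-sample segmentation ---
    set.seed(seeds[3L])
    cn <- GRanges()
    if ("cn" %in% layers) {
        key <- paste(S4Vectors::mcols(planted)$sample,
                     as.character(seqnames(planted)), sep = "\r")
        allKeys <- as.vector(outer(samples, names(genome), paste, sep = "\r"))
        remap <- GRanges(factor(key, levels = allKeys),
                         IRanges(start(planted), end(planted)))
        GenomeInfoDb::seqlengths(remap) <-
            unname(genome[sub("^.*\r", "", allKeys)])
        base <- GenomicRanges::gaps(remap)
        base <- base[BiocGenerics::strand(base) == "*"]
        parts <- strsplit(as.character(seqnames(base)), "\r", fixed = TRUE)
        baseGr <- GRanges(vapply(parts, `[`, "", 2L),
                          IRanges(start(base), end(base)),
                          sample = vapply(parts, `[`, "", 1L),
                          log2_ratio = rnorm(length(base), 0, 0.02))
        cn <- c(planted, baseGr)
        cn <- cn[order(S4Vectors::mcols(cn)$sample, as.factor(seqnames(cn)),
                       start(cn))]
        GenomeInfoDb::seqlevels(cn) <- names(genome)
    }

    ## --- SNP marker grid ---
    set.seed(seeds[4L])
    snp <- GRanges()
    if ("snp" %in% layers) {
        pos <- lapply(names(genome), function(ch)
            seq(floor(markerSpacing / 2), genome[[ch]], by = markerSpacing))
        grid <- GRanges(rep(names(genome), lengths(pos)),
                        IRanges(unlist(pos), width = 1L))
        nG <- length(grid)
        snp <- rep(grid, length(samples))
        S4Vectors::mcols(snp)$sample <- rep(samples, each = nG)
        val <- rnorm(length(snp), 2.0, 0.02)
        # low markers: inside deletion-mediated LOH events and deleted
        # segments; high markers under amplified segments
        lowReg <- c(events[S4Vectors::mcols(events)$truth_label == "deletion_mediated"],
                    planted[S4Vectors::mcols(planted)$log2_ratio < params@delLog2Threshold])
        hiReg <- planted[S4Vectors::mcols(planted)$log2_ratio > params@neutralBand[2L]]
        mark <- function(reg) {
            if (!length(reg)) return(integer())
            ov <- GenomicRanges::findOverlaps(snp, reg)
            keep <- S4Vectors::mcols(snp)$sample[S4Vectors::queryHits(ov)] ==
                S4Vectors::mcols(reg)$sample[S4Vectors::subjectHits(ov)]
            unique(S4Vectors::queryHits(ov)[keep])
        }
        li <- mark(lowReg); hi <- mark(hiReg)
        val[li] <- rnorm(length(li), 1.2, 0.05)
        val[hi] <- rnorm(length(hi), 2.6, 0.05)
        S4Vectors::mcols(snp)$allelic_cn <- pmax(0, val)
    }

    expr <- DataFrame()
    if ("expr" %in% layers) {
        expr <- DataFrame(sample = samples, gene = "BRCA1",
                          value = rnorm(length(samples), 8, 1) +
                              ifelse(isDel, exprShift, 0))
    }

    truth <- list(seed = seed, groupOf = groupOf,
                  lohTruth = data.frame(
                      sample = S4Vectors::mcols(events)$sample,
                      chrom = as.character(seqnames(events)),
                      start = start(events), end = end(events),
                      label = S4Vectors::mcols(events)$truth_label,
                      big = S4Vectors::mcols(events)$truth_big),
                  cnlohCount = vapply(samples, function(s)
                      sum(S4Vectors::mcols(events)$sample == s &
                          S4Vectors::mcols(events)$truth_label == "copy_neutral" &
                          S4Vectors::mcols(events)$truth_big), 0L),
                  lociDeleted = lociDeleted,
                  lohRateWT = lohRateWT, lohRateDel = lohRateDel,
                  exprShift = exprShift)

    evOut <- granges(events)
    S4Vectors::mcols(evOut)$sample <- S4Vectors::mcols(events)$sample
    cohort <- tumorCohort(lohEvents = evOut, cnSegments = cn, snpMarkers = snp,
                          expression = expr, samples = samples)
    list(cohort = cohort, truth = truth)
}

#' Write a synthetic-truth sidecar
#'
#' Serialises the `truth` record of [simulateScreen()] / [simulateCohort()]
#' to JSON next to the generated data files.
#'
#' @param truth A truth list.
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
writeTruthJson <- function(truth, path) {
    jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' Boundary fixtures for classification semantics
#'
#' Hand-built micro-fixtures pinning the strict/non-strict boundary
#' behaviour of the classification rules: coverage exactly at the cutoff,
#' n/N exactly at the cutoff, segments exactly at the log2 threshold and
#' band edges, and events exactly at the size thresholds.
#'
#' @return A list of small `GRanges` layers plus the expected calls,
#'   suitable for direct use with [classifyLOH()] and the locus genotypers.
#' @export
boundaryFixtures <- function() {
    s <- "B1"
    # event of width 1,000,000 exactly; 80% covered exactly
    ev <- GRanges("chr1", IRanges(c(1e6 + 1, 5e6 + 1, 9e6 + 1),
                                  width = c(1e6, 1e6, 1e6 + 1)),
                  sample = s)
    seg <- GRanges("chr1",
                   IRanges(c(1e6 + 1,       # covers exactly 80% of event 1
                             5e6 + 1),      # log2 exactly at threshold: not a deletion
                           width = c(8e5, 1e6)),
                   sample = s,
                   log2_ratio = c(-0.5, -0.20))
    # marker rule: event with N = 10, n = 8 exactly
    mev <- GRanges("chr2", IRanges(1e5 + 1, width = 1e5), sample = s)
    mk <- GRanges("chr2", IRanges(seq(1.1e5, by = 9e3, length.out = 10), width = 1),
                  sample = s,
                  allelic_cn = c(rep(1.2, 8), 2.0, 2.0))
    list(sample = s, events = ev, segments = seg,
         markerEvent = mev, markers = mk,
         expect = list(
             ev1 = "deletion_mediated",   # coverage 0.8 >= 0.8
             ev2 = "copy_neutral",        # log2 -0.20 is not < -0.20
             ev2_retained = FALSE,        # width 1 Mb is not > 1 Mb
             ev3_retained = TRUE,         # width 1 Mb + 1
             markerEvent = "deletion_mediated"))  # n/N = 0.8 >= 0.8
}
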