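#' @importFrom Biostrings readBStringSet
NULL

# normalise a sequence to uppercase RNA characters, validating the alphabet
.rnaChars <- function(x, what = "sequence") {
    if (is(x, "XString") || is(x, "XStringSet")) x <- as.character(x)
    stopifnot(is.character(x), length(x) == 1L)
    if (!nzchar(x)) stop(what, " must be non-empty", call. = FALSE)
    ch <- strsplit(chartr("acgutT", "ACGUUU", x), "")[[1L]]
    bad <- which(!ch %in% c("A", "C", "G", "U"))
    if (length(bad))
        stop(sprintf("invalid character '%s' in %s at position %d",
                     ch[bad[1L]], what, bad[1L]), call. = FALSE)
    ch
}

.pairType <- function(x, y) {
    # x from the miRNA, y from the target; T already mapped to U
    wc <- (x == "A" & y == "U") | (x == "U" & y == "A") |
          (x == "C" & y == "G") | (x == "G" & y == "C")
    gu <- (x == "G" & y == "U") | (x == "U" & y == "G")
    ifelse(wc, "WC", ifelse(gu, "GU", NA_character_))
}

#' Trim cloning overhangs from a printed oligo
#'
#' Reporter-construct oligos carry 5' cloning overhangs (TCGA / GGCC)
#' that are not part of the recognition element; this strips one such
#' leading overhang if present.
#'
#' @param x Sequence (character or `XString`).
#' @return Character sequence without the overhang.
#' @export
trimOverhang <- function(x) {
    if (is(x, "XString") || is(x, "XStringSet")) x <- as.character(x)
    sub("^(TCGA|GGCC|UCGA)", "", toupper(x))
}

#' Best ungapped miRNA:target duplex
#'
#' Slides the target site against the miRNA over every ungapped
#' antiparallel offset and returns the alignment with the most paired
#' bases, counting Watson-Crick pairs (A:U, C:G) and G:U wobbles; ties
#' break to the smallest offset. Both sequences are given 5'->3'; T and U
#' are equivalent.
#'
#' @param mirna,site Sequences (character or `XString`), 5'->3'.
#' @return A list: `offset`, `pairs` (data.frame `mirna_pos`, `site_pos`,
#'   `type` in WC/GU), `n_pairs`, and `seed_paired` (TRUE when miRNA
#'   positions 2-7 are all Watson-Crick paired in this alignment).
#' @examples
#' bestUngappedDuplex("UGAGGUAG", "CUACCUCA")$n_pairs  # perfect 8-mer duplex
#' @export
bestUngappedDuplex <- function(mirna, site) {
    m <- .rnaChars(mirna, "miRNA")
    s <- .rnaChars(site, "site")
    rs <- rev(s)           # antiparallel: walk the site 3'->5'
    nm <- length(m); ns <- length(s)
    best <- NULL
    for (k in seq(1L - nm, ns - 1L)) {
        i <- seq(max(1L, 1L - k), min(nm, ns - k))
        ty <- .pairType(m[i], rs[i + k])
        np <- sum(!is.na(ty))
        if (is.null(best) || np > best$n_pairs) {
            paired <- which(!is.na(ty))
            best <- list(offset = k,
                         pairs = data.frame(
                             mirna_pos = i[paired],
                             site_pos = ns - (i[paired] + k) + 1L,
                             type = ty[paired]),
                         n_pairs = np)
        }
    }
    seedIdx <- best$pairs$mirna_pos %in% 2:7 & best$pairs$type == "WC"
    best$seed_paired <- nm >= 7L &&
        all(2:7 %in% best$pairs$mirna_pos[seedIdx])
    best
}

#' Canonical seed-site test
#'
#' A canonical site pairs by Watson-Crick only (no G:U wobble) with miRNA
#' positions 2-7 (6-mer seed) or 2-8 (7-mer seed): the 3' UTR context must
#' contain the exact reverse complement of that seed.
#'
#' @param mirna miRNA sequence, 5'->3' (length >= 8).
#' @param context 3' UTR context sequence to scan.
#' @return A list: `match` (logical), `type` (`"7mer"`, `"6mer"` or `NA`),
#'   `at` (1-based start of the match in `context`, or `NA`).
#' @export
isCanonicalSeedSite <- function(mirna, context) {
    m <- .rnaChars(mirna, "miRNA")
    if (length(m) < 8L)
        stop("miRNA must be at least 8 nt", call. = FALSE)
    ctx <- paste(.rnaChars(context, "context"), collapse = "")
    rc <- function(chars) paste(rev(chartr("ACGU", "UGCA", chars)), collapse = "")
    for (len in c(8L, 7L)) {   # prefer reporting the longer 2-8 match
        seed <- m[2:len]
        hit <- regexpr(rc(seed), ctx, fixed = TRUE)
        if (hit > 0L)
            return(list(match = TRUE, type = if (len == 8L) "7mer" else "6mer",
                        at = as.integer(hit)))
    }
    list(match = FALSE, type = NA_character_, at = NA_integer_)
}

#' Read sequences for duplex scanning
#'
#' Thin FASTA reader returning plain character sequences (T mapped to U on
#' use by the pairing functions).
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
readSequencesFasta <- function(path) {
    x <- Biostrings::readBStringSet(path)
    setNames(as.character(x), names(x))
}
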