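# Independent brute-force oracles; deliberately written on different
# principles than the package code paths they check.

# per-base coverage of an event [1, evLen] by segments given in event-local
# 1-based closed coordinates
bruteCoveredFraction <- function(evLen, segStart, segEnd) {
    covered <- logical(evLen)
    for (i in seq_along(segStart)) {
        lo <- max(1L, segStart[i])
        hi <- min(evLen, segEnd[i])
        if (hi >= lo) covered[lo:hi] <- TRUE
    }
    mean(covered)
}

# pairwise-count U statistic (no ranks): pairs with a > b plus half ties
bruteU <- function(a, b) {
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
}

# one-tailed p by full enumeration of group assignments of the pooled values
brutePermPvalue <- function(a, b) {
    pooled <- c(a, b)
    na <- length(a)
    uObs <- bruteU(a, b)
    idx <- utils::combn(length(pooled), na)
    us <- apply(idx, 2L, function(i) bruteU(pooled[i], pooled[-i]))
    mean(us >= uObs - 1e-9)
}

# nearest-marker status by linear search, ties to the lower position
bruteNearestCn <- function(pos, cn, locusStart, locusEnd) {
    d <- pmax(locusStart - pos, pos - locusEnd, 0)
    cn[order(d, pos)[1L]]
}

# duplex pair count by triple loop over offsets and positions
RC_PAIRS <- list(A = "U", U = c("A", "G"), G = c("C", "U"), C = "G")
bruteDuplexPairs <- function(mirna, site) {
    m <- strsplit(chartr("tT", "uU", toupper(mirna)), "")[[1L]]
    s <- rev(strsplit(chartr("tT", "uU", toupper(site)), "")[[1L]])
    best <- 0L
    for (k in seq(1L - length(m), length(s) - 1L)) {
        np <- 0L
        for (i in seq_along(m)) {
            j <- i + k
            if (j < 1L || j > length(s)) next
            if (s[j] %in% RC_PAIRS[[m[i]]]) np <- np + 1L
        }
        best <- max(best, np)
    }
    best
}

# independent re-count of SCNA events: walk sorted segments, count sign changes
bruteScnaCount <- function(df, lo = -0.2, hi = 0.2) {
    cnt <- 0L
    for (key in unique(paste(df$sample, df$chrom))) {
        sub <- df[paste(df$sample, df$chrom) == key, ]
        sub <- sub[order(sub$start), ]
        sgn <- ifelse(sub$log2 < lo, -1L, ifelse(sub$log2 > hi, 1L, 0L))
        prev <- 0L
        for (x in sgn) {
            if (x != 0L && x != prev) cnt <- cnt + 1L
            prev <- x
        }
    }
    cnt
}

suppressPackageStartupMessages({
    library(GenomicRanges)
    library(S4Vectors)
})

makeGR <- function(chrom, start, end, ...) {
    GenomicRanges::GRanges(rep(chrom, length.out = length(start)),
                           IRanges::IRanges(start, end), ...)
}
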