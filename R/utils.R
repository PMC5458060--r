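## Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed`, then restores the
#' previous RNG state, so library calls never leak global randomness.
#'
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
withSeed <- function(seed, code) {
    if (is.null(seed) || is.na(seed))
        return(force(code))
    env <- globalenv()
    had <- exists(".Random.seed", envir = env, inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
    on.exit({
        if (had) assign(".Random.seed", old, envir = env)
        else if (exists(".Random.seed", envir = env, inherits = FALSE))
            rm(".Random.seed", envir = env)
    })
    set.seed(as.integer(seed))
    force(code)
}

## Empirical upper-tail threshold: smallest order statistic such that values
## >= threshold form (at least) the top `topFraction`.  Inverse-ECDF quantile
## (type 1); ties at the threshold are included by the >= comparison the
## callers use.
.upperThreshold <- function(values, topFraction) {
    values <- values[is.finite(values)]
    if (length(values) == 0L)
        stop("no defined values to threshold")
    stats::quantile(values, probs = 1 - topFraction, type = 1L, names = FALSE)
}

## 0-based start positions of sliding windows covering [0, chromLen).
.windowStarts <- function(chromLen, size, step) {
    if (size <= 0 || step <= 0 || size < step)
        stop("window size and step must satisfy size >= step > 0")
    seq.int(0L, max(0, chromLen - 1), by = step)
}

## Sum (and count) of per-site values falling in each sliding window.
## `pos` is 1-based and sorted; windows are 0-based half-open [s, s+size).
.windowSums <- function(pos, values, starts, size) {
    cs <- c(0, cumsum(values))
    lo <- findInterval(starts, pos)            # sites with pos <= s
    hi <- findInterval(starts + size, pos)     # sites with pos <= s+size
    list(sum = cs[hi + 1L] - cs[lo + 1L], n = hi - lo)
}

.chromLengths <- function(x) {
    gr <- rowRanges(x)
    sl <- seqlengths(gr)
    chroms <- as.character(unique(seqnames(gr)))
    out <- numeric(length(chroms))
    names(out) <- chroms
    for (ch in chroms) {
        len <- suppressWarnings(sl[[ch]])
        if (is.null(len) || is.na(len))
            len <- max(end(gr)[as.character(seqnames(gr)) == ch])
        out[[ch]] <- len
    }
    out
}

.fmtNum <- function(x) {
    out <- vapply(x, function(v) {
        if (is.na(v)) "NA" else sprintf("%.10g", v)
    }, character(1))
    out
}

#' Write a window track as BedGraph
#'
#' @param track `GRanges` with a `value` metadata column (as returned by
#'   [windowedPi()], [windowedFst()], [piRatio()] or [tabulateWindows()]).
#'   Windows with undefined values are dropped.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
writeBedGraph <- function(track, path) {
    keep <- is.finite(track$value)
    tr <- track[keep]
    lines <- sprintf("%s\t%d\t%d\t%s",
                     as.character(seqnames(tr)),
                     start(tr) - 1L, end(tr),
                     .fmtNum(tr$value))
    writeLines(lines, path)
    invisible(path)
}

#' Write regions as BED6
#'
#' Scores are written as-is in the BED score column (not clamped to 0-1000).
#'
#' @param regions `GRanges` with a `score` metadata column (as returned by
#'   [topQuantileRegions()] or [callSweeps()]).
#' @param path Output file.
#' @param namePrefix Prefix for the BED name column.
#' @return Invisibly, `path`.
#' @export
writeRegionsBed <- function(regions, path, namePrefix = "region") {
    if (length(regions) == 0L) {
        writeLines(character(0), path)
        return(invisible(path))
    }
    lines <- sprintf("%s\t%d\t%d\t%s_%d\t%s\t.",
                     as.character(seqnames(regions)),
                     start(regions) - 1L, end(regions),
                     namePrefix, seq_along(regions),
                     .fmtNum(regions$score))
    writeLines(lines, path)
    invisible(path)
}
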