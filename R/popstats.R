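## Nucleotide diversity, Weir-Cockerham FST, sliding windows, quantile
## thresholding and region merging.

.popColumns <- function(x, population, dropExcluded = TRUE) {
    sel <- populations(x) == population
    if (dropExcluded)
        sel <- sel & !excludedSamples(x)
    if (sum(sel) < 2L)
        stop("population '", population, "' has fewer than 2 usable samples")
    which(sel)
}

#' Per-site nucleotide diversity
#'
#' With `c1` alternate alleles among `n` non-missing alleles,
#' `pi = c1 * (n - c1) / choose(n, 2)`: the mean pairwise difference per
#' site.  Sites with fewer than 2 non-missing alleles are `NA`.
#'
#' @param gt Dosage matrix (sites x samples) for one population, or a
#'   vector for a single site.
#' @return Numeric vector of per-site pi.
#' @examples
#' sitePi(matrix(c(1L, 1L), 1))  # c1 = 2 of n = 4 -> 2*2/6
#' @export
sitePi <- function(gt) {
    if (is.null(dim(gt)))
        gt <- matrix(gt, nrow = 1L)
    nAll <- 2L * rowSums(!is.na(gt))
    c1 <- rowSums(gt, na.rm = TRUE)
    pi <- ifelse(nAll >= 2, c1 * (nAll - c1) / (nAll * (nAll - 1) / 2),
                 NA_real_)
    as.numeric(pi)
}

.makeWindows <- function(chromLens, size, step) {
    sl <- lapply(names(chromLens), function(ch)
        .windowStarts(chromLens[[ch]], size, step))
    ch <- rep(names(chromLens), lengths(sl))
    starts <- unlist(sl)
    lens <- unname(chromLens[ch])
    out <- GRanges(ch, IRanges(starts + 1L, pmin(starts + size, lens)),
                   windowStart = starts, partial = starts + size > lens)
    seqlengths(out) <- chromLens[seqlevels(out)]
    out
}

## Shared sliding-window machinery: per-window sum and count of site values.
.windowTrack <- function(x, siteValues, size, step,
                         perBp = TRUE, denomValues = NULL) {
    chromLens <- .chromLengths(x)
    win <- .makeWindows(chromLens, size, step)
    rr <- rowRanges(x)
    chrom <- as.character(seqnames(rr))
    val <- rep(NA_real_, length(win))
    n <- rep(0L, length(win))
    den <- rep(NA_real_, length(win))
    for (ch in names(chromLens)) {
        si <- which(chrom == ch & !is.na(siteValues))
        wi <- which(as.character(seqnames(win)) == ch)
        starts <- win$windowStart[wi]
        if (length(si)) {
            ws <- .windowSums(start(rr)[si], siteValues[si], starts, size)
            val[wi] <- ws$sum
            n[wi] <- ws$n
            if (!is.null(denomValues)) {
                wd <- .windowSums(start(rr)[si], denomValues[si], starts, size)
                den[wi] <- wd$sum
            }
        } else {
            val[wi] <- 0
            n[wi] <- 0L
        }
    }
    list(windows = win, sum = val, n = n, denomSum = den)
}

#' Windowed nucleotide diversity
#'
#' Sliding-window pi: per-site pi values (sites genotyped in at least
#' `minGenotyped` of the population's samples) summed per window and
#' divided by the window span in bp (invariant positions contribute zero
#' difference).  Windows are anchored at 0 on each chromosome; the last
#' partial windows keep the full-size denominator and are flagged
#' `partial`.
#'
#' @param x A [GenotypeMatrix-class].
#' @param population Population label to analyse.
#' @param windowSize,step Window and step size in bp (default 10 kb / 1 kb).
#' @param minGenotyped Minimum genotyped fraction for a site to be used
#'   (default 0.90).
#' @param genotypedScope Samples over which the genotyped fraction is
#'   computed: `"all"` (default; all non-excluded accessions, so every
#'   population's pi uses the same site set) or `"population"`.
#' @param denominator `"window"` divides by the window span (default);
#'   `"sites"` divides by the number of SNPs used (per-SNP pi).
#' @return `GRanges` track with metadata columns `value`, `nSites`,
#'   `partial`.
#' @export
windowedPi <- function(x, population, windowSize = 10000L, step = 1000L,
                       minGenotyped = 0.90,
                       genotypedScope = c("all", "population"),
                       denominator = c("window", "sites")) {
    denominator <- match.arg(denominator)
    genotypedScope <- match.arg(genotypedScope)
    cols <- .popColumns(x, population)
    gt <- genotypes(x)[, cols, drop = FALSE]
    if (genotypedScope == "all") {
        allCols <- which(!excludedSamples(x))
        gAll <- genotypes(x)[, allCols, drop = FALSE]
        genoFrac <- rowSums(!is.na(gAll)) / length(allCols)
    } else {
        genoFrac <- rowSums(!is.na(gt)) / length(cols)
    }
    pis <- sitePi(gt)
    pis[genoFrac < minGenotyped] <- NA_real_
    wt <- .windowTrack(x, pis, windowSize, step)
    win <- wt$windows
    win$value <- if (denominator == "window") wt$sum / windowSize
                 else ifelse(wt$n > 0, wt$sum / wt$n, 0)
    win$nSites <- wt$n
    metadata(win) <- list(statistic = "pi", population = population,
                          windowSize = windowSize, step = step)
    win
}

#' Ratio of wild to cultivated diversity per window
#'
#' `pi_w / pi_c` on the shared window grid.  Windows where the denominator
#' is zero are flagged undefined (`NA` value), not infinite.
#'
#' @param trackWild,trackCult `GRanges` tracks from [windowedPi()] on
#'   identical grids.
#' @return `GRanges` track with `value` (the ratio) and `defined`.
#' @export
piRatio <- function(trackWild, trackCult) {
    if (length(trackWild) != length(trackCult) ||
        !all(as.character(seqnames(trackWild)) ==
                 as.character(seqnames(trackCult))) ||
        !all(start(trackWild) == start(trackCult)))
        stop("pi tracks are not on the same window grid")
    out <- granges(trackWild)
    defined <- !is.na(trackWild$value) & !is.na(trackCult$value) &
        trackCult$value > 0
    out$value <- ifelse(defined, trackWild$value / trackCult$value, NA_real_)
    out$defined <- defined
    metadata(out) <- list(statistic = "piRatio")
    out
}

#' Weir-Cockerham (1984) per-site variance components
#'
#' Computes the among-population (a), among-individual (b) and
#' within-individual (c) variance components for diploid biallelic data
#' from the two populations' sample sizes, allele frequencies and observed
#' heterozygosities.  Sites where either population has fewer than two
#' genotyped samples are `NA`.
#'
#' @param gt1,gt2 Dosage matrices (sites x samples) for the two
#'   populations.
#' @return `data.frame` with columns `a`, `b`, `c`.
#' @export
fstSiteComponents <- function(gt1, gt2) {
    if (is.null(dim(gt1))) gt1 <- matrix(gt1, nrow = 1L)
    if (is.null(dim(gt2))) gt2 <- matrix(gt2, nrow = 1L)
    n1 <- rowSums(!is.na(gt1)); n2 <- rowSums(!is.na(gt2))
    p1 <- rowSums(gt1, na.rm = TRUE) / (2 * pmax(n1, 1L))
    p2 <- rowSums(gt2, na.rm = TRUE) / (2 * pmax(n2, 1L))
    h1 <- rowSums(gt1 == 1L, na.rm = TRUE) / pmax(n1, 1L)
    h2 <- rowSums(gt2 == 1L, na.rm = TRUE) / pmax(n2, 1L)
    r <- 2
    nbar <- (n1 + n2) / r
    nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
    a <- (nbar / nc) *
        (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
        (pbar * (1 - pbar) - s2 * (r - 1) / r -
             hbar * (2 * nbar - 1) / (4 * nbar))
    cc <- hbar / 2
    bad <- n1 < 2L | n2 < 2L
    a[bad] <- b[bad] <- cc[bad] <- NA_real_
    data.frame(a = a, b = b, c = cc)
}

#' Windowed Weir-Cockerham FST
#'
#' Window value is the ratio of sums `sum(a) / sum(a + b + c)` over the
#' sites in the window (negative per-site components are retained in the
#' sums).  Windows with no usable site or a zero denominator are undefined.
#'
#' @param x A [GenotypeMatrix-class] whose `colData` assigns samples to
#'   `pop1` and `pop2`.
#' @param pop1,pop2 Population labels (default wild vs cultivated).
#' @param windowSize,step Window and step size in bp.
#' @return `GRanges` track with `value`, `nSites`, `defined`, `partial`.
#' @export
windowedFst <- function(x, pop1 = "wild_progenitor", pop2 = "cultivated",
                        windowSize = 10000L, step = 1000L) {
    c1 <- .popColumns(x, pop1)
    c2 <- .popColumns(x, pop2)
    comp <- fstSiteComponents(genotypes(x)[, c1, drop = FALSE],
                              genotypes(x)[, c2, drop = FALSE])
    usable <- !is.na(comp$a)
    aVal <- ifelse(usable, comp$a, NA_real_)
    tot <- comp$a + comp$b + comp$c
    wt <- .windowTrack(x, aVal, windowSize, step,
                       denomValues = ifelse(usable, tot, NA_real_))
    win <- wt$windows
    defined <- !is.na(wt$denomSum) & wt$n > 0 & wt$denomSum != 0
    win$value <- ifelse(defined, wt$sum / wt$denomSum, NA_real_)
    win$nSites <- wt$n
    win$defined <- defined
    metadata(win) <- list(statistic = "fst",
                          windowSize = windowSize, step = step)
    win
}

#' Call top-quantile regions from a window track
#'
#' Thresholds the defined window values at the empirical `1 - topFraction`
#' quantile (inverse ECDF; ties at the threshold are included), merges
#' passing windows that overlap or abut, and scores each region with the
#' maximum member window value.
#'
#' @param track `GRanges` window track with a `value` column.
#' @param topFraction Upper tail fraction (e.g. 0.01 for the top 1%).
#' @param merge Merge adjacent passing windows (default `TRUE`).
#' @param positiveOnly Additionally require `value > 0` (used for
#'   composite-likelihood tracks, where a zero score means no sweep
#'   evidence at all and the zero atom would otherwise swallow the
#'   quantile threshold).
#' @return Sorted, non-overlapping `GRanges` with `score` and `nWindows`.
#' @export
topQuantileRegions <- function(track, topFraction, merge = TRUE,
                               positiveOnly = FALSE) {
    vals <- track$value
    if (all(!is.finite(vals)))
        stop("window track has no defined values")
    thr <- .upperThreshold(vals, topFraction)
    pass <- !is.na(vals) & is.finite(vals) & vals >= thr
    if (positiveOnly)
        pass <- pass & vals > 0
    passing <- track[pass]
    if (length(passing) == 0L) {
        out <- GRanges()
        out$score <- numeric(0)
        out$nWindows <- integer(0)
        return(out)
    }
    if (!merge) {
        out <- granges(passing)
        out$score <- passing$value
        out$nWindows <- 1L
        return(sort(out))
    }
    regions <- reduce(granges(passing), min.gapwidth = 1L)
    ov <- findOverlaps(passing, regions)
    score <- vapply(seq_along(regions), function(i)
        max(passing$value[queryHits(ov)[subjectHits(ov) == i]]), numeric(1))
    nw <- vapply(seq_along(regions), function(i)
        sum(subjectHits(ov) == i), integer(1))
    regions$score <- score
    regions$nWindows <- nw
    metadata(regions) <- list(threshold = thr, topFraction = topFraction)
    sort(regions)
}

#' Genes overlapping regions
#'
#' A gene is reported for a region when their spans overlap by at least
#' 1 bp.
#'
#' @param regions `GRanges` of regions.
#' @param gff GFF3 path or `GRanges` with `type == "gene"` features
#'   carrying `ID`s.
#' @return List (one element per region) of gene ID character vectors.
#' @export
genesInRegions <- function(regions, gff) {
    gffGr <- .loadGff(gff)
    genes <- gffGr[gffGr$type == "gene"]
    ids <- as.character(genes$ID)
    ov <- findOverlaps(genes, regions, minoverlap = 1L)
    lapply(seq_along(regions), function(i)
        ids[queryHits(ov)[subjectHits(ov) == i]])
}
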