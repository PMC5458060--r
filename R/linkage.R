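## Two-locus r-squared from unphased genotypes (EM over phase ambiguity),
## exact Hardy-Weinberg test, LD-decay curve and decay distance.

#' Exact Hardy-Weinberg equilibrium test
#'
#' Conditional-on-allele-counts exact test: all heterozygote counts with the
#' observed parity are enumerated, each gets its hypergeometric-type
#' probability, and the p-value is the sum of the probabilities of all
#' configurations no more probable than the observed one.  Monomorphic
#' sites return 1 by convention.
#'
#' @param nAA,nAa,naa Genotype counts (non-negative; vectors are accepted
#'   and handled elementwise).
#' @return p-value(s) in `(0, 1]`.
#' @examples
#' hweExactP(5, 10, 5)
#' @export
hweExactP <- function(nAA, nAa, naa) {
    if (length(nAA) > 1L || length(nAa) > 1L || length(naa) > 1L) {
        m <- cbind(nAA, nAa, naa)
        return(apply(m, 1L, function(r) hweExactP(r[1], r[2], r[3])))
    }
    if (nAA < 0 || nAa < 0 || naa < 0)
        stop("genotype counts must be non-negative")
    n <- nAA + nAa + naa
    if (n < 1L)
        stop("need at least one genotype")
    nAlt <- 2L * naa + nAa
    n1 <- min(nAlt, 2L * n - nAlt)          # rarer allele count
    if (n1 == 0L)
        return(1)
    hs <- seq.int(n1 %% 2L, n1, by = 2L)
    lw <- lgamma(n + 1) - lgamma((n1 - hs) / 2 + 1) - lgamma(hs + 1) -
        lgamma((2 * n - n1 - hs) / 2 + 1) + hs * log(2)
    pr <- exp(lw - max(lw))
    pr <- pr / sum(pr)
    pObs <- pr[match(nAa, hs)]
    sum(pr[pr <= pObs * (1 + 1e-9)])
}

## Vectorised EM for two-locus haplotype frequencies from 3x3 genotype
## count tables.  Each argument is a vector over pairs; ngh = count of
## individuals with dosage g at locus A and h at locus B.
.emHaplotypes <- function(n00, n01, n02, n10, n11, n12, n20, n21, n22,
                          maxit = 50L, tol = 1e-8) {
    N <- n00 + n01 + n02 + n10 + n11 + n12 + n20 + n21 + n22
    pA <- (2 * (n20 + n21 + n22) + n10 + n11 + n12) / (2 * N)
    pB <- (2 * (n02 + n12 + n22) + n01 + n11 + n21) / (2 * N)
    f11 <- pA * pB; f10 <- pA * (1 - pB)
    f01 <- (1 - pA) * pB; f00 <- (1 - pA) * (1 - pB)
    for (it in seq_len(maxit)) {
        den <- f11 * f00 + f10 * f01
        pcis <- ifelse(den > 0, f11 * f00 / den, 0.5)
        c11 <- 2 * n22 + n21 + n12 + n11 * pcis
        c10 <- 2 * n20 + n21 + n10 + n11 * (1 - pcis)
        c01 <- 2 * n02 + n12 + n01 + n11 * (1 - pcis)
        c00 <- 2 * n00 + n10 + n01 + n11 * pcis
        tot <- 2 * N
        g11 <- c11 / tot; g10 <- c10 / tot
        g01 <- c01 / tot; g00 <- c00 / tot
        delta <- pmax(abs(g11 - f11), abs(g10 - f10),
                      abs(g01 - f01), abs(g00 - f00))
        f11 <- g11; f10 <- g10; f01 <- g01; f00 <- g00
        if (all(delta < tol)) break
    }
    list(f11 = f11, f10 = f10, f01 = f01, f00 = f00, N = N)
}

.r2FromHapFreqs <- function(em) {
    pA <- em$f11 + em$f10
    pB <- em$f11 + em$f01
    D <- em$f11 - pA * pB
    den <- pA * (1 - pA) * pB * (1 - pB)
    ifelse(den > 0, D * D / den, NA_real_)
}

#' Two-locus r-squared from unphased genotypes
#'
#' Haplotype frequencies are estimated by EM over the phase ambiguity of
#' double heterozygotes (at most 50 iterations or change < 1e-8), and
#' `r^2 = D^2 / (pA qA pB qB)`.  Samples missing at either site are
#' excluded pairwise; monomorphic sites are undefined (`NA`).
#'
#' @param dosA,dosB Dosage vectors of the two sites over the same samples.
#' @return r-squared in `[0, 1]` or `NA`.
#' @export
r2Pair <- function(dosA, dosB) {
    keep <- !is.na(dosA) & !is.na(dosB)
    a <- dosA[keep]; b <- dosB[keep]
    if (length(a) < 2L)
        return(NA_real_)
    cnt <- function(g, h) sum(a == g & b == h)
    em <- .emHaplotypes(cnt(0, 0), cnt(0, 1), cnt(0, 2),
                        cnt(1, 0), cnt(1, 1), cnt(1, 2),
                        cnt(2, 0), cnt(2, 1), cnt(2, 2))
    .r2FromHapFreqs(em)
}

## All within-chromosome pairs (i < j) with separation <= maxDistance.
.admissiblePairs <- function(chrom, pos, maxDistance) {
    ii <- jj <- integer(0)
    for (ch in unique(chrom)) {
        idx <- which(chrom == ch)
        p <- pos[idx]
        ub <- findInterval(p + maxDistance, p)
        cnt <- ub - seq_along(p)
        has <- cnt > 0L
        if (!any(has)) next
        ii <- c(ii, idx[rep.int(seq_along(p)[has], cnt[has])])
        jj <- c(jj, idx[sequence(cnt[has], from = seq_along(p)[has] + 1L)])
    }
    list(i = ii, j = jj)
}

## r-squared for many pairs at once, chunked to bound memory.
.pairwiseR2 <- function(gt, ii, jj, chunk = 200000L) {
    I <- list(g0 = !is.na(gt) & gt == 0L,
              g1 = !is.na(gt) & gt == 1L,
              g2 = !is.na(gt) & gt == 2L)
    out <- numeric(length(ii))
    for (s in seq(1L, length(ii), by = chunk)) {
        e <- min(s + chunk - 1L, length(ii))
        a <- ii[s:e]; b <- jj[s:e]
        cnt <- function(g, h)
            rowSums(I[[g + 1L]][a, , drop = FALSE] &
                        I[[h + 1L]][b, , drop = FALSE])
        em <- .emHaplotypes(cnt(0, 0), cnt(0, 1), cnt(0, 2),
                            cnt(1, 0), cnt(1, 1), cnt(1, 2),
                            cnt(2, 0), cnt(2, 1), cnt(2, 2))
        out[s:e] <- .r2FromHapFreqs(em)
    }
    out
}

#' Linkage-disequilibrium decay curve
#'
#' Sites failing the population MAF filter or the exact Hardy-Weinberg
#' filter (`p < hweAlpha`) are dropped; r-squared is computed for all
#' within-chromosome pairs separated by at most `maxDistance` and averaged
#' in distance bins.
#'
#' @param x A [GenotypeMatrix-class].
#' @param population Population label to analyse.
#' @param maxDistance Maximum pair separation in bp (default 1 Mb, the
#'   cited program's `maxdistance 1000` kb convention).
#' @param minMaf Minor-allele-frequency filter (strict `>`, default 0.05).
#' @param hweAlpha Hardy-Weinberg exact-test cutoff (default 0.001).
#' @param binWidth Distance bin width in bp (default 1 kb).
#' @return `data.frame` with `distance` (bin midpoint), `meanR2`,
#'   `nPairs`.
#' @export
ldDecay <- function(x, population, maxDistance = 1000000L, minMaf = 0.05,
                    hweAlpha = 0.001, binWidth = 1000L) {
    cols <- .popColumns(x, population)
    gt <- genotypes(x)[, cols, drop = FALSE]
    nGeno <- rowSums(!is.na(gt))
    p <- rowSums(gt, na.rm = TRUE) / (2 * pmax(nGeno, 1L))
    maf <- pmin(p, 1 - p)
    hwe <- hweExactP(rowSums(gt == 0L, na.rm = TRUE),
                     rowSums(gt == 1L, na.rm = TRUE),
                     rowSums(gt == 2L, na.rm = TRUE))
    keep <- nGeno >= 2L & maf > minMaf & hwe >= hweAlpha
    if (sum(keep) < 2L)
        stop("fewer than 2 sites pass the MAF/HWE filters")
    rr <- rowRanges(x)[keep]
    gt <- gt[keep, , drop = FALSE]
    pr <- .admissiblePairs(as.character(seqnames(rr)), start(rr),
                           maxDistance)
    if (!length(pr$i))
        stop("no SNP pairs within maxDistance")
    r2 <- .pairwiseR2(gt, pr$i, pr$j)
    dist <- start(rr)[pr$j] - start(rr)[pr$i]
    ok <- !is.na(r2)
    bin <- pmax(1L, ceiling(dist[ok] / binWidth))
    mean2 <- tapply(r2[ok], bin, mean)
    cnt <- tapply(r2[ok], bin, length)
    bins <- as.integer(names(mean2))
    out <- data.frame(distance = (bins - 0.5) * binWidth,
                      meanR2 = as.numeric(mean2),
                      nPairs = as.integer(cnt))
    out[order(out$distance), , drop = FALSE]
}

#' Distance at which LD decays to a threshold
#'
#' The smallest distance at which linear interpolation between adjacent
#' bin means crosses `threshold` from above.  Undefined (`NA`) when the
#' curve never exceeds the threshold or never drops to it.
#'
#' @param curve `data.frame` from [ldDecay()] (columns `distance`,
#'   `meanR2`).
#' @param threshold r-squared level (default 0.2).
#' @return Distance in bp, or `NA`.
#' @export
decayDistance <- function(curve, threshold = 0.2) {
    if (nrow(curve) == 0L)
        stop("empty decay curve")
    d <- curve$distance; r <- curve$meanR2
    for (i in seq_len(nrow(curve) - 1L)) {
        if (r[i] >= threshold && r[i + 1L] <= threshold) {
            if (r[i] == r[i + 1L])
                return(d[i])
            return(d[i] + (r[i] - threshold) / (r[i] - r[i + 1L]) *
                       (d[i + 1L] - d[i]))
        }
    }
    NA_real_
}
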