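## Cross-population composite-likelihood sweep scan: genetic-map
## interpolation, drift-variance estimation, drift-null and hitchhiking
## likelihoods, correlation down-weighting, grid scan, 10-kb tabulation and
## region calling with the pi-ratio cross-filter.

#' Interpolate genetic position from a physical position
#'
#' Piecewise-linear interpolation between genetic-map anchors; beyond the
#' terminal anchors (or with no map at all) positions are extrapolated at
#' `fallbackCMperMb`.
#'
#' @param bp Physical position(s) in bp.
#' @param map Optional `data.frame` with columns `chrom`, `bp`, `cM`
#'   (anchors, cM non-decreasing with bp within a chromosome).
#' @param chrom Chromosome of the query positions (required with a map).
#' @param fallbackCMperMb Uniform rate used without a map and beyond the
#'   terminal anchors (default 1 cM/Mb).
#' @return Genetic position(s) in Morgans.
#' @examples
#' interpolateGeneticPosition(250000)           # 0.0025 M at 1 cM/Mb
#' @export
interpolateGeneticPosition <- function(bp, map = NULL, chrom = NULL,
                                       fallbackCMperMb = 1.0) {
    if (any(bp < 0))
        stop("bp must be non-negative")
    rate <- fallbackCMperMb / 100 / 1e6          # Morgans per bp
    if (is.null(map))
        return(bp * rate)
    if (is.null(chrom))
        stop("chrom is required when a genetic map is supplied")
    chrom <- rep_len(as.character(chrom), length(bp))
    out <- numeric(length(bp))
    for (ch in unique(chrom)) {
        sel <- chrom == ch
        anchors <- map[map$chrom == ch, , drop = FALSE]
        if (nrow(anchors) == 0L) {
            out[sel] <- bp[sel] * rate
            next
        }
        anchors <- anchors[order(anchors$bp), , drop = FALSE]
        if (is.unsorted(anchors$cM))
            stop("genetic map cM must be non-decreasing with bp on ", ch)
        q <- bp[sel]
        g <- numeric(length(q))
        if (nrow(anchors) == 1L) {
            g <- anchors$cM[1] / 100 + (q - anchors$bp[1]) * rate
        } else {
            inside <- q >= anchors$bp[1] & q <= anchors$bp[nrow(anchors)]
            g[inside] <- approx(anchors$bp, anchors$cM, q[inside],
                                ties = "ordered")$y / 100
            lo <- q < anchors$bp[1]
            hi <- q > anchors$bp[nrow(anchors)]
            g[lo] <- anchors$cM[1] / 100 - (anchors$bp[1] - q[lo]) * rate
            g[hi] <- anchors$cM[nrow(anchors)] / 100 +
                (q[hi] - anchors$bp[nrow(anchors)]) * rate
        }
        out[sel] <- g
    }
    out
}

#' Estimate the drift variance scale omega
#'
#' Method-of-moments estimator of the variance of objective-population
#' allele frequencies around the reference frequencies, rescaled by
#' `p(1-p)` and corrected for binomial sampling noise:
#' `omega = mean[ ((x/n - p_ref)^2 - (x/n)(1 - x/n)/n) / (p_ref(1-p_ref)) ]`,
#' clipped below at 1e-6.
#'
#' @param pRef Reference-population allele frequencies (only SNPs with
#'   `0 < pRef < 1` are used).
#' @param altCounts Alt-allele counts in the objective population.
#' @param nAlleles Non-missing allele totals in the objective population.
#' @return The scalar omega estimate.
#' @export
estimateDriftVariance <- function(pRef, altCounts, nAlleles) {
    use <- pRef > 0 & pRef < 1 & nAlleles > 0
    if (sum(use) < 500L)
        stop("need at least 500 polymorphic reference SNPs to estimate omega")
    p <- pRef[use]
    ph <- altCounts[use] / nAlleles[use]
    num <- (ph - p)^2 - ph * (1 - ph) / nAlleles[use]
    max(mean(num / (p * (1 - p))), 1e-6)
}

## Normal drift law around p0 truncated to (0,1); the truncated tail
## masses sit as point masses at 0 and 1.  Interior integration uses K
## quantile nodes of the untruncated normal (mass-exact, so per-SNP
## likelihoods sum to one over x = 0..n, and stable as omega -> 0).
.nullLik <- function(x, n, p0, omega, K = 512L) {
    if (omega <= 0)
        stop("omega must be positive")
    if (p0 <= 0 || p0 >= 1)
        stop("p0 must lie in (0, 1)")
    sigma <- sqrt(omega * p0 * (1 - p0))
    F0 <- pnorm(0, p0, sigma)
    F1 <- pnorm(1, p0, sigma)
    M <- F1 - F0
    u <- F0 + (seq_len(K) - 0.5) / K * M
    pk <- qnorm(u, p0, sigma)
    pk <- pmin(pmax(pk, 1e-12), 1 - 1e-12)
    interior <- vapply(x, function(xi)
        sum(dbinom(xi, n, pk)) * M / K, numeric(1))
    F0 * as.numeric(x == 0) + (1 - F1) * as.numeric(x == n) + interior
}

#' Drift-null log-likelihood of an objective-population allele count
#'
#' The latent objective frequency follows `Normal(p0, omega * p0(1-p0))`
#' truncated to (0,1) with the truncated tail masses placed at 0 and 1;
#' the observed count is `Binomial(n, p1)` and the marginal likelihood is
#' obtained by numerical integration over the latent frequency.
#'
#' @param x Observed alt-allele count(s), `0 <= x <= n`.
#' @param n Number of sampled alleles.
#' @param p0 Reference-population frequency in (0, 1).
#' @param omega Drift variance scale (> 0).
#' @param integrationPoints Latent grid size (default 512).
#' @return Log-likelihood value(s).
#' @export
nullLoglik <- function(x, n, p0, omega, integrationPoints = 512L) {
    log(.nullLik(x, n, p0, omega, integrationPoints))
}

#' Hitchhiking escape probability
#'
#' Probability that a neutral lineage at genetic distance `d` recombines
#' off the sweeping haplotype: `c = 1 - exp(-d * ln(2 Ne s)/s)`, clipped
#' to `[0, 1]`; when `2 Ne s <= 1` there is no effective sweep and
#' `c = 1`.
#'
#' @param d Genetic distance(s) in Morgans (>= 0).
#' @param s Selection coefficient (> 0).
#' @param Ne Effective population size.
#' @return Escape probability(ies) in `[0, 1]`.
#' @export
escapeProbability <- function(d, s, Ne) {
    if (any(d < 0)) stop("d must be non-negative")
    if (any(s <= 0)) stop("s must be positive")
    if (2 * Ne * s <= 1)
        return(rep(1, length(d)))
    pmin(pmax(1 - exp(-d * log(2 * Ne * s) / s), 0), 1)
}

## Swept-branch likelihood: lineages escape the sweeping background
## independently with probability c, so the post-sweep frequency of the
## beneficial background is 1 - c(1 - p0) (and c*p0 for the lost
## background), bounded away from 0/1 by eps = 1/(2 Ne).  At c = 0 this
## reduces to point near-fixation/near-loss.  `cc` may be a vector or a
## matrix recycled against x/n/p0.
.sweptLik <- function(x, n, p0, Ne, cc = 0) {
    eps <- 1 / (2 * Ne)
    qhi <- pmin(1 - cc * (1 - p0), 1 - eps)
    qlo <- pmax(cc * p0, eps)
    if (is.matrix(cc)) {
        S <- ncol(cc)
        matrix(p0 * dbinom(rep(x, S), rep(n, S), as.vector(qhi)) +
                   (1 - p0) * dbinom(rep(x, S), rep(n, S), as.vector(qlo)),
               nrow(cc), S)
    } else {
        p0 * dbinom(x, n, qhi) + (1 - p0) * dbinom(x, n, qlo)
    }
}

#' Sweep-model log-likelihood
#'
#' Mixture over the hitchhiking outcome: with probability `c` (escape) the
#' latent frequency follows the drift null; with probability `1 - c` the
#' site hitchhikes — the beneficial background (probability `p0`) carries
#' the derived allele to frequency `1 - c(1 - p0)` (escaping lineages
#' retain the reference frequency), the lost background (probability
#' `1 - p0`) leaves it at `c * p0`; both are bounded away from 0/1 by
#' `eps = 1/(2 Ne)`, so at `c = 0` the branch degenerates to
#' near-fixation/near-loss.  At `c = 1` the whole mixture reduces exactly
#' to [nullLoglik()].
#'
#' @inheritParams nullLoglik
#' @param c Escape probability in `[0, 1]` (see [escapeProbability()]).
#' @param Ne Effective population size.
#' @return Log-likelihood value(s).
#' @export
sweepLoglik <- function(x, n, p0, omega, c, Ne = 10000,
                        integrationPoints = 512L) {
    if (any(c < 0) || any(c > 1))
        stop("c must lie in [0, 1]")
    Lnull <- .nullLik(x, n, p0, omega, integrationPoints)
    Lsw <- .sweptLik(x, n, p0, Ne, c)
    log(c * Lnull + (1 - c) * Lsw)
}

## 1/m down-weighting: m_i = number of kept SNPs (including self) whose
## reference-population dosage correlation squared exceeds corrThreshold.
.snpWeights <- function(refDosage, corrThreshold) {
    m <- nrow(refDosage)
    if (m == 1L) return(1)
    cm <- suppressWarnings(cor(t(refDosage)))
    r2 <- cm * cm
    r2[is.na(r2)] <- 0
    diag(r2) <- 1
    1 / pmax(rowSums(r2 > corrThreshold), 1)
}

## Core composite score at one grid point.
## d: genetic distances (M); w: weights; lnull: per-SNP null log-lik;
## Lnull: per-SNP null likelihoods; x/n/p0: per-SNP data.
## Returns 2*max(0, max_s sum_i w_i dLL).
.clrScore <- function(d, w, lnull, Lnull, x, n, p0, sGrid, Ne) {
    ok <- 2 * Ne * sGrid > 1
    sfac <- ifelse(ok, log(2 * Ne * sGrid) / sGrid, 0)
    cc <- 1 - exp(-outer(d, sfac))            # m x S escape probabilities
    cc[cc > 1] <- 1; cc[cc < 0] <- 0
    if (any(!ok))
        cc[, !ok] <- 1                        # no effective sweep: null law
    Lsw <- .sweptLik(x, n, p0, Ne, cc)        # m x S
    ll <- log(cc * Lnull + (1 - cc) * Lsw)    # recycle per column
    scores <- colSums(w * (ll - lnull))
    best <- which.max(scores)
    clr <- 2 * max(0, scores[best])
    list(clr = clr,
         sHat = if (scores[best] > 0) sGrid[best] else NA_real_)
}

## Prepare per-SNP quantities for the scan from a GenotypeMatrix.
.prepareScanSnps <- function(x, model, map, refPop, objPop) {
    refCols <- .popColumns(x, refPop)
    objCols <- .popColumns(x, objPop)
    gt <- genotypes(x)
    ref <- gt[, refCols, drop = FALSE]
    obj <- gt[, objCols, drop = FALSE]
    nRef <- 2L * rowSums(!is.na(ref))
    p0 <- rowSums(ref, na.rm = TRUE) / pmax(nRef, 1L)
    n <- 2L * rowSums(!is.na(obj))
    xcnt <- rowSums(obj, na.rm = TRUE)
    keep <- p0 > 0 & p0 < 1 & n > 0
    rr <- rowRanges(x)[keep]
    refImp <- ref[keep, , drop = FALSE]
    rm <- rowMeans(refImp, na.rm = TRUE)
    idx <- which(is.na(refImp))
    if (length(idx))
        refImp[idx] <- rm[(idx - 1L) %% nrow(refImp) + 1L]
    chrom <- as.character(seqnames(rr))
    gpos <- interpolateGeneticPosition(start(rr), map, chrom)
    list(chrom = chrom, pos = start(rr), gpos = gpos,
         p0 = p0[keep], x = xcnt[keep], n = n[keep], refDosage = refImp,
         nDropped = sum(!keep))
}

#' Composite likelihood ratio at a single grid point
#'
#' Collects the SNPs within `windowMorgans/2` of the grid point in genetic
#' distance (at most `maxSnps`, keeping the nearest), down-weights
#' correlated SNPs by `1/m`, and maximises the summed weighted
#' log-likelihood ratio of the sweep model over the selection grid.
#'
#' @param posBp Physical grid position in bp.
#' @param snps `data.frame`/list with per-SNP `pos`, `p0` (reference
#'   frequency), `x` (objective alt count), `n` (objective allele total),
#'   and optionally `gpos` (Morgans).
#' @param model A [SweepModel-class] (its `omega` must be set).
#' @param map Optional genetic map (see [interpolateGeneticPosition()]).
#' @param chrom Chromosome of `posBp` when a map is used.
#' @param refGeno Optional reference-population dosage matrix (rows =
#'   the SNPs in `snps`) used for correlation down-weighting; without it
#'   all weights are 1.
#' @return List with `clr`, `sHat` and `nSnps` (`clr = NA` when the
#'   window holds no SNP).
#' @export
clrAtGridpoint <- function(posBp, snps, model, map = NULL, chrom = NULL,
                           refGeno = NULL) {
    if (is.na(model@omega))
        stop("model@omega must be set (see estimateDriftVariance)")
    gpos <- snps$gpos
    if (is.null(gpos))
        gpos <- interpolateGeneticPosition(snps$pos, map, chrom)
    g0 <- interpolateGeneticPosition(posBp, map, chrom)
    d <- abs(gpos - g0)
    sel <- which(d <= model@windowMorgans / 2)
    if (!length(sel))
        return(list(clr = NA_real_, sHat = NA_real_, nSnps = 0L))
    if (length(sel) > model@maxSnps)
        sel <- sel[order(d[sel])[seq_len(model@maxSnps)]]
    w <- if (is.null(refGeno)) rep(1, length(sel))
         else .snpWeights(refGeno[sel, , drop = FALSE], model@corrThreshold)
    lnull <- vapply(seq_along(sel), function(k)
        nullLoglik(snps$x[sel[k]], snps$n[sel[k]], snps$p0[sel[k]],
                   model@omega, model@integrationPoints), numeric(1))
    sc <- .clrScore(d[sel], w, lnull, exp(lnull), snps$x[sel],
                    snps$n[sel], snps$p0[sel], model@sGrid, model@Ne)
    list(clr = sc$clr, sHat = sc$sHat, nSnps = length(sel))
}

#' Genome-wide composite-likelihood sweep scan
#'
#' Evaluates the cross-population composite likelihood ratio on a regular
#' physical grid (`gridBp` spacing), contrasting allele-frequency
#' differentiation of the objective population against the drift null
#' relative to the reference population.  When `model@omega` is `NA` it is
#' first estimated genome-wide with [estimateDriftVariance()].
#'
#' @param x A [GenotypeMatrix-class].
#' @param model A [SweepModel-class].
#' @param map Optional genetic map `data.frame` (`chrom`, `bp`, `cM`).
#' @param refPop,objPop Population labels: the reference (wild progenitor)
#'   supplies baseline frequencies; sweeps are sought in the objective
#'   (cultivated) population.
#' @return `GRanges` of grid points with metadata `value` (CLR), `sHat`
#'   and `nSnps`; `metadata()` records the omega used.
#' @export
clrScan <- function(x, model = SweepModel(), map = NULL,
                    refPop = "wild_progenitor", objPop = "cultivated") {
    sn <- .prepareScanSnps(x, model, map, refPop, objPop)
    omega <- model@omega
    if (is.na(omega))
        omega <- estimateDriftVariance(sn$p0, sn$x, sn$n)
    K <- model@integrationPoints
    nS <- length(sn$p0)
    lnull <- numeric(nS)
    for (i in seq_len(nS))
        lnull[i] <- log(.nullLik(sn$x[i], sn$n[i], sn$p0[i], omega, K))
    Lnull <- exp(lnull)

    chromLens <- .chromLengths(x)
    half <- model@windowMorgans / 2
    outChrom <- character(0); outPos <- integer(0)
    outClr <- outShat <- numeric(0); outN <- integer(0)
    for (ch in names(chromLens)) {
        si <- which(sn$chrom == ch)
        if (!length(si)) next
        g <- sn$gpos[si]
        gridPos <- seq.int(1L, chromLens[[ch]], by = model@gridBp)
        g0 <- interpolateGeneticPosition(gridPos, map, ch)
        lo <- findInterval(g0 - half, g) + 1L
        hi <- findInterval(g0 + half, g)
        hasSnp <- hi >= lo
        gridPos <- gridPos[hasSnp]
        g0 <- g0[hasSnp]; lo <- lo[hasSnp]; hi <- hi[hasSnp]
        nP <- length(gridPos)
        clr <- shat <- numeric(nP); nn <- integer(nP)
        wCache <- new.env(parent = emptyenv())
        for (k in seq_len(nP)) {
            a <- lo[k]; b <- hi[k]
            while (b - a + 1L > model@maxSnps) {
                if (g0[k] - g[a] >= g[b] - g0[k]) a <- a + 1L
                else b <- b - 1L
            }
            key <- paste0(a, "_", b)
            w <- wCache[[key]]
            if (is.null(w)) {
                w <- .snpWeights(sn$refDosage[si[a:b], , drop = FALSE],
                                 model@corrThreshold)
                wCache[[key]] <- w
            }
            kk <- si[a:b]
            sc <- .clrScore(abs(g[a:b] - g0[k]), w, lnull[kk], Lnull[kk],
                            sn$x[kk], sn$n[kk], sn$p0[kk],
                            model@sGrid, model@Ne)
            clr[k] <- sc$clr; shat[k] <- sc$sHat; nn[k] <- b - a + 1L
        }
        outChrom <- c(outChrom, rep(ch, nP))
        outPos <- c(outPos, gridPos)
        outClr <- c(outClr, clr); outShat <- c(outShat, shat)
        outN <- c(outN, nn)
    }
    out <- GRanges(outChrom, IRanges(outPos, width = 1L),
                   value = outClr, sHat = outShat, nSnps = outN)
    seqlengths(out) <- chromLens[seqlevels(out)]
    metadata(out) <- list(statistic = "clr", omega = omega,
                          nSnpsUsed = nS, nSnpsDropped = sn$nDropped)
    out
}

#' Tabulate a CLR grid track into non-overlapping windows
#'
#' Window value is the maximum CLR over the grid points it contains;
#' windows with no grid point are undefined.
#'
#' @param clrTrack `GRanges` from [clrScan()].
#' @param windowSize Window size in bp (default 10 kb).
#' @return `GRanges` of non-overlapping windows with `value` and
#'   `defined`.
#' @export
tabulateWindows <- function(clrTrack, windowSize = 10000L) {
    sl <- seqlengths(clrTrack)
    chroms <- seqlevels(clrTrack)
    outs <- lapply(chroms, function(ch) {
        sel <- as.character(seqnames(clrTrack)) == ch
        pos <- start(clrTrack)[sel]
        val <- clrTrack$value[sel]
        len <- sl[[ch]]
        if (is.na(len)) len <- max(pos)
        starts <- seq.int(0L, max(0L, len - 1L), by = windowSize)
        wi <- findInterval(pos - 1L, starts)
        vals <- rep(NA_real_, length(starts))
        agg <- tapply(val, wi, function(v)
            if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE))
        vals[as.integer(names(agg))] <- as.numeric(agg)
        list(ch = ch, starts = starts, len = len, vals = vals)
    })
    out <- GRanges(
        rep(vapply(outs, `[[`, character(1), "ch"),
            vapply(outs, function(o) length(o$starts), integer(1))),
        IRanges(unlist(lapply(outs, `[[`, "starts")) + 1L,
                pmin(unlist(lapply(outs, `[[`, "starts")) + windowSize,
                     rep(vapply(outs, `[[`, numeric(1), "len"),
                         vapply(outs, function(o) length(o$starts),
                                integer(1))))),
        value = unlist(lapply(outs, `[[`, "vals")))
    out$defined <- !is.na(out$value)
    if (!all(is.na(sl)))
        seqlengths(out) <- sl[seqlevels(out)]
    metadata(out) <- list(statistic = "clrWindows", windowSize = windowSize)
    out
}

#' Call sweep regions from tabulated CLR windows
#'
#' (1) Windows in the top `topGroup` fraction of defined CLR values are
#' thresholded; (2) passing windows that overlap or abut are merged into
#' regions scored by their maximum member window; (3) regions whose score
#' reaches the top `topRegion` quantile of window values are retained;
#' (4) regions that do not overlap any window in the top `piTop` fraction
#' of the pi-ratio track are excluded (diversity-reduction cross-filter).
#'
#' @param clrWindows `GRanges` from [tabulateWindows()].
#' @param piRatioTrack `GRanges` from [piRatio()].
#' @param topGroup Grouping quantile fraction (default 0.03).
#' @param topRegion Region-call quantile fraction (default 0.01, applied
#'   on the window-value scale).
#' @param piTop Pi-ratio overlap fraction (default 0.50; `>= 1` disables
#'   the filter).
#' @return Sorted `GRanges` of sweep regions with `score` and `nWindows`.
#' @export
callSweeps <- function(clrWindows, piRatioTrack, topGroup = 0.03,
                       topRegion = 0.01, piTop = 0.50) {
    vals <- clrWindows$value[clrWindows$defined]
    if (!length(vals))
        stop("no defined CLR windows")
    regions <- topQuantileRegions(clrWindows, topGroup, positiveOnly = TRUE)
    if (length(regions) == 0L)
        return(regions)
    thr1 <- .upperThreshold(vals, topRegion)
    regions <- regions[regions$score >= thr1]
    if (length(regions) == 0L || piTop >= 1)
        return(regions)
    piVals <- piRatioTrack$value
    if (all(!is.finite(piVals)))
        stop("pi-ratio track has no defined windows")
    piThr <- .upperThreshold(piVals, piTop)
    qualifying <- piRatioTrack[!is.na(piVals) & piVals >= piThr]
    keep <- countOverlaps(regions, qualifying, minoverlap = 1L) > 0L
    regions[keep]
}
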