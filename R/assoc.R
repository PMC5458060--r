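## Stratification-adjusted association for a quantitative phenotype:
## genotype normalization, principal components, residual-correlation
## chi-squared statistic.

#' Normalize a genotype matrix for PCA and association
#'
#' Per site: missing dosages are imputed to the site mean, the mean is
#' subtracted and the column is scaled by `sqrt(p(1-p))` with
#' `p = mean dosage / 2`.  Monomorphic (or all-missing) sites are dropped.
#'
#' @param x A [GenotypeMatrix-class] or a sites x samples dosage matrix.
#' @return List with `mat` (normalized sites x samples matrix, imputed),
#'   `imputed` (mean-imputed but unscaled dosages), and `kept` (row
#'   indices of retained sites).
#' @export
normalizeGenotypes <- function(x) {
    gt <- if (is(x, "GenotypeMatrix")) genotypes(x) else as.matrix(x)
    storage.mode(gt) <- "double"
    rm <- rowMeans(gt, na.rm = TRUE)
    idx <- which(is.na(gt))
    if (length(idx))
        gt[idx] <- rm[(idx - 1L) %% nrow(gt) + 1L]
    p <- rm / 2
    keep <- which(!is.na(p) & p > 0 & p < 1)
    if (length(keep) < nrow(gt))
        message(nrow(gt) - length(keep),
                " monomorphic or all-missing site(s) dropped")
    m <- gt[keep, , drop = FALSE] - rm[keep]
    m <- m / sqrt(p[keep] * (1 - p[keep]))
    list(mat = m, imputed = gt[keep, , drop = FALSE], kept = keep)
}

#' Principal components of a normalized genotype matrix
#'
#' Eigendecomposition of the sample-by-sample covariance of the normalized
#' matrix.  Axes are unit-norm eigenvectors; the sign is fixed so that the
#' largest-magnitude coordinate of each axis is positive.
#'
#' @param normMat Normalized sites x samples matrix (from
#'   [normalizeGenotypes()]).
#' @param k Number of axes (default 10).
#' @return List with `vectors` (samples x k orthonormal axes), `values`
#'   (all eigenvalues, non-increasing) and `k`.
#' @export
computePCA <- function(normMat, k = 10L) {
    n <- ncol(normMat)
    if (k >= n)
        stop("k must be smaller than the number of samples")
    cov <- crossprod(normMat) / nrow(normMat)
    eig <- eigen(cov, symmetric = TRUE)
    vec <- eig$vectors[, seq_len(k), drop = FALSE]
    for (j in seq_len(ncol(vec))) {
        i <- which.max(abs(vec[, j]))
        if (vec[i, j] < 0)
            vec[, j] <- -vec[, j]
    }
    rownames(vec) <- colnames(normMat)
    list(vectors = vec, values = eig$values, k = as.integer(k))
}

## Orthonormal basis of span(1, axes); residualization helper.
.axisBasis <- function(n, axes) {
    X <- cbind(rep(1, n), axes)
    qr.Q(qr(X))[, seq_len(qr(X)$rank), drop = FALSE]
}

.residualize <- function(v, Q) {
    v - Q %*% crossprod(Q, v)
}

#' Stratification-adjusted association statistic for one SNP
#'
#' Residualizes both the genotype and the phenotype on the top principal
#' axes (plus an intercept) and forms `stat = (n - k - 1) * rho^2`, where
#' `rho` is the correlation of the two residual vectors; the p-value is
#' the upper chi-squared(1) tail.  With `axes = NULL` (k = 0) this is the
#' quantitative-trait trend test on the raw correlation.
#'
#' @param genotype Dosage vector (mean-imputed or with `NA`s, which are
#'   imputed here).
#' @param phenotype Numeric phenotype vector.
#' @param axes Samples x k matrix of principal axes, or `NULL`.
#' @return List with `stat`, `p`, `sign` (effect sign) and
#'   `zeroVariance`.
#' @export
eigenstratStat <- function(genotype, phenotype, axes = NULL) {
    g <- as.numeric(genotype)
    if (anyNA(g))
        g[is.na(g)] <- mean(g, na.rm = TRUE)
    y <- as.numeric(phenotype)
    n <- length(y)
    k <- if (is.null(axes)) 0L else ncol(axes)
    Q <- .axisBasis(n, axes)
    gr <- .residualize(g, Q)
    yr <- .residualize(y, Q)
    sg <- sqrt(sum(gr^2)); sy <- sqrt(sum(yr^2))
    if (sg < 1e-12 || sy < 1e-12)
        return(list(stat = 0, p = 1, sign = 0, zeroVariance = TRUE))
    rho <- sum(gr * yr) / (sg * sy)
    stat <- (n - k - 1) * rho^2
    list(stat = stat, p = pchisq(stat, df = 1, lower.tail = FALSE),
         sign = sign(rho), zeroVariance = FALSE)
}

#' Genome-wide association scan for a quantitative trait
#'
#' Computes the stratification-adjusted statistic at every polymorphic SNP
#' using the top `k` principal components of the same SNP set, and flags
#' SNPs with `p < alpha` (no multiple-testing correction; a fixed
#' threshold is applied).
#'
#' @param x A [GenotypeMatrix-class].
#' @param phenotype Named numeric vector (names = samples) or
#'   `data.frame` with columns `sample` and a value column (e.g. `days`).
#' @param k Number of principal components to adjust for (default 10).
#' @param alpha Significance threshold on the p-value (default 1e-4).
#' @return `data.frame` with `chrom`, `pos`, `stat`, `p`, `sign`,
#'   `significant`, one row per tested SNP; the PCA is attached as
#'   attribute `"pca"`.
#' @export
gwasScan <- function(x, phenotype, k = 10L, alpha = 1e-4) {
    if (is.data.frame(phenotype)) {
        valueCol <- setdiff(names(phenotype), "sample")[1]
        phenotype <- setNames(phenotype[[valueCol]], phenotype$sample)
    }
    common <- intersect(colnames(x), names(phenotype))
    if (length(common) < 20L)
        warning("fewer than 20 phenotyped samples; the scan is underpowered")
    xs <- x[, common]
    y <- as.numeric(phenotype[common])
    norm <- normalizeGenotypes(xs)
    n <- length(y)
    pca <- computePCA(norm$mat, k = k)
    Q <- .axisBasis(n, pca$vectors)
    G <- norm$imputed
    Gr <- G - (G %*% Q) %*% t(Q)
    yr <- as.numeric(.residualize(y, Q))
    sy <- sqrt(sum(yr^2))
    sg <- sqrt(rowSums(Gr^2))
    rho <- as.numeric(Gr %*% yr) / (sg * sy)
    zero <- sg < 1e-12 | sy < 1e-12
    rho[zero] <- 0
    stat <- (n - k - 1) * rho^2
    p <- pchisq(stat, df = 1, lower.tail = FALSE)
    p[zero] <- 1
    rr <- rowRanges(xs)[norm$kept]
    out <- data.frame(chrom = as.character(seqnames(rr)),
                      pos = start(rr),
                      stat = stat, p = p, sign = sign(rho),
                      significant = p < alpha)
    attr(out, "pca") <- pca
    attr(out, "alpha") <- alpha
    out
}

#' Manhattan-style plot of an association scan
#'
#' Simple base-graphics Manhattan plot of `-log10(p)` with the
#' significance threshold drawn as a dashed line.
#'
#' @param assoc Result of [gwasScan()].
#' @param alpha Threshold line (default: the scan's alpha).
#' @return Invisibly, `NULL`.
#' @export
plotManhattan <- function(assoc, alpha = attr(assoc, "alpha")) {
    if (is.null(alpha)) alpha <- 1e-4
    chroms <- unique(assoc$chrom)
    offset <- 0
    xs <- numeric(nrow(assoc))
    for (ch in chroms) {
        sel <- assoc$chrom == ch
        xs[sel] <- assoc$pos[sel] + offset
        offset <- offset + max(assoc$pos[sel])
    }
    graphics::plot(xs, -log10(assoc$p),
                   col = (match(assoc$chrom, chroms) %% 2) + 1,
                   pch = 20, cex = 0.4, xlab = "genome position",
                   ylab = expression(-log[10](italic(p))))
    graphics::abline(h = -log10(alpha), lty = 2)
    invisible(NULL)
}
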