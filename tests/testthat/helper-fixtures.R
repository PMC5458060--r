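suppressPackageStartupMessages({
    library(GenomicRanges)
    library(IRanges)
    library(SummarizedExperiment)
})

## Heavy fixtures are computed once per test run and shared across files.
.fixtures <- new.env(parent = emptyenv())

## The canonical study simulation: the default configuration at seed 1.
defaultSim <- function() {
    if (is.null(.fixtures$sim))
        .fixtures$sim <- simulatePopulations(SimConfig(seed = 1L))
    .fixtures$sim
}

## Full pipeline products on the canonical simulation.
defaultScan <- function() {
    if (is.null(.fixtures$scan)) {
        sim <- defaultSim()
        .fixtures$scan <- suppressMessages(
            runDomesticationScan(genotypes(sim), phenotypes(sim)))
    }
    .fixtures$scan
}

## Structured fixture for stratification tests: two populations with a
## phenotype shift along population membership but no genetic effect.
structuredNull <- function(nSites = 5000L, nPer = 30L, shift = 3,
                           seed = 70L) {
    if (is.null(.fixtures$structNull)) {
        cfg <- SimConfig(nSites = nSites, nWild = nPer, nCult = nPer,
                         sweeps = GRanges(), FWild = 0.05, FCult = 0.10,
                         chromLengths = c(chr1 = 3e6, chr2 = 3e6),
                         seed = seed)
        sim <- simulatePopulations(cfg)
        gm <- filterMafMissing(genotypes(sim))
        y <- withr::with_seed(71L, {
            60 + shift * (populations(gm) == "cultivated") +
                rnorm(ncol(gm), 0, 2)
        })
        .fixtures$structNull <- list(gm = gm, y = setNames(y, colnames(gm)))
    }
    .fixtures$structNull
}

## Small GenotypeMatrix builder for toy cases.
toyGM <- function(gt, pos = seq_len(nrow(gt)) * 100L, chrom = "chr1",
                  population = rep("cultivated", ncol(gt)),
                  ref = rep("A", nrow(gt)), alt = rep("G", nrow(gt)),
                  chromLengths = NULL, ...) {
    GenotypeMatrix(chrom = chrom, pos = as.integer(pos), ref = ref,
                   alt = alt, genotypes = gt, population = population,
                   chromLengths = chromLengths, ...)
}

randomDosages <- function(nSites, nSamples, p = NULL, missing = 0) {
    if (is.null(p))
        p <- runif(nSites, 0.1, 0.9)
    g <- matrix(rbinom(nSites * nSamples, 2, rep(p, nSamples)),
                nSites, nSamples)
    if (missing > 0)
        g[runif(length(g)) < missing] <- NA
    g
}

## ---- independent oracles ------------------------------------------------

## Brute-force per-site pi: enumerate every pair of non-missing alleles.
oracleSitePi <- function(dosages) {
    ## explicit allele expansion: dosage d contributes alleles (0,0), (0,1)
    ## or (1,1)
    alleles <- unlist(lapply(dosages[!is.na(dosages)], function(d)
        switch(d + 1L, c(0L, 0L), c(0L, 1L), c(1L, 1L))))
    n <- length(alleles)
    if (n < 2L) return(NA_real_)
    diffs <- 0L
    for (i in seq_len(n - 1L))
        for (j in (i + 1L):n)
            diffs <- diffs + as.integer(alleles[i] != alleles[j])
    diffs / (n * (n - 1) / 2)
}

## Direct transcription of the Weir & Cockerham (1984) diploid two-allele
## variance components for r = 2 populations, scalar arithmetic only.
oracleWC <- function(dos1, dos2) {
    ni <- c(sum(!is.na(dos1)), sum(!is.na(dos2)))
    if (any(ni < 2)) return(c(a = NA_real_, b = NA_real_, c = NA_real_))
    pi <- c(sum(dos1, na.rm = TRUE) / (2 * ni[1]),
            sum(dos2, na.rm = TRUE) / (2 * ni[2]))
    hi <- c(sum(dos1 == 1, na.rm = TRUE) / ni[1],
            sum(dos2 == 1, na.rm = TRUE) / ni[2])
    r <- 2
    nbar <- mean(ni)
    CV2 <- sum((ni - nbar)^2) / (r * nbar^2)   # squared CV of sample sizes
    nc <- nbar * (1 - CV2)                      # equals the 1984 n_c
    pbar <- sum(ni * pi) / (r * nbar)
    s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(ni * hi) / (r * nbar)
    a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
        (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
        ((2 * nbar - 1) / (4 * nbar)) * hbar)
    cc <- hbar / 2
    c(a = a, b = b, c = cc)
}

## Exhaustive exact Hardy-Weinberg p-value: enumerate every genotype table
## compatible with the observed allele counts and sum the probabilities of
## the tables no more probable than the observed one.
oracleHwe <- function(nAA, nAa, naa) {
    n <- nAA + nAa + naa
    nA <- 2 * nAA + nAa                        # "A" allele count
    if (nA == 0 || nA == 2 * n) return(1)
    hets <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
    prob <- vapply(hets, function(h) {
        aa <- (nA - h) / 2
        bb <- n - aa - h
        exp(lfactorial(n) - lfactorial(aa) - lfactorial(h) -
                lfactorial(bb) + h * log(2) -
                (lfactorial(2 * n) - lfactorial(nA) -
                     lfactorial(2 * n - nA)))
    }, numeric(1))
    pObs <- prob[match(nAa, hets)]
    sum(prob[prob <= pObs * (1 + 1e-9)])
}

## Dense-grid brute-force integration of the drift-null likelihood.
oracleNullLik <- function(x, n, p0, omega, K = 100000L) {
    sigma <- sqrt(omega * p0 * (1 - p0))
    m0 <- pnorm(0, p0, sigma)
    m1 <- 1 - pnorm(1, p0, sigma)
    pk <- (seq_len(K) - 0.5) / K
    interior <- sum(dnorm(pk, p0, sigma) * dbinom(x, n, pk)) / K
    m0 * (x == 0) + m1 * (x == n) + interior
}

## Allele-relabelled copy of a dosage matrix at the given sites.
relabelSites <- function(gt, sites) {
    gt[sites, ] <- 2L - gt[sites, ]
    gt
}
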