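test_that("Balding-Nichols frequencies honour the zero-drift limit and the seed", {
    cfg <- SimConfig(nSites = 500L, FWild = 0, FCult = 0, seed = 5L)
    fr <- simulateFrequencies(cfg)
    expect_identical(fr$pWild, fr$pAnc)
    expect_identical(fr$pCult, fr$pAnc)
    expect_true(all(fr$pAnc >= 0.05 & fr$pAnc <= 0.95))

    cfg2 <- SimConfig(nSites = 500L, seed = 5L)
    expect_identical(simulateFrequencies(cfg2), simulateFrequencies(cfg2))

    expect_error(simulateFrequencies(SimConfig(seed = 1L, FCult = 0.2),
                                     seed = 1L), NA)
})

test_that("drifted frequencies satisfy the Beta variance identity", {
    cfg <- SimConfig(nSites = 20000L, FWild = 0, FCult = 0.05, seed = 8L)
    fr <- simulateFrequencies(cfg)
    ratio <- mean((fr$pCult - fr$pAnc)^2 / (fr$pAnc * (1 - fr$pAnc)))
    expect_lt(abs(ratio - 0.05), 0.01)
})

test_that("invalid drift parameters are rejected", {
    expect_error(SimConfig(FCult = 1.0), "F must lie")
    expect_error(SimConfig(FWild = -0.1), "F must lie")
})

test_that("haplotype marginals match the target frequencies", {
    set.seed(2)
    p <- runif(800, 0.1, 0.9)
    pos <- sort(sample.int(4e5, 800))
    hap <- simulateHaplotypes(p, "chr1", pos, 400L, 2000, seed = 3L)
    se <- sqrt(p * (1 - p) / 400)
    within <- abs(rowMeans(hap) - p) <= 3 * se
    expect_gte(mean(within), 0.99)
})

test_that("copying scale controls linkage between sites", {
    ## huge scale + equal frequencies: sites are duplicates
    hap <- simulateHaplotypes(c(0.4, 0.4), "chr1", c(100L, 200L), 400L,
                              1e12, seed = 4L)
    dos <- hap[, seq(1, 400, 2)] + hap[, seq(2, 400, 2)]
    expect_equal(r2Pair(dos[1, ], dos[2, ]), 1)

    ## vanishing scale: adjacent-site r2 sits at the finite-sample baseline
    ## obtained by permuting one site's samples
    set.seed(9)
    p <- runif(400, 0.2, 0.8)
    pos <- seq(100L, by = 100L, length.out = 400)
    hap0 <- simulateHaplotypes(p, "chr1", pos, 120L, 0, seed = 10L)
    dos0 <- hap0[, seq(1, 120, 2)] + hap0[, seq(2, 120, 2)]
    obs <- vapply(seq_len(399), function(j)
        r2Pair(dos0[j, ], dos0[j + 1, ]), numeric(1))
    perm <- vapply(seq_len(399), function(j)
        r2Pair(dos0[j, ], dos0[j + 1, sample.int(60)]), numeric(1))
    expect_lt(abs(mean(obs, na.rm = TRUE) - mean(perm, na.rm = TRUE)), 0.02)
})

test_that("planted sweeps distort cultivated haplotypes as specified", {
    p <- rep(0.5, 100)
    pos <- seq(1000L, by = 500L, length.out = 100)
    hap <- simulateHaplotypes(p, "chr1", pos, 200L, 0, seed = 6L)
    sweep0 <- GRanges("chr1", IRanges(1L, 60000L), intensity = 1e-9)
    expect_identical(applySweeps(hap, "chr1", pos, sweep0, seed = 1L), hap)

    sweep1 <- GRanges("chr1", IRanges(1L, 60000L), intensity = 1)
    h1 <- applySweeps(hap, "chr1", pos, sweep1, seed = 1L)
    expect_true(all(h1 == 1L))

    sweep9 <- GRanges("chr1", IRanges(1L, 60000L), intensity = 0.9)
    h9 <- applySweeps(hap, "chr1", pos, sweep9, seed = 2L)
    ## mixture expectation 0.9 + 0.1 * p = 0.95 per interior site
    expect_gte(mean(h9), 0.95 - 3 * sqrt(0.05 * 0.95 / 200))

    outside <- GRanges("chr1", IRanges(70000L, 90000L), intensity = 1)
    expect_error(applySweeps(hap, "chr1", pos, outside,
                             chromLengths = c(chr1 = 80000)),
                 "outside the genome")
})

test_that("read-depth evidence reproduces truth at high depth and masks at random", {
    dos <- randomDosages(300, 20)
    d <- simulateReadDepths(dos, meanDepth = 1000, missingRate = 0,
                            seed = 11L)
    calls <- callGenotypesFromDepths(d$ref, d$alt)
    expect_gt(mean(calls == dos), 0.999)

    d1 <- simulateReadDepths(dos, meanDepth = 20, missingRate = 1,
                             seed = 12L)
    expect_true(all(d1$ref + d1$alt == 0L))
    expect_true(all(is.na(callGenotypesFromDepths(d1$ref, d1$alt))))

    ## Poisson tail: at mean depth 0.5 the fraction of entries with < 3
    ## reads matches ppois(2, 0.5)
    d2 <- simulateReadDepths(randomDosages(400, 40), meanDepth = 0.5,
                             missingRate = 0, seed = 13L)
    frac <- mean(d2$ref + d2$alt < 3)
    expect_lt(abs(frac - ppois(2, 0.5)), 0.01)

    expect_error(simulateReadDepths(dos, meanDepth = 0), "positive")
})

test_that("phenotype generation follows the linear model", {
    dos <- rep(c(0, 1, 2), each = 20)
    y0 <- simulatePhenotype(dos, effect = 5, residSd = 0, baseline = 60,
                            seed = 14L)
    expect_equal(unique(y0), c(60, 65, 70))

    y <- simulatePhenotype(dos, effect = 5, residSd = 2, seed = 15L)
    fit <- lm(y ~ dos)
    expect_lt(abs(coef(fit)[["dos"]] - 5), 1)

    expect_warning(simulatePhenotype(rep(1, 10), 5, 1, seed = 1L),
                   "monomorphic")

    ## zero effect: phenotype carries no association signal
    g <- randomDosages(400, 40)
    yn <- suppressWarnings(simulatePhenotype(rep(0, 40), effect = 0,
                                             residSd = 2, seed = 16L))
    ps <- vapply(seq_len(400), function(j)
        eigenstratStat(g[j, ], yn)$p, numeric(1))
    expect_gt(mean(ps < 0.05), 0.01)
    expect_lt(mean(ps < 0.05), 0.10)
})

test_that("simulated studies are deterministic and internally consistent", {
    cfg <- SimConfig(nSites = 400L, chromLengths = c(chr1 = 2e5, chr2 = 2e5),
                     sweeps = GRanges("chr1", IRanges(50001L, 62000L),
                                      intensity = 0.9),
                     seed = 17L)
    s1 <- simulatePopulations(cfg)
    s2 <- simulatePopulations(cfg)
    expect_identical(genotypes(genotypes(s1)), genotypes(genotypes(s2)))
    expect_identical(phenotypes(s1), phenotypes(s2))
    expect_identical(truth(s1)@pCult, truth(s2)@pCult)

    ## SNPs land only inside genic intervals
    rr <- rowRanges(genotypes(s1))
    expect_true(all(overlapsAny(rr, simConfig(s1)@genicIntervals)))
    ## truth sweeps equal the configured intervals
    expect_identical(ranges(sweepRegions(s1)), ranges(cfg@sweeps))
})

test_that("written outputs round-trip and are byte-deterministic", {
    cfg <- SimConfig(nSites = 300L, chromLengths = c(chr1 = 2e5, chr2 = 2e5),
                     sweeps = GRanges("chr2", IRanges(30001L, 42000L),
                                      intensity = 0.95),
                     seed = 18L)
    sim <- simulatePopulations(cfg)
    d1 <- file.path(tempdir(), "simout1")
    d2 <- file.path(tempdir(), "simout2")
    p1 <- writeSimOutputs(sim, d1)
    p2 <- writeSimOutputs(simulatePopulations(cfg), d2)
    for (f in names(p1))
        expect_identical(unname(tools::md5sum(p1[[f]])),
                         unname(tools::md5sum(p2[[f]])), label = f)

    vcfLines <- readLines(p1[["vcf"]])
    expect_equal(sum(!startsWith(vcfLines, "#")), 300L)
    expect_equal(length(readLines(p1[["truth"]])), 1L)
    bed <- read.table(p1[["truth"]])
    expect_equal(bed$V2, 30000L)   # 0-based half-open
    expect_equal(bed$V3, 42000L)

    st <- data.frame(sample = colnames(genotypes(sim)),
                     population = populations(genotypes(sim)),
                     excluded = FALSE)
    gm2 <- readGenotypeVcf(p1[["vcf"]], st)
    expect_identical(genotypes(gm2), genotypes(genotypes(sim)))
    expect_identical(alleleDepths(gm2)$ref,
                     alleleDepths(genotypes(sim))$ref)
    expect_identical(populations(gm2), populations(genotypes(sim)))
})

test_that("diversity scales with ancestral heterozygosity and drops in sweeps", {
    ## windowed pi is proportional to per-site heterozygosity
    pos <- sort(sample.int(190000L, 600L))
    mk <- function(p) {
        hap <- simulateHaplotypes(p, "chr1", pos, 60L, 2000, seed = 19L)
        dos <- hap[, seq(1, 60, 2)] + hap[, seq(2, 60, 2)]
        toyGM(dos, pos = pos, chromLengths = c(chr1 = 200000L))
    }
    set.seed(20)
    pLow <- runif(600, 0.03, 0.105)           # E[2pq] ~ 0.121
    gmLow <- mk(pLow)
    hLow <- mean(2 * pLow * (1 - pLow))
    pHigh <- (1 - sqrt(1 - 4 * hLow)) / 2      # solves 2p(1-p) = 2*hLow
    gmHigh <- mk(rep(pHigh, 600))
    mLow <- mean(windowedPi(gmLow, "cultivated")$value)
    mHigh <- mean(windowedPi(gmHigh, "cultivated")$value)
    expect_lt(abs(mHigh / mLow - 2), 0.2)

    ## cultivated diversity collapses inside planted sweeps (canonical seed)
    sim <- defaultSim()
    piC <- windowedPi(genotypes(sim), "cultivated")
    inside <- overlapsAny(piC, sweepRegions(sim), type = "within")
    expect_lt(mean(piC$value[inside]), 0.25 * median(piC$value))
})
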