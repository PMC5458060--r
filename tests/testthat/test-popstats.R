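test_that("per-site pi matches pairwise-difference enumeration", {
    ## monomorphic
    expect_equal(sitePi(matrix(c(0L, 0L, 0L), 1)), 0)
    ## two diploid heterozygotes: c1 = 2 of n = 4 alleles -> 2*2/6
    expect_equal(sitePi(matrix(c(1L, 1L), 1)), 2/3)
    ## maximal at c1 = n/2
    pis <- vapply(0:8, function(c1) {
        dos <- c(rep(2L, c1 %/% 2), if (c1 %% 2) 1L,
                 rep(0L, (8 - c1) %/% 2))
        sitePi(matrix(dos, 1))
    }, numeric(1))
    expect_equal(which.max(pis) - 1L, 4L)

    ## random instances against the brute-force allele-pair oracle
    set.seed(40)
    for (i in 1:50) {
        dos <- sample(c(0:2, NA), 8, TRUE)
        if (sum(!is.na(dos)) < 1) next
        expect_equal(sitePi(matrix(dos, 1)), oracleSitePi(dos),
                     tolerance = 1e-12)
    }
})

test_that("windowed pi divides site sums by the window span", {
    ## one SNP with pi = 2/3 alone in each 10-kb window
    gm <- toyGM(matrix(c(1L, 1L), 1), pos = 5000L,
                chromLengths = c(chr1 = 10000L))
    tr <- windowedPi(gm, "cultivated", windowSize = 10000L, step = 1000L)
    expect_equal(tr$value[1], (2/3) / 10000)
    ## windows with no SNP are zero
    gm2 <- toyGM(matrix(c(1L, 1L), 1), pos = 5000L,
                 chromLengths = c(chr1 = 30000L))
    tr2 <- windowedPi(gm2, "cultivated")
    expect_equal(tr2$value[start(tr2) > 15000], rep(0, sum(start(tr2) > 15000)))
    ## doubling the step halves the window count (within one per end)
    n1 <- length(windowedPi(gm2, "cultivated", step = 1000L))
    n2 <- length(windowedPi(gm2, "cultivated", step = 2000L))
    expect_lte(abs(n1 - 2 * n2), 2L)
})

test_that("windowed pi equals a brute-force all-pairs computation", {
    set.seed(41)
    for (i in 1:20) {
        nS <- sample(5:50, 1)
        nSamp <- sample(3:10, 1)
        pos <- sort(sample.int(5000L, nS))
        gt <- randomDosages(nS, nSamp, missing = 0.15)
        gm <- toyGM(gt, pos = pos, chromLengths = c(chr1 = 5000L))
        tr <- windowedPi(gm, "cultivated", windowSize = 1000L, step = 500L,
                         minGenotyped = 0)
        for (w in seq_along(tr)) {
            s0 <- start(tr)[w] - 1L
            inWin <- pos > s0 & pos <= s0 + 1000L
            brute <- sum(vapply(which(inWin), function(j)
                oracleSitePi(gt[j, ]), numeric(1)), na.rm = TRUE) / 1000
            expect_equal(tr$value[w], brute, tolerance = 1e-12)
        }
    }
})

test_that("FST components match the Weir-Cockerham 1984 transcription", {
    ## both populations fixed for the same allele
    comp <- fstSiteComponents(matrix(0L, 1, 4), matrix(0L, 1, 4))
    expect_equal(unlist(comp), c(a = 0, b = 0, c = 0))
    ## opposite fixation, n = 4 each: FST = 1
    comp <- fstSiteComponents(matrix(0L, 1, 4), matrix(2L, 1, 4))
    expect_equal(comp$a / (comp$a + comp$b + comp$c), 1)
    ## printed toy table: pop1 6xAA 2xAa; pop2 1xAA 3xAa 4xaa
    d1 <- c(rep(0L, 6), rep(1L, 2))
    d2 <- c(0L, rep(1L, 3), rep(2L, 4))
    comp <- fstSiteComponents(matrix(d1, 1), matrix(d2, 1))
    orc <- oracleWC(d1, d2)
    expect_equal(unlist(comp), orc, tolerance = 1e-12,
                 ignore_attr = TRUE)

    ## random tables
    set.seed(42)
    for (i in 1:100) {
        d1 <- sample(c(0:2, NA), sample(3:10, 1), TRUE)
        d2 <- sample(c(0:2, NA), sample(3:10, 1), TRUE)
        comp <- unlist(fstSiteComponents(matrix(d1, 1), matrix(d2, 1)))
        orc <- oracleWC(d1, d2)
        if (all(is.na(orc))) expect_true(all(is.na(comp)))
        else expect_equal(comp, orc, tolerance = 1e-12, ignore_attr = TRUE)
    }
})

test_that("windowed FST is the ratio of summed components", {
    set.seed(43)
    gt <- cbind(randomDosages(30, 5), randomDosages(30, 7))
    pos <- sort(sample.int(3000L, 30))
    gm <- toyGM(gt, pos = pos,
                population = rep(c("wild_progenitor", "cultivated"), c(5, 7)),
                chromLengths = c(chr1 = 3000L))
    tr <- windowedFst(gm, windowSize = 1000L, step = 1000L)
    for (w in seq_along(tr)) {
        s0 <- start(tr)[w] - 1L
        inWin <- which(pos > s0 & pos <= s0 + 1000L)
        if (!length(inWin)) {
            expect_false(tr$defined[w])
            next
        }
        comps <- t(vapply(inWin, function(j)
            oracleWC(gt[j, 1:5], gt[j, 6:12]), numeric(3)))
        expect_equal(tr$value[w],
                     sum(comps[, 1]) / sum(comps),
                     tolerance = 1e-12)
    }
    ## single polymorphic site: window equals that site's a/(a+b+c)
    one <- toyGM(matrix(c(0L, 0L, 1L, 2L, 2L, 1L), 1),
                 pos = 500L,
                 population = rep(c("wild_progenitor", "cultivated"), c(3, 3)),
                 chromLengths = c(chr1 = 1000L))
    trOne <- windowedFst(one, windowSize = 1000L, step = 1000L)
    orc <- oracleWC(c(0L, 0L, 1L), c(2L, 2L, 1L))
    expect_equal(trOne$value[1], orc[["a"]] / sum(orc))
    ## all-monomorphic window is undefined
    mono <- toyGM(matrix(0L, 2, 6), pos = c(100L, 200L),
                  population = rep(c("wild_progenitor", "cultivated"), c(3, 3)),
                  chromLengths = c(chr1 = 1000L))
    expect_false(windowedFst(mono, windowSize = 1000L, step = 1000L)$defined[1])
})

test_that("pi and FST are invariant to allele relabeling", {
    set.seed(44)
    gt <- cbind(randomDosages(40, 6), randomDosages(40, 6))
    pos <- sort(sample.int(20000L, 40))
    pops <- rep(c("wild_progenitor", "cultivated"), c(6, 6))
    gm1 <- toyGM(gt, pos = pos, population = pops,
                 chromLengths = c(chr1 = 20000L))
    flip <- sample.int(40, 15)
    gm2 <- toyGM(relabelSites(gt, flip), pos = pos, population = pops,
                 chromLengths = c(chr1 = 20000L))
    expect_equal(windowedPi(gm1, "cultivated")$value,
                 windowedPi(gm2, "cultivated")$value)
    expect_equal(windowedFst(gm1)$value, windowedFst(gm2)$value)
})

test_that("pi-ratio flags undefined windows instead of dividing by zero", {
    w <- GRanges("chr1", IRanges(c(1, 1001), width = 1000),
                 value = c(2e-4, 3e-4))
    c1 <- GRanges("chr1", IRanges(c(1, 1001), width = 1000),
                  value = c(2e-4, 0))
    pr <- piRatio(w, c1)
    expect_equal(pr$value[1], 1)
    expect_true(is.na(pr$value[2]))
    expect_false(pr$defined[2])
    ## grid mismatch is an error
    c2 <- GRanges("chr1", IRanges(c(1, 2001), width = 1000),
                  value = c(1, 1))
    expect_error(piRatio(w, c2), "grid")
})

test_that("quantile thresholding and merging follow the inverse-ECDF rule", {
    ## 200 sliding 10-kb windows, values 1..200: inverse-ECDF 99% threshold
    ## is the 198th order statistic; the three top windows merge into one
    ## region scored by its maximum
    w <- GRanges("chr1", IRanges(seq(1, by = 1000, length.out = 200),
                                 width = 10000), value = as.numeric(1:200))
    reg <- topQuantileRegions(w, 0.01)
    expect_equal(length(reg), 1L)
    expect_equal(reg$score, 200)
    expect_equal(reg$nWindows, 3L)
    expect_equal(start(reg), 197001L)

    ## merging is idempotent
    expect_identical(GenomicRanges::reduce(GenomicRanges::granges(reg)),
                     GenomicRanges::granges(reg))

    ## regions cover exactly the union of thresholded windows
    thr <- quantile(w$value, 0.99, type = 1)
    expect_identical(GenomicRanges::granges(reg),
                     GenomicRanges::reduce(GenomicRanges::granges(
                         w[w$value >= thr])))

    ## regions are sorted and non-overlapping on multi-hit tracks
    set.seed(45)
    w2 <- GRanges(rep(c("chr1", "chr2"), each = 300),
                  IRanges(rep(seq(1, by = 1000, length.out = 300), 2),
                          width = 10000), value = runif(600))
    reg2 <- topQuantileRegions(w2, 0.05)
    expect_true(all(diff(start(reg2)[as.character(seqnames(reg2)) == "chr1"]) > 0))
    expect_equal(sum(GenomicRanges::countOverlaps(reg2, reg2) != 1), 0L)

    expect_error(topQuantileRegions(
        GRanges("chr1", IRanges(1, 10), value = NA_real_), 0.1),
        "no defined")
})

test_that("genes are reported for any 1-bp overlap with a region", {
    gff <- GRanges("chr1", IRanges(c(100, 500, 901), c(200, 600, 1000)),
                   type = "gene", ID = c("gA", "gB", "gC"))
    regions <- GRanges("chr1", IRanges(150, 901))
    hits <- genesInRegions(regions, gff)
    expect_identical(sort(hits[[1]]), c("gA", "gB", "gC"))
    regions2 <- GRanges("chr1", IRanges(601, 900))
    expect_identical(genesInRegions(regions2, gff)[[1]], character(0))
})
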