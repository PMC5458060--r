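## Two-population genotype simulator: Balding-Nichols drift frequencies,
## Markov haplotype copying for linkage, planted sweeps, Poisson/binomial
## read-depth evidence and a quantitative phenotype with one causal SNP.

.BASES <- c("A", "C", "G", "T")

## Codon table indexed 1..64 over integer base codes; stop codons excluded
## when simulating coding sequence.
.codonInts <- function() {
    grid <- expand.grid(b3 = 1:4, b2 = 1:4, b1 = 1:4)[, 3:1]
    codons <- apply(grid, 1L, function(r) paste(.BASES[r], collapse = ""))
    list(grid = as.matrix(grid), codon = codons,
         stop = codons %in% c("TAA", "TAG", "TGA"))
}

## Deterministic CDS layout of a 1,400-bp simulated gene: two 600-bp CDS
## parts separated by a 200-bp intron.
.geneCdsOffsets <- function() list(cds1 = 0:599, intron = 600:799, cds2 = 800:1399)

## Simulate the genome backbone and overwrite gene bodies with stop-free
## coding sequence (ATG ... TAA in transcription order, strand-aware).
## Returns a list of integer vectors (1..4 = ACGT), one per chromosome.
## Seeded independently of the main simulation stream so that it can be
## regenerated when writing outputs.
.simulateGenome <- function(config) {
    ct <- .codonInts()
    freeIdx <- which(!ct$stop)
    startIdx <- which(ct$codon == "ATG")
    stopIdx <- which(ct$codon == "TAA")
    off <- .geneCdsOffsets()
    withSeed((config@seed + 105943L) %% .Machine$integer.max, {
        genome <- lapply(config@chromLengths, function(len) {
            sample.int(4L, len, replace = TRUE)
        })
        gi <- config@genicIntervals
        for (i in seq_along(gi)) {
            ch <- as.character(seqnames(gi))[i]
            s <- start(gi)[i]
            nCodon <- (length(off$cds1) + length(off$cds2)) / 3L
            codons <- c(startIdx,
                        sample(freeIdx, nCodon - 2L, replace = TRUE),
                        stopIdx)
            bases <- as.vector(t(ct$grid[codons, , drop = FALSE]))
            posInGene <- c(off$cds1, off$cds2)
            if (as.character(strand(gi))[i] == "-")
                bases <- rev(5L - bases)   # reverse complement
            genome[[ch]][s + posInGene] <- bases
        }
        genome
    })
}

#' Simulate ancestral and population allele frequencies
#'
#' Draws ancestral frequencies i.i.d. Uniform(0.05, 0.95) and, for each
#' population with drift parameter F > 0, Balding-Nichols frequencies
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)`, whose conditional variance is
#' `F * p * (1-p)`.  With F = 0 the population frequency equals the
#' ancestral one.
#'
#' @param config A [SimConfig-class].
#' @param seed Seed for this draw (default: the config seed); `NULL` uses
#'   the current RNG stream.
#' @return List with numeric vectors `pAnc`, `pWild`, `pCult` of length
#'   `nSites`.
#' @export
simulateFrequencies <- function(config, seed = config@seed) {
    if (config@FWild >= 1 || config@FCult >= 1 || config@FWild < 0 ||
        config@FCult < 0)
        stop("drift parameters F must lie in [0, 1)")
    withSeed(seed, {
        p <- runif(config@nSites, 0.05, 0.95)
        drift <- function(p, F) {
            if (F == 0) return(p)
            rbeta(length(p), p * (1 - F) / F, (1 - p) * (1 - F) / F)
        }
        list(pAnc = p, pWild = drift(p, config@FWild),
             pCult = drift(p, config@FCult))
    })
}

#' Simulate haplotypes with distance-dependent copying
#'
#' Haplotypes are generated site by site.  Each haplotype carries a latent
#' uniform "template" value; moving a physical distance `delta` to the next
#' site, the template is retained with probability `exp(-delta/ldBlockScale)`
#' (copying, which preserves allele association) and redrawn otherwise.  The
#' allele at a site is 1 when the template value falls below the site's
#' population frequency, so the per-site marginal is exactly Bernoulli(p)
#' while r-squared between nearby sites decays with distance on the
#' `ldBlockScale` scale.  The template is always redrawn across chromosome
#' boundaries.
#'
#' @param p Per-site allele-1 frequencies.
#' @param chrom,pos Site coordinates (sorted by chrom, pos).
#' @param nHaplotypes Number of haplotypes (2 per diploid sample).
#' @param ldBlockScale Copying decay length in bp; 0 gives independent sites.
#' @param seed Optional seed; `NULL` uses the current stream.
#' @return Integer 0/1 matrix, sites x haplotypes.
#' @export
simulateHaplotypes <- function(p, chrom, pos, nHaplotypes, ldBlockScale,
                               seed = NULL) {
    withSeed(seed, {
        nS <- length(p)
        hap <- matrix(0L, nS, nHaplotypes)
        chrom <- rep_len(as.character(chrom), nS)
        u <- runif(nHaplotypes)
        for (j in seq_len(nS)) {
            if (j > 1L) {
                pcopy <- if (chrom[j] != chrom[j - 1L]) 0
                         else if (ldBlockScale <= 0) 0
                         else exp(-(pos[j] - pos[j - 1L]) / ldBlockScale)
                redraw <- runif(nHaplotypes) >= pcopy
                if (any(redraw))
                    u[redraw] <- runif(sum(redraw))
            }
            hap[j, ] <- as.integer(u < p[j])
        }
        hap
    })
}

#' Plant selective sweeps into cultivated haplotypes
#'
#' Inside each sweep interval, every haplotype is independently "swept" with
#' probability `intensity`; swept haplotypes carry allele 1 (the beneficial
#' background) at all interior sites.  Non-swept haplotypes escape
#' unchanged.  Wild haplotypes are never touched.
#'
#' @param hap Sites x haplotypes 0/1 matrix (cultivated population).
#' @param chrom,pos Site coordinates matching `hap` rows.
#' @param sweeps `GRanges` of sweep intervals with an `intensity` column.
#' @param chromLengths Optional named lengths used to validate the sweeps.
#' @param seed Optional seed.
#' @return The modified haplotype matrix.
#' @export
applySweeps <- function(hap, chrom, pos, sweeps, chromLengths = NULL,
                        seed = NULL) {
    if (!is.null(chromLengths)) {
        lens <- chromLengths[as.character(seqnames(sweeps))]
        if (anyNA(lens) || any(end(sweeps) > lens) || any(start(sweeps) < 1))
            stop("sweep interval outside the genome")
    }
    chrom <- rep_len(as.character(chrom), length(pos))
    withSeed(seed, {
        for (i in seq_along(sweeps)) {
            inside <- chrom == as.character(seqnames(sweeps))[i] &
                pos >= start(sweeps)[i] & pos <= end(sweeps)[i]
            swept <- runif(ncol(hap)) < sweeps$intensity[i]
            if (any(inside) && any(swept))
                hap[inside, swept] <- 1L
        }
        hap
    })
}

#' Simulate per-sample read depths over true genotypes
#'
#' Depth is Poisson(`meanDepth`) per sample/site; reads supporting the
#' alternate allele are Binomial(depth, dosage/2); with probability
#' `missingRate` an entry is masked (zero depth).
#'
#' @param dosages Sites x samples matrix of true alt-allele dosages (0/1/2).
#' @param meanDepth Mean reads per site per sample (> 0).
#' @param missingRate Fraction of masked entries in `[0, 1)`
#'   (`missingRate = 1` masks everything and is allowed for testing).
#' @param seed Optional seed.
#' @return List of matrices `ref` and `alt` (read counts).
#' @export
simulateReadDepths <- function(dosages, meanDepth, missingRate = 0,
                               seed = NULL) {
    if (meanDepth <= 0)
        stop("meanDepth must be positive")
    withSeed(seed, {
        n <- length(dosages)
        depth <- rpois(n, meanDepth)
        if (missingRate > 0)
            depth[runif(n) < missingRate] <- 0L
        altReads <- rbinom(n, depth, as.vector(dosages) / 2)
        ref <- matrix(depth - altReads, nrow(dosages), ncol(dosages))
        alt <- matrix(altReads, nrow(dosages), ncol(dosages))
        dimnames(ref) <- dimnames(alt) <- dimnames(dosages)
        list(ref = ref, alt = alt)
    })
}

#' Simulate a quantitative phenotype from a causal SNP
#'
#' `days = baseline + effect * dosage + Normal(0, residSd)`.
#'
#' @param causalDosage True dosages at the causal site, one per phenotyped
#'   sample.
#' @param effect Effect size in days per alt allele.
#' @param residSd Residual standard deviation in days.
#' @param baseline Baseline in days.
#' @param seed Optional seed.
#' @return Numeric vector of phenotype values (days).
#' @export
simulatePhenotype <- function(causalDosage, effect, residSd, baseline = 60,
                              seed = NULL) {
    if (length(unique(causalDosage[!is.na(causalDosage)])) < 2L)
        warning("causal site is monomorphic; effect is unidentifiable")
    withSeed(seed,
             baseline + effect * causalDosage +
                 rnorm(length(causalDosage), 0, residSd))
}

## Map draws in cumulative genic-bp space to (chrom, pos).
.drawSitePositions <- function(config) {
    gi <- config@genicIntervals
    w <- width(gi)
    total <- sum(w)
    if (total < config@nSites)
        stop("genic space smaller than the requested number of SNPs")
    drawn <- sort(sample.int(total, config@nSites))
    cum <- cumsum(w)
    iv <- findInterval(drawn - 1L, c(0L, cum), rightmost.closed = FALSE)
    offset <- drawn - c(0L, cum)[iv] - 1L
    list(chrom = as.character(seqnames(gi))[iv], pos = start(gi)[iv] + offset)
}

## Deterministic causal-site choice: a mid-genome polymorphic site with
## comfortable cultivated MAF, outside planted sweeps.
.pickCausalSite <- function(chrom, pos, pCult, sweeps) {
    maf <- pmin(pCult, 1 - pCult)
    inSweep <- rep(FALSE, length(pos))
    for (i in seq_along(sweeps))
        inSweep <- inSweep | (chrom == as.character(seqnames(sweeps))[i] &
                                  pos >= start(sweeps)[i] &
                                  pos <= end(sweeps)[i])
    cand <- which(maf >= 0.25 & !inSweep)
    if (!length(cand))
        cand <- which(maf > 0)
    cand[ceiling(length(cand) / 2)]
}

#' Simulate a complete two-population study
#'
#' Runs the whole generative model under the config seed: site placement in
#' genic intervals, Balding-Nichols frequencies, copying haplotypes, planted
#' sweeps, read depths, depth-based genotype calls and the phenotype.  All
#' randomness flows from `config@seed`; identical configs give identical
#' results.
#'
#' @param config A [SimConfig-class].
#' @return A [PopulationSim-class].
#' @examples
#' sim <- simulatePopulations(SimConfig(nSites = 500L,
#'     chromLengths = c(chr1 = 2e5, chr2 = 2e5),
#'     sweeps = GenomicRanges::GRanges("chr1",
#'         IRanges::IRanges(50001, 60000), intensity = 0.9),
#'     seed = 7L))
#' sim
#' @export
simulatePopulations <- function(config) {
    validObject(config)
    genome <- .simulateGenome(config)
    withSeed(config@seed, {
        sites <- .drawSitePositions(config)
        fr <- simulateFrequencies(config, seed = NULL)
        hapW <- simulateHaplotypes(fr$pWild, sites$chrom, sites$pos,
                                   2L * config@nWild, config@ldBlockScale)
        hapC <- simulateHaplotypes(fr$pCult, sites$chrom, sites$pos,
                                   2L * config@nCult, config@ldBlockScale)
        hapC <- applySweeps(hapC, sites$chrom, sites$pos, config@sweeps,
                            config@chromLengths)
        dosW <- hapW[, seq(1, ncol(hapW), 2), drop = FALSE] +
            hapW[, seq(2, ncol(hapW), 2), drop = FALSE]
        dosC <- hapC[, seq(1, ncol(hapC), 2), drop = FALSE] +
            hapC[, seq(2, ncol(hapC), 2), drop = FALSE]
        dosAll <- cbind(dosW, dosC)
        samples <- c(sprintf("W%02d", seq_len(config@nWild)),
                     sprintf("C%03d", seq_len(config@nCult)))
        colnames(dosAll) <- samples
        depths <- simulateReadDepths(dosAll, config@meanDepth,
                                     config@missingRate)
        calls <- callGenotypesFromDepths(depths$ref, depths$alt)

        refIdx <- mapply(function(ch, p) genome[[ch]][p],
                         sites$chrom, sites$pos, USE.NAMES = FALSE)
        altIdx <- (refIdx - 1L + sample.int(3L, config@nSites,
                                            replace = TRUE)) %% 4L + 1L

        causal <- config@phenoCausalSite
        if (is.na(causal))
            causal <- .pickCausalSite(sites$chrom, sites$pos, fr$pCult,
                                      config@sweeps)
        pheno <- data.frame(
            sample = samples[config@nWild + seq_len(config@nCult)],
            days = simulatePhenotype(dosC[causal, ], config@phenoEffect,
                                     config@phenoResidSd,
                                     config@phenoBaseline))

        gm <- GenotypeMatrix(
            chrom = sites$chrom, pos = sites$pos,
            ref = .BASES[refIdx], alt = .BASES[altIdx],
            genotypes = calls, refDepth = depths$ref, altDepth = depths$alt,
            samples = samples,
            population = rep(c("wild_progenitor", "cultivated"),
                             c(config@nWild, config@nCult)),
            chromLengths = config@chromLengths)
        tr <- new("SimTruth", sweepRegions = config@sweeps,
                  pAnc = fr$pAnc, pWild = fr$pWild, pCult = fr$pCult,
                  causalSite = as.integer(causal),
                  hapWild = hapW, hapCult = hapC)
        new("PopulationSim", genotypes = gm, truth = tr,
            phenotype = pheno, config = config)
    })
}

## Gene models of the simulated genome, GFF3-ready.
.simGeneModels <- function(config) {
    gi <- config@genicIntervals
    off <- .geneCdsOffsets()
    n <- length(gi)
    if (n == 0L) return(GRanges())
    geneId <- sprintf("gene%05d", seq_len(n))
    rnaId <- sprintf("mRNA%05d", seq_len(n))
    ch <- as.character(seqnames(gi)); st <- as.character(strand(gi))
    s <- start(gi)
    feat <- function(type, starts, ends, id, parent, phase) {
        GRanges(ch, IRanges(starts, ends), strand = st,
                type = type, ID = id, Parent = CharacterList(parent),
                phase = phase)
    }
    genes <- feat("gene", s, s + 1399L, geneId,
                  as.list(rep("", n)), NA_integer_)
    genes$Parent <- CharacterList(lapply(seq_len(n), function(i) character(0)))
    rnas <- feat("mRNA", s, s + 1399L, rnaId, as.list(geneId), NA_integer_)
    cds1 <- feat("CDS", s + off$cds1[1], s + off$cds1[length(off$cds1)],
                 sprintf("CDS%05d.1", seq_len(n)), as.list(rnaId), 0L)
    cds2 <- feat("CDS", s + off$cds2[1], s + off$cds2[length(off$cds2)],
                 sprintf("CDS%05d.2", seq_len(n)), as.list(rnaId), 0L)
    out <- c(genes, rnas, cds1, cds2)
    seqlengths(out) <- config@chromLengths[seqlevels(out)]
    sort(out, ignore.strand = TRUE)
}

#' Write simulated data to standard files
#'
#' Writes VCF v4.2 (GT:AD), GFF3 gene models, the genome FASTA, the
#' phenotype TSV (`sample`, `days`) and the truth BED of planted sweep
#' intervals (BED3, 0-based half-open).
#'
#' @param sim A [PopulationSim-class].
#' @param dir Output directory (created if absent).
#' @return Named character vector of the file paths.
#' @export
writeSimOutputs <- function(sim, dir) {
    if (!dir.exists(dir))
        dir.create(dir, recursive = TRUE)
    cfg <- sim@config
    paths <- c(vcf = file.path(dir, "genotypes.vcf"),
               gff = file.path(dir, "genes.gff3"),
               fasta = file.path(dir, "genome.fa"),
               phenotype = file.path(dir, "phenotype.tsv"),
               truth = file.path(dir, "truth_sweeps.bed"))
    writeGenotypeVcf(sim@genotypes, paths[["vcf"]])
    export(.simGeneModels(cfg), paths[["gff"]], format = "gff3")
    genome <- .simulateGenome(cfg)
    dss <- DNAStringSet(vapply(genome, function(g)
        paste(.BASES[g], collapse = ""), character(1)))
    writeXStringSet(dss, paths[["fasta"]], width = 80L)
    write.table(sim@phenotype, paths[["phenotype"]], sep = "\t",
                quote = FALSE, row.names = FALSE)
    sw <- sweepRegions(sim)
    writeLines(sprintf("%s\t%d\t%d", as.character(seqnames(sw)),
                       start(sw) - 1L, end(sw)), paths[["truth"]])
    invisible(paths)
}
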