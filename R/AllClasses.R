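## S4 classes: genotype container, simulation configuration/truth, sweep-scan
## model parameters.

#' GenotypeMatrix: biallelic SNP genotypes with positions and allele depths
#'
#' A `RangedSummarizedExperiment` subclass holding diploid genotype calls for
#' biallelic SNPs.  Rows are sites (a width-1 `GRanges` with `ref`/`alt`
#' metadata columns), columns are samples.  The `"GT"` assay stores the
#' alt-allele dosage (0, 1, 2 or `NA` for missing); optional `"AD_REF"` and
#' `"AD_ALT"` assays store per-sample read depths for the two alleles.
#' `colData` carries the population label of each sample
#' (`"wild_progenitor"`, `"cultivated"` or `"other"`) and an optional
#' `excluded` flag.
#'
#' @export
setClass("GenotypeMatrix", contains = "RangedSummarizedExperiment")

setValidity("GenotypeMatrix", function(object) {
    msg <- character(0)
    if (!"GT" %in% names(assays(object)))
        msg <- c(msg, "assay 'GT' (alt-allele dosage) is required")
    else {
        gt <- assay(object, "GT")
        bad <- !is.na(gt) & !(gt %in% c(0, 1, 2))
        if (any(bad))
            msg <- c(msg, "dosages must be 0, 1, 2 or NA")
    }
    rr <- rowRanges(object)
    if (length(rr)) {
        if (any(width(rr) != 1L))
            msg <- c(msg, "sites must have width 1 (SNPs only)")
        if (is.null(rr$ref) || is.null(rr$alt))
            msg <- c(msg, "rowRanges must carry 'ref' and 'alt' alleles")
        else {
            ok <- rr$ref %in% c("A", "C", "G", "T") &
                rr$alt %in% c("A", "C", "G", "T") & rr$ref != rr$alt
            if (!all(ok))
                msg <- c(msg, "ref/alt must be distinct single bases")
        }
        ds <- diff(start(rr))
        same <- as.character(seqnames(rr))[-1] ==
            as.character(seqnames(rr))[-length(rr)]
        if (any(same & ds <= 0))
            msg <- c(msg, "positions must be strictly increasing within chromosome")
    }
    if (!"population" %in% colnames(colData(object)))
        msg <- c(msg, "colData must carry a 'population' column")
    if (length(msg)) msg else TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param chrom Character vector of chromosome names, one per site.
#' @param pos Integer vector of 1-based positions (as in VCF).
#' @param ref,alt Single-base reference and alternate alleles per site.
#' @param genotypes Sites x samples integer matrix of alt-allele dosages
#'   (0/1/2, `NA` = missing).
#' @param refDepth,altDepth Optional sites x samples matrices of read counts
#'   supporting the reference and alternate allele.
#' @param samples Sample identifiers (default: `colnames(genotypes)`).
#' @param population Population label per sample; one of
#'   `"wild_progenitor"`, `"cultivated"`, `"other"`.
#' @param excluded Logical per-sample exclusion flag (excluded samples are
#'   kept in the object but can be dropped by analyses).
#' @param chromLengths Optional named vector of chromosome lengths.
#' @return A [GenotypeMatrix-class] object, sites sorted by position.
#' @examples
#' gm <- GenotypeMatrix(chrom = "chr1", pos = c(100L, 200L),
#'                      ref = c("A", "G"), alt = c("T", "C"),
#'                      genotypes = matrix(c(0L, 1L, 2L, 1L), 2),
#'                      population = c("wild_progenitor", "cultivated"))
#' genotypes(gm)
#' @export
GenotypeMatrix <- function(chrom, pos, ref, alt, genotypes,
                           refDepth = NULL, altDepth = NULL,
                           samples = colnames(genotypes),
                           population = rep("other", ncol(genotypes)),
                           excluded = rep(FALSE, ncol(genotypes)),
                           chromLengths = NULL) {
    genotypes <- as.matrix(genotypes)
    if (is.null(samples))
        samples <- paste0("S", seq_len(ncol(genotypes)))
    chrom <- rep_len(as.character(chrom), length(pos))
    o <- order(chrom, pos)
    rr <- GRanges(chrom[o], IRanges(pos[o], width = 1L),
                  ref = as.character(ref)[o], alt = as.character(alt)[o])
    if (!is.null(chromLengths)) {
        sl <- chromLengths[seqlevels(rr)]
        names(sl) <- seqlevels(rr)
        seqlengths(rr) <- sl
    }
    asys <- list(GT = genotypes[o, , drop = FALSE])
    if (!is.null(refDepth) && !is.null(altDepth)) {
        asys$AD_REF <- as.matrix(refDepth)[o, , drop = FALSE]
        asys$AD_ALT <- as.matrix(altDepth)[o, , drop = FALSE]
    }
    asys <- lapply(asys, function(m) {
        dimnames(m) <- list(NULL, samples); m
    })
    cd <- DataFrame(population = as.character(population),
                    excluded = as.logical(excluded),
                    row.names = samples)
    new("GenotypeMatrix",
        SummarizedExperiment(assays = asys, rowRanges = rr, colData = cd))
}

#' Simulation configuration for the two-population genotype simulator
#'
#' Parameters of the Balding-Nichols two-population model with
#' haplotype-copying linkage, planted sweeps, read-depth genotype evidence
#' and a quantitative phenotype.  `SimConfig()` with no arguments gives the
#' default study design: 2 chromosomes x 5 Mb, 20,000 transcriptome-placed
#' SNPs, 8 wild and 30 cultivated accessions, F_wild = 0.05,
#' F_cult = 0.10 (weak cultivation bottleneck), LD copying scale 2 kb,
#' three 50-kb sweeps of intensity 0.9, mean read depth 20 and 5% missing
#' genotypes.
#'
#' @slot chromLengths Named numeric, chromosome lengths in bp.
#' @slot genicIntervals `GRanges` of gene spans; SNPs are placed only inside
#'   these (transcriptome ascertainment).
#' @slot nWild,nCult Sample counts per population.
#' @slot nSites Number of SNPs to simulate.
#' @slot FWild,FCult Balding-Nichols drift parameters in `[0, 1)`;
#'   `FCult >= FWild` encodes the domestication bottleneck.
#' @slot sweeps `GRanges` of planted sweep intervals with an `intensity`
#'   metadata column (probability a cultivated haplotype is swept).
#' @slot ldBlockScale Haplotype-copying decay length in bp.
#' @slot meanDepth Mean sequencing depth (reads/site/sample).
#' @slot missingRate Fraction of genotype entries masked to missing.
#' @slot phenoCausalSite Index of the causal SNP (`NA` = pick automatically).
#' @slot phenoEffect Phenotype effect size, days per alt allele.
#' @slot phenoResidSd Residual standard deviation, days.
#' @slot phenoBaseline Baseline phenotype, days.
#' @slot seed Integer seed; all simulator randomness flows from it.
#' @export
setClass("SimConfig", representation(
    chromLengths = "numeric",
    genicIntervals = "GRanges",
    nWild = "integer",
    nCult = "integer",
    nSites = "integer",
    FWild = "numeric",
    FCult = "numeric",
    sweeps = "GRanges",
    ldBlockScale = "numeric",
    meanDepth = "numeric",
    missingRate = "numeric",
    phenoCausalSite = "integer",
    phenoEffect = "numeric",
    phenoResidSd = "numeric",
    phenoBaseline = "numeric",
    seed = "integer"))

setValidity("SimConfig", function(object) {
    msg <- character(0)
    if (object@nWild < 2L || object@nCult < 2L)
        msg <- c(msg, "need at least 2 samples per population")
    if (object@FWild < 0 || object@FWild >= 1 ||
        object@FCult < 0 || object@FCult >= 1)
        msg <- c(msg, "drift parameters F must lie in [0, 1)")
    if (object@missingRate < 0 || object@missingRate >= 1)
        msg <- c(msg, "missingRate must lie in [0, 1)")
    if (object@meanDepth <= 0)
        msg <- c(msg, "meanDepth must be positive")
    if (length(object@sweeps)) {
        sw <- object@sweeps
        lens <- object@chromLengths[as.character(seqnames(sw))]
        if (anyNA(lens) || any(end(sw) > lens) || any(start(sw) < 1))
            msg <- c(msg, "sweep intervals must lie within the genome")
        if (is.null(sw$intensity) || any(sw$intensity <= 0) ||
            any(sw$intensity > 1))
            msg <- c(msg, "sweep intensity must lie in (0, 1]")
        if (any(width(sw) < 10000L))
            msg <- c(msg, "sweeps must span at least one 10-kb window")
    }
    gl <- object@chromLengths[as.character(seqnames(object@genicIntervals))]
    if (length(object@genicIntervals) &&
        (anyNA(gl) || any(end(object@genicIntervals) > gl)))
        msg <- c(msg, "genic intervals must lie within the genome")
    if (length(msg)) msg else TRUE
})

## Deterministic gene layout: genes of 1,400 bp (600-bp CDS, 200-bp intron,
## 600-bp CDS) tiled every 2,800 bp, strands alternating.
.defaultGenicIntervals <- function(chromLengths) {
    sl <- lapply(names(chromLengths), function(ch) {
        len <- chromLengths[[ch]]
        seq.int(701L, by = 2800L,
                length.out = max(0L, (len - 1400L) %/% 2800L))
    })
    ch <- rep(names(chromLengths), lengths(sl))
    starts <- unlist(sl)
    out <- GRanges(ch, IRanges(starts, width = 1400L),
                   strand = unlist(lapply(lengths(sl), function(n)
                       rep_len(c("+", "-"), n))))
    seqlengths(out) <- chromLengths[seqlevels(out)]
    out
}

.defaultSweeps <- function() {
    GRanges(c("chr1", "chr1", "chr2"),
            IRanges(start = c(1000001L, 3200001L, 2000001L), width = 50000L),
            intensity = 0.9)
}

#' @param chromLengths,genicIntervals,nWild,nCult,nSites,FWild,FCult,sweeps,ldBlockScale,meanDepth,missingRate,phenoCausalSite,phenoEffect,phenoResidSd,phenoBaseline,seed
#'   See the slot documentation above.
#' @return A validated `SimConfig`.
#' @examples
#' cfg <- SimConfig(seed = 1L)
#' cfg
#' @rdname SimConfig-class
#' @export
SimConfig <- function(chromLengths = c(chr1 = 5e6, chr2 = 5e6),
                      genicIntervals = NULL,
                      nWild = 8L, nCult = 30L, nSites = 20000L,
                      FWild = 0.05, FCult = 0.10,
                      sweeps = .defaultSweeps(),
                      ldBlockScale = 2000,
                      meanDepth = 20, missingRate = 0.05,
                      phenoCausalSite = NA_integer_,
                      phenoEffect = 5, phenoResidSd = 2,
                      phenoBaseline = 60,
                      seed = 1L) {
    if (is.null(genicIntervals))
        genicIntervals <- .defaultGenicIntervals(chromLengths)
    new("SimConfig",
        chromLengths = chromLengths, genicIntervals = genicIntervals,
        nWild = as.integer(nWild), nCult = as.integer(nCult),
        nSites = as.integer(nSites), FWild = FWild, FCult = FCult,
        sweeps = sweeps, ldBlockScale = ldBlockScale,
        meanDepth = meanDepth, missingRate = missingRate,
        phenoCausalSite = as.integer(phenoCausalSite),
        phenoEffect = phenoEffect, phenoResidSd = phenoResidSd,
        phenoBaseline = phenoBaseline, seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig:",
        sprintf("%d chromosomes (%.3g Mb), %d SNPs",
                length(object@chromLengths),
                sum(object@chromLengths) / 1e6, object@nSites), "\n")
    cat(sprintf("  samples: %d wild / %d cultivated;  F = %.3g / %.3g\n",
                object@nWild, object@nCult, object@FWild, object@FCult))
    cat(sprintf("  LD scale %g bp; depth %g; missing %.3g; %d sweep(s); seed %d\n",
                object@ldBlockScale, object@meanDepth, object@missingRate,
                length(object@sweeps), object@seed))
})

#' Ground truth of a simulated data set
#'
#' @slot sweepRegions Planted sweep intervals (`GRanges`, equal to the
#'   configured sweeps).
#' @slot pAnc,pWild,pCult Per-site allele frequencies: ancestral, and the
#'   drifted (pre-sweep) population frequencies.
#' @slot causalSite Index of the causal phenotype SNP.
#' @slot hapWild,hapCult Haplotype matrices (sites x 2n), post-sweep.
#' @export
setClass("SimTruth", representation(
    sweepRegions = "GRanges",
    pAnc = "numeric", pWild = "numeric", pCult = "numeric",
    causalSite = "integer",
    hapWild = "matrix", hapCult = "matrix"))

setMethod("show", "SimTruth", function(object) {
    cat(sprintf("SimTruth: %d sites, %d planted sweep(s), causal site %d\n",
                length(object@pAnc), length(object@sweepRegions),
                object@causalSite))
})

#' A complete simulated study
#'
#' Returned by [simulatePopulations()]: depth-called genotypes, the ground
#' truth, the phenotype table and the configuration.
#'
#' @slot genotypes [GenotypeMatrix-class] of depth-derived calls with AD.
#' @slot truth [SimTruth-class].
#' @slot phenotype `data.frame` with columns `sample`, `days`.
#' @slot config [SimConfig-class].
#' @export
setClass("PopulationSim", representation(
    genotypes = "GenotypeMatrix",
    truth = "SimTruth",
    phenotype = "data.frame",
    config = "SimConfig"))

setMethod("show", "PopulationSim", function(object) {
    cat("PopulationSim\n")
    show(object@config)
    cat(sprintf("  genotypes: %d sites x %d samples; %d phenotyped\n",
                nrow(object@genotypes), ncol(object@genotypes),
                nrow(object@phenotype)))
})

#' Sweep-scan model parameters
#'
#' Parameters of the cross-population composite-likelihood scan: the drift
#' variance of the objective population relative to the reference (`omega`,
#' estimated from genome-wide data when `NA`), the selection-coefficient
#' grid, the effective population size used by the hitchhiking escape
#' probability, the r-squared level above which SNPs share weight, the
#' genetic window width, the per-window SNP cap, the physical grid spacing
#' and the latent-frequency integration grid size.
#'
#' @slot omega Drift variance scale (dimensionless); `NA` = estimate.
#' @slot sGrid Candidate selection coefficients.
#' @slot Ne Effective population size.
#' @slot corrThreshold r-squared level for SNP down-weighting.
#' @slot windowMorgans Scan window width in Morgans.
#' @slot maxSnps Maximum SNPs used per grid point.
#' @slot gridBp Grid spacing in bp.
#' @slot integrationPoints Latent-frequency integration grid size.
#' @export
setClass("SweepModel", representation(
    omega = "numeric", sGrid = "numeric", Ne = "numeric",
    corrThreshold = "numeric", windowMorgans = "numeric",
    maxSnps = "integer", gridBp = "integer",
    integrationPoints = "integer"))

setValidity("SweepModel", function(object) {
    msg <- character(0)
    if (!is.na(object@omega) && object@omega <= 0)
        msg <- c(msg, "omega must be positive")
    if (any(object@sGrid <= 0))
        msg <- c(msg, "selection coefficients must be positive")
    if (object@corrThreshold <= 0 || object@corrThreshold > 1)
        msg <- c(msg, "corrThreshold must lie in (0, 1]")
    if (object@windowMorgans <= 0 || object@gridBp <= 0 ||
        object@maxSnps < 1 || object@integrationPoints < 16)
        msg <- c(msg, "window, grid and integration sizes must be positive")
    if (length(msg)) msg else TRUE
})

#' @param omega,sGrid,Ne,corrThreshold,windowMorgans,maxSnps,gridBp,integrationPoints
#'   See the slot documentation above.
#' @return A validated `SweepModel`.
#' @examples
#' SweepModel()
#' @rdname SweepModel-class
#' @export
SweepModel <- function(omega = NA_real_,
                       sGrid = exp(seq(log(1e-4), log(0.5), length.out = 15)),
                       Ne = 10000,
                       corrThreshold = 0.7,
                       windowMorgans = 5e-4,
                       maxSnps = 100L,
                       gridBp = 100L,
                       integrationPoints = 512L) {
    new("SweepModel", omega = omega, sGrid = sGrid, Ne = Ne,
        corrThreshold = corrThreshold, windowMorgans = windowMorgans,
        maxSnps = as.integer(maxSnps), gridBp = as.integer(gridBp),
        integrationPoints = as.integer(integrationPoints))
}

setMethod("show", "SweepModel", function(object) {
    cat(sprintf(
        "SweepModel: omega=%s, Ne=%g, window=%g M, grid=%d bp, <=%d SNPs, r2>%.2g shared weight\n",
        if (is.na(object@omega)) "estimate" else format(object@omega),
        object@Ne, object@windowMorgans, object@gridBp, object@maxSnps,
        object@corrThreshold))
})
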