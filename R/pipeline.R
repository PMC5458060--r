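## End-to-end driver: filters -> diversity/differentiation windows -> LD
## decay -> sweep scan -> region calling -> association.

#' Run the full domestication-scan pipeline
#'
#' Applies the read-support and MAF/missingness filters, computes windowed
#' pi for both populations and their ratio, windowed Weir-Cockerham FST
#' with top-quantile differentiated regions, LD-decay curves and decay
#' distances, the composite-likelihood sweep scan with region calling, and
#' (when a phenotype is supplied) the stratification-adjusted association
#' scan on the MAF-filtered SNP set.
#'
#' @param x A [GenotypeMatrix-class] (with AD assays for the read-support
#'   filter; without them that filter is skipped).
#' @param phenotype Optional phenotype (`data.frame` with `sample`/value
#'   columns, or named vector).
#' @param model A [SweepModel-class].
#' @param map Optional genetic map `data.frame` (`chrom`, `bp`, `cM`).
#' @param windowSize,step Sliding-window geometry in bp.
#' @param maf,maxMissing Association-set filters (defaults 0.05 / 0.10).
#' @param topGroup,topRegion,piTop Sweep region-calling fractions.
#' @param fstTop Differentiated-region fraction (default 0.01).
#' @param ldMaxDistance Maximum pair distance for the LD-decay curves
#'   (default 50 kb).
#' @param k,alpha Association adjustment axes and significance threshold.
#' @param wildPop,cultPop Population labels.
#' @return Named list: `genotypes` (filtered), `assocSet`, `piWild`,
#'   `piCult`, `piRatio`, `fst`, `fstRegions`, `ldWild`, `ldCult`,
#'   `ldDecayWild`, `ldDecayCult`, `clr`, `clrWindows`, `sweeps`,
#'   `assoc` (or `NULL`), `omega`.
#' @export
runDomesticationScan <- function(x, phenotype = NULL,
                                 model = SweepModel(), map = NULL,
                                 windowSize = 10000L, step = 1000L,
                                 maf = 0.05, maxMissing = 0.10,
                                 topGroup = 0.03, topRegion = 0.01,
                                 piTop = 0.50, fstTop = 0.01,
                                 ldMaxDistance = 50000L,
                                 k = 10L, alpha = 1e-4,
                                 wildPop = "wild_progenitor",
                                 cultPop = "cultivated") {
    if (!is.null(alleleDepths(x)))
        x <- filterSiteSupport(x)
    assocSet <- filterMafMissing(x, maf = maf, maxMissing = maxMissing)

    piW <- windowedPi(x, wildPop, windowSize, step)
    piC <- windowedPi(x, cultPop, windowSize, step)
    piR <- piRatio(piW, piC)

    fst <- windowedFst(x, wildPop, cultPop, windowSize, step)
    fstRegions <- topQuantileRegions(fst, fstTop)

    ldW <- ldDecay(x, wildPop, maxDistance = ldMaxDistance)
    ldC <- ldDecay(x, cultPop, maxDistance = ldMaxDistance)

    clr <- clrScan(x, model, map, refPop = wildPop, objPop = cultPop)
    clrWin <- tabulateWindows(clr, windowSize)
    sweeps <- callSweeps(clrWin, piR, topGroup, topRegion, piTop)

    assoc <- NULL
    if (!is.null(phenotype))
        assoc <- gwasScan(assocSet, phenotype, k = k, alpha = alpha)

    list(genotypes = x, assocSet = assocSet,
         piWild = piW, piCult = piC, piRatio = piR,
         fst = fst, fstRegions = fstRegions,
         ldWild = ldW, ldCult = ldC,
         ldDecayWild = decayDistance(ldW),
         ldDecayCult = decayDistance(ldC),
         clr = clr, clrWindows = clrWin, sweeps = sweeps,
         assoc = assoc, omega = metadata(clr)$omega)
}

#' Write the pipeline products to files
#'
#' Deterministic plain-text outputs: BedGraph tracks for pi (both
#' populations), pi-ratio, FST and tabulated CLR windows; BED6 for
#' differentiated regions and sweep regions; TSVs for the LD-decay curves
#' and the association table.
#'
#' @param result List from [runDomesticationScan()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, a named character vector of paths.
#' @export
writePipelineOutputs <- function(result, dir) {
    if (!dir.exists(dir))
        dir.create(dir, recursive = TRUE)
    paths <- c(
        piWild = "pi_wild.bedgraph", piCult = "pi_cultivated.bedgraph",
        piRatio = "pi_ratio.bedgraph", fst = "fst.bedgraph",
        clrWindows = "clr_windows.bedgraph")
    paths <- vapply(paths, function(p) file.path(dir, p), character(1))
    writeBedGraph(result$piWild, paths[["piWild"]])
    writeBedGraph(result$piCult, paths[["piCult"]])
    writeBedGraph(result$piRatio, paths[["piRatio"]])
    writeBedGraph(result$fst, paths[["fst"]])
    writeBedGraph(result$clrWindows, paths[["clrWindows"]])
    paths[["fstRegions"]] <- file.path(dir, "differentiated_regions.bed")
    writeRegionsBed(result$fstRegions, paths[["fstRegions"]], "fst")
    paths[["sweeps"]] <- file.path(dir, "sweep_regions.bed")
    writeRegionsBed(result$sweeps, paths[["sweeps"]], "sweep")
    for (pop in c("ldWild", "ldCult")) {
        f <- file.path(dir, paste0(tolower(pop), ".tsv"))
        df <- result[[pop]]
        df$meanR2 <- .fmtNum(df$meanR2)
        write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
        paths[[pop]] <- f
    }
    if (!is.null(result$assoc)) {
        f <- file.path(dir, "association.tsv")
        df <- result$assoc
        df$stat <- .fmtNum(df$stat)
        df$p <- .fmtNum(df$p)
        write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
        paths[["assoc"]] <- f
    }
    invisible(paths)
}
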