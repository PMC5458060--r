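## Accessor generics and methods.

#' @name accessors
#' @title Accessors for popsweep objects
#' @param x A [GenotypeMatrix-class], [PopulationSim-class] or
#'   [SimTruth-class] object.
#' @param value Replacement value.
#' @description `genotypes()` returns the sites x samples dosage matrix;
#'   `alleleDepths()` the list of ref/alt depth matrices (or `NULL`);
#'   `refAllele()`/`altAllele()` the per-site alleles; `populations()` the
#'   per-sample population labels; `excludedSamples()` the exclusion flags.
#'   For simulations, `truth()`, `phenotypes()` and `simConfig()` return the
#'   ground truth, the phenotype table and the configuration;
#'   `sweepRegions()` returns planted sweep intervals.
NULL

#' @rdname accessors
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' @rdname accessors
#' @export
setMethod("genotypes", "GenotypeMatrix", function(x) assay(x, "GT"))

#' @rdname accessors
#' @export
setGeneric("alleleDepths", function(x) standardGeneric("alleleDepths"))

#' @rdname accessors
#' @export
setMethod("alleleDepths", "GenotypeMatrix", function(x) {
    if (!all(c("AD_REF", "AD_ALT") %in% names(assays(x))))
        return(NULL)
    list(ref = assay(x, "AD_REF"), alt = assay(x, "AD_ALT"))
})

#' @rdname accessors
#' @export
setGeneric("refAllele", function(x) standardGeneric("refAllele"))

#' @rdname accessors
#' @export
setMethod("refAllele", "GenotypeMatrix", function(x) rowRanges(x)$ref)

#' @rdname accessors
#' @export
setGeneric("altAllele", function(x) standardGeneric("altAllele"))

#' @rdname accessors
#' @export
setMethod("altAllele", "GenotypeMatrix", function(x) rowRanges(x)$alt)

#' @rdname accessors
#' @export
setGeneric("populations", function(x) standardGeneric("populations"))

#' @rdname accessors
#' @export
setMethod("populations", "GenotypeMatrix", function(x) {
    setNames(colData(x)$population, colnames(x))
})

#' @rdname accessors
#' @export
setGeneric("populations<-", function(x, value) standardGeneric("populations<-"))

#' @rdname accessors
#' @export
setMethod("populations<-", "GenotypeMatrix", function(x, value) {
    colData(x)$population <- as.character(value)
    x
})

#' @rdname accessors
#' @export
setGeneric("excludedSamples", function(x) standardGeneric("excludedSamples"))

#' @rdname accessors
#' @export
setMethod("excludedSamples", "GenotypeMatrix", function(x) {
    setNames(colData(x)$excluded, colnames(x))
})

#' @rdname accessors
#' @export
setGeneric("truth", function(x) standardGeneric("truth"))

#' @rdname accessors
#' @export
setMethod("truth", "PopulationSim", function(x) x@truth)

#' @rdname accessors
#' @export
setGeneric("phenotypes", function(x) standardGeneric("phenotypes"))

#' @rdname accessors
#' @export
setMethod("phenotypes", "PopulationSim", function(x) x@phenotype)

#' @rdname accessors
#' @export
setGeneric("simConfig", function(x) standardGeneric("simConfig"))

#' @rdname accessors
#' @export
setMethod("simConfig", "PopulationSim", function(x) x@config)

#' @rdname accessors
#' @export
setMethod("genotypes", "PopulationSim", function(x) x@genotypes)

#' @rdname accessors
#' @export
setGeneric("sweepRegions", function(x) standardGeneric("sweepRegions"))

#' @rdname accessors
#' @export
setMethod("sweepRegions", "SimTruth", function(x) x@sweepRegions)

#' @rdname accessors
#' @export
setMethod("sweepRegions", "PopulationSim", function(x) x@truth@sweepRegions)

#' @rdname accessors
#' @export
setGeneric("filterReport", function(x) standardGeneric("filterReport"))

#' @rdname accessors
#' @export
setMethod("filterReport", "GenotypeMatrix", function(x) {
    metadata(x)$filterReport
})
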