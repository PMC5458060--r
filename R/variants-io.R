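## VCF input/output, genotype-evidence calling and the site filters.

#' Call a diploid genotype from allele read depths
#'
#' A genotype needs at least three reads in total; each called allele must
#' be supported by more than 25% of the reads.  With `total = ref + alt`:
#' fewer than 3 reads gives missing; both allele fractions > 0.25 gives a
#' heterozygote (dosage 1); only the alt (ref) fraction > 0.25 gives a
#' homozygote dosage 2 (0).  A fraction of exactly 25% does not support the
#' allele, so e.g. `(ref = 3, alt = 1)` calls the reference homozygote.
#'
#' @param refReads,altReads Non-negative integer scalars, vectors or
#'   matrices of read counts (recycled to a common shape).
#' @return Integer dosages (0/1/2) with `NA` for missing, shaped like the
#'   input.
#' @examples
#' callGenotypesFromDepths(c(0, 3, 1), c(5, 1, 1))  # 2, 0, NA
#' @export
callGenotypesFromDepths <- function(refReads, altReads) {
    if (any(refReads < 0, na.rm = TRUE) || any(altReads < 0, na.rm = TRUE))
        stop("read counts must be non-negative")
    total <- refReads + altReads
    fAlt <- ifelse(total > 0, altReads / total, 0)
    fRef <- ifelse(total > 0, refReads / total, 0)
    out <- ifelse(total < 3, NA_integer_,
           ifelse(fAlt > 0.25 & fRef > 0.25, 1L,
           ifelse(fAlt > 0.25, 2L,
           ifelse(fRef > 0.25, 0L, NA_integer_))))
    if (is.matrix(refReads))
        out <- matrix(as.integer(out), nrow(refReads), ncol(refReads),
                      dimnames = dimnames(refReads))
    else
        out <- as.integer(out)
    out
}

#' Read a population/sample table
#'
#' Tab-separated file with columns `sample`, `population`
#' (`wild_progenitor`, `cultivated` or `other`) and optionally `excluded`
#' (logical).
#'
#' @param path File path.
#' @return `data.frame` with columns `sample`, `population`, `excluded`.
#' @export
readSampleTable <- function(path) {
    df <- read.table(path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
    if (!all(c("sample", "population") %in% names(df)))
        stop("sample table needs 'sample' and 'population' columns")
    if (is.null(df$excluded))
        df$excluded <- FALSE
    df[c("sample", "population", "excluded")]
}

.gtToDosage <- function(gt) {
    codes <- c("0/0" = 0L, "0|0" = 0L, "0/1" = 1L, "1/0" = 1L,
               "0|1" = 1L, "1|0" = 1L, "1/1" = 2L, "1|1" = 2L)
    out <- codes[gt]
    matrix(out, nrow(gt), ncol(gt), dimnames = dimnames(gt))
}

.extractAD <- function(ad, i) {
    ## VariantAnnotation returns AD (Number=R) as a 3-d array or a
    ## list-matrix depending on uniformity.
    if (is.array(ad) && length(dim(ad)) == 3L)
        return(ad[, , i, drop = TRUE])
    if (is.list(ad)) {
        m <- matrix(vapply(ad, function(v) {
            if (length(v) >= i && !is.na(v[i])) as.integer(v[i]) else NA_integer_
        }, integer(1)), nrow(ad), ncol(ad))
        dimnames(m) <- dimnames(ad)
        return(m)
    }
    stop("unrecognised AD representation")
}

#' Read biallelic SNP genotypes from a VCF
#'
#' Parses GT (and AD when present) with `VariantAnnotation`.  Multi-allelic
#' and indel records are skipped and counted; `./.` genotypes become
#' missing.
#'
#' @param path VCF v4.x file.
#' @param sampleTable Optional `data.frame` as from [readSampleTable()];
#'   population labels are joined onto the samples.
#' @return A [GenotypeMatrix-class]; `metadata(x)$skipped` holds the count
#'   of non-SNP/multi-allelic records.
#' @export
readGenotypeVcf <- function(path, sampleTable = NULL) {
    vcf <- tryCatch(suppressWarnings(readVcf(path)),
                    error = function(e)
                        stop("VCF parse error in '", path, "': ",
                             conditionMessage(e), call. = FALSE))
    rr <- rowRanges(vcf)
    refs <- as.character(ref(vcf))
    altList <- alt(vcf)
    nAlt <- lengths(altList)
    altFirst <- rep(NA_character_, length(nAlt))
    altFirst[nAlt == 1L] <- as.character(unlist(altList[nAlt == 1L]))
    keep <- nAlt == 1L & nchar(refs) == 1L & !is.na(altFirst) &
        nchar(altFirst) == 1L &
        refs %in% c("A", "C", "G", "T") & altFirst %in% c("A", "C", "G", "T")
    skipped <- sum(!keep)
    gt <- .gtToDosage(geno(vcf)$GT[keep, , drop = FALSE])
    refD <- altD <- NULL
    if ("AD" %in% names(geno(vcf))) {
        ad <- geno(vcf)$AD[keep, , drop = FALSE]
        refD <- .extractAD(ad, 1L)
        altD <- .extractAD(ad, 2L)
    }
    samples <- colnames(gt)
    population <- rep("other", length(samples))
    excluded <- rep(FALSE, length(samples))
    if (!is.null(sampleTable)) {
        m <- match(samples, sampleTable$sample)
        population[!is.na(m)] <- sampleTable$population[m[!is.na(m)]]
        excluded[!is.na(m)] <- sampleTable$excluded[m[!is.na(m)]]
    }
    sl <- seqlengths(rr)
    gm <- GenotypeMatrix(
        chrom = as.character(seqnames(rr))[keep],
        pos = start(rr)[keep],
        ref = refs[keep], alt = altFirst[keep],
        genotypes = gt, refDepth = refD, altDepth = altD,
        samples = samples, population = population, excluded = excluded,
        chromLengths = if (all(is.na(sl))) NULL else sl)
    metadata(gm)$skipped <- skipped
    gm
}

#' Write a GenotypeMatrix as VCF v4.2
#'
#' Emits one biallelic SNP record per site with `GT:AD` per sample
#' (`GT` from the dosage, `AD` from the stored depths or `.` when absent).
#' Output is plain text and byte-deterministic.
#'
#' @param x A [GenotypeMatrix-class].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
writeGenotypeVcf <- function(x, path) {
    gt <- genotypes(x)
    ad <- alleleDepths(x)
    gtStr <- matrix("./.", nrow(gt), ncol(gt))
    gtStr[!is.na(gt) & gt == 0L] <- "0/0"
    gtStr[!is.na(gt) & gt == 1L] <- "0/1"
    gtStr[!is.na(gt) & gt == 2L] <- "1/1"
    if (!is.null(ad)) {
        cell <- matrix(sprintf("%s:%d,%d", gtStr, ad$ref, ad$alt),
                       nrow(gt), ncol(gt))
        fmt <- "GT:AD"
    } else {
        cell <- gtStr
        fmt <- "GT"
    }
    chroms <- as.character(seqnames(rowRanges(x)))
    lens <- .chromLengths(x)
    header <- c(
        "##fileformat=VCFv4.2",
        "##source=popsweep",
        sprintf("##contig=<ID=%s,length=%d>", names(lens), as.integer(lens)),
        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
        "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
        paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                "INFO", "FORMAT", colnames(x)), collapse = "\t"))
    body <- paste(chroms, start(rowRanges(x)), ".", refAllele(x),
                  altAllele(x), ".", "PASS", ".", fmt,
                  apply(cell, 1L, paste, collapse = "\t"), sep = "\t")
    writeLines(c(header, body), path)
    invisible(path)
}

.addFilterReport <- function(x, name, report) {
    rep0 <- metadata(x)$filterReport
    if (is.null(rep0)) rep0 <- list()
    rep0[[name]] <- report
    metadata(x)$filterReport <- rep0
    x
}

#' Drop sites without read support for the alternate allele
#'
#' A site is kept only if at least one sample carries the alternate allele
#' on at least three reads.
#'
#' @param x A [GenotypeMatrix-class] with allele depths.
#' @return The filtered object; the dropped count is recorded in
#'   `filterReport(x)$siteSupport`.
#' @export
filterSiteSupport <- function(x) {
    ad <- alleleDepths(x)
    if (is.null(ad))
        stop("no allele depths (AD) present; skip the read-support filter")
    if (nrow(x) == 0L)
        return(.addFilterReport(x, "siteSupport",
                                list(kept = 0L, dropped = 0L)))
    maxAlt <- apply(ad$alt, 1L, max, na.rm = TRUE)
    keep <- maxAlt >= 3L
    out <- x[keep, ]
    .addFilterReport(out, "siteSupport",
                     list(kept = sum(keep), dropped = sum(!keep)))
}

#' Filter sites on minor allele frequency and missingness
#'
#' Keeps a site iff its minor allele frequency over non-missing alleles is
#' strictly greater than `maf` and its missing fraction over samples is
#' strictly less than `maxMissing`.
#'
#' @param x A [GenotypeMatrix-class].
#' @param maf MAF threshold in `[0, 0.5]` (default 0.05).
#' @param maxMissing Missingness threshold (default 0.10).
#' @return The filtered object; counts are recorded in
#'   `filterReport(x)$mafMissing`.
#' @export
filterMafMissing <- function(x, maf = 0.05, maxMissing = 0.10) {
    if (maf < 0 || maf > 0.5)
        stop("maf must lie in [0, 0.5]")
    gt <- genotypes(x)
    nMiss <- rowSums(is.na(gt))
    missFrac <- nMiss / ncol(gt)
    nGeno <- ncol(gt) - nMiss
    altFreq <- rowSums(gt, na.rm = TRUE) / (2 * pmax(nGeno, 1L))
    mafObs <- pmin(altFreq, 1 - altFreq)
    keep <- (maf == 0 | mafObs > maf) & (missFrac < maxMissing |
                                             maxMissing >= 1)
    keep[nGeno == 0L] <- maf == 0 & maxMissing >= 1
    out <- x[keep, ]
    .addFilterReport(out, "mafMissing",
                     list(kept = sum(keep), dropped = sum(!keep),
                          maf = maf, maxMissing = maxMissing))
}

#' Write the accumulated filter report as JSON
#'
#' @param x A filtered [GenotypeMatrix-class].
#' @param path Output JSON file.
#' @return Invisibly, `path`.
#' @export
writeFilterReport <- function(x, path) {
    rep <- filterReport(x)
    if (is.null(rep)) rep <- list()
    write_json(rep, path, auto_unbox = TRUE, pretty = TRUE)
    invisible(path)
}
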