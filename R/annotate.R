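## Site-class annotation: codon degeneracy and coding effect of SNPs from
## GFF3 gene models and the genome FASTA.

.COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

.loadGenome <- function(fasta) {
    if (is.character(fasta)) {
        g <- readDNAStringSet(fasta)
        names(g) <- sub("\\s.*$", "", names(g))
        g
    } else fasta
}

.loadGff <- function(gff) {
    if (is.character(gff)) import(gff) else gff
}

.parentOf <- function(gr) {
    p <- gr$Parent
    if (is.null(p)) return(as.character(gr$ID))
    if (is(p, "List") || is.list(p))
        vapply(p, function(v) if (length(v)) as.character(v[1]) else NA_character_,
               character(1))
    else as.character(p)
}

## Assemble per-transcript CDS models: exon coordinates, strand, phase of
## the transcription-first segment, and the spliced CDS sequence.
.transcriptModels <- function(gffGr, genome) {
    cds <- gffGr[gffGr$type == "CDS"]
    if (length(cds) == 0L)
        return(list())
    par <- .parentOf(cds)
    models <- lapply(split(seq_along(cds), par), function(idx) {
        ex <- cds[idx]
        o <- order(start(ex))
        ex <- ex[o]
        ch <- as.character(seqnames(ex))[1]
        str <- as.character(strand(ex))[1]
        phase <- ex$phase
        if (is.null(phase)) phase <- rep(0L, length(ex))
        phase[is.na(phase)] <- 0L
        ph <- if (str == "-") phase[length(ex)] else phase[1]
        segs <- lapply(seq_along(ex), function(i) {
            s <- as.character(subseq(genome[[ch]], start(ex)[i], end(ex)[i]))
            strsplit(s, "")[[1]]
        })
        bases <- unlist(segs)                 # genomic ascending order
        posVec <- unlist(lapply(seq_along(ex),
                                function(i) start(ex)[i]:end(ex)[i]))
        L <- length(bases)
        if (str == "-") {
            cdsChars <- unname(.COMP[rev(bases)])
            cdsIndex <- L - seq_len(L) + 1L   # cds position of genomic base i
        } else {
            cdsChars <- bases
            cdsIndex <- seq_len(L)
        }
        list(chrom = ch, strand = str, exons = ex, phase = ph,
             posVec = posVec, cdsIndex = cdsIndex, cdsChars = cdsChars)
    })
    models
}

.translateCodon <- function(codon) {
    aa <- GENETIC_CODE[codon]
    ifelse(is.na(aa), "X", aa)
}

## Check a model for frame and internal stops; returns NULL (with a warning)
## when the model is unusable.
.checkModel <- function(m, name) {
    eff <- length(m$cdsChars) - m$phase
    if (eff %% 3L != 0L) {
        warning("CDS length of ", name, " not divisible by 3; gene skipped")
        return(NULL)
    }
    seq <- m$cdsChars[(m$phase + 1L):length(m$cdsChars)]
    codons <- vapply(seq(1L, length(seq), 3L),
                     function(i) paste(seq[i:(i + 2L)], collapse = ""),
                     character(1))
    aa <- .translateCodon(codons)
    if (any(aa[-length(aa)] == "*")) {
        warning("internal stop codon in ", name, "; gene skipped")
        return(NULL)
    }
    m$codons <- codons
    m$aa <- aa
    m
}

.annotationEngine <- function(x, gff, fasta) {
    gffGr <- .loadGff(gff)
    genome <- .loadGenome(fasta)
    models <- .transcriptModels(gffGr, genome)
    rr <- rowRanges(x)
    chromS <- as.character(seqnames(rr))
    posS <- start(rr)
    refS <- refAllele(x)
    altS <- altAllele(x)
    nS <- length(posS)

    ## reference-allele consistency against the FASTA
    for (ch in unique(chromS)) {
        if (!ch %in% names(genome)) next
        i <- which(chromS == ch)
        gBase <- as.character(Biostrings::extractAt(
            genome[[ch]], IRanges(posS[i], width = 1L)))
        bad <- gBase != refS[i]
        if (any(bad))
            stop("reference allele disagrees with FASTA at: ",
                 paste(sprintf("%s:%d (vcf %s, fasta %s)", ch, posS[i][bad],
                               refS[i][bad], gBase[bad]), collapse = ", "))
    }

    degCount <- rep(NA_integer_, nS)
    effect <- rep("noncoding", nS)
    codonIdx <- rep(NA_integer_, nS)

    for (name in names(models)) {
        m <- .checkModel(models[[name]], name)
        if (is.null(m)) next

        ## splice sites: first/last 2 bp of each intron
        ex <- m$exons
        if (length(ex) > 1L) {
            for (i in seq_len(length(ex) - 1L)) {
                is0 <- end(ex)[i] + 1L
                ie0 <- start(ex)[i + 1L] - 1L
                if (ie0 < is0) next
                splicePos <- unique(c(is0, min(is0 + 1L, ie0),
                                      max(ie0 - 1L, is0), ie0))
                hit <- chromS == m$chrom & posS %in% splicePos
                effect[hit & effect == "noncoding"] <- "splice_site"
            }
        }

        inTx <- which(chromS == m$chrom & posS %in% m$posVec &
                          is.na(degCount))
        if (!length(inTx)) next
        gi <- match(posS[inTx], m$posVec)
        cp <- m$cdsIndex[gi] - m$phase
        ok <- cp >= 1L
        inTx <- inTx[ok]; cp <- cp[ok]
        if (!length(inTx)) next
        ci <- (cp - 1L) %/% 3L
        off <- (cp - 1L) %% 3L
        for (k in seq_along(inTx)) {
            site <- inTx[k]
            codon <- m$codons[ci[k] + 1L]
            aa0 <- .translateCodon(codon)
            chars <- strsplit(codon, "")[[1]]
            variants <- vapply(c("A", "C", "G", "T"), function(b) {
                v <- chars; v[off[k] + 1L] <- b
                paste(v, collapse = "")
            }, character(1))
            degCount[site] <- sum(.translateCodon(variants) == aa0)
            codonIdx[site] <- ci[k]
            altCds <- if (m$strand == "-") unname(.COMP[altS[site]])
                      else altS[site]
            newCodon <- chars
            newCodon[off[k] + 1L] <- altCds
            aa1 <- .translateCodon(paste(newCodon, collapse = ""))
            effect[site] <-
                if (aa0 == "*" && aa1 != "*") "start_stop"         # stop loss
                else if (aa1 == "*" && aa0 != "*") "start_stop"    # stop gain
                else if (ci[k] == 0L && aa1 != aa0) "start_stop"   # start change
                else if (aa1 == aa0) "synonymous"
                else "nonsynonymous"
        }
    }

    degeneracy <- rep("noncoding", nS)
    degeneracy[!is.na(degCount)] <-
        c("0-fold", "2-fold", "3-fold", "4-fold")[degCount[!is.na(degCount)]]
    DataFrame(degeneracy = degeneracy, degCount = degCount,
              effect = effect, codonIndex = codonIdx)
}

#' Annotate SNP sites with codon degeneracy
#'
#' For every SNP inside an annotated CDS, determines the codon and
#' within-codon offset (honouring strand and phase) and counts how many of
#' the four nucleotides at that offset encode the same amino acid under the
#' standard genetic code: 4 gives a fourfold-degenerate site.  Sites outside
#' any CDS are `"noncoding"`.  Genes whose joined CDS contains an internal
#' stop or is not a multiple of 3 long are skipped with a warning; a SNP
#' reference allele that disagrees with the FASTA is an error.
#'
#' @param x A [GenotypeMatrix-class].
#' @param gff GFF3 path or an imported `GRanges` with `type`, `ID`,
#'   `Parent` and `phase`.
#' @param fasta Genome FASTA path or a `DNAStringSet`.
#' @return A `DataFrame` (one row per site) with columns `degeneracy`
#'   (`"noncoding"`, `"0-fold"`, `"2-fold"`, `"3-fold"`, `"4-fold"`),
#'   `degCount`, and `codonIndex`.
#' @export
annotateDegeneracy <- function(x, gff, fasta) {
    ann <- .annotationEngine(x, gff, fasta)
    ann[c("degeneracy", "degCount", "codonIndex")]
}

#' Classify the coding effect of each SNP
#'
#' Substitutes the alternate allele into its codon: same amino acid gives
#' `"synonymous"`, a different one `"nonsynonymous"`; gain or loss of a stop
#' codon, or any change in the annotated start codon, gives `"start_stop"`;
#' a SNP in the first or last 2 bp of an annotated intron gives
#' `"splice_site"`; everything else is `"noncoding"`.
#'
#' @inheritParams annotateDegeneracy
#' @param siteClass Optional result of [annotateDegeneracy()] (accepted for
#'   symmetry; the classification is computed from the gene models either
#'   way).
#' @return Character vector of effects, one per site.
#' @export
classifyCodingEffect <- function(x, gff, fasta, siteClass = NULL) {
    ann <- .annotationEngine(x, gff, fasta)
    ann$effect
}
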