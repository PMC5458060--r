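# popsweep

Population-genomic analysis of crop domestication from
transcriptome-derived SNPs.

Leafy crops such as spinach were domesticated from wild progenitors
recently enough that the genome-wide loss of diversity is mild — a weak
domestication bottleneck — and the footprints of selection are confined
to localized *selective sweeps*.  `popsweep` implements the full desk
analysis for such a system, starting from a VCF of biallelic SNPs called
in a wild-progenitor panel and a cultivated panel:

* **Genotype evidence filters** — a genotype needs ≥ 3 reads and each
  called allele > 25% of them; sites need ≥ 3 alt-supporting reads in
  some sample, minor allele frequency > 5% and missingness < 10% for the
  association set.
* **Diversity and differentiation** — per-site nucleotide diversity
  π = c₁(n−c₁)/C(n,2) summed in 10-kb windows (1-kb step) per bp; the
  π_w/π_c ratio; Weir–Cockerham (1984) F<sub>ST</sub> as the
  ratio-of-sums Σa/Σ(a+b+c) per window, with top-1% differentiated
  regions.
* **Linkage disequilibrium** — EM-based r² between unphased genotype
  pairs (exact Hardy–Weinberg filtering), distance-binned decay curves
  and the distance at which r² falls to 0.2.
* **Sweep scan** — a cross-population composite likelihood ratio
  (XP-CLR-style): a truncated-normal drift null
  p₁ ~ N(p₀, ω·p₀(1−p₀)) against a hitchhiking mixture with escape
  probability c = 1 − exp(−d·ln(2Nₑs)/s), evaluated on a 100-bp grid in
  0.0005-Morgan windows of ≤ 100 SNPs with 1/m correlation
  down-weighting, tabulated as 10-kb window maxima; adjacent top-3%
  windows merge into regions, top-1% regions are candidate sweeps, and
  regions outside the top half of the π-ratio track are excluded.
* **Association** — EIGENSTRAT-style quantitative-trait GWAS for
  bolting days: genotype and phenotype residualized on the top 10
  genotype principal components, stat = (n−k−1)ρ² ~ χ²₁, fixed threshold
  P < 10⁻⁴.
* **Synthetic data** — a Balding–Nichols two-population simulator
  (F_wild = 0.05, F_cult = 0.10) with transcriptome-restricted SNP
  placement, Markov haplotype copying for LD, planted 50-kb sweeps,
  Poisson read depths with missingness, and a causal bolting SNP — so
  the whole pipeline is testable with known truth and no downloads.

The central objects are Bioconductor-style: genotypes live in a
`GenotypeMatrix` (a `RangedSummarizedExperiment` subclass), window
statistics and regions are `GRanges`.

## Worked example

Simulate the default two-population study (two 5-Mb chromosomes, 20,000
transcriptome SNPs, 8 wild / 30 cultivated accessions, three planted
50-kb sweeps of intensity 0.9) and run the full analysis:

```r
library(popsweep)

sim <- simulatePopulations(SimConfig(seed = 1L))
res <- runDomesticationScan(genotypes(sim), phenotypes(sim))

mean(res$piWild$value)            # 0.0006017024  (pi_w per bp)
mean(res$piCult$value)            # 0.0005661243  (pi_c per bp)
median(res$piRatio$value, na.rm = TRUE)   # 1.05656
mean(res$fst$value, na.rm = TRUE)         # 0.08754101
res$ldDecayCult                   # 758.0266 bp  (r2 = 0.2 crossing)
res$omega                         # 0.2979287 (drift variance scale)
res$sweeps
## GRanges object with 3 ranges and 2 metadata columns:
##       seqnames          ranges strand |     score  nWindows
##   [1]     chr1 1000001-1060000      * |   416.524         6
##   [2]     chr1 3180001-3270000      * |   470.991         9
##   [3]     chr2 1990001-2060000      * |   321.901         7
```

Wild diversity exceeds cultivated diversity (the weak bottleneck), mean
windowed F<sub>ST</sub> sits near the Balding–Nichols expectation for
(F_w, F_c) = (0.05, 0.10), and the three called sweep regions coincide
with the three planted intervals (chr1:1.00–1.05 Mb, chr1:3.20–3.25 Mb,
chr2:2.00–2.05 Mb) with scores far above the neutral background.  Note
ω estimated from *observed* wild frequencies absorbs wild drift and
reference sampling noise, so it exceeds F_cult by design; window
rankings are insensitive to this scale.  The GWAS on the simulated
bolting phenotype is in `res$assoc`; with the default 30-accession
cultivated panel the causal SNP is near, but not always past, the fixed
10⁻⁴ threshold — the 59-accession panel used in `scripts/acceptance.R`
recovers it decisively.

All outputs can be written as BedGraph/BED/TSV with
`writePipelineOutputs(res, "out/")`, and the simulated study itself as
VCF + GFF3 + FASTA + phenotype TSV + truth BED with
`writeSimOutputs(sim, "simdata/")`.

## Scope

The package deliberately omits read alignment and variant calling
upstream of the VCF, haplotype-based selection statistics (iHS,
XP-EHH), model-based ancestry clustering, coalescent significance
testing, and mixed-model association.  See the methods vignette
(`vignettes/domestication-scan.Rmd`) for the model derivations, the
simulator's design and its limitations.
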