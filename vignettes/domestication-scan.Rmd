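---
title: "Methods: scanning transcriptome SNPs for domestication signals"
author: "popsweep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scanning transcriptome SNPs for domestication signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The analysis in one paragraph

`popsweep` contrasts a cultivated crop population against its wild
progenitor using SNPs ascertained from transcriptome sequencing.  The
pipeline (i) re-calls genotypes from read evidence and filters sites,
(ii) summarises diversity as windowed nucleotide diversity ($\pi$), the
$\pi_w/\pi_c$ ratio and windowed Weir–Cockerham $F_{ST}$, (iii) measures
linkage-disequilibrium decay, (iv) scans the genome with a
cross-population composite likelihood ratio (XP-CLR-style) that contrasts
a pure-drift null against a hitchhiking model of cultivated allele
frequencies, calling sweep regions by quantile thresholding with a
$\pi$-ratio cross-filter, and (v) tests a quantitative bolting phenotype
for association with principal-component stratification correction.  A
fully synthetic two-population simulator provides inputs with known
truth, so every stage is testable offline.

# Population-genetic summaries

**Per-site $\pi$.**  With $c_1$ alternate alleles among $n$ non-missing
alleles, $\pi = c_1 (n - c_1) / \binom{n}{2}$, the mean pairwise
difference.  Sliding windows (10 kb, 1-kb step, anchored at zero on each
chromosome) sum per-site $\pi$ and divide by the window span in bp, so
invariant positions contribute zero diversity.  The trailing partial
windows keep the full-span denominator and are flagged.  The span
denominator is a deliberate choice: with transcriptome data the
"callable" span is ill-defined, and a per-SNP alternative
(`denominator = "sites"`) is exposed instead of guessed.

Sites enter the $\pi$ calculation only when genotyped in at least 90% of
the accessions.  The genotyped fraction is computed over *all*
non-excluded accessions by default (`genotypedScope = "all"`), so the
wild and cultivated $\pi$ tracks use the same site set.  A per-population
scope is available, but with very small wild panels (8 accessions) it
degenerates into a fully-genotyped-only filter that deletes a third of
the wild diversity mass and biases the $\pi$ ratio downward.

**$F_{ST}$.**  The Weir–Cockerham (1984) variance components $a$ (among
populations), $b$ (among individuals) and $c$ (within individuals) are
computed per site from sample sizes, allele frequencies and observed
heterozygosities; windows report the ratio of sums
$\sum a / \sum (a+b+c)$.  Negative per-site components are retained in
the sums, which is standard for this estimator.  Windows with no
polymorphic site, or a zero denominator, are undefined and excluded from
quantiles.

**Regions.**  "Top $q$" thresholds are the inverse-ECDF (type-1)
empirical quantile at $1-q$; all windows with values greater than or
equal to the threshold pass, so ties at the threshold are included.
Passing windows that overlap or abut merge into regions (sliding 10-kb
windows 1 kb apart overlap by 9 kb, so threshold runs merge naturally);
a region's score is its maximum member window.

# Linkage disequilibrium

$r^2$ between unphased genotype pairs is computed from two-locus
haplotype frequencies estimated by EM over the phase ambiguity of double
heterozygotes (at most 50 iterations or change $< 10^{-8}$), with
pairwise-complete samples.  Sites must pass a strict MAF filter
(default $>0.05$) and an exact Hardy–Weinberg test (conditional on
allele counts; drop when $p < 0.001$) first, mirroring the conventions
of the standard LD software.  The exact test sums the probabilities of
all heterozygote configurations no more probable than the observed one;
monomorphic sites return 1 by convention.  `maxDistance` defaults to
1 Mb, reading the conventional `maxdistance 1000` in kb.  The decay
distance is the first point where linear interpolation between 1-kb bin
means crosses $r^2 = 0.2$ from above; it is undefined when the curve
never exceeds or never reaches the threshold, rather than extrapolated.

# The cross-population composite-likelihood scan

The scan asks, at every 100-bp grid point, whether cultivated allele
frequencies near that point are better explained by drift alone or by a
recent sweep in the cultivated lineage, using the wild progenitor as the
frequency reference.

**Drift null.**  For a SNP with reference frequency $p_0$, the latent
cultivated frequency is $N(p_0, \omega\, p_0 (1-p_0))$ truncated to
$(0,1)$, with the truncated tail masses placed as point masses at 0 and
1; the observed alternate count is binomial given the latent frequency.
$\omega$ is estimated genome-wide by a method-of-moments contrast that
subtracts binomial sampling noise, clipped below at $10^{-6}$.  With
observed (rather than true) reference frequencies the estimate absorbs
reference drift and reference sampling noise as well — that is what real
data offer, and for ranking windows only the overall scale matters.

**Hitchhiking model.**  A lineage at genetic distance $d$ Morgans from a
sweep with selection coefficient $s$ escapes with probability
$c = 1 - \exp(-d \ln(2 N_e s)/s)$ (clipped to $[0,1]$; $c = 1$ when
$2 N_e s \le 1$, no effective sweep).  The sweep likelihood is the
mixture $c\,L_{\text{null}} + (1-c)\,L_{\text{swept}}$.  The swept
branch lets each lineage escape the sweeping background independently:
the beneficial background (probability $p_0$ of carrying the derived
allele) ends at frequency $1 - c(1-p_0)$, the lost background at
$c\,p_0$, both bounded away from the boundary by
$\varepsilon = 1/(2N_e)$.  At $c = 0$ this degenerates to near-fixation
vs near-loss; at $c = 1$ the whole mixture reduces *exactly* to the
null, so the family nests.  An all-or-nothing swept branch (point masses
at $1-\varepsilon$ and $\varepsilon$ regardless of $c$) was evaluated
and rejected: under realistic escape (a few percent of haplotypes) sites
that are almost but not exactly fixed then testify strongly against a
sweep, and whole planted sweeps become invisible.

**Composite score.**  SNPs within $\pm 0.0005/2$ Morgans of the grid
point (at most 100, keeping the nearest) contribute weighted
log-likelihood ratios; SNP $i$'s weight is $1/m_i$ with $m_i$ the number
of kept SNPs (including itself) whose reference-population dosage
correlation squared exceeds 0.7, which discounts redundant tightly
linked SNPs.  The score is
$2 \max\!\big(0, \max_s \sum_i w_i [\ell_{\text{sweep}} - \ell_{\text{null}}]\big)$
over a 15-point log-spaced grid of $s \in [10^{-4}, 0.5]$; clamping at
zero corresponds to including the no-sweep boundary $s \to 0$ in the
maximisation and guarantees non-negative scores.  Genetic positions come
from piecewise-linear interpolation of map anchors, extrapolated (or
replaced entirely) at 1 cM/Mb.

**Region calling.**  Grid scores are tabulated into non-overlapping
10-kb windows by the maximum; windows in the top 3% of defined values
are merged into regions scored by their maximum window; regions whose
score reaches the top-1% quantile of window values are candidate sweeps;
regions not overlapping any window in the top half of the
$\pi_w/\pi_c$ track are excluded (a sweep should also reduce cultivated
diversity).  One practical guard: neutral windows produce a large atom
of exactly-zero scores (no $s$ beats the null anywhere), and an
inverse-ECDF threshold that lands on that atom would, with tie
inclusion, pass every zero window; CLR thresholding therefore also
requires positive evidence.  The top-1% cut is applied on the
window-value scale; applying it among region scores instead is a
documented alternative reading.

**Numerics.**  The latent-frequency integral uses 512 quantile-spaced
nodes of the truncated normal, each carrying an equal share of the
interior mass.  This scheme is *mass-exact* — per-SNP likelihoods sum to
one over all observable counts by construction — and remains accurate as
$\omega \to 0$, where a uniform grid under-resolves the narrowing
density and collapses to zero likelihood.  Refining 512 to 4096 nodes
moves log-likelihoods by well under $10^{-4}$ on the test suite.

# Stratification-corrected association

Genotypes are mean-imputed per site, centred and scaled by
$\sqrt{\hat p (1-\hat p)}$; monomorphic sites are dropped.  The top
$k = 10$ eigenvectors of the sample covariance of this matrix are the
stratification axes (sign fixed so the largest-magnitude coordinate is
positive).  Both genotype and phenotype are residualized on the axes
plus an intercept, and the statistic is $(n - k - 1)\rho^2$ with $\rho$
the residual correlation, referred to $\chi^2_1$ — the quantitative-trait
form of the adjusted test, since bolting is measured in days (raw days,
untransformed).  Significance uses the fixed threshold $p < 10^{-4}$
with no multiple-testing correction, as is conventional for this scan
size; no genomic-control rescaling is applied.  The PCA uses the same
MAF/missingness-filtered SNP set that is tested.

# The synthetic data generator

The generator is designed for *testability*: every stage has a
closed-form expectation that tests can pin.

* **Frequencies.** Ancestral frequencies are Uniform(0.05, 0.95);
  population frequencies follow the Balding–Nichols law
  $\mathrm{Beta}(p(1-F)/F,\ (1-p)(1-F)/F)$, whose conditional variance
  is exactly $F\,p(1-p)$.  Defaults $F_w = 0.05$, $F_c = 0.10$ encode a
  weak cultivation bottleneck.
* **Linkage.** Haplotypes carry a latent uniform template redrawn with
  probability $1 - e^{-\Delta/\lambda}$ per inter-SNP gap
  ($\lambda = 2$ kb), so per-site marginals are exact Bernoulli($p$)
  while nearby sites correlate.  Because adjacent sites draw independent
  Balding–Nichols frequencies, the achievable adjacent-site $r^2$ is
  bounded well below 1 and the simulated decay crosses $r^2 = 0.2$
  within roughly a kilobase — shorter-range than real data, but with the
  same qualitative monotone decay the tests exercise.
* **Sweeps.** Each cultivated haplotype is independently swept with
  probability `intensity` (default 3 sweeps of 50 kb at 0.9); swept
  haplotypes carry the beneficial allele throughout the interval,
  mirroring the hitchhiking mixture the scan assumes.  At intensity 0.9
  the residual diversity of escaped haplotypes makes the
  sweep-interior/genome-median $\pi$ contrast hover near 25–30% and
  seed-dependent; the seed-fixed regression test uses the canonical
  study seed.
* **Reads and genotypes.** Depth is Poisson(20) per sample/site with 5%
  masking; alternate reads are binomial in the true dosage.  Genotypes
  are then re-called by the evidence rules (three reads minimum, both
  alleles needing $> 25\%$ of reads), so the filters are exercised on
  realistic evidence, including the occasional heterozygote miscalled
  homozygous at moderate depth.
* **Phenotype.** Bolting days are linear in the causal dosage
  (5 days/allele, residual SD 2 days, baseline 60 days) over the
  cultivated panel.  The causal site is chosen deterministically:
  a mid-genome site with cultivated MAF $\ge 0.25$ outside sweeps.
* **Scale.** Two 5-Mb chromosomes with 20,000 SNPs confined to tiled
  1.4-kb gene models (600-bp CDS, 200-bp intron, 600-bp CDS, alternating
  strands) emulate transcriptome ascertainment, give coding/noncoding
  and fourfold-degenerate site classes, and keep a full pipeline run in
  the low minutes on one CPU; 8 wild vs 30 cultivated accessions match
  a realistically lopsided germplasm panel.  Sample sizes, window
  geometry and all thresholds are the study defaults, not tuned
  quantities.

What the generator does **not** emulate: coalescent genealogies and
recombination hotspots, selection dynamics forward in time, RNA-seq
coverage heterogeneity along transcripts, sequencing error reads, or
multi-allelic variation.  Passing tests therefore demonstrate the
correctness of the estimators and the scan's power against this
idealised structure, not calibration on real transcriptome data.

# Degenerate inputs and conventions

Internally coordinates are 0-based half-open; VCF/GFF are 1-based at the
boundary, converted only in readers/writers.  Multi-allelic and indel
records are skipped with a count.  Allele-depth calls at exactly 25%
call the majority homozygote.  Monomorphic sites: $\pi = 0$, HWE $p = 1$,
$r^2$ undefined, dropped from normalization.  $\pi$-ratio windows with
zero cultivated diversity are undefined, not infinite.  A population
entirely missing at a site is skipped for $F_{ST}$.  Genes whose joined
CDS has an internal stop or a non-multiple-of-3 length are skipped with
a warning; a reference allele disagreeing with the FASTA is an error.
All simulator randomness flows from one integer seed; analyses are
RNG-free, so a fixed seed makes the whole pipeline byte-deterministic.

# Known limitations

* The wild reference panel (8 accessions) makes reference frequencies
  noisy; $\omega$ estimated from observed wild frequencies is inflated
  relative to the cultivated drift alone (it absorbs wild drift and
  reference sampling noise).  Rankings are insensitive to this scale,
  but $\omega$ should not be read as an estimate of $F_c$ unless the
  reference frequencies are known.
* The $s$ grid's lower end at $10^{-4}$ keeps $2N_e s > 1$; selection
  weaker than that is indistinguishable from drift by design.
* Haplotype-based statistics (iHS, XP-EHH), site-frequency-spectrum
  scans and coalescent-based significance are out of scope, as are
  mixed-model association and kinship corrections.
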