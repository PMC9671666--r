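---
title: "Models and methods behind apomixkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind apomixkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

apomixkit implements the population-genomic analyses used to study the
evolution of apomixis (nucellar embryony) in Citrinae: where apomixis
alleles came from (introgression statistics), what clonal reproduction does
to deleterious load (burden accounting and forward simulation), where the
apomixis locus maps (bulked-segregant analysis), and what the causal
promoter insertion looks like (MITE unit decomposition). Every analysis
runs end-to-end on synthetic data with recorded ground truth; this vignette
explains the models, the defaults, and what the synthetic validation does
and does not show about real data.

## Data model and shared machinery

Variants (SNPs and SVs) live in a sorted biallelic table with per-site
annotations (SIFT score, LOF flag, SV type and length, ancestral state);
genotypes are a samples x variants dosage matrix, optionally phased.
Internally all intervals are 0-based half-open; VCF positions are converted
at I/O. Multi-allelic records are dropped by default (all statistics are
biallelic) with an optional split mode.

**Polarization.** The ancestral allele is the outgroup major allele. Sites
where the outgroup minor-allele frequency exceeds `max_og_minor` (default
0.1), or where the outgroup is uncalled, are excluded from polarized
statistics. The rule is deliberately simple and idempotent; missing
genotypes never enter frequency denominators (no imputation), and each
population needs at least `min_n = 2` called alleles per site.

**Block jackknife.** Genome-wide ratio statistics (D, f4, f4-ratio, f-hom)
get standard errors from a Busing-style weighted delete-one-block
jackknife over 20 equal-span genomic blocks, with weights equal to the
informative sites per block; Z = estimate/SE and a two-sided normal
p-value. When all leave-one-out estimates coincide the SE is zero and the
result carries a degenerate flag rather than a fabricated p-value.
Multiple testing uses Benjamini-Hochberg step-up q-values throughout.

## Introgression statistics

Site patterns use the frequency (population-level) formulation:
`abba = (1-p1) p2 p3 (1-pO)`, `baba = p1 (1-p2) p3 (1-pO)`, with
`D = sum(abba-baba)/sum(abba+baba)`. The window estimator f_d replaces P2
and P3 in the denominator by whichever has the higher derived frequency at
each site, and is reported only where window D >= 0 (outside that domain
the estimator is undefined); the genome-wide figure is the mean over
defined windows. f4 is the mean site product `(pA-pB)(pC-pD)`; the
f4-ratio alpha divides two f4 statistics in Patterson's admixture
configuration, with the population roles always given explicitly. The
f-branch summary assigns excess sharing to tree branches via the
median-of-minima of f-hom estimates over the rooted binary population
tree; donors descended from the focal branch are undefined by
construction, and significance comes from the jackknife p of the pair
realising the median, BH-corrected across the matrix.

**Window sizes.** Window statistics need enough informative sites to be
stable: f_d in particular is noisy and upward-selected in windows with few
sites (windows with D < 0 drop out, leaving positive noise). We therefore
size windows by expected informative sites, not bp: at the synthetic
density (30k SNPs over 50 Mb) a 500 kb window holds ~150 usable sites,
comparable to a 25 kb window at a real resequencing density of ~6 sites
per kb. Windows with fewer than `min_sites` (default 10; 20 in the
scan drivers) informative sites are `NA`, never 0.

**Diagnostic markers.** Species-specific markers are sites fixed for
different alleles between two reference panels (`min_delta = 1`). A
sample's donor ancestry is its donor-allele dosage summed over genotyped
markers divided by twice the marker count; fragments are maximal runs of
windows with donor fraction >= 0.5 (one heterozygous donor tract gives
0.5). Markers ascertained as "fixed in the panel" can still segregate at
low frequency in the population, which inflates recovered ancestry by
about +0.01 at our panel sizes; a 30-sample reference panel keeps this
within the validation band. This is a known property of diagnostic-marker
profiling, not specific to the synthetic data.

## Synthetic cohort

Genotypes follow the Balding-Nichols model: ancestral frequencies from a
symmetric Beta(0.5, 0.5), population frequencies from Beta distributions
parameterised by a per-population drift parameter F, haplotypes Bernoulli.
Defaults: three ingroup populations of 20 samples at F = 0.3, an outgroup
of 8 samples at F = 0.99 (near-fixed, standing in for a diverged genus),
50k SNPs on five 10 Mb chromosomes. Two populations drifted at F have
pairwise Hudson Fst = F in expectation, which the tests verify.

Introgression is planted by replacing tracts of recipient haplotypes with
random donor haplotype segments: geometric tract lengths (mean 1 Mb),
placed without overlap via stick-breaking gaps, with the last tract
trimmed so the planted fraction is exact — recovery checks then measure
the profiler, not generator jitter. The admixture-validation cohort uses
40 samples per population and a donor at F = 0.7: truly diagnostic
markers only exist between strongly diverged species (the real analysis
uses mandarin-vs-pummelo species markers), and the Balding-Nichols star
topology means the f4-ratio needs a donor-side reference that shares the
donor's drift — supplied by splitting the donor panel in half.

What this emulates: drift-structured frequencies, planted ancestry tracts,
SIFT-like annotations, read-depth sampling. What it does not: linkage
disequilibrium within populations (sites are exchangeable given the
frequencies), reference bias, calling error, selection during the drift
phase. Passing recovery tests therefore show the estimators are correct
and calibrated under the stated models, not that real-data complications
are handled.

## Burden, hemizygosity and crosses

Deleterious SNPs are SIFT <= 0.05 (inclusive); LOF variants form their own
class; SVs of types DEL/DUP/TRA/INV count as deleterious wholesale, with a
genic-overlap restriction available. Additive burden counts alleles
(`het + 2*hom`), recessive burden counts homozygous-derived genotypes; the
identity `additive = het + 2*hom` is asserted on every output. A gene is
hemizygous when merged heterozygous deletions remove strictly more than
50% of it; merging first makes g_h invariant to how deletions are split
into pieces. The burden-ancestry association uses Spearman's rho (average
ranks) with the two-sided t approximation for p — adequate at cohort sizes
here; exact permutation p-values are not implemented.

Hypothetical crosses quantify recessive exposure in an F1: the primary
metric is the expected fraction of deleterious loci homozygous-derived
under Mendelian gamete sampling, `mean((d_i/2)(d_j/2))` over usable loci;
a Jaccard shared-carrier metric is kept as an alternative reading, and a
seeded Monte-Carlo gamete sampler validates the closed form. Groups are
down-sampled (without replacement, seeded) to a common size before pair
enumeration so group size does not drive the comparison.

## BSA QTL scan

The family is a pseudo-testcross: one parent heterozygous at the QTL and
at every marker, the other homozygous, so markers segregate 1:1 and the
carrier-bulk allele frequency at a fully linked marker is 0.5 versus 0.0,
i.e. a delta SNP-index of 0.5. Gametes follow a Markov chain with Haldane
recombination fractions at 3 cM/Mb over a 9 x 36 Mb genome (citrus-like
scale; the QTL region must be a small fraction of the genome or the
null-distribution fit below is contaminated).

Per marker: SNP index = alt/(alt+ref) per bulk (masked below 10x), the
2x2 G statistic (`0*log 0 = 0`), and tricube-smoothed G' over a 1 Mb
half-window (weights renormalised in-window, so G' is a convex combination
of in-window G). p-values come from a log-normal null fitted robustly to
the bulk of the G' distribution — median and MAD on the log scale by
default (an outlier-trimmed moments variant is behind a flag; at our depth
and marker density the median/MAD fit is the better calibrated of the
two) — followed by BH. Significant regions are maximal runs of >= 3
markers with q < 0.01, merged across gaps < 500 kb. The segregation test
is the plain Pearson chi-squared without continuity correction — with
counts 290:264 this gives chi2 = 1.2202, p = 0.2693, whereas the
Yates-corrected value (~0.288) does not match the published figure.

## Forward simulation

Individual-based diploid Wright-Fisher model with a sparse representation
(each haplotype stores its deleterious-allele loci). Fitness is
multiplicative, `w = prod (1-h s)^het (1-s)^hom`, with no epistasis;
parents are drawn proportional to fitness; sexual offspring come from two
free-recombination gametes, clonal offspring copy the mother; the
facultative apomictic mode clones with probability 1 - sigma (default
sigma = 0.05, the residual-sex level at which theory says the ratchet is
arrested). Mutation adds Poisson(U/2) deleterious alleles per gamete
(U = 0.2 per diploid genome per generation by default); loci fixed in
every population are folded into a permanent log-fitness term and
recycled, approximating infinite sites at finite L. The simulator owns a
mt19937_64 RNG, so runs are reproducible across platforms and independent
of R's RNG state.

The transition scenario: sexual burn-in of 10N generations, split into pO
(sexual) and pI (apomictic), one pulse moving 10% of pI's ancestry from
pO, an apomictic phase (500 generations by default), then a split of pI
into pS — which switches to sex at the split — and pA. Under recessive
selection the apomictic phase shelters heterozygous load; the switch to
sex re-forms homozygotes and mean fitness dips sharply in pS while pA is
unaffected; under additive selection (h = 0.5) heterozygotes were never
sheltered and the dip largely disappears. The magnitude of the dip depends
on N, U, the DFE and the length of the apomictic phase, so only its
direction and model contrast are asserted, not a specific percentage.

Validation anchors: the recessive single-locus recursion
`q' = q(1-sq)/(1-sq^2)` at N = 20k; mutation-selection balance
`q_hat ~ sqrt(u/s)` (within 30%; drift at 2Nq ~ 30 biases the classical
formula upward, so the simulated mean sits ~20% below it); neutral
heterozygosity decay `1 - 1/(2N)` within 15%; Muller's ratchet
monotonicity at sigma = 0 and its arrest at sigma = 0.05. Problem sizes
used by the test suite: transition runs N = 1000, L = 5000 with 6
recessive and 3 additive replicates (the effect is ~40 versus ~0.2
percentage points, so small replicate counts are conclusive); balance
N = 2000 with 2 replicates; drift N = 100 with 10.

## MITE genotyping and decomposition

Insertion genotypes come from read-support fractions with explicit bands:
absent <= 0.05, het in [0.2, 0.8], hom >= 0.95, no_call below 10x depth or
between bands. Between-band fractions are deliberately not forced into a
call; concordance is therefore evaluated among called genotypes.

Decomposition treats the target-site duplication as a 5-bp overlap shared
by consecutive MITE units — the only model consistent with the printed
haplotype lengths (3 x 202 - 2 x 5 = 596; 202 + 227 - 5 = 424). Unit
boundaries are positions where the leading 12-mer of the insertion recurs
(<= 2 mismatches; MITE family members share their termini), subject to a
minimum unit length, a TSD check at every boundary, the exact length
identity `sum(units) - (n-1)*5 = insertion length`, and >= 80% pairwise
unit identity by alignment. Anything unresolvable is reported as a single
unit of class "other" rather than a forced decomposition. Known
haplotype classes are assigned by unit lengths within a 5 bp tolerance.

## Repository shape

The package's functions carry all computation; the numbered scripts under
`analysis/` are thin narrative drivers that generate the synthetic inputs
as standard files (VCF, GFF3, TSV, FASTA), run each analysis, and write
tables under `results/`. `scripts/acceptance.R` recomputes the headline
quantities from scratch on fresh synthetic data for a given seed.
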