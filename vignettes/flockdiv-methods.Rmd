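---
title: "Models and methods behind flockdiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind flockdiv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

flockdiv analyses dense unphased biallelic SNP panels from structured
diploid populations — the typical SNP-array breed survey: a few diverged
pure breeds plus F1-type crosses, ~50k markers at ~50–60 kb spacing,
hundreds of animals per population. This vignette explains the models, the
parameters that matter, the numerical choices, and what the built-in
simulator does and does not emulate.

## Data model

Genotypes are B-allele dosages 0/1/2 with `NA` for missing calls; every
statistic is computed on complete cases for the entries it touches, and all
statistics are invariant to allele relabeling, so the arbitrary strand of
array data is harmless. Coordinates are 1-based bp (PLINK/VCF convention);
lengths are carried in bp and converted to kb/Mb only for reporting.
Population labels come from the PED family-ID column or an explicit
sample-to-population table for VCF, which has no population field.

## Quality control

Filters run in a fixed order — non-autosomal, unmapped, low GC score (only
when per-SNP GenCall scores are supplied), call rate < 0.95, MAF < 0.01,
exact Hardy–Weinberg p < 1e-15, per-SNP heterozygosity beyond 3 SD — and a
removed SNP is attributed to the *first* rule it fails. That makes the
per-reason counts mutually exclusive and keeps the identity
removed + surviving = input. The order itself is a convention; fixing one is
what makes exclusion reports comparable across runs.

The HWE test is the exact conditional test: given the observed allele
counts, it enumerates every heterozygote count of the same parity, computes
the conditional probabilities through a log-space formula, and sums those no
more probable than the observed table. At a cutoff of 1e-15 a chi-square
approximation has no meaning — the exact tail is the only defensible
construction. MAF and HWE are pooled across populations by default because
the downstream analyses share a single SNP set; per-population screens can
be run by subsetting the panel first.

The individual call-rate threshold defaults to 0 (report-only): sample-level
exclusion is a study decision, not something a pipeline should silently do.

## Heterozygosity, FST, GRM-PCA

He per SNP is 2p(1−p) from within-population frequencies; Ho is the
heterozygote fraction; both are averaged over SNPs. Pairwise FST is the
Nei-style (H_T − H_S)/H_T with sample-size-weighted frequencies, with H_S
and H_T each averaged across loci *before* the final ratio ("ratio of
averages"). SNPs monomorphic in the pooled pair contribute 0/0 and are
excluded from both averages — with both populations fixed for the same
allele there is no information about differentiation.

The GRM is VanRaden method 1 with pooled-cohort frequencies (all populations
live in one relationship space, which is what a joint PCA needs); missing
dosages are centered to zero, i.e. imputed at the mean. PCA scores are
eigenvectors scaled by the square root of eigenvalues; tiny negative
eigenvalues (numerical) are floored at zero in the variance-explained
denominator.

## LD from unphased genotypes

For two biallelic SNPs the 3×3 genotype table determines all haplotype
counts except for double heterozygotes. The EM estimator starts at linkage
equilibrium and splits the double heterozygotes each iteration in the ratio
f11·f00 : f10·f01, until no frequency moves by 1e-10 (at most 1000
iterations; typical tables converge in tens). The log-likelihood is
monotonically non-decreasing — asserted in the tests — and for tables
without double heterozygotes EM reproduces direct haplotype counting
exactly. Pairs where either locus is monomorphic among complete cases are
undefined and skipped with a count.

r² = D²/(p1 q1 p2 q2) and D′ = |D|/Dmax with the standard Dmax convention.
The D′ confidence bounds follow the Gabriel/Haploview construction: hold the
allele frequencies at their MLEs, orient the pair so D ≥ 0, evaluate the
genotype-table likelihood on the grid D′ ∈ {0, 0.01, …, 1}, normalize to a
discrete distribution, and read the 5th and 95th percentiles. The 0.01 grid
step is the resolution at which the block thresholds (0.70, 0.90, 0.98) are
defined; degenerate tables return the uninformative bounds (0, 1).

Decay tables use 14 half-open distance bins [low, high): <10 kb, 10–20,
20–40, 40–60, 60–100, 100–200, 200–500 kb, 500 kb–1 Mb, 1–2, 2–5, 5–10,
10–20, 20–50, >50 Mb — a pair at exactly 10 kb falls in 10–20 kb. All
syntenic pairs are evaluated by default (`max_distance_bp` caps the work on
large panels). The non-syntenic baseline samples a seeded fraction
(default 5%) of SNPs per chromosome and evaluates all cross-chromosome
pairs; in a panmictic population its mean r² approaches the pure sampling
floor ≈ 1/S + 3.19/S².

## Haplotype blocks

A candidate block is a map interval whose outermost pair is strong LD
(D′ bounds ≥ 0.70 and ≥ 0.98), spanning at most 500 kb (the Haploview cap —
the reason maximum block lengths in dense panels sit just below 500 kb),
in which at least 95% of informative pairs are strong; uninformative pairs
are excluded from the denominator. Candidates are accepted greedily by
decreasing physical length, discarding overlaps. A two-SNP candidate is its
own outermost pair, so it must itself be strong; no minimum block length is
imposed beyond two SNPs.

## Runs of homozygosity

Windows of consecutive SNPs spanning at most `window_span_kb` (default
1000 kb) slide one SNP at a time; a window is homozygous when it contains at
most 1 heterozygous and 2 missing calls. Each SNP's hit fraction is the
proportion of windows containing it that are homozygous; SNPs with hit
fraction ≥ 0.05 are eligible. Maximal runs of eligible SNPs are split at
inter-SNP gaps > 250 kb and kept when they have at least *l* SNPs and span
at least 500 kb. The minimum count

l = ⌈ ln(α/(n_s·n_i)) / ln(1 − het) ⌉

bounds the expected number of chance all-homozygous stretches in the whole
dataset by α (default 0.05); het is the mean observed per-SNP
heterozygosity, computed over the whole cohort by default. The ceiling makes
the count integral.

A geometric consequence worth knowing: a window can only be called
homozygous when it fits (almost) inside a run, so runs shorter than the
window span are undetectable regardless of thresholds. With the default
1000 kb span the effective minimum detectable run is well above 1 Mb — and
the l bound itself implies ~2.5 Mb at 50 kb marker spacing. The test
fixtures that plant 400–1200 kb runs therefore use a 300 kb window span;
that choice probes the mechanism (span-bounded windows, hit fractions, gap
splitting, the 500 kb length filter) at fixture scale rather than changing
the pipeline defaults.

ROH length categories are half-open Mb bins [1,5), [5,10), [10,15),
[15,20), [20,25), ≥25; segments of 0.5–1 Mb count toward totals but no
category. Per-chromosome coverage follows the two-step construction: summed
ROH length divided by the number of animals with ROH on that chromosome,
then divided by chromosome length.

## Effective population size

The single-sample LD method under random mating. The Burrows composite
disequilibrium is cov(x, y)/2 with the sample (S−1) covariance, and
r̂² uses the composite denominator (p q + D_hom) per locus, D_hom being the
homozygote excess over HWE — estimable from unphased genotypes without
assuming HWE. The (S−1) scaling matters: the sampling floor
1/S + 3.19/S² and the bias-corrected solver

N̂e = (1/3 + √(1/9 − 2.76·r̂²_drift)) / (2·r̂²_drift)

are calibrated to that estimator, and with it the simulator recovery runs
(true Ne 50/100/200, S = 60, 300 unlinked loci, 10 seeds) land within
~10% in the median. For a duplicated locus the MLE identity Δ = pq + D_hom
makes r̂² exactly 1; the small (S/(S−1))² inflation is clipped at 1.
Non-positive drift r² yields an infinite estimate, the estimator's honest
answer when sampling noise swallows the drift signal.

Pairs default to non-syntenic (cross-chromosome) from a seeded per-autosome
subsample because the bias correction assumes unlinked loci; an `all` mode
exists for comparability and is downward-biased by physical linkage
(asserted directionally in the tests). The MAF screen defaults to
p_crit = 0.05. Samples under 30 require the small-sample constants
(0.0018 + 0.907/S + 4.44/S²; 0.308 and 2.08 in the solver), engaged
explicitly via `small_sample = TRUE`.

## Inbreeding coefficients

Three per-individual estimators, each with zero expectation under HWE:
from the additive-genotype variance, (x−2p)²/(2pq) − 1; from homozygote
excess, 1 − x(2−x)/(2pq); and from the correlation of uniting gametes,
(x² − (1+2p)x + 2p²)/(2pq). Frequencies are *within-population* — this is
what makes F1 crosses of diverged parents come out negative (they carry
more heterozygotes than their own gene pool predicts). Per-SNP terms are
averaged with equal weights by default; a ratio-of-means variant for the
homozygote-excess form exists because tools differ in this convention, and
the two agree in sign on every case the tests exercise. Monomorphic SNPs
within a population are skipped and counted.

## The simulator: what it emulates, what it does not

`simulate_panel()` runs discrete-generation Wright–Fisher diploids:
founder haplotypes drawn at linkage equilibrium from a 1/p (neutral) site
frequency spectrum on [0.01, 0.99]; Poisson crossovers on a uniform
1 cM/Mb map; each breed drifting through an optional formation bottleneck
then its post-split size; crosses built by sampling one gamete from each
parent population; sampled animals drawn as an offspring cohort (so samples
may exceed Ne and contain half-sib families, as real breed surveys do);
array-style ascertainment on pooled MAF ≥ 0.01; missingness and genotype
error applied last. Everything is reproducible from the scenario seed.

The sheep-like default (`sheep_scenario()`) encodes the five-population
design: 26 autosomes at their published approximate lengths, ~55 kb SNP
spacing, a large diverse wool-type breed (Ne 348), two bottlenecked
meat-type breeds (Ne 140 and 152, bottleneck 50 for 20 generations), an F1
and a three-way terminal cross, and the study's sample sizes
(253/264/265/260/231). Tests and the acceptance script pass reduced
scenarios (2–3 chromosomes, tens of Mb, 30–60 animals per population, and
for the Ne experiments 150 × 1 Mb chromosomes carrying two SNPs each);
those sizes are the package's choice of desk-scale validation conditions.

Emulated features: drift-driven LD decay differences between small- and
large-Ne breeds (bottlenecked breeds dominate the decay curve pointwise);
rare-allele-skewed MAF spectra in bottlenecked breeds (emergent, not
imposed); heterosis and negative marker-based F in crosses; ROH arising
from recent common ancestry; heterozygosity decay at the (1 − 1/2N)^t rate
(asserted within 10% in tests).

Not emulated: mutation after founding (drift-only is adequate over ≤200
generations); selection and sweeps (planted autozygous regions via
`plant_roh()` stand in for positive controls); non-uniform recombination
maps; genotyping artefacts beyond symmetric genotype error; linkage
disequilibrium already present in the founder pool. Passing tests therefore
demonstrate correctness of the estimators under neutral drift with known
truth — not that real data meet those assumptions.

## Numerical and degenerate-input conventions

* EM tolerance 1e-10 on frequencies, 1000-iteration cap; equilibrium start.
* D′ grid step 0.01; bounds are percentiles of the normalized discrete
  likelihood; monomorphic margins return (0, 1).
* Monomorphic SNPs: dropped per population before LD and blocks (logged),
  skipped and counted in inbreeding, excluded from the GRM denominator.
* FST with H_T = 0 everywhere returns 0 with a warning; all-missing SNPs
  report NaN frequencies and are flagged by QC.
* Empty results (no blocks, no ROH, empty bins) return zero-row tables or
  NA means with counts of 0, never errors.
* Reports are written with fixed 15-significant-digit formatting and "\n"
  line endings, so identical configs and seeds give byte-identical bundles.
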