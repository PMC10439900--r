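---
title: "MRE-Seq cfDNA analysis: model, simulator, and evaluation protocol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MRE-Seq cfDNA analysis: model, simulator, and evaluation protocol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement principle

Methylation-sensitive restriction enzyme sequencing (MRE-Seq) reads DNA
methylation through enzyme accessibility. SacII recognizes the CpG-dense
palindrome CCGCGG and cuts only when the site is unmethylated; after
digestion, adapter ligation at the cut ends, amplification, and paired-end
sequencing, the deduplicated read depth at each SacII site is a monotone
readout of that site's *unmethylated* fraction in the input cell-free DNA
(cfDNA). Cancer genomes are globally hypomethylated and additionally lose
methylation at tumor-type-specific loci, so a cancer patient's plasma —
a mixture of normal cfDNA with a tumor fraction of circulating tumor DNA —
shows elevated depth at demethylated sites. The package implements the
full computational path: site enumeration, library simulation, read
preprocessing, neural-network cancer scoring under repeated nested
cross-validation, sensitivity evaluation at an anchored specificity, a
two-stage cancer-signal-origin (CSO) cascade, and interpretation
diagnostics.

`mreseq::enumerate_sacii_sites()` scans a genome FASTA for CCGCGG. The
motif is its own reverse complement, so a single forward-strand scan finds
every site exactly once, and the 6-mer cannot overlap itself, so sites are
disjoint. Coordinates are 0-based half-open internally and on disk (BED6).
Reads generated by a SacII cut begin two bases into the motif — the 5'
"GCGG" signature — so the cut offset is fixed at +2. The enzymological cut
within CCGC^GG produces 3' overhangs; the +2 read start is adopted
phenomenologically because it is what defines an on-target read, and the
simulator and the preprocessing classifier use the same convention, which
keeps the two self-consistent. Soft-masked (lowercase) bases are folded to
upper case before scanning so repeat masking cannot suppress sites. On
hg19 this scan yields tens of thousands of sites genome-wide; autosome
filtering (`autosomes_only = TRUE`) restricts the marker universe to
chr1–chr22, the configuration used for classification.

## The generative model behind the simulator

The synthetic-data generator is first-class, tested code, and its defaults
define the study conditions used throughout the test suite.

**Methylation atlas.** Per-site control methylation is drawn from
Beta(8, 2) (mean 0.8 — SacII sites concentrate in CpG islands, which are
mostly methylated in plasma-dominant leukocyte DNA, with a long tail of
unmethylated regulatory sites). Each cancer class copies the control row,
subtracts a global hypomethylation shift δ (default 0.15, clipped at 0),
and forces its class-specific demethylated set (default 50 sites per
class, disjoint between classes so that the cancer types remain
separable) down to Beta(1, 9) (mean 0.1). δ and the demethylated-set size
are the two effect-size dials; the defaults give a clearly detectable but
not trivial signal at realistic depths.

**Sample depths.** A sample with tumor fraction `tf` and class `c` has
per-site cut probability

    p = (1 - tf) * (1 - m[control, s]) + tf * (1 - m[c, s])

and deduplicated depth `Poisson(D * p)` plus a Poisson off-target
background `D * off_target_rate` (default 5% of the mean on-target depth
D, default 30). Poisson was chosen over negative-binomial as the minimal
count model; biological overdispersion can be emulated by widening the
atlas Betas. Tumor fraction — not stage — is the generative driver;
stages map to increasing tf ranges (I: 0.05–0.15 up to IV: 0.35–0.70), so
stage-stratified sensitivity inherits the known monotone detectability
trend without asserting any quantitative stage model.

**Read-level simulation.** `simulate_reads()` emits, per molecule: a
fragment whose 5' terminus is at `motif_start + 2` (read 1 therefore
starts with GCGG), a length uniform on the 200–550 bp size-selection
window, a random 10 bp UMI written both to the read headers and to the
first 10 cycles of read 2 (as in the real library, where the UMI is read
as the start of R2), `1 + Poisson(pcr_duplication_mean - 1)` PCR
duplicate copies sharing the UMI, and per-base substitution errors at
`seq_error_rate`. Off-target molecules start at uniform random positions.
Only the downstream (+ strand) fragment of each cut is emitted: the
on-target definition is orientation-symmetric, so one orientation
suffices for every contract the pipeline tests. Fragments that would run
past a contig end are resampled (background) or truncated (on-target,
which is pinned to its site), with a warning and a count. The FASTQ path
and the direct depth path draw per-site molecule counts from the same
seeded Poisson stream, so preprocessing an error-free simulated library
reproduces the directly simulated depths exactly — a cross-path identity
the test suite asserts. With a nonzero off-target rate the two paths
differ by construction: the depth path adds background at sites, while
read-level background lands at random positions and is pooled, not
counted into site depths.

What the generator does **not** emulate: sequencer quality-score
profiles, indels, adapter read-through, GC or fragment-length coverage
bias, batch-specific depth effects, and age-related methylation drift.
Covariates (age, sex, batch) are drawn independently of class, so they
are null confounders by construction. Passing tests therefore demonstrate
correctness of the pipeline's bookkeeping and its behavior under the
stated statistical structure — not performance on real plasma libraries.

## Preprocessing

QC drops single-end reads, reads with a mate shorter than 20 bp, and
reads whose UMI contains an N or a quality-0 base. Reads are assigned to
a site when their 5'-most base coincides exactly with the site's cut
position; everything else is background. UMIs are deduplicated per site
with the directional method: unique UMIs are nodes weighted by read
count, an edge `u -> v` exists when Hamming(u, v) ≤ 1 and
`count(u) ≥ 2·count(v) − 1`, and clusters grow greedily from the
highest-count node. This is the accepted standard for UMI error
correction (the rule used by the widely deployed directional-adjacency
deduplicators), and it is tested here against an exhaustive
pairwise-distance oracle. A molecule is on-target when its
representative read 1 begins with GCGG; the on-target ratio is computed
at molecule (deduplicated) level.

Per-sample normalization divides raw depths by a trimmed mean: sort the
row, drop the `floor(0.05 n)` lowest and highest values ("excluding 10%
outliers", read as symmetric 5% per tail — the standard trimmed-mean
definition; a one-tailed reading would shift every sample's scale by a
constant factor and is not offered), and average the rest. Rows with
fewer than 10 sites fall back to the plain mean with a warning;
an all-zero row is an error. Normalized values are plain ratios, not
log-transformed: depth is already a linear readout of the unmethylated
fraction, and standardization inside the classifier handles scale.

## The cancer-score model and cross-validation protocol

The classifier is a feed-forward network: normalized site depths enter
the input layer, pass through two hidden layers of 64 rectified-linear
units, and end in a 2-way softmax trained by cross-entropy
backpropagation for exactly 120 epochs. The cancer score of a sample is
the softmax probability of the cancer output unit. Hyperparameters that
the architecture does not pin down are fixed for reproducibility: Adam
with learning rate 1e-3, mini-batches of 16, He-scaled Gaussian
initialization, all driven by one seed so that a run is bit-for-bit
reproducible. No early stopping is used — the epoch count is part of the
architecture. Features are standardized per training set (means and
standard deviations of the training rows only, stored in the model), so
no statistic of a scored sample ever enters training: the normalized
depths have heavy right tails and raw inputs would slow optimization.
Class imbalance is handled by stratified folds only.

The evaluation protocol is 20 independent repetitions of nested 5-fold
cross-validation. Per repetition: a stratified outer 5-fold split; within
each outer-training set, a stratified inner 5-fold split trains five
models (each inner fold held out as a validation part); each outer-fold
test sample is scored by all five inner models. That yields 5 scores per
sample per repetition — the only scheme consistent with 100 scores per
sample over 20 repetitions while keeping every scoring model blind to
the scored sample — and the leakage audit (`audit_no_leakage()`)
verifies the blindness exhaustively from the recorded fold log on every
run. Per-sample summaries are the mean score (used for all downstream
evaluation) and the interquartile range of the 100 scores
(linear-interpolation quantiles), a stability measure; `score_summary()`
averages the IQR per truth class.

## Evaluation, CSO, and interpretation

**Anchored specificity.** The decision threshold is set from the control
scores alone: with `k` allowed false positives it sits midway between
the k-th and (k+1)-th largest control scores (ties collapse upward so
false positives never exceed `k`; `k = 0` uses the maximum control
score). One false positive among 126 controls gives specificity
125/126 = 99.2%. Sensitivity, overall and per stratum (stage, subtype),
is the fraction of cases whose *mean* score exceeds the threshold, with
Wilson score 95% confidence intervals, the standard interval for
proportions near a boundary (75/96 → 68.9–85.2; 125/126 → 95.6–99.9);
unlike the Wald interval it never collapses at 0% or 100% sensitivity.

**CSO cascade.** Plain stratified 5-fold cross-validation (80%/20%), not
the nested scheme: per fold a Cancer Classifier (both cancer types vs
controls) gates a Cancer Type Classifier (type 1 vs type 2, argmax
probability). The gate threshold defaults to 0.5 on the cancer
probability — the cascade is a different operating point from the
anchored-specificity screen, and the config accepts an anchored
threshold where that is wanted. Gate consistency (a type call exists iff
the gate fired) and confusion-matrix marginals are asserted invariants.

**Interpretation.** Marker discovery uses pooled-variance Student t
tests per site (Welch via flag), ranked by P against a fixed cutoff;
zero-variance sites get P = 1 with a warning. Feature importance offers
a Monte-Carlo permutation-sampling Shapley estimator (background
reference = column means by default) and a model-agnostic permutation
importance; the tested contract is the *ranking*. Region annotation
classifies each site with precedence promoter > 5'UTR > exon > intron >
intergenic, where the promoter window is TSS − 2000 to TSS + 500 on the
annotated strand — a common convention, configurable, since no single
annotation release is canonical. Confounder diagnostics: PCA on the
feature-centered normalized matrix with a configurable PC1 outlier
threshold (any absolute cutoff is data-specific) and one-way ANOVA of
the top components against batch; Pearson correlation of score against
numeric covariates and two-group t tests for categorical ones, plus an
optional multivariable linear-model hook.

## Problem sizes and numerical choices

The test suite and the acceptance script run everything at desk scale,
chosen so the full statistical protocol is exercised unchanged: the CV
bookkeeping check runs the complete 20 × (5 outer × 5 inner) protocol on
a 40-sample, 500-site cohort; the separability check uses 60 + 60
samples at 500 sites with atlas gap δ = 0.3 and tumor fractions ≥ 0.2;
the end-to-end FASTQ path uses ~2,000 planted sites and 60 samples at a
mean site depth of 8 with PCR duplication 1.3; the site-census check
compares a seeded random megabase against a brute-force sliding-window
scan. Site enumeration itself is genome-scale (a full hg19 scan is a
single `read_genome_fasta()` + `enumerate_sacii_sites()` call) but needs
the reference FASTA on disk. Degenerate inputs are errors, not silent
repairs: single-class training sets, all-zero depth rows, dimension
mismatches, unknown atlas classes. Ties are handled explicitly: midrank
AUC (ties count 1/2), upward-collapsing anchored thresholds,
first-occurrence rank ties in marker tables.

## Known limitations

Real-cohort performance values cannot be established here — they require
hundreds of sequenced patient plasma libraries — so the package asserts
the evaluation *machinery* (proportion and interval arithmetic, scheme
bookkeeping, oracle equalities) and property-level behavior on synthetic
cohorts.
Alignment is externalized: the preprocessing accepts simulator truth
coordinates or an external coordinate-sorted BAM, and does not align
reads itself. The hg19 site census depends on exactly which contigs the
FASTA contains; the package counts what is in the file and exposes the
autosome filter.
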