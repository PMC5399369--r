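---
title: "Methods: imaging genetics of the CBGT circuit in Parkinson's disease"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: imaging genetics of the CBGT circuit in Parkinson's disease}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parkig)
```

# The analysis design

Parkinson's disease (PD) arises from dopaminergic neuron loss in the
substantia nigra and downstream dysfunction of the cortico-basal
ganglia-thalamocortical (CBGT) circuit.  Genome-wide association needs
large samples; quantitative-trait ("imaging genetics") designs reduce that
requirement by associating candidate variants with heritable,
disease-correlated *intermediate phenotypes* — here, weighted degree
centralities (DC) of an 8-region CBGT structural connectome and the
MDS-UPDRS clinical severity score.  The package implements that full
design: genotype quality control, connectome construction, group
comparison, covariate-adjusted per-SNP association with permutation
inference, and stepwise multi-source regression of MDS-UPDRS with
leave-one-out validation — together with a synthetic-cohort generator that
makes every stage testable because the clinical source data are access
restricted.

# The synthetic cohort

`simulate_cohort()` generates, from one master seed, a cohort designed to
match the real study's shape: 40 healthy controls and 40 PD patients,
demographically matched (age and sex drawn from identical distributions in
both groups), with handedness, family history, GDS, MoCA, site and the
candidate SNP panel of seven PD-linked variants (PARK2, PARK7, SNCA, HtrA2,
GIGYF2).  Choices the source material leaves open were fixed once and are
configurable rather than inferred:

* **Age** Normal(62, 9) years, a typical PD-cohort profile; what matters —
  and what tests assert — is the matching between groups, not the absolute
  values.  **GDS** integer 0–15, **MoCA** integer 20–30, the instruments'
  plausible ranges.
* **Genotypes** are drawn per SNP from Hardy–Weinberg proportions at the
  target minor-allele frequency.  HWE violation is parameterised by a
  single inbreeding-style coefficient *f* that moves mass between
  heterozygotes and homozygotes at fixed allele frequency — one
  interpretable knob that drives the exact-test p-value.  Missing calls
  are injected per SNP at a configured rate.  SNPs are independent: no
  linkage-disequilibrium structure is simulated.
* **Streamlines are synthesised backward from degree-centrality targets.**
  Raw tractography is out of scope, and only the DC distribution matters
  downstream, so for each subject node DCs are drawn from the group's
  target normal distribution (defaults: the four published group contrasts
  — associative 0.017→0.019, motor 0.012→0.015, thalamus 0.007→0.008 in
  PD, pallidum 0.006→0.005 — plus four unchanged nodes at plausible
  magnitudes), split into a symmetric zero-diagonal edge matrix with
  exactly those row sums by symmetric Sinkhorn balancing, and each edge is
  realised as fiber records (lognormal lengths around 40 mm, per-fiber FA
  near 0.5) rescaled so the fiber-density formula reproduces the edge
  weight exactly.  Optional per-allele DC shifts plant genotype →
  connectivity effects for the association stage to recover.
* **MDS-UPDRS** is generated from a declared linear model — three node
  DCs, two SNPs, a SNP×SNP and an imaging×SNP interaction, plus GDS, sex
  and age — with Gaussian noise.  `noise_sd = 6` puts the generating model
  at R² ≈ 0.72 at n = 80, the regime of the real analysis.  Scores are
  clipped at zero with the clip count reported, because silent clipping
  would bias coefficient-recovery tests (at the default intercept of 30 the
  count is essentially always zero).

What passing tests on this cohort show is that the *procedures* behave as
specified under known ground truth; they cannot certify performance on
real data, whose missingness patterns, LD structure, site effects and
score distributions are richer than the generator's.

# Stage-by-stage numerical choices

## Genotype QC

MAF is folded (`min(f, 1-f)`), computed over non-missing calls; the minor
allele is determined empirically, keeping the declared minor at an exact
0.5 tie.  The Hardy–Weinberg test is the exact conditional test (all
heterozygote counts of matching parity given the allele counts, via a
numerically stable log-ratio recurrence) rather than the chi-square
approximation, which is unreliable near the 1% MAF boundary where the
filter operates.  Per-criterion exclusion counts are reported
non-exclusively — a SNP failing two filters increments both — while the
union is removed once; the convention is printed in the report because
published exclusion tallies rarely state it.  Subject-level call rates are
reported but not filtered on by default (no published threshold).
Population structure uses identity-by-state distances (1 − mean shared
allele fraction over jointly observed SNPs) and classical MDS via
`stats::cmdscale`; negative eigenvalues (non-Euclidean input) carry no
coordinates and are reported.

## Connectome

The fiber-density edge weight is
`meanFA(i,j) * 2/(S_i+S_j) * sum_f 1/l(f)`: the named ingredients are
streamline count, length normalisation, surface-area normalisation and
mean FA, following the connection-efficiency literature.  The formula is
isolated in `fiber_density_edge()` so it can be swapped, and the variant
identifier is recorded in every run manifest.  Mean FA is the mean of
fiber-level summaries for the pair.  Lengths are mm and areas mm²; DC is
reported as a unitless value at the magnitudes conventional in this
analysis.  Group tests run on the 8 node DC values (Bonferroni m = 8), not
the 28 edges — results are reported at node level; edge-level testing is a
documented extension.  Welch's t-test is the default (a pooled-variance
variant is a flag) since homoscedasticity between patient groups is not
guaranteed.

## Association

The additive model regresses each phenotype on [1, minor-allele count,
age, sex] by OLS, with per-SNP complete-case handling of missing calls and
sex coded F = 0, M = 1 (fixed for reproducibility and stated in output
headers).  Empirical p-values permute the *phenotype* labels — the
standard quantitative-trait null, equivalent under exchangeability to
permuting residualised scores — with covariates refit inside each
permutation and two-sided comparison of |t|; permuting genotype labels
instead is available as a flag.  The add-one rule
`(1 + exceedances) / (1 + N)` keeps p in `[1/(N+1), 1]` and unbiased.  No
correction is applied across the candidate panel beyond the per-SNP
empirical p (the panel is small and pre-specified); a scan row's
permutation stream is derived from the master seed and the (phenotype,
SNP) label, and subjects are canonicalised by id first, so the scan is
invariant to input row order.  A constant SNP column is flagged untestable
rather than failing the whole scan.

## Modeling

Design matrices put main effects before interactions; interaction columns
are elementwise products of *uncentered* operands, and the multi-site
covariate enters as reference-coded indicators (main effect only).  The
stepwise criterion is exactly the stated rule — remove the term whose
removal most lowers the overall model p-value, repeat until no removal
improves — with ties broken toward the earliest term, making the
elimination path deterministic.  No main-effect hierarchy is enforced: an
interaction may outlive its parents, as the published models themselves
contain both.  Variance is decomposed by sequential (Type-I) sums of
squares in retained-term order, because only the sequential decomposition
makes per-term percent-explained sum to 100·R², which is how the published
per-term tables total; F statistics are taken against the final model's
residual mean square.  The initial term set takes all two-way interactions
among candidates in a deterministic order (feature×feature, then
feature×covariate, then covariate×covariate), truncated at a configurable
cap (default 16) with a guard keeping at least ten residual degrees of
freedom — "all possible interactions" is not fittable at n = 80 without
one.

Backward elimination on the overall p is optimistic by construction: on
pure noise at n = 80 with ~20 candidates the selected model's adjusted R²
has median ≈ 0.11–0.16, and because LOOCV holds the selected term set
fixed (matching the real analysis: one stated model, n folds), a residual
selection optimism of r ≈ 0.25 survives cross-validation on noise.  Both
facts are asserted in the test suite rather than hidden; per-fold
re-selection is the stricter alternative left to the caller by refitting
`backward_stepwise()` inside a manual fold loop.

## Validation

LOOCV refits coefficients on each n−1 subset with the term set fixed and
predicts the held-out subject; per-fold refits are verified in tests
against the closed-form leave-one-out identity `residual / (1 − h_ii)`.
Performance is RMSE plus the Pearson correlation (with p-value) between
predicted and actual scores.  Rank-deficient folds are skipped and
reported.

## Pipeline

`run_pipeline()` executes the stages in dependency order from one
configuration and one master seed; per-stage sub-seeds are derived by
hashing the stage label with the master seed so streams never collide, and
a manifest records the configuration fingerprint, seeds, output checksums
and timings.  Two runs with the same seed are byte-identical (the manifest
timings aside), and `cache = TRUE` reuses a previous run only after its
checksums verify, so caching can never change results.  Significant DC
nodes and scan-significant SNPs flow into the models automatically; when a
seed yields fewer than `min_features` of either, the top-ranked candidates
are used instead so models A–C remain constructible at every seed (the
manifest records the sets actually used).  Missing genotype calls of a SNP
selected into the models are mean-imputed at that point — regression terms
must be complete and the design keeps all subjects through LOOCV — with
the imputed count recorded in the manifest.  Hoehn–Yahr staging is
collected by the study design but not offered as a model covariate
(absent from the published models); the MDS-UPDRS is treated as an opaque
non-negative score.  This package is a library: the exported functions,
this vignette and `scripts/acceptance.R` are the interface, and no shell
entry point is shipped.

# Problem sizes used in the test suite

The suite exercises each stochastic guarantee at sizes chosen to make the
Monte-Carlo error small relative to the asserted bound while keeping a
laptop-scale run: HWE oracle equivalence over all genotype tables to
n = 30; null HWE calibration at 10,000 SNPs × 500 subjects; family-wise
error of the Bonferroni group test over 1,000 replicates of 40 + 40;
permutation-p uniformity over 500 null datasets (199 permutations each)
plus one fixed dataset at 10,000 permutations; coefficient-recovery
coverage over 500 simulated cohorts; stepwise selection power and
model-ordering over 100 seeds; LOOCV noise-recovery over 100 seeds; and
two full default pipeline runs for byte-level determinism.

# Known limitations

* The generator reproduces marginal distributions and planted effects, not
  LD, site-specific batch structure, or realistic missingness mechanisms.
* Node-level (not edge-level) group testing; no relatedness estimation,
  reference-panel comparison, imputation, or mixed-model association.
* The stepwise rule inherits the optimism of its published definition;
  comparisons between models A–C are internally consistent but absolute
  adjusted R² values on selected models overstate out-of-sample fit.
* Degree centrality depends on the declared fiber-density variant; the
  variant identifier in the manifest should accompany any reported DC
  value.
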