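---
title: "Ensemble transcriptome-profile classification of gliomas: models and methods"
author: "gliomaTP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble transcriptome-profile classification of gliomas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Gliomas are classified by a combination of histology and molecular markers,
but histological grading is subjective and molecular markers are often
missing from archival material. Expression-based classification assigns each
tumor to one of four *transcriptome profiles* — TP1, TP2a, TP2b and TP3 —
where TP1 carries markedly worse prognosis. gliomaTP implements a complete
pipeline for making these calls from nCounter-style single-molecule count
data: a 168-probe panel (160 endogenous classifier genes plus 8 housekeeping
genes, with positive and negative controls) measured on archival FFPE or
flash-frozen tissue, classified against a large labelled reference
compendium of glioma expression profiles.

Because the clinical cohorts such a pipeline is validated on are not
publicly available, the package ships a first-class synthetic-data module
that generates every input — reference compendium, raw RCC lanes, technical
replicates, survival tables — with known ground truth. All tests and the
acceptance script run on these synthetic inputs.

# Stage 1: lane QC and normalization

An RCC lane holds raw molecule counts for every probe plus lane attributes.
Five checks decide whether a lane is usable:

* imaging: fields-of-view counted / attempted >= 0.75;
* binding density within 0.1–2.25;
* positive-control linearity: R² of log2(count) against log2(input
  concentration) over the 6-point spike-in ladder >= 0.95;
* positive normalization factor within 0.3–3;
* housekeeping normalization factor within 0.1–10.

The platform vendor's QC names these checks but the thresholds above are the
platform-standard defaults; they are exposed via `defaultQcThresholds()`.
The positive-control input series is fixed to the standard 6-point geometric
ladder (relative concentrations 128, 32, 8, 2, 0.5, 0.125).

Normalization is two multiplicative geometric-mean stages applied
sequentially — first to the positive controls, then to the eight
housekeeping genes (GAPDH, HNRNPL, IPO8, MRPL19, MRPL30, NRF1, RNF10, TBP)
recomputed on the positive-normalized counts — followed by log2(x+1). A
lane's factor is the cohort mean of per-lane geometric means divided by the
lane's own geometric mean. Zero counts are replaced by 1 before control
geometric means (guards log 0; platform convention), and the +1 in the log
transform guards zero endogenous counts. Two consequences are tested: after
both stages the housekeeping geometric mean is identical across lanes (to
1e-9 on the log2 scale), and a lane equal to another lane with every count
scaled normalizes to an identical column — per-lane scale cancels exactly
through the factor algebra, so sample loading differences do not reach the
classifier. By default the factor cohort is the whole lane set passed to
`normalizeLanes()` (per-cartridge cohorts are available through `cohortBy`
in `qcLanes()`); the whole-set default is what makes the housekeeping
geometric means equal across *all* lanes rather than within cartridges.

# Stage 2: integration with the reference compendium

The reference compendium is a genes-by-samples matrix with subtype labels
(emulating, at reduced scale, a compendium of a thousand-plus samples;
the synthetic default is 100 per subtype). Both matrices are z-scored per
gene (denominator n−1; constant genes are dropped with a warning), then
merged with an empirical-Bayes location/scale batch adjustment. Per gene g
and batch i the model is Y = α_g + γ_ig + δ_ig·ε. The batch estimates are
shrunk toward parametric cross-gene priors — γ ~ Normal(γ̄, τ²), δ² ~
Inverse-Gamma(λ, θ), hyperparameters by method of moments — via the coupled
posterior equations iterated to a relative tolerance of 1e-4 (cap 100
iterations).

Design choices, made where the procedure is genuinely open:

* **Reference-batch mode.** The reference compendium is the reference batch
  and is returned bitwise unchanged, so classifiers trained on it remain
  calibrated; only the test lanes move. The implementation agrees with
  `sva::ComBat(ref.batch=)` to ~1e-8 on shared inputs (a unit test).
* **Parametric priors, no biological covariates** — the default form of the
  cited algorithm; subtype labels must not inform the batch model because
  test-sample subtypes are unknown.
* **A single test sample** cannot be z-scored on its own statistics; it is
  centered and scaled with the reference per-gene statistics and receives a
  location-only adjustment (the batch variance is fixed at 1). With two or
  more test samples the test matrix is standardized on its own statistics.

# Stage 3: the ensemble classifier

The 160 endogenous genes are partitioned into six groups by k-means (10
restarts) on each gene's vector of four subtype means, groups indexed by
descending size. Each of 1000 base models then:

1. draws half of each group (⌈m/2⌉ without replacement) — a stratified
   draw of ~80 genes;
2. runs recursive feature elimination with a one-vs-rest linear SVC
   (L2-regularized hinge loss, C = 1, features pre-standardized): at each
   step the mean stratified 3-fold CV accuracy is recorded, genes are
   ranked by the sum of squared one-vs-rest weights, and the five
   lowest-ranked are dropped (never below a floor of 5 genes, so the
   5-per-step elimination terminates cleanly);
3. returns the smallest recorded subset attaining the maximum CV accuracy,
   refit on all training samples.

Models with mean CV accuracy below 95% are discarded. For reference-cohort
calls a 4-fold stratified outer split keeps training and calling disjoint:
the dictionary is rebuilt on three folds and votes only on the fourth.
External (test) samples are classified by models trained on the full
reference; the out-of-fold scheme exists to avoid optimistic calls on the
training cohort itself, a concern that does not arise for external samples.

Votes are combined by plurality. With p1 and p2 the top and second vote
fractions, the confidence score is c = p1/p2 (infinite when p2 = 0). The
sample is called only when c > 3; c <= 3 yields "Ambiguous". An exact tie
for the top class gives c = 1 and therefore always abstains, so the fixed
tie-break order (TP1, TP2a, TP2b, TP3) can never decide a call.

The base solver is a dual coordinate-descent method for the L2-regularized
L1-loss SVC (the standard algorithm for linear SVMs), written in C++ with a
deterministic shuffle so that fits are bit-reproducible and, in particular,
independent of class labelling order. The whole RFE loop runs in compiled
code; a 1000-model dictionary on a 400-sample reference builds in minutes
on one CPU. Unit tests check the solver against an independent SVM
implementation (libsvm via e1071) on separable and non-separable fixtures.

Open points resolved here: the multiclass RFE ranking rule (the sum of
squared per-class weights, the natural multiclass extension of
squared-weight ranking); ⌈m/2⌉ for "half" of an odd group; and per-fold
refitting of the dictionary in the out-of-fold scheme, which is the only
reading under which no sample is both trained on and called.

# Stage 4: survival

TP1 calls are compared with non-TP1 calls on overall survival:
Kaplan–Meier curves with the standard median convention (smallest time at
which S(t) <= 0.5, "not reached" otherwise), the two-group log-rank test,
and a Cox proportional-hazards fit on the TP1 indicator with Efron tie
handling, Wald 95% CI, and a likelihood-ratio p-value. These are computed
with the survival package behind the package's operation surface and are
checked exactly against brute-force oracles (explicit product-limit
tabulation, per-event-time 2×2 log-rank sums, and direct 1-D maximization
of the Efron partial likelihood) on small hand-computable inputs.
Ambiguous samples join the non-TP1 arm by default — an abstention carries
confident evidence *against* TP1 even when the non-TP1 subtype is
uncertain — and can be dropped instead (`ambiguous = "drop"`). Monotone
likelihood (all events ordered in one group) is detected and flagged
rather than reported as a finite estimate.

# The synthetic-data generator

The generator produces every pipeline input with known truth:

* **Reference**: four subtypes whose per-gene means follow one of six
  archetypal sign patterns over (TP1, TP2a, TP2b, TP3) — up-in-one-subtype
  (four patterns), up-in-TP1/TP2a-down-elsewhere, and alternating — scaled
  by the subtype effect (default 2, in units of the within-subtype SD), on
  a per-gene baseline, with unit-SD Gaussian noise. The six fixed sign
  patterns realize "groups defined by expression differences among the
  subtypes" in the simplest form that k-means provably recovers.
* **Test lanes**: negative-binomial counts on a log2 link — log2-mean =
  baseline + subtype archetype + per-gene batch shift (N(0, 0.5) by
  default) + lane log-scale (uniform 0.7–1.4) — plus the positive-control
  ladder, near-zero negative controls, and lane attributes. Dispersion 0
  is defined as the deterministic rounded-mean limit so noise-free tests
  are exact. The default dispersion of 0.01 reproduces the replicability
  regime of the platform (technical-replicate correlations around 0.99);
  the count model itself is a pragmatic choice, standard for overdispersed
  molecule counts, not a claim about the instrument's error law. A
  configurable fraction of lanes is generated with the positive ladder
  flattened at its geometric mean: linearity R² collapses (the lane fails
  QC) while the positive geometric mean — and hence every other lane's
  factors — is untouched, isolating the failure mode being exercised.
* **Cohort mix**: test subtypes are drawn TP1-heavy (50/17/17/16%),
  emulating a glioblastoma-rich archival cohort.
* **Survival**: exponential event times at hazard h_TP1 for TP1 and
  h_TP1/4.5 otherwise (defaults put the TP1 median at 12.1 months and use
  the hazard ratio 4.5 as generating truth), with an independent
  exponential censoring stream covering both loss to follow-up and
  unrelated death. The default censoring rate 0.008/month censors a
  modest fraction; the acceptance checks use 0.006/month, which censors
  about 20% of this cohort mix. Note the generating model is internally
  consistent by construction: with exponential times, a hazard ratio of
  4.5 fixes the ratio of medians, so the non-TP1 median follows from the
  model rather than being an independent dial.

What the generator does **not** emulate: FFPE RNA degradation chemistry,
probe-specific background (negative controls are uninformative noise),
gene–gene correlation within subtypes, and real cohort label noise. Tests
passing on these synthetics therefore demonstrate the pipeline's
correctness and calibration under its own model assumptions, not clinical
performance.

# Numerical and scale choices

* Solver: dual tolerance 0.1 (the standard default for this algorithm),
  epoch cap 200; both only matter near the margin and never change calls
  on separated data.
* EB iteration: relative tolerance 1e-4, cap 100 iterations.
* k-means: 10 restarts under the caller's seed; group indexing by
  descending size makes the partition label-stable.
* Tie-breaks: accuracy ties in RFE go to the smaller subset; vote ties
  abstain (see above); k-means cluster-size ties resolve by original
  cluster index.
* Default problem sizes — 100 reference samples per subtype, 48 test
  lanes, 1000 models — are the simulated study's conditions; unit tests run
  reduced cohorts (25–40 per subtype, 10–100 models) chosen so the whole
  suite completes in minutes while every property is still exercised at
  meaningful sample sizes.

# Known limitations

* The panel is an input; discovering the 168-gene signature from a
  compendium is out of scope.
* The batch model has no biological covariates and a single test batch;
  multi-site test cohorts would need the symmetric adjustment mode.
* The survival module fits only the single binary TP1 contrast — no
  multivariable or competing-risks models.
* On real data the six pattern groups are a modelling device; k-means on
  subtype means has no guarantee of matching a biological grouping, only
  of stratifying the subsampling.

# A worked run

```{r, eval = FALSE}
library(gliomaTP)
cfg <- SimulationConfig(seed = 1L)
bundle <- runPipeline(cfg, outputDir = "run1", nModels = 1000L)
pipelineReport(bundle)
```

The report prints per-class call counts with median classification
confidence (unanimous classes render as ">1000"), the QC attrition line,
and the TP1 vs non-TP1 hazard ratio with its confidence interval and
likelihood-ratio p-value.
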