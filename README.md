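# gliomaTP

Ensemble transcriptomic classification of gliomas from single-molecule
count data.

## The problem

Gliomas are graded by histology plus molecular markers (IDH mutation,
1p/19q codeletion), but archival FFPE material often lacks the markers and
histological review is subjective. Expression-based classification assigns
each tumor to one of four *transcriptome profiles* — **TP1, TP2a, TP2b,
TP3** — where TP1 carries markedly worse prognosis. This package implements
a complete, tested pipeline for making those calls from NanoString
nCounter-style count data against a labelled reference expression
compendium, for bioinformaticians building or validating expression-based
tumor classifiers.

## What it does

1. **Lane QC and normalization** (`readRcc`, `qcLanes`, `normalizeLanes`):
   parses sectioned RCC lane files; checks imaging (FOV ratio ≥ 0.75),
   binding density (0.1–2.25), positive-control log–log linearity
   (R² ≥ 0.95), and normalization-factor ranges; then applies two
   sequential geometric-mean factors — positive spike-ins first, then the
   8 housekeeping genes — and log2(x+1). After normalization the
   housekeeping geometric mean is identical across lanes.
2. **Reference integration** (`standardizeMatrix`, `ebBatchAdjust`,
   `projectTest`): per-gene z-scores, then an empirical-Bayes
   location/scale batch adjustment. Per gene g and batch i,
   Y = α_g + γ_ig + δ_ig·ε with parametric priors γ ~ N(γ̄, τ²),
   δ² ~ Inv-Gamma(λ, θ) estimated across genes and shrunk by the coupled
   posterior equations; the reference compendium is the reference batch
   and is returned unchanged.
3. **Ensemble classification** (`partitionGenes`, `buildDictionary`,
   `classifySamples`, `outOfFoldCalls`): genes are k-means-partitioned
   into 6 groups by subtype-mean pattern; each of 1000 base models draws
   half of every group, runs recursive feature elimination with a
   one-vs-rest linear SVC (hinge loss, C = 1; 5 genes removed per step;
   mean 3-fold CV accuracy as criterion), and is retained only if its CV
   accuracy is ≥ 95%. Calls use plurality voting with a confidence score
   c = p1/p2 (top over second vote fraction); c ≤ 3 abstains as
   "Ambiguous".
4. **Survival** (`compareTP1`, `kmEstimate`, `logrankTest`, `coxBinary`):
   Kaplan–Meier medians, the log-rank test, and a binary-covariate Cox
   model (Efron ties, Wald CI, likelihood-ratio p) for TP1 vs non-TP1.
5. **Synthetic data** (`SimulationConfig`, `generateReference`,
   `generateTestLanes`, `generateSurvival`): every pipeline input with
   known ground truth — subtype archetypes, negative-binomial counts with
   batch/lane effects, technical replicates, corrupted-QC lanes, and
   exponential survival with a generating hazard ratio of 4.5.

`runPipeline()` chains all stages and writes every artifact plus a
manifest with seed, parameters, and QC attrition counts.

## A worked example

```r
library(gliomaTP)
cfg <- SimulationConfig(seed = 1L)      # 100 ref samples/subtype, 48 lanes
bundle <- runPipeline(cfg, nModels = 200L)
pipelineReport(bundle)
```

```
Classification calls:
  TP1          21  median confidence >1000
  TP2a          9  median confidence >1000
  TP2b         10  median confidence >1000
  TP3           8  median confidence >1000
  Ambiguous     0  median confidence -
QC attrition: 48 lanes in, 48 passed, 0 failed
Survival TP1 vs non-TP1: HR 2.91 (95% CI 1.47-5.78), LR p = 0.002173; median 17.5 vs 42.3 months
```

Reading the output: every lane passed QC (no corruption was configured);
all 48 test lanes were called with unanimous-vote confidence (rendered as
`>1000`), and the calls match the generated ground truth; the TP1 arm
shows the expected survival disadvantage — the generating hazard ratio is
4.5, and a single 48-sample cohort estimates it with wide error bars, here
2.91 with CI 1.47–5.78.

## Documentation

The methods vignette (`vignettes/glioma-tp-classification.Rmd`) describes
the models, the tunable parameters and their defaults, what the synthetic
generator does and does not emulate, and the numerical design choices.
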