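# mclris

Serum antibody-microarray survival signatures and combined risk indices
for relapsed mantle cell lymphoma (MCL).

## What problem this solves

At relapse, MCL patients are rarely re-biopsied, so risk assessment must
work from blood. The clinical standard, the MCL International Prognostic
Index (MIPI — a weighted sum of age, ECOG status, LDH ratio and WBC
count), was built for newly diagnosed patients and often fails to separate
risk groups in relapsed cohorts. `mclris` implements, as reusable and
tested R functions, the full discovery pipeline that turns replicate-level
scFv antibody-microarray spot intensities plus a clinical table into:

1. a batch-corrected log2 expression matrix (CV-rule replicate
   aggregation, winsorization, parametric empirical-Bayes batch
   correction);
2. a consensus protein signature from two independent selection arms —
   a univariate Cox screen refined by repeated backward elimination
   around an SVM with leave-one-out cross-validated ROC AUC (**Cox-BE**),
   intersected with elastic-net regression (**ENR**);
3. the **relapsed immune signature (RIS) score**
   `s = Σ βᵢ·zᵢ` (univariate Cox coefficients on cohort-standardized log2
   signals) with a ternary coding `S ∈ {0,1,2}` at log-rank-optimized
   cutpoints;
4. the combined index **MIPI_ris = w₁·MIPI + w₂·S** (weights refit by
   multivariate Cox; the published pair (0.708, 1.327) is available for
   reproduction mode);
5. three-group risk stratification evaluated by Kaplan-Meier curves,
   k-sample log-rank tests and Harrell's concordance.

Because the underlying patient cohort is not public, the package ships a
first-class synthetic-cohort generator (`generate_cohort()`) emulating the
assay — 371 scFv analytes on 158 proteins, 1–9 clones per target, three
replicate spots, three scan-date and two slide batches, exponential
proportional-hazards survival with a planted protective signature — so the
whole pipeline is testable against known ground truth.

Intended users: biostatisticians and computational biologists building or
auditing serum-proteomic prognostic signatures with small survival
cohorts.

## Worked example

```r
library(mclris)

cfg <- pipeline_config(
  sim  = simulation_config(n_patients = 150, censoring_rate = 0.4),
  seed = 101)
res <- run_pipeline(cfg)
res
```

```
mclris pipeline result
 - simulated cohort (seed 1846358436)
 - aggregated 150 samples x 371 analytes; 0.03% missing
 - ComBat on scan_batch (3 batches)
 - order: bg-subtract > aggregate > QC > trim > log2 > batch-correct
 - screen: 53/371 analytes pass p < 0.05
 - Cox-BE arm: 35 consensus analytes / 15 consensus proteins
 - ENR arm: alpha 0.0, 371 analytes -> 158 proteins
 - intersected signature panel: 15 proteins
```

The screen retains 53 of 371 analytes at p < 0.05 (the planted signature
clones plus the expected ~5% background); the two arms' protein-level
overlap is the signature panel (for this seed the elastic net chose pure
ridge, so the Cox-BE arm alone constrains the panel). Checking it against
the generator's ground truth and inspecting the stratification:

```r
truth <- res$cohort$truth$signature_protein_ids
c(recovered = length(intersect(res$panel$protein_id, truth)),
  false_pos = length(setdiff(res$panel$protein_id, truth)))
#> recovered false_pos
#>        11         4

res$evaluation[, c("index", "cut1", "cut2", "chi2_os", "p_os", "harrell_c")]
#>      index  cut1  cut2  chi2_os      p_os harrell_c
#> 1     MIPI 5.700 6.200   0.5436 7.620e-01    0.4868
#> 2 MIPI_ris 4.107 6.047 266.2456 1.533e-58    0.8956
```

All 11 planted proteins are recovered (4 false positives). MIPI alone —
whose effect is deliberately simulated much weaker than the planted
signature — does not stratify this synthetic cohort (chi² 0.54 at its
published 5.7/6.2 cutoffs), while the combined MIPI_ris index separates
three risk groups sharply (chi² 266 on 2 df, C = 0.90); per-patient
scores, cutpoints and group sizes are in `res$scores` and
`res$evaluation`.

A thin command-line wrapper with `simulate`, `preprocess`, `select`,
`score`, `evaluate` and `run-all` subcommands is installed at
`inst/scripts/mclris-pipeline.R`:

```sh
Rscript inst/scripts/mclris-pipeline.R run-all --out out/ --seed 7 --n-patients 44
```

Every run writes its artifacts (expression TSV, screen/BE/ENR tables,
panel JSON, score CSV, evaluation CSV) plus a `manifest.json` with the
configuration snapshot and per-file checksums; identical seeds give
byte-identical manifests.

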