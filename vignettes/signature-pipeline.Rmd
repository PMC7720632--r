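---
title: "Serum antibody-microarray survival signatures: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Serum antibody-microarray survival signatures: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mclris)
```

## The problem

In relapsed/refractory mantle cell lymphoma (MCL), tumor tissue is rarely
re-biopsied, so prognostic information must come from minimally invasive
sources. The clinical standard, the MCL International Prognostic Index
(MIPI: a weighted sum of age, ECOG performance status, the LDH ratio and
the white-blood-cell count), was developed for newly diagnosed patients and
often fails to separate risk groups at relapse. `mclris` implements a
complete discovery pipeline that derives a serum-protein signature from
recombinant-antibody (scFv) microarray profiles, combines it with MIPI into
a single index, and stratifies patients into three risk groups.

The pipeline covers five stages:

1. **Pre-processing** — replicate spots to a batch-corrected log2
   expression matrix.
2. **Dual-arm consensus selection** — a univariate Cox screen followed by
   repeated backward elimination around an SVM/LOOCV classifier (Cox-BE),
   in parallel with elastic-net regression (ENR); the signature is the
   protein-level overlap of the two arms.
3. **Scoring** — the relapsed immune signature (RIS) score
   $s = \sum_i \beta_i z_i$, where $z_i$ is the cohort-standardized log2
   signal of panel protein $i$ and $\beta_i$ its univariate Cox
   coefficient; a ternary coding $S \in \{0,1,2\}$ via log-rank-optimized
   cutpoints.
4. **Combined index** — $\mathrm{MIPI}_{ris} = w_1\,\mathrm{MIPI} + w_2\,S$
   with weights from a multivariate Cox fit (published defaults
   $(0.708, 1.327)$ are available for reproduction mode; synthetic cohorts
   refit them).
5. **Evaluation** — Kaplan–Meier curves, $k$-sample log-rank tests,
   Harrell's concordance, and an exhaustive two-cutpoint log-rank
   maximization for trichotomization.

Because no public cohort exists for this assay, the package ships a
first-class synthetic-cohort generator with planted ground truth; every
statistical claim the test-suite makes is a property of the method checked
against that truth or against an independent oracle.

## The synthetic cohort

`simulation_config()` encodes the study conditions: 371 scFv analytes
covering 158 proteins (one to nine clones per target), three replicate
spots per analyte, three scan-date batches and two slide batches, and a
clinical table with OS/PFS, MIPI components, Ki-67 and TP53 status.
Survival is exponential proportional hazards,
$h(t) = h_0 \exp(\mathbf{z}^\top \boldsymbol\beta)$, with $h_0 = \log 2 / 15$
per month (median OS 15 months, matching relapsed MCL). An exponential
law was chosen over Weibull deliberately: it has closed-form means for
tests, and every downstream method is rank-based, so the shape is
irrelevant. Censoring combines an independent exponential — whose rate is
solved numerically so the expected censored fraction matches the request —
with an administrative horizon at 36 months.

Choices worth knowing about:

* **Signature correlation.** The planted protective proteins share a
  latent factor with correlation $\rho = 0.5$. This is not cosmetic: the
  signature emulates a functionally coherent immune program, and with
  *independent* planted effects the marginal (univariate) hazard ratios
  attenuate to roughly a third of the conditional ones, far weaker than
  the per-analyte hazard-ratio range (about 0.25–0.4 per SD) this class of
  study reports. $\rho = 0.5$ reproduces that range. The background
  proteome stays independent (`block_correlation = 0`).
* **Replicate noise.** Multiplicative log-normal noise calibrated so the
  *sample* CV of a triplet averages `replicate_cv`; the sample SD of
  $n = 3$ underestimates $\sigma$ by $c_4(3) \approx 0.886$, so the
  population CV is inflated by $1/c_4$. With probability
  `outlier_spot_rate` one replicate is multiplied by a factor far above the
  noise scale, guaranteeing the CV-rule path is exercised.
* **Clone allocation.** Counts are dealt round-robin (capped at nine)
  until 371 is reached, then shuffled with the seed — reproducible, and
  spanning the one-to-nine clone range.
* **MIPI covariates** are drawn from plausible independent ranges (age
  45–85, ECOG 0–3, LDH ratio 0.5–4, WBC 2–40 · 10⁹/L) because no joint
  distribution is published; `mipi_effect` (default 0.68 per unit, the
  published univariate coefficient) enters the hazard.

What the generator does **not** emulate: spatial slide artifacts beyond a
binary quality flag, assay saturation, correlated censoring, cohort
heterogeneity in treatment. Passing recovery tests therefore demonstrates
the pipeline's statistical behaviour, not assay-level robustness on real
slides.

## Pre-processing

The order is fixed and logged: background subtraction → replicate
aggregation → subarray QC → trimming → log2 → batch correction.

**CV rule.** A triplet with CV (SD/mean) at or below 0.15 is averaged; above
that, the replicate farthest from the triplet median is eliminated (ties:
higher replicate index) and the remaining two are averaged; fewer than two
valid replicates yield a missing value. The boundary CV = 0.15 is assigned
to the keep-three branch, a convention the tests pin down. A sample with
more than 30% discarded spots (strictly) is flagged for repetition and
excluded.

**Trimming.** "Discarding 5% of lower and upper extremes" is ambiguous
between deletion and winsorization; the default winsorizes per analyte at
the 5th/95th percentiles (linear-interpolation quantiles, R type 7),
because deleting 10% of a 44-sample cohort per analyte would create heavy
structured missingness the downstream regressions cannot absorb.
`trim_mode = "discard"` preserves the literal reading. Whether trimming
should act per analyte, per subarray or globally is not documented for
this assay class; per analyte is the default here.

**Batch correction** follows the parametric empirical-Bayes location/scale
scheme (standardize per analyte against pooled within-batch variance;
estimate per-batch location/scale; shrink with a normal prior on location
and inverse-gamma on scale, hyperparameters by moment matching, joint
solution by fixed-point iteration; adjust and back-transform). Scan date
is the only factor corrected — it dominates the slide-batch effect — and no
biological covariates enter the design. Two implementation notes:

* A final per-analyte recentring restores each analyte's grand mean
  exactly; EB shrinkage otherwise leaves a small systematic offset.
* With a single batch the input is returned unchanged (there is no batch
  contrast); a batch with one sample is an error instructing merge/drop.

Note the EB estimator deliberately does *not* force per-analyte batch
means to be identical — the residual per-analyte difference after
correction is of the order of the sampling noise of a between-batch mean
difference, which is the intended bias/variance trade-off of shrinkage.

Missing values that remain after aggregation are mean-imputed per analyte
immediately before model fitting and the count is recorded; the upstream
assay literature is silent on imputation.

## Consensus selection

**Cox screen.** Each analyte is standardized and fit in a univariate Cox
model (Efron ties); analytes with Wald $p < 0.05$ pass. Proportional
hazards is checked per passing analyte by the scaled-Schoenfeld test and
violations are *flagged*, not excluded. Raw $p$-values are used for the
screen (the customary practice this pipeline reproduces);
Benjamini–Hochberg $q$-values are reported alongside for transparency.

**Cox-BE arm.** Twelve seeded runs; each draws a stratified 90% patient
subsample, filters candidates by Wilcoxon rank-sum $p < 0.05$ between
outcome classes (died vs. not during follow-up), and then runs backward
elimination around a linear SVM (fixed $C = 1$, no internal tuning — at
$n \approx 44$–150 tuning inside LOOCV would be underpowered) scored by
leave-one-out cross-validated ROC AUC with mid-rank ties.

Two elimination details were genuinely open and deserve their rationale:

* **Removal rule.** The classical "remove while the AUC does not drop"
  rule interacts badly with the fact that a LOOCV AUC is a step function
  (steps of $1/(n_1 n_0) \approx 2\times10^{-4}$ here): plateau removals
  are almost always available, and choosing the best of ~30 candidate
  removals each round adds a selection bias of one to two AUC points.
  Together these drive deep, subsample-specific elimination that churns
  interchangeable clones of the same protein. The default therefore
  removes a feature only when its removal *improves* the AUC by more than
  `auc_tolerance = 0.01`; elimination then prunes clearly detrimental
  features and stops, and the per-run selection is dominated by the
  rank-sum filter — which matches the reported behaviour of this design
  (runs retaining ~38 of 43 candidates). `removal_rule = "no_drop"`
  restores the classical rule.
* **Consensus level.** The run-consensus is computed both over analytes
  (clones) and over target proteins. The pipeline uses the protein-level
  consensus: a protein stays when *every* run retains at least one of its
  clones. With multi-clone targets, interchangeable clones alternate
  across subsamples, so a clone-level all-runs intersection
  systematically loses exactly the multi-clone proteins the assay was
  designed to cover redundantly. The clone-level consensus remains
  available (and is what the null-calibration tests constrain).
* **Intercept-free LOOCV scores.** Held-out samples are scored by the
  fold's discriminant without the intercept: the intercept tracks the
  training class balance, which differs across leave-one-out folds by
  exactly the held-out label, and would otherwise leak it (biasing the
  null AUC well below 0.5).

The LOOCV SVM itself is a dual coordinate-descent solver for the
L2-regularized hinge loss (bias as an augmented regularized feature),
warm-started across folds, with cyclic updates and a projected-gradient
stop — fully deterministic. Its held-out AUCs are cross-checked against an
independent SVM implementation in the tests.

**ENR arm.** The full 371-analyte panel is regressed on observed OS months
with a seeded 80/20 train/test split; for each mixing parameter
$\alpha \in \{0, 0.1, \dots, 1\}$ the penalty strength is chosen by
internal cross-validation on the training split and the model is judged by
test RMSE (ties: higher $R^2$). Using observed months as the response
ignores censoring — a real limitation of the RMSE-in-months design that
this package reproduces deliberately; `response = "events_only"` offers a
censoring-aware alternative. Multi-clone or sign-contradictory selections
defer to the univariate Cox results.

**Intersection.** The signature is the protein-level overlap of the two
arms; each protein carries the univariate Cox coefficient of its
best-$p$ clone as its RIS weight. Alternative signature lengths can be
ranked with `compare_signature_lengths()` (Harrell's C, then Cox $p$ of
the score).

## Scoring and the combined index

MIPI is computed from its published formula
($0.03535\,\mathrm{age} + 0.6978\,[\mathrm{ECOG} > 1] +
1.367 \log_{10} \mathrm{LDH~ratio} + 0.9393 \log_{10} \mathrm{WBC}$) with
categories LR $\le 5.7$, HR $\ge 6.2$, IR strictly between. The RIS score
uses negative (protective) weights, so *low* expression of the signature
proteins gives a *high* score and high risk. Its ternary coding splits the
continuous score at two log-rank-optimized cutpoints; any strictly
increasing transform of the score yields the same coding, since the
search is rank-based. The "partially categorical" form of the published
index — the ternary code entering the weighted sum as a number 0/1/2 — is
an interpretation; it is the only reading consistent with the published
index median arising from MIPI around 5–7 with a weight near 1.3, and a
`ternary = FALSE` switch preserves the continuous alternative.

Index weights default to a refit on the current cohort (mandatory for
synthetic data); `index_weights()` supplies the published pair
$(0.708, 1.327)$ for reproduction mode.

## Survival evaluation

Kaplan–Meier estimation wraps the standard product-limit machinery. The
$k$-sample log-rank statistic (observed-minus-expected with hypergeometric
variance) is implemented in compiled code because the exhaustive
two-cutpoint search evaluates it roughly $10^4$ times per call; it agrees
with the reference implementation to $10^{-8}$ and with a brute-force
double loop exactly. The cutpoint search scans midpoints between
consecutive sorted unique scores, enforces a minimum group fraction
(default `min_frac = 0.10`; published usage evidently allowed a 17%
high-risk group, so 0.10 balances power against degenerate strata) and
breaks ties toward the smaller first, then second cutpoint. The minimized
$p$-value is anti-conservative by construction (no correction for the
optimization is applied, matching field practice); treat it as a ranking
device, not an honest test level.

Harrell's C counts a pair as usable only when censoring leaves the order
of event times determinable and times differ; score ties count one half.
The convention is higher score = higher risk.

## Problem sizes and numerical conventions

The simulation-backed tests run at the sizes the properties are stated
for: recovery and null calibration at $n = 150$ patients × 371 analytes
over 10 seeds; log-rank calibration over 1000 two-group null draws;
oracle equivalences at $n \le 60$. The SVM dual solver uses stopping
tolerance 0.05 (AUC rankings are unchanged down to $10^{-3}$), the EB
fixed-point iterates to $10^{-4}$ relative change, and the Cox screen
relies on the survival package's partial-likelihood Newton iterations with
Efron ties. All randomness flows from one integer seed through
`derive_seed(seed, stage_label)`, so any stage can be re-run in isolation
and reproduce its in-pipeline behaviour, and a rerun of `run_pipeline()`
with the same configuration is byte-identical (manifests carry no
wall-clock timestamp by default for exactly this reason).

## Known limitations

* The ENR response ignores censoring (by design, see above); with heavy
  censoring its selections lean toward proteins correlated with observed
  — not necessarily true — survival time.
* The minimized log-rank $p$ for cutpoints is optimistically small.
* The LOOCV AUC retains a small pessimistic bias (about 0.03 on null
  data) even with intercept-free scoring; it cancels in the within-run
  comparisons the eliminator makes.
* Mean imputation understates variance; at the missingness levels the
  CV rule produces here (well under 1%) this is negligible.
* The synthetic cohort's strong planted effects give concordances well
  above those reported for real relapsed-MCL cohorts; recovery results
  say nothing about effect sizes real serum assays achieve.
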