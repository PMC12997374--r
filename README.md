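# spiralselect

Screening classifiers for small, imbalanced clinical tables — built for
the chronic kidney disease (CKD) laboratory panel setting: a few hundred
patients, two dozen mixed nominal/numeric attributes, pervasive
missingness, and a skewed class split. The package is aimed at
biostatisticians and ML researchers who need the *whole* protocol —
preprocessing, feature selection, classification, tuning, evaluation,
explanation — as tested, leakage-safe, reproducible code rather than a
notebook.

## The method

Five stages, bound into one nested, leakage-safe pipeline:

1. **Preprocessing** — mode/median imputation fitted on training rows
   only; removal of rows with ≥ 50% missing attributes; category
   validation against clinical domains (e.g. htn ∈ {yes, no}); Z-score
   outlier removal at |z| > 3; SMOTE oversampling of the training
   minority (k = 5, Euclidean); z-standardisation and one-hot encoding.

2. **Feature selection** — a binary gravitational search: agent *i*'s
   subset S_i is scored by the wrapper fitness

   f_i = α · Err(S_i) + β · |S_i| / D,  α = 0.9, β = 0.1,

   with masses m_i = (f_max − f_i)/(f_max − f_min + ε), forces
   G(t)·M_i·M_j·(X_j − X_i)/(R_ij + ε) summed over the Kbest agents,
   G(t) = G₀·exp(−15 t/T), and a sigmoid transfer to bits. With
   probability SP an agent instead takes a logarithmic-spiral jump
   toward the incumbent best, X_d ← X_d + (X*_d − X_d)·e^{bθ}cos(2πθ),
   θ = r·U(−1,1) — local exploitation around promising subsets.
   `spiral_prob = 0` is the plain-BGSA ablation.

3. **Classifier** — a deep belief network: stacked RBMs (64, 32 hidden
   units) pretrained by CD-1 (η = 0.01, momentum 0.9, 50 epochs),
   unrolled and fine-tuned by momentum SGD on cross-entropy with dropout
   0.3, L2 1e-4 and early stopping.

4. **Tuning** — elephant herding optimisation over (log η, momentum,
   log λ, hidden width): clans move toward their matriarch
   (x′ = x + a(x_best − x)r, a = 0.5), the worst member is resampled,
   matriarchs take the clan-centre move β·x̄ (β = 0.7); the objective is
   inner-CV mean squared error of the network outputs.

5. **Evaluation & explanation** — nested stratified 5-fold CV (outer
   folds estimate generalisation only), confusion metrics, rank AUC,
   Brier score, expected calibration error, calibration slope; exact
   Shapley attribution of the selected features by full coalition
   enumeration, with efficiency guaranteed to numerical precision.

A synthetic-data generator emulates the CKD panel layout (mixed types,
configurable imbalance and missingness, known informative subset), so
every stage is testable without external data; `vignettes/methods.Rmd`
documents the models, defaults and their rationale.

## Worked example

```r
library(spiralselect)

spec <- synthetic_spec(seed = 42)       # CKD-like panel, 7 planted features
ds   <- generate_dataset(spec)
print(ds)
#> <tabular_dataset> 400 rows, 24 features (11 numeric, 13 nominal)
#>   positives: 254 / 400 (63.5%); missing cells: 5.45%
#>   informative features: num01, num05, num09, nom12, nom16, nom20, nom24

state <- fit_preprocessor(ds)
train <- smote_oversample(ds, smote_config(seed = 42), state)
enc   <- transform_dataset(train, state)
sel   <- run_sss_bgsa(surrogate_evaluator(enc), D = 24, fs_config(seed = 42))
ds$col_meta$name[sel$mask == 1]
#> num01, num04, num05, num08, num09, num11, nom12, nom15, nom16, nom20, nom24
round(sel$fitness, 4)
#> 0.1381
```

The selected mask covers all 7 planted informative features (plus four
spurious ones — the β/D ≈ 0.004 size reward is deliberately gentle); its
fitness 0.1381 combines the cross-validated error of the subset with the
11/24 size penalty. The full nested evaluation:

```r
report <- nested_cv(ds,
                    cv_plan(outer_folds = 5, inner_folds = 5,
                            repeats = 1, seed = 42),
                    benchmark_config(seed = 42))
print(report)
#> <evaluation_report> 5 outer folds x 1 repeats
#>   accuracy     0.870 +/- 0.036
#>   sensitivity  0.913 +/- 0.030
#>   specificity  0.794 +/- 0.130
#>   auc          0.941 +/- 0.026
#>   brier        0.093 +/- 0.022
#>   cal_slope    0.949 +/- 0.370
#>   ...
```

Mean ± SD are over outer folds: the pipeline separates the classes with
AUC ≈ 0.94 on this draw (0.95–0.97 across generator seeds), a Brier
score of 0.09, and a calibration slope near 1 (no systematic over- or
under-confidence). `run_full_pipeline()` adds the exact-Shapley feature
ranking and writes all artifacts plus a provenance manifest;
`inst/cli/spiralselect.R` exposes the same stages as shell subcommands
(`simulate`, `select`, `train`, `evaluate`, `explain`, `run`).

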