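# gaitbac

Estimating blood alcohol content from smartphone tandem-gait sensing.

Alcohol intoxication degrades gait — postural sway grows, step timing
becomes irregular — and a smartphone in a pocket records exactly the
signals that capture it. `gaitbac` implements a complete pipeline for
regressing estimated blood alcohol concentration (eBAC) on features of a
short, standardized tandem-gait walk recorded by a phone's inertial
sensors (tri-axial linear acceleration and attitude at 100 Hz for 30 s)
during hourly ecological momentary assessments (EMA) on drinking evenings.
It is aimed at digital-health researchers who want a tested, reproducible
reference implementation of each stage:

1. **eBAC labels** from hourly self-reported drink counts via the
   Matthews–Miller formula

   ```
   eBAC = (c / 2) · (GC / weight) − 0.017 · t
   ```

   with `c` standard drinks, `GC` = 9.0 (women) / 7.5 (men), weight in
   pounds and 0.017 g/dL/h the clearance rate — with episode accumulation,
   missing-report-as-zero handling and ascending/descending limb labels
   (`compute_ebac()`, `ebac_trajectory()`).
2. **Gait features**: sliding 128-sample windows (hop 64) over each of the
   six channels; per-window mean, population SD, pairwise inter-axis
   Pearson correlation, and FFT energy `Σ|X_k|²/|w|` (= `Σx²` by
   Parseval), averaged across windows into a 24-dimensional descriptor per
   walk (`extract_features()`).
3. **A Bayesian-regularized neural network** written from scratch: one
   sigmoid hidden layer with a linear output, trained by
   Levenberg–Marquardt on `F = βE_D + αE_w`, with the evidence-framework
   updates `γ = N − 2α·tr(H⁻¹)`, `α = γ/2E_w`, `β = (n−γ)/2E_D` after
   every step (`brnn_train()`), plus plain-LM and conjugate-gradient
   comparison trainers and cross-validated hidden-size selection.
4. **Evaluation**: seeded 70/30 splits, the five comparison metrics
   (R, MAE, RMSE, RAE%, RRSE%), 20-bin error histograms, and baselines
   (RBF support-vector regression, ordinary least squares)
   (`compute_metrics()`, `compare_models()`).
5. **A synthetic study generator** emulating the EMA protocol — 10
   subjects, 8 weekend evenings, five hourly slots with 32% completion,
   episode totals of mean 3.6 (SD 2.2) drinks — with gait degradation
   monotone in eBAC, so the whole pipeline is testable end to end
   (`simulate_dataset()`).

## Worked example

```r
library(gaitbac)

cfg <- simulation_config(seed = 1)            # the emulated study
res <- run_pipeline(cfg, n_hidden = 10, seed = 1)

res$metrics_test
#> <eval_report> test (n = 42)
#>   MSE 5.77328e-05  R 0.9918  MAE 0.0035952  RMSE 0.00759821  RAE 9.39%  RRSE 14.46%

res$comparison
#>               model         r         mae        rmse   rae_pct  rrse_pct
#> 1               MLP 0.9918450 0.003595198 0.007598209  9.389974 14.460696
#> 2               SVM 0.8722742 0.016105044 0.029493684 42.063321 56.131544
#> 3 Linear Regression 0.9992033 0.001625463 0.002100915  4.245400  3.998401
```

Reading this: the simulated cohort produced 139 labelled walks; on the
30% held-out split the network's predictions correlate with the true eBAC
at R = 0.99 with an RMSE of ~0.008 g/dL, and the relative errors say it
explains all but ~9–14% of what a predict-the-mean baseline leaves. On
this generator the gait–eBAC coupling is clean and monotone, so the linear
baseline is also strong; the network's advantage appears on nonlinear
relationships (see the model-comparison tests). A negative control with
the gait–eBAC coupling switched off (`impairment_gain = 0`) shows no
systematic test correlation, guarding against label leakage.

Single stages are available directly:

```r
p <- subject_profile("s1", "male", 179)
compute_ebac(p, total_drinks = 4, hours_drinking = 2)
#> [1] 0.04979888

rec <- simulate_gait(0.08, p, cfg, seed = 42)
length(extract_features(rec))
#> [1] 24
```

A thin command-line front end with `simulate` / `features` / `train` /
`evaluate` / `compare` / `pipeline` subcommands is installed at
`inst/cli/gaitbac.R`.

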