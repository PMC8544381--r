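# notescore

Automatic quality scoring of clinical records, with mixed-model calibration
of the scores for reviewer leniency.

## The problem

Hospitals ask senior physicians to review inpatient records and rate their
writing quality on a 0–10 scale. A sequence model can learn to imitate those
ratings from the record text, but two obstacles remain:

1. **Vocabulary.** Embeddings trained only on in-house records (EHR text)
   understand clinical terms but cover a small vocabulary; embeddings
   trained on open corpora cover a huge vocabulary but miss clinical
   semantics. *Projection word embeddings* bridge the two: a linear map
   `W`, fitted by least squares over the shared vocabulary, carries the
   open-corpus table into the domain coordinate system while keeping every
   open-corpus symbol.
2. **Rater effects.** Reviewers differ systematically in leniency, so a
   single model score cannot match every reviewer. A linear mixed model
   (LMM) absorbs this: with records grouped by reviewer,

   ```
   Y = X B + Z u + e,      u ~ N(0, G),  e ~ N(0, sigma^2 I)
   ```

   the best linear unbiased prediction of reviewer m's effect is

   ```
   Sigma_m = Z_m G Z_m' + sigma^2 I
   BLUP_m  = G Z_m' Sigma_m^-1 (Y_m - X_m B)
   B_m     = B + BLUP_m
   ```

   and the *calibrated* ("LMM-modified") score of a record is `x'B +
   z'BLUP_m` — the reviewer-specific regression evaluated at the record's
   raw model score. Performance is measured by mean absolute error,
   `MAE = sum |y_i - yhat_i| / N`, aggregated per reviewer.

Real review corpora are private, so the package ships a synthetic-data
generator with known ground truth (latent record quality, reviewer leniency
and noise, writer effects, marker-token text whose composition encodes
quality, and paired general/domain corpora with a planted linear geometry).
Every stage — PPMI/SVD embedding training, projection fitting, a gated
recurrent (LSTM) scorer, REML estimation of `(B, G, sigma^2)`, BLUP
calibration, and the MAE/heatmap/quartile diagnostics — is testable against
that ground truth.

## Worked example

Fit the calibration stage on a synthetic review corpus with reviewer
leniency SD 0.6 and an unbiased AI scorer with noise SD 0.5:

```r
library(notescore)
cfg <- generator_config(n_records = 1200, n_reviewers = 30, n_writers = 20,
                        reviewer_effect_sd = 0.6, residual_sd = 0.5, seed = 42)
dat <- generate_scoring_dataset(cfg)
records <- simulate_ai_scores(dat$records, noise_sd = 0.5, seed = 43)

designs <- build_designs(records, formula_spec())
fit <- estimate_lmm(designs)
fit
#> <mixed_model_fit> REML, 30 clusters / 1200 records
#>   fixed effects B:
#>   (Intercept)      ai_score departmentD02 departmentD03 departmentD04
#>        1.6382        0.8158       -0.4921       -0.3942       -0.4192
#>   random-effect covariance G:
#>             (Intercept)
#> (Intercept)      0.3428
#>   sigma^2 = 0.4534; restricted log-likelihood -1282.82 (9 iterations)

blups <- compute_blups(fit, designs)
records$calibrated_score <- calibrate_scores(fit, blups, records)$calibrated_score
report <- grouped_report(records, "division")
report[, c("group", "n_records", "raw_mae", "calibrated_mae", "p_value")]
#>                       group n_records raw_mae calibrated_mae  p_value
#> 1                   Overall      1200   0.730          0.532 2.48e-06
#> 2         Internal medicine       300   0.802          0.525 7.81e-03
#> 3 Obstetrics and pediatrics       300   0.701          0.531 1.56e-02
#> 4         Other departments       300   0.758          0.494 3.12e-02
#> 5                   Surgery       300   0.658          0.573 1.56e-02
```

The estimated reviewer-leniency SD (`sqrt(0.343) = 0.59`) recovers the
generating value 0.6, and calibration cuts the per-reviewer MAE from 0.73
to 0.53 (signed-rank p < 1e-5): the direction and mechanism of the
raw-to-calibrated improvement the method is built for. `run_pipeline()`
chains everything — simulation, embeddings, projection, scorer training,
calibration, reports — into one seeded, byte-reproducible artifact
directory; see the methods vignette (`vignettes/notescore-methods.Rmd`).

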