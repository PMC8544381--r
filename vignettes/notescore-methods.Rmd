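---
title: "Scoring clinical records and calibrating the scores: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring clinical records and calibrating the scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(notescore)
```

`notescore` studies a two-stage system for grading the writing quality of
clinical records: a sequence model maps a record's token stream to a raw
0–10 score, and a linear mixed model (LMM) then calibrates that score to
the behavior of the individual reviewing physician. This vignette is the
package's own account of the models, their assumptions, the tunable
parameters, and the choices made where the design was genuinely open.

## 1. The statistical core: mixed model and BLUP calibration

Records are grouped into clusters indexed by the scoring reviewer `m`.
With `Y_m` the reviewer's expert scores (n×1), `X_m` the fixed-effect
design (n×q, leading all-ones column) and `Z_m` the random-effect design
(n×p, columns a subset of `X_m`'s), the model is

$$Y = XB + Zu + e, \qquad u \sim N(0, G), \quad e \sim N(0, \sigma^2 I),$$

with independence of `u` and `e`. The per-cluster response covariance is
$\Sigma_m = Z_m G Z_m^\top + \sigma^2 I$, the cluster's random-effect
prediction is the BLUP
$G Z_m^\top \Sigma_m^{-1}(Y_m - X_m B)$, and the cluster-specific
coefficient vector is $B_m = B + \mathrm{BLUP}_m$. A record's calibrated
score is $x^\top B + z^\top \mathrm{BLUP}_m$.

Choices made here, and why:

* **Cluster = reviewer.** The calibration exists to absorb rater leniency;
  reviewer clustering is what makes the reviewer-bias diagnostics
  (heatmaps, quartiles) meaningful. `formula_spec(cluster = ...)` accepts
  writer or department clustering as alternatives.
* **Fixed design** defaults to intercept + raw AI score + reference-coded
  department indicators; minimal, and configurable. Random effects default
  to an intercept per reviewer, optionally plus an AI-score slope.
* **Estimation = REML**, maximized by quasi-Newton (`nlminb`) over a
  log-Cholesky parameterization of `G` plus `log σ`. REML avoids the
  downward bias of ML variance components; log-Cholesky keeps `G`
  positive semi-definite and `σ² > 0` along the whole search path without
  constraints. `B` is the GLS solution at the optimum. The residual
  covariance is exactly `σ²I` — no heteroscedastic extension.
* **Numerics.** Every linear system goes through the Cholesky factor of
  `Σ_m`; the matrix is never inverted. A condition guard (1e10 on the
  squared diagonal ratio of the factor) rejects numerically singular
  clusters by name. Non-convergence raises an error with the optimizer
  trace rather than returning a half-fit.
* **Unseen clusters** at prediction time get BLUP = 0 (the population
  prediction) and a `population_level` flag.
* **Covariate back-fill.** For forecasting at times with unobserved
  covariates, `fill_covariates()` implements carry-last-forward (one prior
  row required) and per-covariate linear extrapolation against observation
  index (two required). It is provided for completeness of the calibration
  toolkit but unused by the default pipeline, which always has the
  record's covariates in hand.

The test suite pins the implementation to independent oracles: BLUPs must
agree with the joint solution of Henderson's mixed-model equations to
1e-8 on random instances; intercept-only BLUPs must equal the closed-form
shrinkage `n r̄ τ² / (σ² + n τ²)` to 1e-10; REML must match the balanced
one-way ANOVA estimators to 1e-6 and `lme4::lmer` (used as a cross-check
only, never at runtime) to 1e-4.

## 2. Projection word embeddings

`train_embeddings()` is a deterministic, dependency-light trainer:
windowed co-occurrence counts, positive PMI, truncated SVD with rows
$U_d\sqrt{S_d}$ and a fixed sign convention. A stochastic skip-gram
backend could be slotted in behind the same interface, but determinism is
worth more here than the last bit of embedding quality: every downstream
artifact becomes byte-reproducible.

`fit_projection()` solves $W = \arg\min_W \|SW - T\|_F$ by ordinary least
squares over the shared vocabulary. OLS is the fewest-assumptions reading
of "carry one coordinate system into another by matrix multiplication"; an
orthogonal-Procrustes mode (`method = "procrustes"`) and a ridge fallback
(`lambda`) are provided, and neither is claimed to be anyone's exact
historical recipe. The projected table keeps the **full source
vocabulary** — that is the point of the construction: open-corpus
vocabulary coverage expressed in domain coordinates. The pipeline then
concatenates the original and projected general-corpus tables
(`concat_embeddings`), so the scorer reads both embedding sources at once;
concatenating with the raw domain table instead would intersect
vocabularies and defeat the purpose.

## 3. The recurrent scorer

`train_scorer()` fits a single-layer unidirectional LSTM (standard
input/forget/output gates, tanh cell) over frozen embedding rows; the
final hidden state feeds a linear head and a scaled sigmoid maps the
output into `[score_min − 2, score_max + 2]`, so predictions cannot leave
the score scale's neighborhood. Training uses Adam on squared error
(absolute error available) with **epochs 20, batch size 300, learning rate
0.001** as defaults — the training budget the scoring study operates
under. Depth, hidden size (default 64) and loss are package choices, not
reproductions.

Two initialization choices matter under a small fixed step budget and are
worth stating:

* **Chrono-style gate biases.** Forget-gate biases are drawn log-uniformly
  up to the sequence length (with input-gate biases set to their
  negatives), so at initialization the cell population already contains
  units that average token evidence over the whole document. The fixed
  training budget then refines document-scale features rather than having
  to discover memory from scratch.
* **Head bias at the target mean.** The output bias starts at the inverse
  sigmoid of the training-score mean, so no optimizer steps are spent
  locating the score scale. A constant-target corpus is therefore
  predicted correctly from epoch 0.

The backward pass is hand-derived batched BPTT with masking; it is pinned
by a central-difference numerical gradient check (1e-7) and a scalar
hand-rolled single-step reference (1e-10) in the test suite. Batch and
one-by-one prediction agree to 1e-6; training is bit-deterministic given
the config seed.

## 4. What the synthetic generator emulates — and what it does not

`generate_scoring_dataset()` draws departments (mean scores
`N(7.5, 0.5²)`, the high-scoring regime typical of routine record review),
writers with persistent quality offsets (SD 0.5), reviewers with leniency
intercepts `u ~ N(0, τ²)` (default τ = 0.6) and optional random slopes,
and records with latent quality `N(μ_dept + w_writer, 1²)` clipped to
[0, 10]. The expert score is latent quality plus the reviewer effect plus
`N(0, σ²)` noise (default σ = 0.5), clipped; random slopes act on
*centered* latent quality so they do not shift the score scale. Scores are
continuous (a mean over several Likert sub-items is nearly continuous,
and continuity keeps the LMM exact); a 0.1-rounding flag exists. A
configurable fraction of "erratic" reviewers with extra rating noise (SD
2) supports the quartile diagnostic. The truth table (department means,
writer offsets, reviewer intercepts/slopes/erratic flags) is returned so
estimators can be scored against generating values.

Record text is `doc_length` (default 100) abstract symbols: at each
position a *quality marker* is emitted with probability
`strength × budget × q_norm` and a *deficiency marker* with probability
`strength × budget × (1 − q_norm)`; the rest is a Zipf background. The
tier sizes (12 each), budget (0.6) and document length were sized so that
one document determines latent quality to roughly ±0.6 points — the same
order as rater noise, so text carries real but imperfect signal. Strength
0 severs the text–quality link entirely, which the suite uses as a
leakage guard: a scorer trained on strength-0 data must not beat the mean
baseline beyond noise.

`generate_corpora()` supplies the two embedding-training sources: tokens
live in a latent geometry; documents are topic draws; the domain corpus
uses a reduced vocabulary (fraction 0.7), a sharper topic temperature
(0.8), and the general geometry times a planted linear `relation`
(identity by default) — so the map between the two coordinate systems is
known exactly and the projection fit can be tested against it. Marker
tiers share latent directions (`tier_cohesion` 0.7), which makes same-tier
markers co-occur and cluster in trained embeddings — the structure the
scorer exploits, and the property the embedding tests assert.

What passing tests on this corpus do **not** show: anything about real
clinical language (tokens are abstract symbols; no synonymy, negation,
section structure, or length variation), about integer Likert raters,
about non-Gaussian or confounded reviewer assignment, or about the
absolute MAE levels reachable on real review corpora. The synthetic
results validate the machinery and its statistical direction (calibration
reduces per-reviewer MAE when rater effects exist), not clinical
performance.

## 5. Evaluation machinery

`mae()` is the plain mean absolute deviation. `grouped_report()`
aggregates MAE **per reviewer, then averages** (the ± SD is dispersion
across reviewers); per-record pooling sits behind a flag. The paired
raw-vs-calibrated comparison is a Wilcoxon signed-rank test — exact for up
to 25 informative pairs via convolution of the rank generating polynomial
(average ranks doubled to integers, so ties remain exact; `wilcox.test`
declines exactness under ties, which is why the exact branch is authored
here), normal approximation with continuity correction beyond that, a sign
test as an option, and p = 1 with a flag when all differences vanish.
Heatmap cells with no support are missing, never zero. Block summaries
take explicit reviewer/writer block assignments; a k-means helper
(`suggest_blocks()`) can propose blocks from heatmap rows but is labeled
as the heuristic it is. Quartiles of per-reviewer calibrated MAE are
rank-based with a stable tie-break on reviewer id, so quartile sizes never
differ by more than one.

## 6. The pipeline and reproducibility

`run_pipeline()` chains simulate → corpora/embeddings/projection → scorer
training → prediction → LMM calibration → evaluation, writing every
artifact (JSONL records, word2vec-format tables, TSV/CSV reports, a JSON
fit report) plus a manifest with the seed, the full config and per-file
checksums. One master seed derives every stage stream; reports contain no
timestamps, so a rerun with the same config is byte-identical — asserted
in the suite. The default split is by the time field at the one-third
quantile (training on the earlier period), mirroring by-period study
designs; a seeded random-fraction rule is available.

The calibration-data policy is explicit because it is genuinely
ambiguous in deployed systems: `"holdout"` (default) fits the LMM and the
reviewer BLUPs on training-period residuals only and applies them to test
records; `"in_sample"` refits on the test period's expert/AI pairs, which
is what applying "LMM-modified" scores to an evaluation period implies
when reviewer effects are estimated from that same period. Both modes are
labeled in the fit report; neither is asserted to be anyone's exact
procedure.

## 7. Problem sizes and limitations

The shipped tests and the acceptance script run at desk scale, chosen as
the sizes at which every statistical claim is already decidable: 100
random instances for the Henderson-equation equivalence; 200 clusters × 50
records for REML recovery (estimates within 10%, slope within 5%); 40
reviewers × 40 records for the calibration improvement; 2,000 records,
vocabulary 200, for the scorer-vs-baseline comparison; 1,000 records for
the end-to-end determinism check.

Known limitations: one random-effect grouping at a time (no crossed
reviewer × writer effects); `R = σ²I` only; the scorer is CPU-sized and
single-layer (the `predict_scores` interface is backend-agnostic, so a
transformer scorer could be slotted in, and no claim is made about such
models here); clipping to [0, 10] mildly biases variance components when
score mass sits near the boundary — with the default regime (means ≈ 7.5,
component SDs ≤ 1) a few percent of draws clip, which is visible as a
small downward bias in recovered SDs and is absorbed by the recovery
tolerances; and the synthetic corpus, by construction, cannot certify
real-world scoring accuracy.
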