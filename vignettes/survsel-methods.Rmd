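---
title: "Prediction-oriented prognostic feature selection: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prediction-oriented prognostic feature selection: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(survsel)
```

## The problem

Prognostic biomarker discovery asks which of many candidate features
(gene expression, copy number, microbial abundances, ...) carry information
about a patient's survival time, under right censoring: for a censored
patient we only know the event time exceeds the observed follow-up.
Flexible survival learners predict well in this regime but do not, by
themselves, say *which* features matter — importance scores come with no
selection threshold, and raw coefficient supports of penalized fits are
contaminated by false positives. `survsel` implements two
prediction-oriented selection procedures on top of a common Cox-model core,
along with the simulation scenarios and metrics needed to benchmark them.

## The Cox core

All learners share the proportional-hazards frame
$\lambda(t \mid x) = \lambda_0(t)\, e^{H(x)}$, with risk score $H$ linear
for the penalized model and unconstrained for the tree ensembles. The loss
is the negative log partial likelihood
$$
\ell(\eta) \;=\; -\sum_{i:\,\delta_i = 1}\Big[\eta_i -
  \log \sum_{k \in R(t_i)} e^{\eta_k}\Big],
$$
where $R(t)$ is the risk set at $t$ and ties are handled throughout with
the Breslow convention (tied events share one denominator), the standard
choice in boosting implementations. `cox_neg_log_pl()` evaluates this loss
for arbitrary per-sample scores; `cox_grad_hess()` returns its exact
per-sample gradient $g_i$ and diagonal curvature $s_i$. Gradient boosting
uses these directly: the $m$-th weak learner is fit to the targets
$-g_i/s_i$ with weights $s_i$, and the score updates as
$H^{(m)} = H^{(m-1)} + \varepsilon\, \eta^{(m)}$ with learning rate
$\varepsilon$. The curvature is floored at $10^{-12}$ inside the boosting
objective so the targets never blow up; scores are max-shifted before
exponentiation (the loss is translation invariant, so this is exact, not
an approximation).

Three learners are registered: `penalized_cox` (lasso / elastic-net Cox via
coordinate descent, importance $|\hat\beta_j|$), `xgb_cox` (boosted trees
driven by the objective above, importance = total split gain), and `rsf`
(a random survival forest with log-rank splitting; importance = permutation
importance clipped at zero; the risk score is the ensemble cumulative
hazard summed over the event-time grid). The registry is a plug-in
contract, so further learners (e.g. a neural Cox model) attach without
touching the selection code. Absolute survival predictions for Cox-type
learners use the Breslow baseline estimated on the training data,
$S(t \mid x) = \exp\{-\hat H_0(t)\, e^{\eta(x)}\}$; the forest supplies its
own ensemble survival function.

Default hyperparameters follow the recommended ranges for these methods:
boosting learning rate 0.05 from the searched set
$\{0.001, 0.005, 0.01, 0.05\}$ (with 100 rounds the smaller rates barely
move the loss at the sample sizes used here), subsample fraction 0.5, L1/L2
regularization 0.05 from 0.01–0.1, 100 trees. For the survival forest the
minimum leaf size defaults to a *fraction* 0.25 of the sample (from the
recommended {0.25, 0.5}): shallow trees both regularize and keep log-rank
splitting affordable, since survival-forest cost grows roughly
quadratically with the number of distinct event times.

## PROMISE-Cox

The linear route extends prediction-oriented marker selection to censored
outcomes. Stage 1 tunes the penalty by event-stratified 5-fold
cross-validation over the grid $\lambda \in [0.01, 0.1]$ (8 log-spaced
points; for the elastic net also $\alpha \in [0.05, 0.5]$, with the penalty
$\lambda\sum_j\{\alpha|\beta_j| + \tfrac12(1-\alpha)\beta_j^2\}$). Stage 2
refits the penalized model on 100 event-stratified resamples and selects
features whose nonzero-coefficient frequency reaches the stability
threshold (default 0.6 from the recommended 0.6–0.8).

Four design choices in stage 1/2 deserve justification, because naive
defaults measurably break the false-positive control that motivates
stability selection (on signal-free data with $n = 200$, $p = 50$ they
yield 6–21 selections on average; the package's defaults yield < 1):

* **Tuning criterion.** The default is the validation partial likelihood
  rather than the validation C-index (both are available via `tune=`). On
  data without signal the C-index is flat noise across the grid, so its
  argmax drifts by winner's curse toward the smallest, densest penalty; the
  partial likelihood is a proper scoring rule that genuinely deteriorates
  for overfit dense models and reliably lands on the sparsest grid point.
* **One-standard-error rule.** Among grid points within one SE of the best
  mean CV score, the sparsest (largest $\lambda$) is chosen — the usual
  convention for penalized-path tuning, and the sparsity-favouring tie-break
  a flat CV surface requires.
* **Resampling scheme.** Resamples are subsamples of size
  $\lfloor n/2 \rfloor$ drawn *without* replacement (the classic stability
  selection construction), not size-$n$ bootstrap draws. Bootstrap
  resamples of a single dataset inherit its spurious correlations almost
  unchanged, so the same noise features recur above threshold; the
  disagreement between half-subsamples is precisely what the
  threshold exploits. A size-$n$ bootstrap remains available
  (`resample = "bootstrap"`).
* **Penalty rescaling.** The penalty needed to hold a fixed selection
  stringency scales like $1/\sqrt{n}$ (on the score-statistic scale a
  feature enters when $|z_j| \gtrsim c\,\lambda\sqrt{n}$), so each
  half-subsample is fit at $\lambda^\ast \sqrt{n/n_{\mathrm{sub}}}$.
  Refitting subsamples at the full-data $\lambda^\ast$ would systematically
  over-select.

Tuning precedes stability selection (tune-then-resample) rather than being
repeated inside each resample; this is $B\times$ cheaper and is the common
reading of combining CV with stability selection. The procedure requires
complete feature data; the boosted learners tolerate missing values.

## CV + top-k selection for nonlinear learners

Nonlinear learners have no coefficient support to threshold, so the panel
size $k$ is treated as the tuning parameter: for each candidate $k$, each
CV fold fits the learner on its training portion, ranks features by
importance, refits on the top $k$, and scores validation concordance;
$k^\ast$ maximizes the mean validation C-index, with ties going to the
smallest $k$ (parsimony). The final ranking uses the full-data fit's
importance (default) or the mean importance rank across folds
(`aggregate = "mean_rank"`), and the model delivered for prediction is the
learner refit on the selected panel. The default grid is
$\{5, 10, 20, 40, \dots\}$ capped at $\min(p, n/5)$. Importance ties are
broken by feature index so results are reproducible.

## Evaluation metrics

* **Concordance.** Orderable pairs are $(i, j)$ with $t_i < t_j$ and
  $\delta_i = 1$; a pair is concordant when the earlier-failing subject has
  the *higher* risk score. (Written with the inequality on the risk scores
  in the other direction, the estimand would reward anti-concordance;
  `survsel` uses the standard orientation, under which higher values mean
  better discrimination.) Score ties earn half credit by default;
  `tie_policy = "strict"` counts them zero.
* **Brier score / IBS.** The time-dependent squared error of predicted
  survival probabilities, censoring-reweighted by the Kaplan-Meier estimate
  $\hat G$ of the censoring-survival function (computed by flipping the
  event indicator): subjects who failed before the horizon contribute
  $\hat S(t,x_i)^2/\hat G(t_i^-)$, subjects still at risk contribute
  $(1-\hat S(t,x_i))^2/\hat G(t)$, and subjects censored before $t$ — or
  observed exactly at $t$, a boundary treated strictly as printed —
  contribute nothing. The IBS averages BS over $(0, t_{\max}]$ by the
  trapezoidal rule on the observed-time grid. A zero censoring-survival
  weight raises an error naming the offending time point rather than
  returning an unbounded value.
* **Selection TPR/FPR.** Fractions of signal and non-signal features
  selected.

## The synthetic cohorts

Five generators produce right-censored cohorts with known signal sets
(features beyond the first $q$ are pure noise):

1. **linear** — i.i.d. standard-normal features; exponential failure times
   with log conditional expression $x_1 + \dots + x_q$; censoring
   exponential with mean $q$ (about 26% censored at $q = 10$).
2. **quadratic** — as above with $\tfrac12(x_1^2 + \dots + x_q^2)$; the
   signal is invisible to a linear score, which is the point of the
   scenario.
3. **nonlinear** — five probit-transformed single/paired-feature terms
   (indicator, sine, cosine and square components), each bounded in
   $(0,1)$, scaled by 2, plus a linear tail in features 11..q; censoring is
   0.02 with probability 1/3 and Uniform(0, 0.02) otherwise, giving ~30%
   censoring.
4. **interaction** — Weibull failure times (shape 2 by default, exposed)
   whose log expression contains product terms such as an indicator of one
   feature gating the square of another, scaled by 4.
5. **risk_groups** — three groups of 400 samples whose 2000 features are
   normal with group means 5, 10, 15 (unit SD); failure times Weibull with
   shape 2 and a per-sample scale expression $\upsilon$ built from
   thresholded features. The binary high-risk label is $\upsilon$ above the
   cohort median (balanced classes); no censoring by default. Group feature
   variance, the label threshold and the censoring switch are documented
   defaults, since only the group means, sizes and the Weibull shape are
   pinned down by the design.

**Parameterization.** The scenario definitions state conditional-"mean"
expressions $e^{\eta(x)}$ for the failure time. `survsel` reads these on
the *hazard* scale (`rate_reading = TRUE`): $e^{\eta}$ is the exponential
rate, or for Weibull scenarios the reciprocal scale, so larger $\eta$ means
worse survival. The literal mean reading is available but demonstrably not
what the design intends: it censors essentially every subject in the
nonlinear scenario (whose stated censoring rate is ~30%, reproduced at
32-34% by the hazard reading), makes the interaction scenario degenerate,
and inverts the risk-group construction ("larger $\upsilon$, worse
survival" is impossible when $\upsilon$ is a Weibull scale). Under the
hazard reading the linear scenario is exactly a proportional-hazards model
with unit coefficients on the signal features.

Every generator routes randomness through one seeded generator per dataset
and restores the caller's RNG state; identical configurations reproduce
datasets bit for bit. Latent failure/censoring times and the scenario's
internal expressions are retained in the returned object so structural
invariants (observed time = min(T, C), indicator = 1{T <= C}) are testable.

What these cohorts do *not* emulate: correlated feature blocks,
batch/modality structure, heavy-tailed or zero-inflated measurements,
covariate-dependent censoring, or competing risks. Passing the recovery
benchmarks here demonstrates correctness of the machinery under clean
independence assumptions, not performance on real multi-omic data.

## Benchmark design

`run_benchmark()` reproduces the simulation-study design: per replicate,
simulate, split 80/20, run each method's selection on the training portion
only, refit the method's learner on the selected panel, and evaluate the
test C-index and IBS plus selection TPR/FPR. The evaluated model is the
refit-on-panel model (switchable in principle; a full-feature alternative
would change only `run_one_method`). Censoring survival for the IBS is
estimated on training data, with the integration horizon capped at the 80%
quantile of test follow-up so the weights stay bounded. All seeds derive
deterministically from (base seed, scenario, method, replicate); replicate
failures are dropped with a logged message, never imputed.
`rank_methods()` ranks methods 1..M by test C-index within each replicate
(average ranks on ties) and reports per-method means.
`risk_classification_experiment()` trains learners on 1000 of the 1200
risk-group samples, dichotomizes predicted test scores at the training-set
median predicted score, and reports misclassification against the true
labels plus Kaplan-Meier curves for true and predicted groups.

## Problem sizes used by the test suite

The replicated checks run at scaled-down profiles chosen to exercise the
same regimes with 10 replicates instead of 100: signal recovery at
$n = 1000$, $p = 100$, $q = 10$ (linear); method ordering at $n = 400$
(linear, all three learners) and $n = 1000$ (quadratic, boosted vs.
penalized); null-data control at $n = 200$, $p = 50$ over 20 replicates;
and a small fully deterministic benchmark run twice for byte-identity. The
top-k configurations in these runs use 3 folds and the grid {10, 20, 40}.

## Known limitations

* Breslow ties only; Efron weighting is not implemented.
* The stability-selection threshold is a raw frequency cut, not an
  error-controlled bound (no complementary-pairs machinery).
* The boosted and forest learners are deterministic only at
  `nthread/num.threads = 1`, which is how the package always invokes them.
* Per-subject survival curves for boosted models inherit the proportional-
  hazards shape through the Breslow baseline even though boosting itself
  does not enforce proportionality over time.
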