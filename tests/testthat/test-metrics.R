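test_that("concordance index: perfect, anti-perfect and error cases", {
  expect_equal(concordance_index(c(3, 2, 1), c(1, 2, 3), c(1, 1, 1)), 1)
  expect_equal(concordance_index(c(1, 2, 3), c(1, 2, 3), c(1, 1, 1),
                                 tie_policy = "strict"), 0)
  expect_error(concordance_index(c(1, 2), c(1, 1), c(0, 0)), "orderable")
})

test_that("concordance index equals brute-force pair enumeration", {
  for (rep in 1:200) {
    n <- sample(5:50, 1)
    toy <- make_toy_surv(n = n, seed = 1000 + rep, censor = 0.3)
    scores <- round(rnorm(n), 1)  # rounding forces occasional score ties
    if (sum(outer(toy$time, toy$time, "<") & toy$status == 1) == 0) next
    expect_equal(concordance_index(scores, toy$time, toy$status),
                 cindex_bruteforce(scores, toy$time, toy$status, 0.5),
                 tolerance = 1e-12)
    expect_equal(concordance_index(scores, toy$time, toy$status, "strict"),
                 cindex_bruteforce(scores, toy$time, toy$status, 0),
                 tolerance = 1e-12)
  }
})

test_that("concordance is rank-invariant and antisymmetric", {
  toy <- make_toy_surv(n = 40, seed = 13)
  s <- rnorm(40)
  c0 <- concordance_index(s, toy$time, toy$status)
  expect_equal(concordance_index(exp(3 * s), toy$time, toy$status), c0)
  expect_equal(concordance_index(s, toy$time, toy$status, "strict") +
                 concordance_index(-s, toy$time, toy$status, "strict"), 1)
})

test_that("Kaplan-Meier estimator: textbook values and survfit agreement", {
  km <- km_estimator(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  km0 <- km_estimator(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(km0$surv == 1))
  expect_error(km_estimator(numeric(0), numeric(0)), "empty")

  suppressMessages(library(survival))
  for (seed in 1:5) {
    toy <- make_toy_surv(n = 35, seed = 400 + seed)
    km <- km_estimator(toy$time, toy$status)
    ref <- survfit(Surv(toy$time, toy$status) ~ 1)
    expect_equal(surv_prob(km, ref$time), ref$surv, tolerance = 1e-10)
  }
})

test_that("surv_prob evaluates the step function with correct one-sided limits", {
  km <- km_estimator(c(1, 2, 3), c(1, 1, 1))
  expect_equal(surv_prob(km, c(0.5, 1, 1.5, 3.5)), c(1, 2/3, 2/3, 0))
  # left limits: S(t-) at an event time is the value just before the drop
  expect_equal(surv_prob(km, c(1, 2), left = TRUE), c(1, 2/3))
})

test_that("Brier score: closed-form cases", {
  tt <- c(1, 2, 3, 4); st <- rep(1, 4)
  G1 <- km_estimator(tt, rep(0, 4))  # no censoring: G == 1
  # perfect prediction: S = 0 for those dead before t, 1 for survivors
  perfect <- as.numeric(tt > 2.5)
  expect_equal(brier_score(2.5, perfect, tt, st, G1), 0)
  # constant 1/2 prediction, no subject at the horizon: BS = 1/4
  expect_equal(brier_score(2.5, 0.5, tt, st, G1), 0.25)
})

test_that("Brier score equals a direct-summation oracle on censored data", {
  for (rep in 1:50) {
    n <- sample(10:50, 1)
    toy <- make_toy_surv(n = n, seed = 2000 + rep, censor = 0.3)
    G <- km_estimator(toy$time, 1 - toy$status)
    pred <- runif(n)
    t0 <- unname(quantile(toy$time, runif(1, 0.2, 0.8)))
    ours <- tryCatch(brier_score(t0, pred, toy$time, toy$status, G),
                     error = function(e) NULL)
    if (is.null(ours)) next  # G hit zero at a needed point
    oracle <- brier_bruteforce(t0, pred, toy$time, toy$status,
                               G$times, G$surv)
    expect_equal(ours, oracle, tolerance = 1e-10)
  }
})

test_that("integrated Brier score: constant and perfect predictors, grid stability", {
  toy <- make_toy_surv(n = 100, seed = 14, censor = 0)
  toy$status <- rep(1L, 100)
  G1 <- km_estimator(toy$time, rep(0, 100))
  expect_equal(integrated_brier_score(0.5, toy$time, toy$status, G1), 0.25,
               tolerance = 0.01)
  perfect <- function(t) as.numeric(toy$time > t)
  expect_lt(integrated_brier_score(perfect, toy$time, toy$status, G1), 0.01)
  # refining the grid barely moves the integral on a smooth predictor
  smooth <- function(t) rep(exp(-t), 100)
  coarse <- integrated_brier_score(smooth, toy$time, toy$status, G1,
                                   t_max = max(toy$time))
  fine_grid <- sort(unique(c(toy$time, toy$time / 2, max(toy$time))))
  bs <- vapply(c(0, fine_grid),
               function(t) brier_score(t, smooth(t), toy$time, toy$status, G1),
               0)
  g <- c(0, fine_grid)
  fine <- sum(diff(g) * (head(bs, -1) + tail(bs, -1)) / 2) / max(toy$time)
  expect_lt(abs(coarse - fine), 1e-3)
})

test_that("selection TPR/FPR definitions and monotonicity", {
  r <- selection_tpr_fpr(1:10, 1:10, 100)
  expect_equal(c(r$tpr, r$fpr), c(1, 0))
  r <- selection_tpr_fpr(c(1:10, 11:19), 1:10, 100)
  expect_equal(c(r$tpr, r$fpr), c(1, 0.1))
  r <- selection_tpr_fpr(integer(0), 1:10, 100)
  expect_equal(c(r$tpr, r$fpr), c(0, 0))
  expect_error(selection_tpr_fpr(1:3, integer(0), 10), "nonempty")
  # monotone in set inclusion
  small <- selection_tpr_fpr(c(1, 2, 50), 1:10, 100)
  big <- selection_tpr_fpr(c(1, 2, 3, 50, 60), 1:10, 100)
  expect_gte(big$tpr, small$tpr)
  expect_gte(big$fpr, small$fpr)
})

test_that("evaluate_model assembles a coherent report", {
  toy <- make_toy_surv(n = 150, p = 5, seed = 15, hazard_beta = c(2, 0, 0, 0, 0))
  d <- survival_data(toy$X, toy$time, toy$status, true_signals = 1L)
  m <- fit_survival_learner(d, method = "penalized_cox",
                            params = list(lambda = 0.02))
  ev <- evaluate_model(m, d, selected = 1L)
  expect_gt(ev$cindex, 0.6)
  expect_true(is.finite(ev$ibs) && ev$ibs >= 0)
  expect_equal(ev$tpr, 1)
  expect_equal(ev$fpr, 0)
})
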