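# Selection procedures run at reduced sizes here; the full study-condition
# checks live in test-acceptance.R.

test_that("promise_cox recovers strong linear signals and validates input", {
  d <- simulate_survival("linear", n = 500, p = 50, q = 5, seed = 31)
  fit <- promise_cox(d, n_boot = 50, seed = 31)
  r <- selection_tpr_fpr(fit$selected, d$true_signals, 50)
  expect_equal(r$tpr, 1)
  expect_lte(r$fpr, 0.1)
  expect_length(fit$scores, 50)
  expect_true(all(fit$scores >= 0 & fit$scores <= 1))
  expect_true(fit$chosen$lambda >= 0.01 && fit$chosen$lambda <= 0.1)

  expect_error(promise_cox(d, ss_threshold = 0.4), "ss_threshold")
  expect_error(promise_cox(d, n_boot = 1), "n_boot")
  expect_error(promise_cox(d, lambda_grid = numeric(0)), "lambda_grid")
})

test_that("promise_cox methods: print, coef, predict, residuals, importance", {
  d <- simulate_survival("linear", n = 300, p = 20, q = 4, seed = 32)
  fit <- promise_cox(d, n_boot = 30, seed = 32)
  expect_output(print(fit), "promise_cox")
  expect_output(summary(fit), "tuning")
  beta <- coef(fit)
  expect_length(beta, 20)
  expect_true(all(beta[setdiff(1:20, fit$selected)] == 0))
  sc <- predict(fit, d$X)
  expect_length(sc, 300)
  expect_gt(concordance_index(sc, d$time, d$status), 0.7)
  res <- residuals(fit)
  expect_length(res, 300)
  expect_lt(abs(sum(res)), 1e-6)  # martingale residuals sum to zero
  expect_equal(feature_importance(fit), fit$scores)
})

test_that("stability selection is monotone in the threshold and deterministic", {
  d <- simulate_survival("linear", n = 300, p = 30, q = 5, seed = 33)
  lo <- promise_cox(d, ss_threshold = 0.6, n_boot = 40, seed = 5)
  hi <- promise_cox(d, ss_threshold = 0.8, n_boot = 40, seed = 5)
  expect_true(all(hi$selected %in% lo$selected))
  expect_identical(lo$scores, hi$scores)
  again <- promise_cox(d, ss_threshold = 0.6, n_boot = 40, seed = 5)
  expect_identical(lo$selected, again$selected)
  expect_identical(lo$scores, again$scores)
})

test_that("a zero-variance feature is never selected", {
  d <- simulate_survival("linear", n = 200, p = 10, q = 3, seed = 34)
  d$X[, 10] <- 1
  fit <- promise_cox(d$X, d$time, d$status, n_boot = 30, seed = 34)
  expect_equal(unname(fit$scores[10]), 0)
})

test_that("elastic-net penalty tunes alpha within its grid", {
  d <- simulate_survival("linear", n = 300, p = 25, q = 5, seed = 35)
  fit <- promise_cox(d, penalty = "elastic_net", n_boot = 25, seed = 35,
                     alpha_grid = c(0.2, 0.5))
  expect_true(fit$chosen$alpha %in% c(0.2, 0.5))
  expect_equal(selection_tpr_fpr(fit$selected, d$true_signals, 25)$tpr, 1)
})

test_that("topk_select tunes k by CV, is deterministic, and validates k_grid", {
  d <- simulate_survival("quadratic", n = 400, p = 30, q = 10, seed = 36)
  fit <- topk_select(d, learner = "xgb_cox", k_grid = c(5, 10, 20),
                     params = list(nrounds = 40), cv_folds = 3, seed = 36)
  expect_true(fit$chosen$k %in% c(5, 10, 20))
  expect_length(fit$selected, fit$chosen$k)
  expect_equal(nrow(fit$cv_trace), 3)
  again <- topk_select(d, learner = "xgb_cox", k_grid = c(5, 10, 20),
                       params = list(nrounds = 40), cv_folds = 3, seed = 36)
  expect_identical(fit$selected, again$selected)
  expect_identical(fit$chosen$k, again$chosen$k)
  expect_error(topk_select(d, k_grid = c(5, 999)), "k_grid")
  expect_output(print(fit), "topk_select")
})

test_that("topk with k = p keeps the whole panel and mean_rank aggregation works", {
  d <- simulate_survival("linear", n = 200, p = 8, q = 3, seed = 37)
  fit <- topk_select(d, learner = "xgb_cox", k_grid = 8,
                     params = list(nrounds = 30), cv_folds = 3, seed = 37)
  expect_identical(fit$selected, 1:8)
  fr <- topk_select(d, learner = "xgb_cox", k_grid = c(2, 4),
                    params = list(nrounds = 30), cv_folds = 3,
                    aggregate = "mean_rank", seed = 37)
  expect_length(fr$selected, fr$chosen$k)
  expect_length(fr$scores, 8)
})

test_that("refit_on_selected restricts the panel and falls back on empty selection", {
  d <- simulate_survival("linear", n = 300, p = 20, q = 5, seed = 38)
  m_all <- refit_on_selected(d, selected = 1:20, method = "penalized_cox",
                             params = list(lambda = 0.05), seed = 2)
  m_direct <- fit_survival_learner(d, method = "penalized_cox",
                                   params = list(lambda = 0.05), seed = 2)
  expect_equal(feature_importance(m_all), feature_importance(m_direct))

  m_true <- refit_on_selected(d, selected = d$true_signals,
                              method = "penalized_cox",
                              params = list(lambda = 0.05), seed = 2)
  heldout <- simulate_survival("linear", n = 300, p = 20, q = 5, seed = 39)
  sc <- predict(m_true, heldout$X[, d$true_signals])
  expect_gt(concordance_index(sc, heldout$time, heldout$status), 0.5)

  expect_warning(m_fb <- refit_on_selected(d, selected = integer(0),
                                           method = "penalized_cox",
                                           params = list(lambda = 0.05)),
                 "empty selection")
  expect_equal(m_fb$p, 20)
})

test_that("refit on true signals beats chance across seeded replicates", {
  wins <- 0
  for (r in 1:10) {
    d <- simulate_survival("linear", n = 400, p = 15, q = 4, seed = 40 + r)
    tr <- 1:320; te <- 321:400
    m <- refit_on_selected(d$X[tr, ], d$time[tr], d$status[tr],
                           selected = d$true_signals,
                           method = "penalized_cox",
                           params = list(lambda = 0.03), seed = r)
    sc <- predict(m, d$X[te, d$true_signals])
    if (concordance_index(sc, d$time[te], d$status[te]) > 0.5) wins <- wins + 1
  }
  expect_equal(wins, 10)
})
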