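test_that("partial likelihood matches hand computation and degenerate cases", {
  # two subjects, both events, distinct times, equal scores: PL = 1/2
  expect_equal(cox_neg_log_pl(c(0, 0), c(1, 2), c(1, 1)), log(2))
  expect_warning(v <- cox_neg_log_pl(c(1, 2), c(1, 2), c(0, 0)), "no events")
  expect_equal(v, 0)
  expect_error(cox_neg_log_pl(numeric(0), numeric(0), numeric(0)), "empty")
  # translation invariance
  toy <- make_toy_surv(n = 25, seed = 2)
  s <- rnorm(25)
  expect_equal(cox_neg_log_pl(s, toy$time, toy$status),
               cox_neg_log_pl(s + 17.3, toy$time, toy$status))
})

test_that("partial likelihood agrees with the survival package, ties included", {
  suppressMessages(library(survival))
  for (seed in 1:5) {
    toy <- make_toy_surv(n = 30, seed = seed)
    s <- survsel:::with_seed(100 + seed, rnorm(30))
    ref <- coxph(Surv(toy$time, toy$status) ~ offset(s), ties = "breslow")
    expect_equal(cox_neg_log_pl(s, toy$time, toy$status), -ref$loglik[1],
                 tolerance = 1e-8)
  }
  # explicit tied event times exercise the Breslow denominator
  tt <- c(1, 1, 2, 2, 3); st <- c(1, 1, 1, 0, 1)
  s <- c(0.5, -0.2, 0.1, 0.9, -1)
  ref <- coxph(Surv(tt, st) ~ offset(s), ties = "breslow")
  expect_equal(cox_neg_log_pl(s, tt, st), -ref$loglik[1], tolerance = 1e-8)
})

test_that("gradient matches hand computation, sums to zero, and is curvature-positive", {
  gh <- cox_grad_hess(c(0, 0), c(1, 2), c(1, 1))
  expect_equal(gh$grad, c(-0.5, 0.5))
  for (seed in 1:10) {
    toy <- make_toy_surv(n = 40, seed = seed)
    s <- survsel:::with_seed(200 + seed, rnorm(40))
    gh <- cox_grad_hess(s, toy$time, toy$status)
    expect_lt(abs(sum(gh$grad)), 1e-10)
    expect_true(all(gh$hess >= 0))
  }
})

test_that("gradient and curvature match central finite differences", {
  max_rel <- 0
  for (seed in 1:50) {
    n <- sample(5:100, 1)
    toy <- make_toy_surv(n = n, seed = 300 + seed)
    s <- rnorm(n)
    gh <- cox_grad_hess(s, toy$time, toy$status)
    eps <- 1e-5
    for (i in sample(n, min(n, 3))) {
      up <- s; up[i] <- up[i] + eps
      dn <- s; dn[i] <- dn[i] - eps
      f_up <- cox_neg_log_pl(up, toy$time, toy$status)
      f_dn <- cox_neg_log_pl(dn, toy$time, toy$status)
      fd_g <- (f_up - f_dn) / (2 * eps)
      rel <- abs(gh$grad[i] - fd_g) / max(1, abs(fd_g))
      max_rel <- max(max_rel, rel)
      # second derivative needs a larger step to avoid cancellation noise
      eps2 <- 1e-3
      up2 <- s; up2[i] <- up2[i] + eps2
      dn2 <- s; dn2[i] <- dn2[i] - eps2
      fd_h <- (cox_neg_log_pl(up2, toy$time, toy$status) -
                 2 * cox_neg_log_pl(s, toy$time, toy$status) +
                 cox_neg_log_pl(dn2, toy$time, toy$status)) / eps2^2
      expect_lt(abs(gh$hess[i] - fd_h), 1e-4 * max(1, abs(fd_h)))
    }
  }
  expect_lt(max_rel, 1e-5)
})

test_that("learner registry validates names and hyperparameters", {
  expect_setequal(intersect(list_learners(),
                            c("penalized_cox", "xgb_cox", "rsf")),
                  c("penalized_cox", "xgb_cox", "rsf"))
  toy <- make_toy_surv(n = 40, p = 4, seed = 4, hazard_beta = c(1, 0, 0, 0))
  expect_error(fit_survival_learner(toy$X, toy$time, toy$status,
                                    method = "nope"), "unknown learner")
  expect_error(fit_survival_learner(toy$X, toy$time, toy$status,
                                    method = "xgb_cox",
                                    params = list(bogus = 1)),
               "unknown hyperparameter")
  xna <- toy$X; xna[1, 1] <- NA
  expect_error(fit_survival_learner(xna, toy$time, toy$status,
                                    method = "penalized_cox"), "missing")
})

test_that("penalized Cox risk scores are the linear predictor and importance |beta|", {
  toy <- make_toy_surv(n = 120, p = 5, seed = 5, hazard_beta = c(2, -1.5, 0, 0, 0))
  m <- fit_survival_learner(toy$X, toy$time, toy$status,
                            method = "penalized_cox",
                            params = list(lambda = 0.02))
  expect_equal(predict(m, toy$X), as.numeric(toy$X %*% m$fit$beta))
  expect_equal(unname(feature_importance(m)), abs(m$fit$beta))
  # shifting every feature by a constant shifts scores uniformly: the
  # concordance is unchanged
  shifted <- predict(m, toy$X + 1)
  expect_equal(concordance_index(shifted, toy$time, toy$status),
               concordance_index(predict(m, toy$X), toy$time, toy$status))
  expect_error(predict(m, toy$X[, 1:3]), "columns")
})

test_that("boosted Cox training loss is nonincreasing and fits are deterministic", {
  toy <- make_toy_surv(n = 200, p = 6, seed = 6,
                       hazard_beta = c(1, 1, 0, 0, 0, 0))
  m <- fit_survival_learner(toy$X, toy$time, toy$status, method = "xgb_cox",
                            params = list(nrounds = 60, eta = 0.05), seed = 11)
  loss <- m$fit$train_loss
  expect_length(loss, 60)
  expect_true(all(diff(loss) <= 1e-8))
  m2 <- fit_survival_learner(toy$X, toy$time, toy$status, method = "xgb_cox",
                             params = list(nrounds = 60, eta = 0.05), seed = 11)
  expect_identical(feature_importance(m), feature_importance(m2))
  expect_identical(predict(m, toy$X), predict(m2, toy$X))
  # a zero-variance feature can never split: importance exactly 0
  xz <- cbind(toy$X, fz = 0)
  mz <- fit_survival_learner(xz, toy$time, toy$status, method = "xgb_cox",
                             params = list(nrounds = 30), seed = 3)
  expect_identical(unname(feature_importance(mz)["fz"]), 0)
  expect_length(feature_importance(mz), 7)
})

test_that("random survival forest fits, predicts reproducibly, ranks signal", {
  toy <- make_toy_surv(n = 150, p = 5, seed = 7, hazard_beta = c(2, 0, 0, 0, 0))
  m <- fit_survival_learner(toy$X, toy$time, toy$status, method = "rsf",
                            params = list(num_trees = 100), seed = 21)
  m2 <- fit_survival_learner(toy$X, toy$time, toy$status, method = "rsf",
                             params = list(num_trees = 100), seed = 21)
  expect_identical(predict(m, toy$X), predict(m2, toy$X))
  imp <- feature_importance(m)
  expect_true(all(imp >= 0))
  expect_identical(names(which.max(imp)), "f1")
})

test_that("predicted survival curves are proper and track the baseline hazard", {
  toy <- make_toy_surv(n = 150, p = 4, seed = 8, hazard_beta = c(1.5, 0, 0, 0))
  m <- fit_survival_learner(toy$X, toy$time, toy$status,
                            method = "penalized_cox",
                            params = list(lambda = 0.02))
  times <- quantile(toy$time, c(0.2, 0.5, 0.8))
  S <- predict_survival(m, toy$X, times)
  expect_true(all(S >= 0 & S <= 1))
  expect_true(all(diff(t(S)) <= 1e-12))  # nonincreasing in time per subject
  # higher risk score => lower survival at a fixed horizon
  sc <- predict(m, toy$X)
  expect_lt(S[which.max(sc), 2], S[which.min(sc), 2])
})

test_that("a plug-in learner can be registered and used", {
  register_learner("dummy_mean",
                   fit = function(x, time, status, params, seed)
                     list(w = rep(1 / ncol(x), ncol(x)), p = ncol(x)),
                   predict = function(object, x) rowMeans(x),
                   importance = function(object) object$w)
  on.exit(rm("dummy_mean", envir = survsel:::.learners))
  toy <- make_toy_surv(n = 40, p = 3, seed = 9)
  m <- fit_survival_learner(toy$X, toy$time, toy$status, method = "dummy_mean")
  expect_equal(predict(m, toy$X), rowMeans(toy$X))
  expect_length(feature_importance(m), 3)
})
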