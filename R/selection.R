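# Prediction-oriented feature selection: PROMISE-Cox (CV-tuned penalized Cox
# followed by bootstrap stability selection) and CV + top-k importance
# selection for nonlinear survival learners.

# Event-stratified fold assignment: events and censored subjects are spread
# evenly so every training/validation portion keeps a usable event rate.
stratified_folds <- function(status, k, seed) {
  with_seed(seed, {
    fold <- integer(length(status))
    for (g in unique(status)) {
      idx <- which(status == g)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    fold
  })
}

# Event-stratified resample for stability selection. "subsample" draws
# floor(n/2) samples without replacement (the classic stability-selection
# construction, whose disagreement across resamples is what controls false
# positives); "bootstrap" draws n with replacement. Events and censored
# subjects are drawn separately so the event rate is preserved.
stratified_resample <- function(status, type) {
  ev <- which(status == 1); ce <- which(status == 0)
  if (type == "bootstrap") {
    c(sample(ev, length(ev), replace = TRUE),
      sample(ce, length(ce), replace = TRUE))
  } else {
    c(sample(ev, max(1L, floor(length(ev) / 2))),
      sample(ce, floor(length(ce) / 2)))
  }
}

fit_glmnet_path <- function(x, time, status, alpha, lambda_path) {
  glmnet::glmnet(x, survival::Surv(time, status), family = "cox",
                 alpha = alpha, lambda = lambda_path, standardize = TRUE)
}

#' PROMISE-Cox: stability selection over cross-validated penalized Cox
#'
#' Prediction-oriented marker selection for right-censored outcomes. The
#' penalty strength lambda (and, for the elastic net, the mixing weight
#' alpha) is first tuned by event-stratified k-fold cross-validation,
#' maximizing validation concordance (or minimizing validation partial
#' likelihood). The penalized Cox model is then refit on \code{n_boot}
#' event-stratified bootstrap resamples at the tuned penalty; a feature's
#' selection frequency is the fraction of resamples in which its coefficient
#' is nonzero, and features at or above \code{ss_threshold} are selected.
#'
#' @param x feature matrix (n x p) or a \code{survdata} object.
#' @param time,status outcome vectors (ignored when \code{x} is
#'   \code{survdata}).
#' @param penalty \code{"lasso"} or \code{"elastic_net"}.
#' @param lambda_grid candidate penalty strengths (default: 8 log-spaced
#'   values in [0.01, 0.1]).
#' @param alpha_grid candidate elastic-net mixing weights in [0.05, 0.5]
#'   (elastic net only; lasso fixes alpha = 1).
#' @param ss_threshold stability-selection frequency threshold in (0.5, 1].
#' @param n_boot number of resamples (default 100).
#' @param resample \code{"subsample"} (default; floor(n/2) without
#'   replacement, the classic stability-selection scheme) or
#'   \code{"bootstrap"} (size n with replacement).
#' @param cv_folds cross-validation folds (default 5).
#' @param tune tuning criterion: validation \code{"partial_likelihood"}
#'   (default; a proper scoring rule that penalizes overfit dense models
#'   even when discrimination is flat) or validation \code{"cindex"}.
#' @param tune_rule \code{"1se"} (default) picks the sparsest grid point
#'   whose mean CV score is within one standard error of the best;
#'   \code{"min"} picks the best mean score outright.
#' @param seed integer seed; the whole procedure is deterministic given it.
#' @param refit refit a final penalized Cox model on the selected panel
#'   (enables \code{predict}/\code{coef}).
#' @return Object of class \code{"promise_cox"} with elements
#'   \code{selected} (indices), \code{scores} (selection frequencies),
#'   \code{chosen} (tuned lambda/alpha), \code{cv_trace} and the final fit.
#' @examples
#' d <- simulate_survival("linear", n = 300, p = 30, q = 5, seed = 7)
#' fit <- promise_cox(d, n_boot = 25, seed = 7)
#' print(fit)
#' @export
promise_cox <- function(x, time = NULL, status = NULL,
                        penalty = c("lasso", "elastic_net"),
                        lambda_grid = exp(seq(log(0.01), log(0.1),
                                              length.out = 8)),
                        alpha_grid = c(0.05, 0.2, 0.35, 0.5),
                        ss_threshold = 0.6, n_boot = 100L, cv_folds = 5L,
                        tune = c("partial_likelihood", "cindex"),
                        tune_rule = c("1se", "min"),
                        resample = c("subsample", "bootstrap"),
                        seed = 1L, refit = TRUE) {
  cl <- match.call()
  if (inherits(x, "survdata")) {
    time <- x$time; status <- x$status; x <- x$X
  }
  penalty <- match.arg(penalty)
  tune <- match.arg(tune)
  tune_rule <- match.arg(tune_rule)
  resample <- match.arg(resample)
  x <- as.matrix(x)
  if (anyNA(x)) stopf("promise_cox does not allow missing feature values")
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  n <- nrow(x); p <- ncol(x)
  if (ss_threshold <= 0.5 || ss_threshold > 1)
    stopf("ss_threshold must lie in (0.5, 1]")
  if (n_boot < 2) stopf("n_boot must be >= 2")
  if (length(lambda_grid) == 0) stopf("lambda_grid must be nonempty")
  if (sum(status) < cv_folds)
    stopf("need at least cv_folds = %d events", cv_folds)
  alphas <- if (penalty == "lasso") 1 else alpha_grid
  lambda_path <- sort(unique(lambda_grid), decreasing = TRUE)

  # 1) tune (lambda, alpha) by cross-validated predictive performance
  fold <- stratified_folds(status, cv_folds, derive_seed(seed, 1L))
  trace <- expand.grid(alpha = alphas, lambda = lambda_path,
                       KEEP.OUT.ATTRS = FALSE)
  trace$score <- trace$se <- 0
  for (a in alphas) {
    acc <- matrix(0, cv_folds, length(lambda_path))
    for (f in seq_len(cv_folds)) {
      tr <- fold != f
      fit <- fit_glmnet_path(x[tr, , drop = FALSE], time[tr], status[tr],
                             a, lambda_path)
      lp <- stats::predict(fit, newx = x[!tr, , drop = FALSE],
                           s = lambda_path)
      for (j in seq_along(lambda_path)) {
        acc[f, j] <- if (tune == "cindex") {
          concordance_index(lp[, j], time[!tr], status[!tr])
        } else {
          -cox_neg_log_pl(lp[, j], time[!tr], status[!tr]) / sum(!tr)
        }
      }
    }
    sel <- match(trace$lambda, lambda_path)[trace$alpha == a]
    trace$score[trace$alpha == a] <- colMeans(acc)[sel]
    trace$se[trace$alpha == a] <-
      (apply(acc, 2, stats::sd) / sqrt(cv_folds))[sel]
  }
  # one-standard-error rule: among grid points within one SE of the best CV
  # score, prefer the sparsest (largest lambda, then smallest alpha). On
  # signal-free data the CV surface is flat noise; without this rule the
  # argmax drifts to the smallest penalty, where dense fits defeat the
  # stability threshold.
  best_i <- order(-trace$score, -trace$lambda, trace$alpha)[1]
  if (tune_rule == "1se") {
    ok <- trace$score >= trace$score[best_i] - trace$se[best_i]
    cand <- trace[ok, ]
    pick <- cand[order(-cand$lambda, cand$alpha)[1], ]
  } else {
    pick <- trace[best_i, ]
  }
  lambda_star <- pick$lambda; alpha_star <- pick$alpha

  # 2) bootstrap stability selection at the tuned penalty
  freq <- numeric(p)
  with_seed(derive_seed(seed, 2L), {
    for (b in seq_len(n_boot)) {
      idx <- NULL
      for (try in 1:10) {
        cand <- stratified_resample(status, resample)
        if (sum(status[cand]) >= 2 &&
            length(unique(time[cand][status[cand] == 1])) >= 1) {
          idx <- cand; break
        }
      }
      if (is.null(idx)) stopf("could not draw a fittable bootstrap resample")
      # the penalty that achieves a given selection stringency scales like
      # 1/sqrt(sample size); refitting a subsample at the full-data lambda
      # would systematically over-select, so rescale to the resample size
      lambda_ss <- lambda_star * sqrt(n / length(idx))
      fit <- fit_glmnet_path(x[idx, , drop = FALSE], time[idx], status[idx],
                             alpha_star, sort(unique(lambda_ss * c(20, 10, 5, 2, 1)),
                                              decreasing = TRUE))
      beta <- as.numeric(stats::coef(fit, s = lambda_ss))
      freq <- freq + (beta != 0)
    }
  })
  freq <- freq / n_boot
  names(freq) <- colnames(x)
  selected <- which(freq >= ss_threshold)

  final <- NULL
  if (refit && length(selected)) {
    final <- fit_survival_learner(x[, selected, drop = FALSE], time, status,
                                  method = "penalized_cox",
                                  params = list(lambda = lambda_star,
                                                alpha = alpha_star),
                                  seed = derive_seed(seed, 3L))
  }
  structure(list(selected = selected, scores = freq,
                 chosen = list(lambda = lambda_star, alpha = alpha_star),
                 cv_trace = trace, penalty = penalty,
                 ss_threshold = ss_threshold, n_boot = n_boot,
                 cv_folds = cv_folds, tune = tune, tune_rule = tune_rule,
                 resample = resample, seed = seed,
                 fit = final, p = p, feature_names = colnames(x),
                 train_time = time, train_status = status, call = cl),
            class = "promise_cox")
}

#' @export
print.promise_cox <- function(x, ...) {
  cat(sprintf("<promise_cox> %s penalty, lambda* = %.4g%s, threshold = %.2f\n",
              x$penalty, x$chosen$lambda,
              if (x$penalty == "elastic_net")
                sprintf(", alpha* = %.2f", x$chosen$alpha) else "",
              x$ss_threshold))
  cat(sprintf("  selected %d of %d features", length(x$selected), x$p))
  if (length(x$selected))
    cat(":", paste(utils::head(x$feature_names[x$selected], 10),
                   collapse = ", "),
        if (length(x$selected) > 10) "..." else "")
  cat("\n")
  invisible(x)
}

#' @export
summary.promise_cox <- function(object, ...) {
  print(object)
  cat(sprintf("  tuning: %d-fold CV on %s over %d grid points; %d bootstrap resamples\n",
              object$cv_folds, object$tune, nrow(object$cv_trace),
              object$n_boot))
  sel <- order(-object$scores)[seq_len(min(10, object$p))]
  tab <- data.frame(feature = object$feature_names[sel],
                    frequency = object$scores[sel],
                    selected = sel %in% object$selected, row.names = NULL)
  print(tab)
  invisible(object)
}

#' @export
coef.promise_cox <- function(object, ...) {
  beta <- numeric(object$p)
  names(beta) <- object$feature_names
  if (!is.null(object$fit))
    beta[object$selected] <- object$fit$fit$beta
  beta
}

#' @export
predict.promise_cox <- function(object, newdata, ...) {
  if (is.null(object$fit))
    stopf("no final model (empty selection or refit = FALSE)")
  if (inherits(newdata, "survdata")) newdata <- newdata$X
  newdata <- as.matrix(newdata)
  if (ncol(newdata) == object$p)
    newdata <- newdata[, object$selected, drop = FALSE]
  predict(object$fit, newdata)
}

#' @export
plot.promise_cox <- function(x, ...) {
  ord <- order(-x$scores)
  graphics::barplot(x$scores[ord], names.arg = x$feature_names[ord],
                    las = 2, cex.names = 0.6, ylim = c(0, 1),
                    ylab = "selection frequency", ...)
  graphics::abline(h = x$ss_threshold, lty = 2, col = 2)
  invisible(x)
}

#' Martingale residuals of the final PROMISE-Cox model
#'
#' \code{status_i - H0(t_i) exp(eta_i)} on the training data, with the
#' Breslow baseline cumulative hazard of the refit model.
#' @param object a \code{promise_cox} fit with a final model.
#' @param ... unused.
#' @export
residuals.promise_cox <- function(object, ...) {
  if (is.null(object$fit)) stopf("no final model to compute residuals from")
  bl <- object$fit$fit$breslow
  eta <- object$fit$fit$lp - bl$center
  H0 <- c(0, bl$H0)[findInterval(object$train_time, bl$times) + 1L]
  object$train_status - H0 * exp(eta)
}

#' @export
feature_importance.promise_cox <- function(object, ...) object$scores

#' CV + top-k importance selection for survival learners
#'
#' Prediction-oriented selection for nonlinear learners whose coefficients
#' are not directly interpretable. For each candidate panel size k, each
#' cross-validation fold fits the learner on the training portion, ranks
#' features by importance, refits on the top k, and scores validation
#' concordance; k* maximizes the mean validation concordance (ties go to the
#' smallest k). The final ranking aggregates importance (full-data fit by
#' default, or mean rank across folds) and the top k* features are returned,
#' along with a final model refit on that panel.
#'
#' @inheritParams promise_cox
#' @param learner registered learner name (\code{"xgb_cox"}, \code{"rsf"},
#'   ...).
#' @param k_grid increasing candidate panel sizes; default
#'   \{5, 10, 20, 40, ...\} capped at \code{min(p, n/5)}.
#' @param params learner hyperparameters (see
#'   \code{\link{fit_survival_learner}}).
#' @param aggregate \code{"mean_importance"} (importance of the full-data
#'   fit) or \code{"mean_rank"} (average importance rank across folds).
#' @return Object of class \code{"topk_select"} with \code{selected},
#'   \code{scores} (aggregated importance), \code{chosen$k} and
#'   \code{cv_trace}.
#' @export
topk_select <- function(x, time = NULL, status = NULL, learner = "xgb_cox",
                        k_grid = NULL, params = list(), cv_folds = 5L,
                        aggregate = c("mean_importance", "mean_rank"),
                        seed = 1L, refit = TRUE) {
  cl <- match.call()
  if (inherits(x, "survdata")) {
    time <- x$time; status <- x$status; x <- x$X
  }
  aggregate <- match.arg(aggregate)
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  n <- nrow(x); p <- ncol(x)
  if (is.null(k_grid)) {
    cap <- max(1, min(p, floor(n / 5)))
    k_grid <- unique(pmin(c(5, 10, 20, 40, 80, 160), cap))
  }
  k_grid <- sort(unique(as.integer(k_grid)))
  if (length(k_grid) == 0) stopf("k_grid must be nonempty")
  if (max(k_grid) > p) stopf("k_grid contains k = %d > p = %d", max(k_grid), p)
  learner_entry(learner)  # validate name early

  fold <- stratified_folds(status, cv_folds, derive_seed(seed, 1L))
  rank_by_fold <- matrix(NA_real_, cv_folds, p)
  cv_ci <- matrix(NA_real_, cv_folds, length(k_grid))
  for (f in seq_len(cv_folds)) {
    tr <- fold != f
    full <- fit_survival_learner(x[tr, , drop = FALSE], time[tr], status[tr],
                                 method = learner, params = params,
                                 seed = derive_seed(seed, 10L, f))
    imp <- feature_importance(full)
    # importance ranking; ties broken by feature index for determinism
    rk <- order(-imp, seq_len(p))
    rank_by_fold[f, ] <- match(seq_len(p), rk)
    for (j in seq_along(k_grid)) {
      top <- rk[seq_len(k_grid[j])]
      sub <- fit_survival_learner(x[tr, top, drop = FALSE], time[tr],
                                  status[tr], method = learner,
                                  params = params,
                                  seed = derive_seed(seed, 20L, f, j))
      sc <- predict(sub, x[!tr, top, drop = FALSE])
      cv_ci[f, j] <- concordance_index(sc, time[!tr], status[!tr])
    }
  }
  mean_ci <- colMeans(cv_ci)
  k_star <- k_grid[which.max(mean_ci)]  # which.max takes the smallest on ties

  final_full <- fit_survival_learner(x, time, status, method = learner,
                                     params = params,
                                     seed = derive_seed(seed, 30L))
  scores <- if (aggregate == "mean_importance") {
    feature_importance(final_full)
  } else {
    s <- p + 1 - colMeans(rank_by_fold)  # higher = better average rank
    names(s) <- colnames(x)
    s
  }
  selected <- order(-scores, seq_len(p))[seq_len(k_star)]
  selected <- sort(selected)

  final <- NULL
  if (refit)
    final <- refit_on_selected(x, time, status, selected, method = learner,
                               params = params, seed = derive_seed(seed, 40L))
  structure(list(selected = selected, scores = scores,
                 chosen = list(k = k_star),
                 cv_trace = data.frame(k = k_grid, cindex = mean_ci),
                 learner = learner, params = params, cv_folds = cv_folds,
                 aggregate = aggregate, seed = seed, fit = final, p = p,
                 feature_names = colnames(x), call = cl),
            class = "topk_select")
}

#' @export
print.topk_select <- function(x, ...) {
  cat(sprintf("<topk_select> learner = %s, k* = %d (CV C-index %.4f)\n",
              x$learner, x$chosen$k,
              max(x$cv_trace$cindex)))
  cat(sprintf("  selected %d of %d features: %s%s\n", length(x$selected), x$p,
              paste(utils::head(x$feature_names[x$selected], 10),
                    collapse = ", "),
              if (length(x$selected) > 10) ", ..." else ""))
  invisible(x)
}

#' @export
summary.topk_select <- function(object, ...) {
  print(object)
  cat("  CV trace:\n")
  print(object$cv_trace, row.names = FALSE)
  invisible(object)
}

#' @export
predict.topk_select <- function(object, newdata, ...) {
  if (is.null(object$fit)) stopf("no final model (refit = FALSE)")
  if (inherits(newdata, "survdata")) newdata <- newdata$X
  newdata <- as.matrix(newdata)
  if (ncol(newdata) == object$p)
    newdata <- newdata[, object$selected, drop = FALSE]
  predict(object$fit, newdata)
}

#' @export
plot.topk_select <- function(x, ...) {
  plot(x$cv_trace$k, x$cv_trace$cindex, type = "b", log = "x",
       xlab = "panel size k", ylab = "CV C-index", ...)
  graphics::abline(v = x$chosen$k, lty = 2, col = 2)
  invisible(x)
}

#' @export
feature_importance.topk_select <- function(object, ...) object$scores

#' Refit a learner on a selected feature panel
#'
#' Trains the learner on the restricted feature matrix; this is the
#' prediction model evaluated on held-out data by the benchmark. An empty
#' selection falls back to the full feature matrix with a warning.
#'
#' @inheritParams fit_survival_learner
#' @param selected integer indices of the selected features.
#' @return A \code{surv_learner} fitted on \code{x[, selected]}.
#' @export
refit_on_selected <- function(x, time = NULL, status = NULL, selected,
                              method = "penalized_cox", params = list(),
                              seed = 1L) {
  if (inherits(x, "survdata")) {
    time <- x$time; status <- x$status; x <- x$X
  }
  x <- as.matrix(x)
  if (length(selected) == 0) {
    warnf("empty selection: refitting on all %d features", ncol(x))
    selected <- seq_len(ncol(x))
  }
  fit_survival_learner(x[, selected, drop = FALSE], time, status,
                       method = method, params = params, seed = seed)
}
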