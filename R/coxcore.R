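#' Negative log Cox partial likelihood
#'
#' Evaluates the negative log partial likelihood of per-sample risk scores
#' under the Cox proportional-hazards model,
#' \code{-sum_{i: d_i = 1} [eta_i - log sum_{k in R(t_i)} exp(eta_k)]},
#' where R(t) is the risk set of subjects with observed time >= t. Tied event
#' times are handled with the Breslow approximation (tied events share one
#' denominator). The value is invariant to adding a constant to all scores.
#'
#' @param scores per-sample risk scores (higher = worse prognosis).
#' @param time observed times.
#' @param status event indicators in \{0, 1\}.
#' @return Nonnegative scalar loss; 0 (with a warning) if no events.
#' @export
cox_neg_log_pl <- function(scores, time, status) {
  n <- length(scores)
  if (n == 0) stopf("empty input")
  if (length(time) != n || length(status) != n) stopf("length mismatch")
  if (any(!is.finite(scores))) stopf("non-finite scores")
  if (!all(status %in% c(0, 1))) stopf("status must be coded 0/1")
  if (sum(status) == 0) {
    warnf("no events: partial likelihood is vacuous, returning 0")
    return(0)
  }
  ord <- order(time)
  st <- time[ord]; d <- status[ord]
  s <- scores[ord] - max(scores)
  e <- exp(s)
  # risk-set denominators: sum of exp(score) over time >= t, shared by ties
  rs <- rev(cumsum(rev(e)))
  denom <- rs[match(st, st)]
  -sum(d * (s - log(denom)))
}

#' Per-sample gradient and curvature of the Cox partial-likelihood loss
#'
#' Analytic first and (diagonal) second derivatives of
#' \code{\link{cox_neg_log_pl}} with respect to the risk scores, in the form
#' used as a custom objective by gradient-boosting learners: the boosting
#' step fits a weak learner to the targets \code{-g/s} with weights \code{s}.
#' Breslow handling of ties matches the loss. The gradient sums to zero
#' (score-translation invariance) and the curvature is nonnegative.
#'
#' @inheritParams cox_neg_log_pl
#' @return List with components \code{grad} and \code{hess}, each length n.
#' @export
cox_grad_hess <- function(scores, time, status) {
  n <- length(scores)
  if (n == 0) stopf("empty input")
  if (length(time) != n || length(status) != n) stopf("length mismatch")
  if (!all(status %in% c(0, 1))) stopf("status must be coded 0/1")
  if (sum(status) == 0) {
    warnf("no events: gradient is identically zero")
    return(list(grad = numeric(n), hess = numeric(n)))
  }
  ord <- order(time)
  st <- time[ord]; d <- status[ord]
  s <- scores[ord] - max(scores)
  e <- exp(s)
  rs <- rev(cumsum(rev(e)))
  denom <- rs[match(st, st)]
  # A_i = sum over event times u <= t_i of d_u / S_u (and B with S_u^2);
  # cumulative sums must include events tied with t_i, so read the cumsum at
  # the last index of each tie group.
  last <- n + 1L - match(st, rev(st))
  A <- cumsum(d / denom)[last]
  B <- cumsum(d / denom^2)[last]
  g <- -d + e * A
  h <- e * A - e^2 * B
  grad <- hess <- numeric(n)
  grad[ord] <- g
  hess[ord] <- pmax(h, 0)
  list(grad = grad, hess = hess)
}

# ---------------------------------------------------------------------------
# Learner registry: a plug-in contract mapping a method name to fit /
# predict / importance functions, so additional survival learners can be
# attached without touching the selection code.

.learners <- new.env(parent = emptyenv())

#' Register a survival learner
#'
#' @param name method name.
#' @param fit function(x, time, status, params, seed) returning a fitted
#'   backend object (a list; must contain what predict/importance need).
#' @param predict function(object, x) returning risk scores (higher = worse).
#' @param importance function(object) returning a nonnegative vector, length p.
#' @export
register_learner <- function(name, fit, predict, importance) {
  assign(name, list(fit = fit, predict = predict, importance = importance),
         envir = .learners)
  invisible(name)
}

#' List registered survival learners
#' @return Character vector of method names.
#' @export
list_learners <- function() sort(ls(.learners))

learner_entry <- function(name) {
  if (!exists(name, envir = .learners))
    stopf("unknown learner '%s' (registered: %s)", name,
          paste(list_learners(), collapse = ", "))
  get(name, envir = .learners)
}

validate_params <- function(params, schema, method) {
  bad <- setdiff(names(params), names(schema))
  if (length(bad))
    stopf("unknown hyperparameter(s) for %s: %s", method,
          paste(bad, collapse = ", "))
  utils::modifyList(schema, params)
}

#' Fit a survival learner
#'
#' Uniform interface over the registered survival learners:
#' \describe{
#'   \item{penalized_cox}{L1/elastic-net Cox regression (glmnet) at a fixed
#'     penalty \code{lambda} and mixing \code{alpha}; importance is
#'     \code{|beta|}.}
#'   \item{xgb_cox}{gradient-boosted trees (xgboost) trained with
#'     \code{\link{cox_grad_hess}} as the custom objective on the negative
#'     partial likelihood; importance is total split gain per feature.}
#'   \item{rsf}{random survival forest (ranger) with log-rank splitting;
#'     importance is permutation importance with negative values clipped to
#'     zero; the risk score is the ensemble cumulative hazard summed over the
#'     event-time grid.}
#' }
#'
#' @param x numeric feature matrix (n x p) or a \code{survdata} object.
#' @param time,status outcome vectors (ignored when \code{x} is
#'   \code{survdata}).
#' @param method one of \code{list_learners()}.
#' @param params named list of hyperparameters (validated per method).
#' @param seed integer seed; fits are reproducible given (method, params,
#'   seed).
#' @return Object of class \code{"surv_learner"}.
#' @export
fit_survival_learner <- function(x, time = NULL, status = NULL,
                                 method = c("penalized_cox", "xgb_cox", "rsf"),
                                 params = list(), seed = 1L) {
  if (inherits(x, "survdata")) {
    time <- x$time; status <- x$status; x <- x$X
  }
  method <- if (length(method) > 1) match.arg(method) else method
  x <- as.matrix(x)
  if (ncol(x) == 0) stopf("no features to fit")
  if (nrow(x) < 2 || sum(status) < 1) stopf("need >= 2 samples and >= 1 event")
  entry <- learner_entry(method)
  if (method == "penalized_cox" && anyNA(x))
    stopf("penalized_cox does not allow missing feature values")
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  fit <- entry$fit(x, time, status, params, seed)
  structure(list(method = method, fit = fit, p = ncol(x),
                 feature_names = colnames(x), seed = seed,
                 train_time = time, train_status = status),
            class = "surv_learner")
}

#' Predict risk scores
#'
#' Higher score = higher hazard (worse prognosis) for every learner.
#' @param object a \code{surv_learner}.
#' @param newdata feature matrix with the training columns.
#' @param ... unused.
#' @return Numeric risk-score vector.
#' @export
predict.surv_learner <- function(object, newdata, ...) {
  if (inherits(newdata, "survdata")) newdata <- newdata$X
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$p)
    stopf("newdata has %d columns; model was fit on %d", ncol(newdata), object$p)
  colnames(newdata) <- object$feature_names
  scores <- learner_entry(object$method)$predict(object$fit, newdata)
  if (any(!is.finite(scores))) stopf("non-finite risk scores produced")
  as.numeric(scores)
}

#' Per-feature importance of a fitted learner
#'
#' \code{|beta|} for the penalized Cox model, total split gain for boosted
#' trees, clipped permutation importance for the survival forest. Features
#' never used by the model get importance 0.
#'
#' @param object a fitted model (\code{surv_learner}, \code{promise_cox} or
#'   \code{topk_select}).
#' @param ... unused.
#' @return Nonnegative numeric vector of length p, named by feature.
#' @export
feature_importance <- function(object, ...) UseMethod("feature_importance")

#' @rdname feature_importance
#' @export
feature_importance.surv_learner <- function(object, ...) {
  imp <- learner_entry(object$method)$importance(object$fit)
  imp <- pmax(as.numeric(imp), 0)
  names(imp) <- object$feature_names
  imp
}

#' @export
print.surv_learner <- function(x, ...) {
  cat(sprintf("<surv_learner> method = %s, p = %d, n = %d (%d events)\n",
              x$method, x$p, length(x$train_time), sum(x$train_status)))
  invisible(x)
}

# --- penalized Cox (glmnet) -------------------------------------------------

penalized_cox_schema <- list(lambda = 0.05, alpha = 1)

fit_penalized_cox <- function(x, time, status, params, seed) {
  pp <- validate_params(params, penalized_cox_schema, "penalized_cox")
  y <- survival::Surv(time, status)
  # glmnet requires >= 2 columns; pad single-feature panels with a zero dummy
  pad <- ncol(x) == 1
  xf <- if (pad) cbind(x, 0) else x
  # fit along a short descending path ending at the requested lambda; warm
  # starts make the solution at the target penalty stable
  path <- sort(unique(c(pp$lambda * c(20, 10, 5, 2, 1), pp$lambda)),
               decreasing = TRUE)
  fit <- glmnet::glmnet(xf, y, family = "cox", alpha = pp$alpha,
                        lambda = path, standardize = TRUE)
  beta <- as.numeric(stats::coef(fit, s = pp$lambda))
  if (pad) beta <- beta[1]
  lp <- as.numeric(x %*% beta)
  list(glmnet = fit, lambda = pp$lambda, alpha = pp$alpha, beta = beta,
       lp = lp, breslow = breslow_baseline(lp, time, status))
}

register_learner(
  "penalized_cox",
  fit = fit_penalized_cox,
  predict = function(object, x) as.numeric(x %*% object$beta),
  importance = function(object) abs(object$beta)
)

# --- boosted Cox (xgboost with the package's custom objective) --------------

xgb_cox_schema <- list(eta = 0.05, nrounds = 100, max_depth = 3,
                       subsample = 0.5, reg_lambda = 0.05, reg_alpha = 0.05,
                       colsample_bytree = 1)

fit_xgb_cox <- function(x, time, status, params, seed) {
  pp <- validate_params(params, xgb_cox_schema, "xgb_cox")
  dtrain <- xgboost::xgb.DMatrix(x, label = time, nthread = 1)
  objective <- function(preds, dtrain) {
    gh <- cox_grad_hess(preds, time, status)
    list(grad = gh$grad, hess = pmax(gh$hess, 1e-12))
  }
  eval_pl <- function(preds, dtrain) {
    list(metric = "cox_nloglik",
         value = cox_neg_log_pl(preds, time, status) / length(preds))
  }
  bst <- xgboost::xgb.train(
    params = list(eta = pp$eta, max_depth = pp$max_depth,
                  subsample = pp$subsample, lambda = pp$reg_lambda,
                  alpha = pp$reg_alpha, colsample_bytree = pp$colsample_bytree,
                  base_score = 0, nthread = 1, seed = seed,
                  disable_default_eval_metric = TRUE),
    data = dtrain, nrounds = pp$nrounds,
    evals = list(train = dtrain), objective = objective,
    custom_metric = eval_pl, verbose = 0)
  lp <- stats::predict(bst, dtrain)
  list(booster = bst, train_loss = attributes(bst)$evaluation_log$train_cox_nloglik,
       p = ncol(x), feature_names = colnames(x),
       breslow = breslow_baseline(lp, time, status))
}

register_learner(
  "xgb_cox",
  fit = fit_xgb_cox,
  predict = function(object, x) {
    as.numeric(stats::predict(object$booster,
                              xgboost::xgb.DMatrix(x, nthread = 1)))
  },
  importance = function(object) {
    imp <- numeric(object$p)
    names(imp) <- object$feature_names
    tab <- xgboost::xgb.importance(model = object$booster)
    if (nrow(tab)) imp[tab$Feature] <- tab$Gain
    imp
  }
)

# --- random survival forest (ranger, log-rank splitting) --------------------

# min_node_frac: minimum leaf size as a fraction of n (0.25 keeps trees
# shallow, which both regularizes and keeps survival-forest fits cheap);
# an explicit min_node_size overrides it.
rsf_schema <- list(num_trees = 100, mtry = NULL, min_node_size = NULL,
                   min_node_frac = 0.25, importance = "permutation")

fit_rsf <- function(x, time, status, params, seed) {
  pp <- validate_params(params, rsf_schema, "rsf")
  df <- data.frame(x, check.names = FALSE)
  args <- list(x = df, y = survival::Surv(time, status),
               num.trees = pp$num_trees, splitrule = "logrank",
               importance = pp$importance, seed = seed, num.threads = 1,
               verbose = FALSE,
               min.node.size = ceiling(pp$min_node_frac * nrow(x)))
  if (!is.null(pp$mtry)) args$mtry <- pp$mtry
  if (!is.null(pp$min_node_size)) args$min.node.size <- pp$min_node_size
  fit <- do.call(ranger::ranger, args)
  list(ranger = fit, feature_names = colnames(x))
}

register_learner(
  "rsf",
  fit = fit_rsf,
  predict = function(object, x) {
    pr <- stats::predict(object$ranger, data.frame(x, check.names = FALSE),
                         num.threads = 1)
    # ensemble mortality: cumulative hazard summed over the event-time grid
    rowSums(pr$chf)
  },
  importance = function(object) {
    pmax(ranger::importance(object$ranger), 0)[object$feature_names]
  }
)

# ---------------------------------------------------------------------------

# Breslow baseline cumulative hazard from training scores: H0(t) =
# sum_{event times t_i <= t} d_i / sum_{k in R(t_i)} exp(eta_k). Scores are
# centered for numerical stability; the centering constant is kept so that
# absolute survival predictions are consistent.
breslow_baseline <- function(scores, time, status) {
  center <- mean(scores)
  s <- scores - center
  ord <- order(time)
  st <- time[ord]; d <- status[ord]; e <- exp(s[ord])
  rs <- rev(cumsum(rev(e)))
  denom <- rs[match(st, st)]
  ut <- unique(st[d == 1])
  dH <- vapply(ut, function(u) sum(d[st == u]) / denom[match(u, st)], 0)
  list(times = ut, H0 = cumsum(dH), center = center)
}

#' Predicted survival probabilities
#'
#' Survival curves on a time grid. Cox-type learners (penalized or boosted)
#' use the Breslow baseline cumulative hazard estimated on their training
#' data: \code{S(t|x) = exp(-H0(t) exp(eta(x) - center))}. The survival
#' forest uses its own ensemble survival estimate, interpolated as a
#' right-continuous step function.
#'
#' @param object a fitted \code{surv_learner}.
#' @param newdata feature matrix.
#' @param times increasing evaluation times.
#' @return Matrix, rows = samples, columns = \code{times}.
#' @export
predict_survival <- function(object, newdata, times) {
  stopifnot(inherits(object, "surv_learner"))
  if (inherits(newdata, "survdata")) newdata <- newdata$X
  newdata <- as.matrix(newdata)
  if (object$method == "rsf") {
    pr <- stats::predict(object$fit$ranger,
                         data.frame(newdata, check.names = FALSE),
                         num.threads = 1)
    grid <- pr$unique.death.times
    idx <- findInterval(times, grid)
    out <- vapply(seq_along(times), function(j) {
      if (idx[j] == 0) rep(1, nrow(newdata)) else pr$survival[, idx[j]]
    }, numeric(nrow(newdata)))
    return(matrix(out, nrow = nrow(newdata)))
  }
  bl <- object$fit$breslow
  eta <- predict(object, newdata) - bl$center
  H0 <- c(0, bl$H0)[findInterval(times, bl$times) + 1L]
  outer(exp(eta), H0, function(r, h) exp(-h * r))
}
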