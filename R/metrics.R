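#' Harrell's concordance index
#'
#' Fraction of orderable pairs whose predicted risk ordering matches the
#' observed event-time ordering. Orderable pairs are \code{(i, j)} with
#' \code{t_i < t_j} and subject i experiencing the event; a pair is
#' concordant when the earlier-failing subject has the higher risk score.
#' Score ties count 1/2 under \code{tie_policy = "half"} (default) and 0
#' under \code{"strict"}.
#'
#' @param scores risk scores (higher = worse prognosis).
#' @param time observed times.
#' @param status event indicators in \{0, 1\}.
#' @param tie_policy \code{"half"} or \code{"strict"}.
#' @return Concordance in [0, 1].
#' @export
concordance_index <- function(scores, time, status,
                              tie_policy = c("half", "strict")) {
  tie_policy <- match.arg(tie_policy)
  n <- length(scores)
  if (length(time) != n || length(status) != n) stopf("length mismatch")
  orderable <- outer(time, time, "<") & (status == 1)
  n_pairs <- sum(orderable)
  if (n_pairs == 0)
    stopf("no orderable pairs: need at least one event preceding another observed time")
  conc <- sum(orderable & outer(scores, scores, ">"))
  ties <- sum(orderable & outer(scores, scores, "=="))
  credit <- if (tie_policy == "half") 0.5 else 0
  (conc + credit * ties) / n_pairs
}

#' Kaplan-Meier product-limit estimator
#'
#' Nonparametric survival-function estimate. For the censoring distribution
#' G(t) = P(C > t) used in Brier scoring, pass the flipped indicator
#' \code{1 - status}.
#'
#' @param time observed times.
#' @param indicator indicators in \{0, 1\} for the event whose survival
#'   function is estimated.
#' @return Object of class \code{"surv_curve"}: strictly increasing
#'   \code{times}, nonincreasing right-continuous step \code{surv} starting
#'   from S(0) = 1, plus \code{n_risk}/\code{n_event} tables.
#' @export
km_estimator <- function(time, indicator) {
  n <- length(time)
  if (n == 0) stopf("empty input")
  if (length(indicator) != n) stopf("length mismatch")
  if (!all(indicator %in% c(0, 1))) stopf("indicator must be coded 0/1")
  ut <- sort(unique(time))
  n_risk <- vapply(ut, function(u) sum(time >= u), 0)
  n_event <- vapply(ut, function(u) sum(time == u & indicator == 1), 0)
  surv <- cumprod(1 - n_event / n_risk)
  structure(list(times = ut, surv = surv, n_risk = n_risk, n_event = n_event),
            class = "surv_curve")
}

#' Evaluate a survival step function
#'
#' @param curve a \code{surv_curve}.
#' @param t evaluation times.
#' @param left if \code{TRUE}, return the left limit S(t-) instead of the
#'   right-continuous value S(t).
#' @return Survival probabilities at \code{t}.
#' @export
surv_prob <- function(curve, t, left = FALSE) {
  stopifnot(inherits(curve, "surv_curve"))
  idx <- if (left) findInterval(t, curve$times, left.open = TRUE)
         else findInterval(t, curve$times)
  c(1, curve$surv)[idx + 1L]
}

#' @export
print.surv_curve <- function(x, ...) {
  cat(sprintf("<surv_curve> %d time points, S(max) = %.4f\n",
              length(x$times), x$surv[length(x$surv)]))
  invisible(x)
}

#' @export
plot.surv_curve <- function(x, add = FALSE, ...) {
  tt <- c(0, rep(x$times, each = 2))
  ss <- c(1, 1, rep(x$surv, each = 2)[-(2 * length(x$surv))])
  if (add) graphics::lines(tt, ss, ...)
  else plot(tt, ss, type = "l", xlab = "time", ylab = "survival",
            ylim = c(0, 1), ...)
  invisible(x)
}

#' Inverse-probability-of-censoring-weighted Brier score
#'
#' Time-dependent squared error of predicted survival probabilities at a
#' fixed horizon t, reweighted for censoring:
#' \deqn{BS(t) = (1/N) \sum_i [ 1\{t_i < t, d_i = 1\} S(t, x_i)^2 / G(t_i-)
#'   + 1\{t_i > t\} (1 - S(t, x_i))^2 / G(t) ].}
#' Subjects censored before t contribute nothing; subjects with \code{t_i}
#' exactly equal to t fall in neither branch (strict inequalities as
#' defined). The censoring-survival G is evaluated left-continuously at event
#' times and right-continuously at the horizon.
#'
#' @param t evaluation horizon.
#' @param pred predicted survival probabilities S(t, x_i) at the horizon,
#'   length n (a scalar is recycled).
#' @param time,status outcome vectors.
#' @param Ghat censoring-survival \code{surv_curve} (typically
#'   \code{km_estimator(time, 1 - status)}).
#' @return Nonnegative Brier score.
#' @export
brier_score <- function(t, pred, time, status, Ghat) {
  n <- length(time)
  pred <- rep_len(pred, n)
  if (any(pred < 0 | pred > 1)) stopf("predicted survival must lie in [0, 1]")
  died <- time < t & status == 1
  alive <- time > t
  out <- numeric(n)
  if (any(died)) {
    g <- surv_prob(Ghat, time[died], left = TRUE)
    if (any(g <= 0))
      stopf("censoring survival is 0 at time %g; Brier weight undefined",
            min(time[died][g <= 0]))
    out[died] <- pred[died]^2 / g
  }
  if (any(alive)) {
    gt <- surv_prob(Ghat, t)
    if (gt <= 0)
      stopf("censoring survival is 0 at time %g; Brier weight undefined", t)
    out[alive] <- (1 - pred[alive])^2 / gt
  }
  sum(out) / n
}

#' Integrated Brier score
#'
#' Time-averaged Brier score \code{(1/t_max) integral_0^t_max BS(t) dt},
#' computed with the trapezoidal rule on the grid \{0\} followed by the
#' unique observed times in (0, t_max] and t_max itself.
#'
#' @param pred either a function(t) returning the n predicted survival
#'   probabilities at horizon t, or a single number/vector of constant
#'   survival probabilities.
#' @param time,status outcome vectors.
#' @param Ghat censoring-survival \code{surv_curve}.
#' @param t_max upper integration limit (default: largest observed time).
#' @return Nonnegative integrated Brier score.
#' @export
integrated_brier_score <- function(pred, time, status, Ghat,
                                   t_max = max(time)) {
  if (t_max <= 0) stopf("t_max must be positive")
  if (!is.function(pred)) {
    const <- pred
    pred <- function(t) rep_len(const, length(time))
  }
  grid <- c(0, sort(unique(time[time > 0 & time <= t_max])))
  if (grid[length(grid)] < t_max) grid <- c(grid, t_max)
  bs <- vapply(grid, function(t) brier_score(t, pred(t), time, status, Ghat), 0)
  sum(diff(grid) * (utils::head(bs, -1) + utils::tail(bs, -1)) / 2) / t_max
}

#' Selection true/false positive rates
#'
#' TPR = selected true signals / total true signals; FPR = selected
#' non-signals / total non-signals.
#'
#' @param selected integer indices of selected features.
#' @param true_signals integer indices of signal features (nonempty).
#' @param p total feature count.
#' @return List with \code{tpr} and \code{fpr}.
#' @export
selection_tpr_fpr <- function(selected, true_signals, p) {
  if (length(true_signals) == 0) stopf("true_signals must be nonempty")
  if (length(selected) && (any(selected < 1) || any(selected > p)))
    stopf("selected indices out of range 1..p")
  if (length(true_signals) >= p) stopf("true_signals must leave some non-signals")
  tpr <- length(intersect(selected, true_signals)) / length(true_signals)
  fpr <- length(setdiff(selected, true_signals)) / (p - length(true_signals))
  list(tpr = tpr, fpr = fpr)
}

#' Evaluate a fitted model on a survival dataset
#'
#' Convenience wrapper producing the standard report: test concordance,
#' integrated Brier score (censoring distribution estimated on the training
#' data), and, when ground-truth signals are known, selection TPR/FPR.
#'
#' @param model a \code{surv_learner} (or any object with a
#'   \code{predict} method returning risk scores and, for IBS, a
#'   \code{predict_survival}-compatible fit).
#' @param data test \code{survdata}.
#' @param train optional training \code{survdata} used for the censoring
#'   estimate (defaults to \code{data}).
#' @param selected optional selected index set for TPR/FPR.
#' @param ibs logical; compute the integrated Brier score (default TRUE for
#'   \code{surv_learner}s).
#' @return List of class \code{"surv_eval"}: \code{cindex}, \code{ibs},
#'   \code{tpr}, \code{fpr}, \code{n_selected}.
#' @export
evaluate_model <- function(model, data, train = data, selected = NULL,
                           ibs = inherits(model, "surv_learner")) {
  scores <- predict(model, data$X)
  ci <- concordance_index(scores, data$time, data$status)
  ibs_val <- NA_real_
  if (isTRUE(ibs)) {
    Ghat <- km_estimator(train$time, 1 - train$status)
    t_max <- min(stats::quantile(data$time, 0.8), max(train$time))
    ibs_val <- integrated_brier_score(
      function(t) predict_survival(model, data$X, t)[, 1],
      data$time, data$status, Ghat, t_max = t_max)
  }
  tpr <- fpr <- NA_real_
  if (!is.null(selected) && length(data$true_signals)) {
    r <- selection_tpr_fpr(selected, data$true_signals, ncol(data$X))
    tpr <- r$tpr; fpr <- r$fpr
  }
  structure(list(cindex = ci, ibs = ibs_val, tpr = tpr, fpr = fpr,
                 n_selected = length(selected %||% integer(0))),
            class = "surv_eval")
}

#' @export
print.surv_eval <- function(x, ...) {
  cat(sprintf("<surv_eval> C-index = %.4f, IBS = %s, TPR = %s, FPR = %s (%d selected)\n",
              x$cindex,
              ifelse(is.na(x$ibs), "NA", sprintf("%.4f", x$ibs)),
              ifelse(is.na(x$tpr), "NA", sprintf("%.3f", x$tpr)),
              ifelse(is.na(x$fpr), "NA", sprintf("%.3f", x$fpr)),
              x$n_selected))
  invisible(x)
}
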