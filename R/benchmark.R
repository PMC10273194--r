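# Replicated simulation benchmark: selection + refit + held-out evaluation
# across scenarios and methods, plus the risk-group classification
# experiment.

# A method spec is a named list: name (label), type ("promise" or "topk"),
# and args forwarded to promise_cox()/topk_select() (learner, params, grids,
# ...). Helper constructors for the common cases:

#' Benchmark method specifications
#'
#' @param name display label.
#' @param ... arguments forwarded to \code{\link{promise_cox}} or
#'   \code{\link{topk_select}} (e.g. \code{learner}, \code{params},
#'   \code{n_boot}, \code{k_grid}).
#' @return A method-spec list consumed by \code{\link{run_benchmark}}.
#' @export
method_promise <- function(name = "PROMISE-Cox", ...) {
  list(name = name, type = "promise", args = list(...))
}

#' @rdname method_promise
#' @param learner registered learner name for the top-k route.
#' @export
method_topk <- function(learner, name = paste0(learner, "-topk"), ...) {
  list(name = name, type = "topk", args = c(list(learner = learner),
                                            list(...)))
}

run_one_method <- function(method, train, test, seed) {
  t0 <- proc.time()[["elapsed"]]
  sel_obj <- if (method$type == "promise") {
    do.call(promise_cox, c(list(x = train, seed = seed, refit = FALSE),
                           method$args))
  } else {
    do.call(topk_select, c(list(x = train, seed = seed, refit = FALSE),
                           method$args))
  }
  selected <- sel_obj$selected
  refit_method <- if (method$type == "promise") "penalized_cox"
                  else method$args$learner
  refit_params <- if (method$type == "promise") {
    list(lambda = sel_obj$chosen$lambda, alpha = sel_obj$chosen$alpha)
  } else method$args$params %||% list()
  model <- suppressWarnings(
    refit_on_selected(train$X, train$time, train$status, selected,
                      method = refit_method, params = refit_params,
                      seed = derive_seed(seed, 99L)))
  scores <- predict(model, test$X[, if (length(selected)) selected
                                  else seq_len(ncol(test$X)), drop = FALSE])
  ci <- concordance_index(scores, test$time, test$status)
  Ghat <- km_estimator(train$time, 1 - train$status)
  t_max <- min(stats::quantile(test$time, 0.8), max(train$time))
  Xtest <- test$X[, if (length(selected)) selected else seq_len(ncol(test$X)),
                  drop = FALSE]
  ibs <- tryCatch(
    integrated_brier_score(function(t) predict_survival(model, Xtest, t)[, 1],
                           test$time, test$status, Ghat, t_max = t_max),
    error = function(e) NA_real_)
  rates <- selection_tpr_fpr(selected, test$true_signals, ncol(test$X))
  list(tpr = rates$tpr, fpr = rates$fpr, n_selected = length(selected),
       test_cindex = ci, test_ibs = ibs,
       runtime_seconds = proc.time()[["elapsed"]] - t0)
}

#' Run the replicated selection/prediction benchmark
#'
#' For every (scenario, replicate): simulate a dataset, split it 80/20 into
#' training and test, run each method's selection on the training portion
#' only, refit the method's learner on the selected panel, and score test
#' concordance, integrated Brier score and selection TPR/FPR against the
#' generator's ground-truth signals. All seeds derive deterministically from
#' (base seed, scenario, method, replicate); test indices never enter any
#' selection or tuning step.
#'
#' @param scenarios list of scenario configs, each a list with
#'   \code{scenario}, \code{n}, \code{p}, \code{q} (extra entries forwarded
#'   to \code{\link{simulate_survival}}).
#' @param methods list of method specs from \code{\link{method_promise}} /
#'   \code{\link{method_topk}}.
#' @param n_replicates replicates per scenario (the full design uses 100; a
#'   scaled-down profile of ~10 is the practical default).
#' @param train_fraction training share of each replicate (default 0.8).
#' @param seed base seed.
#' @return Object of class \code{"benchmark_result"}: \code{records} (one
#'   row per scenario x method x replicate), \code{summary} (per-cell means,
#'   standard errors and mean rank by test concordance) and the echoed
#'   configuration. Replicate failures are dropped with a message, never
#'   imputed.
#' @export
run_benchmark <- function(scenarios, methods, n_replicates = 10L,
                          train_fraction = 0.8, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1, n_replicates >= 1)
  if (is.null(names(methods)) || any(!nzchar(names(methods))))
    names(methods) <- vapply(methods, function(m) m$name, "")
  rows <- list()
  for (si in seq_along(scenarios)) {
    sc <- scenarios[[si]]
    for (r in seq_len(n_replicates)) {
      data_seed <- derive_seed(seed, si, r)
      dat <- do.call(simulate_survival,
                     c(list(seed = data_seed),
                       sc[setdiff(names(sc), "seed")]))
      n <- nrow(dat$X)
      split <- with_seed(derive_seed(seed, si, r, 7L),
                         sample(n, round(train_fraction * n)))
      train <- subset_survdata(dat, split)
      test <- subset_survdata(dat, setdiff(seq_len(n), split))
      for (mi in seq_along(methods)) {
        res <- tryCatch(
          run_one_method(methods[[mi]], train, test,
                         seed = derive_seed(seed, si, r, mi)),
          error = function(e) {
            message(sprintf("replicate dropped (%s / %s / rep %d): %s",
                            sc$scenario, names(methods)[mi], r,
                            conditionMessage(e)))
            NULL
          })
        if (is.null(res)) next
        rows[[length(rows) + 1L]] <-
          data.frame(scenario = sc$scenario, method = names(methods)[mi],
                     replicate = r, res, stringsAsFactors = FALSE)
      }
    }
  }
  records <- do.call(rbind, rows)
  structure(list(records = records, summary = summarize_benchmark(records),
                 scenarios = scenarios, methods = names(methods),
                 n_replicates = n_replicates,
                 train_fraction = train_fraction, seed = seed),
            class = "benchmark_result")
}

subset_survdata <- function(data, idx) {
  survival_data(data$X[idx, , drop = FALSE], data$time[idx], data$status[idx],
                true_signals = data$true_signals,
                risk_group = data$risk_group[idx],
                latent = lapply(data$latent, function(v)
                  if (length(v) == length(data$time)) v[idx] else v),
                scenario = data$scenario, config = data$config)
}

summarize_benchmark <- function(records) {
  if (is.null(records) || nrow(records) == 0) return(NULL)
  ranks <- if (length(unique(records$method)) >= 2) {
    rank_methods(records)
  } else {
    data.frame(scenario = unique(records$scenario),
               method = records$method[1], mean_rank = 1)
  }
  cells <- split(records, list(records$scenario, records$method), drop = TRUE)
  out <- do.call(rbind, lapply(cells, function(d) {
    se <- function(v) stats::sd(v) / sqrt(sum(!is.na(v)))
    data.frame(scenario = d$scenario[1], method = d$method[1],
               n_replicates = nrow(d),
               mean_tpr = mean(d$tpr), se_tpr = se(d$tpr),
               mean_fpr = mean(d$fpr), se_fpr = se(d$fpr),
               mean_cindex = mean(d$test_cindex), se_cindex = se(d$test_cindex),
               mean_ibs = mean(d$test_ibs, na.rm = TRUE),
               mean_n_selected = mean(d$n_selected),
               stringsAsFactors = FALSE)
  }))
  out <- merge(out, ranks, by = c("scenario", "method"), sort = FALSE)
  out <- out[order(out$scenario, out$mean_rank), ]
  rownames(out) <- NULL
  out
}

#' Mean rank of methods by test concordance
#'
#' Within each (scenario, replicate), methods are ranked 1..M by test
#' C-index (rank 1 = best; ties get the average rank); ranks are averaged
#' per (scenario, method).
#'
#' @param x a \code{benchmark_result} or its \code{records} data frame.
#' @return Data frame with \code{scenario}, \code{method}, \code{mean_rank}.
#' @export
rank_methods <- function(x) {
  records <- if (inherits(x, "benchmark_result")) x$records else x
  if (length(unique(records$method)) < 2)
    stopf("ranking needs at least 2 methods")
  grp <- split(records, list(records$scenario, records$replicate), drop = TRUE)
  ranked <- do.call(rbind, lapply(grp, function(d) {
    d$rk <- rank(-d$test_cindex, ties.method = "average")
    d[, c("scenario", "method", "rk")]
  }))
  agg <- stats::aggregate(rk ~ scenario + method, data = ranked, FUN = mean)
  names(agg)[3] <- "mean_rank"
  agg[order(agg$scenario, agg$mean_rank), ]
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("<benchmark_result> %d scenarios x %d methods x %d replicates (%d records)\n",
              length(x$scenarios), length(x$methods), x$n_replicates,
              nrow(x$records)))
  print(x$summary, digits = 3, row.names = FALSE)
  invisible(x)
}

#' @export
plot.benchmark_result <- function(x, metric = "test_cindex", ...) {
  graphics::boxplot(stats::reformulate("method", metric), data = x$records,
                    ylab = metric, las = 2, ...)
  invisible(x)
}

#' Risk-group classification experiment
#'
#' Generates the three-group risk cohort, splits it into training and test
#' samples, fits each learner on the training features, dichotomizes the
#' predicted test risk scores at the training-set median predicted score,
#' and reports the misclassification rate against the true high/low-risk
#' labels together with Kaplan-Meier curve data for true and predicted
#' groups.
#'
#' @param seed base seed.
#' @param methods named list; each element either a registered learner name
#'   with parameters (\code{list(method = "xgb_cox", params = list())}) or a
#'   scoring function \code{function(data, train_idx, test_idx)} returning
#'   \code{list(train_scores, test_scores)} (testing hook, e.g. an oracle on
#'   the latent scale variable).
#' @param n_train,n_test training/test sample counts (defaults 1000 / 200).
#' @param data optional pre-generated risk-group dataset.
#' @return List of class \code{"risk_experiment"}: \code{rates} (per-method
#'   misclassification), \code{km} (tidy per-group KM curve data, true and
#'   predicted), and the split indices.
#' @export
risk_classification_experiment <- function(seed = 1L,
                                           methods = list(
                                             `XGB-Cox` = list(method = "xgb_cox"),
                                             RSF = list(method = "rsf")),
                                           n_train = 1000L, n_test = 200L,
                                           data = NULL) {
  if (is.null(data)) data <- sim_risk_groups(seed = derive_seed(seed, 1L))
  n <- nrow(data$X)
  stopifnot(n_train + n_test <= n)
  idx <- with_seed(derive_seed(seed, 2L), sample(n, n_train + n_test))
  train_idx <- idx[seq_len(n_train)]
  test_idx <- idx[n_train + seq_len(n_test)]
  train <- subset_survdata(data, train_idx)
  test <- subset_survdata(data, test_idx)

  km_rows <- list()
  add_km <- function(label, group_type, method, times, status, group) {
    for (g in unique(group)) {
      cv <- km_estimator(times[group == g], status[group == g])
      km_rows[[length(km_rows) + 1L]] <<-
        data.frame(method = method, group_type = group_type,
                   risk = ifelse(g == 1, "high", "low"),
                   time = cv$times, surv = cv$surv, stringsAsFactors = FALSE)
    }
  }
  add_km("true", "true", "none", test$time, test$status, test$risk_group)

  rates <- data.frame(method = character(0), misclassification = numeric(0),
                      stringsAsFactors = FALSE)
  for (mi in seq_along(methods)) {
    m <- methods[[mi]]; mname <- names(methods)[mi]
    if (is.function(m)) {
      sc <- m(data, train_idx, test_idx)
      train_scores <- sc$train_scores; test_scores <- sc$test_scores
    } else {
      fit <- fit_survival_learner(train$X, train$time, train$status,
                                  method = m$method,
                                  params = m$params %||% list(),
                                  seed = derive_seed(seed, 3L, mi))
      train_scores <- predict(fit, train$X)
      test_scores <- predict(fit, test$X)
    }
    cut <- stats::median(train_scores)
    pred_group <- as.integer(test_scores > cut)
    if (length(unique(pred_group)) == 1)
      warnf("method %s predicts a single risk class", mname)
    rate <- mean(pred_group != test$risk_group)
    rates <- rbind(rates, data.frame(method = mname, misclassification = rate,
                                     stringsAsFactors = FALSE))
    add_km("pred", "predicted", mname, test$time, test$status, pred_group)
  }
  structure(list(rates = rates, km = do.call(rbind, km_rows),
                 train_idx = train_idx, test_idx = test_idx, seed = seed),
            class = "risk_experiment")
}

#' @export
print.risk_experiment <- function(x, ...) {
  cat("<risk_experiment> misclassification rates:\n")
  print(x$rates, row.names = FALSE, digits = 3)
  invisible(x)
}
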