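# Tabular survival I/O: delimited tables with a sidecar JSON manifest, plus
# JSON/TSV writers for selection results and evaluation reports. Every
# artifact embeds the seed and resolved configuration.

IO_SCHEMA_VERSION <- "1.0"

detect_sep <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

manifest_path <- function(path) paste0(path, ".json")

#' Read a survival table
#'
#' Parses a delimited text file (TSV/CSV by extension) with named time and
#' event columns; every remaining numeric column becomes a feature. Times
#' must be strictly positive, events coded 0/1; violations are reported with
#' the offending column and row. A sidecar manifest \code{<path>.json}
#' written by \code{\link{write_survival_table}} restores the scenario
#' metadata and true-signal indices when present.
#'
#' @param path input file.
#' @param time_col,event_col column names (defaults \code{"time"},
#'   \code{"status"}).
#' @param sep field separator; default inferred from the extension.
#' @return A \code{\link{survival_data}} object.
#' @export
read_survival_table <- function(path, time_col = "time",
                                event_col = "status", sep = NULL) {
  if (!file.exists(path)) stopf("input file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = detect_sep(path, sep),
                          check.names = FALSE, stringsAsFactors = FALSE)
  for (cn in c(time_col, event_col))
    if (!cn %in% names(df)) stopf("column '%s' not found in %s", cn, path)
  time <- df[[time_col]]
  if (!is.numeric(time) || any(!is.finite(time)))
    stopf("column '%s' must be finite numeric", time_col)
  if (any(time <= 0))
    stopf("column '%s' must be strictly positive (first offending row: %d)",
          time_col, which(time <= 0)[1])
  ev <- df[[event_col]]
  if (!all(ev %in% c(0, 1)))
    stopf("column '%s' must be coded 0/1 (first offending row: %d)",
          event_col, which(!ev %in% c(0, 1))[1])
  feats <- setdiff(names(df), c(time_col, event_col))
  for (cn in feats)
    if (!is.numeric(df[[cn]]))
      stopf("feature column '%s' is not numeric", cn)
  X <- as.matrix(df[feats])
  ts <- integer(0); scenario <- NULL; config <- list()
  mp <- manifest_path(path)
  if (file.exists(mp)) {
    man <- jsonlite::read_json(mp, simplifyVector = TRUE)
    ts <- as.integer(man$true_signals %||% integer(0))
    scenario <- man$scenario
    config <- as.list(man$config %||% list())
  }
  survival_data(X, time, ev, true_signals = ts, scenario = scenario,
                config = config)
}

#' Write a survival table
#'
#' Emits a delimited table with columns \code{time}, \code{status} and the
#' features, plus a JSON manifest \code{<path>.json} carrying the scenario,
#' configuration, seed and true-signal indices. Round-trips through
#' \code{\link{read_survival_table}}.
#'
#' @param data a \code{survdata} object.
#' @param path output file (\code{.tsv} or \code{.csv}).
#' @param sep field separator; default inferred from the extension.
#' @return \code{path}, invisibly.
#' @export
write_survival_table <- function(data, path, sep = NULL) {
  stopifnot(inherits(data, "survdata"))
  df <- data.frame(time = data$time, status = data$status,
                   data$X, check.names = FALSE)
  utils::write.table(df, path, sep = detect_sep(path, sep), quote = FALSE,
                     row.names = FALSE)
  man <- list(schema_version = IO_SCHEMA_VERSION,
              scenario = data$scenario,
              config = data$config,
              true_signals = data$true_signals,
              n = nrow(data$X), p = ncol(data$X))
  jsonlite::write_json(man, manifest_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Write a selection result
#'
#' JSON artifact (schema version, seed, configuration echo, selected feature
#' names, per-feature scores, tuned hyperparameters, CV trace) plus a TSV
#' twin \code{<path>.tsv} with one row per feature.
#'
#' @param result a \code{promise_cox} or \code{topk_select} object.
#' @param path output JSON file.
#' @return \code{path}, invisibly.
#' @export
write_selection <- function(result, path) {
  stopifnot(inherits(result, c("promise_cox", "topk_select")))
  cfg <- if (inherits(result, "promise_cox")) {
    list(method = "promise_cox", penalty = result$penalty,
         ss_threshold = result$ss_threshold, n_boot = result$n_boot,
         cv_folds = result$cv_folds, tune = result$tune)
  } else {
    list(method = "topk_select", learner = result$learner,
         cv_folds = result$cv_folds, aggregate = result$aggregate,
         params = result$params)
  }
  out <- list(schema_version = IO_SCHEMA_VERSION, seed = result$seed,
              config = cfg,
              selected = as.list(result$feature_names[result$selected]),
              chosen = result$chosen,
              scores = as.list(stats::setNames(as.numeric(result$scores),
                                               result$feature_names)),
              cv_trace = result$cv_trace)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  tsv <- data.frame(feature = result$feature_names,
                    score = as.numeric(result$scores),
                    selected = as.integer(seq_along(result$scores) %in%
                                            result$selected))
  utils::write.table(tsv, paste0(path, ".tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a selection result artifact
#' @param path JSON file written by \code{\link{write_selection}}.
#' @return The parsed list.
#' @export
read_selection <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write an evaluation report
#'
#' @param report a \code{surv_eval} object (or list with cindex/ibs/tpr/fpr/
#'   n_selected).
#' @param path output JSON file; a TSV twin is written to \code{<path>.tsv}.
#' @param seed seed to embed.
#' @param config configuration echo to embed.
#' @return \code{path}, invisibly.
#' @export
write_report <- function(report, path, seed = NA_integer_, config = list()) {
  fields <- c("cindex", "ibs", "tpr", "fpr", "n_selected")
  vals <- lapply(fields, function(f) report[[f]] %||% NA_real_)
  names(vals) <- fields
  out <- c(list(schema_version = IO_SCHEMA_VERSION, seed = seed,
                config = config), vals)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  utils::write.table(data.frame(vals), paste0(path, ".tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write benchmark outputs
#'
#' Records as TSV and the summary (with configuration and seed) as JSON.
#' @param result a \code{benchmark_result}.
#' @param records_path TSV output for per-replicate records.
#' @param summary_path JSON output for the summary.
#' @return \code{summary_path}, invisibly.
#' @export
write_benchmark <- function(result, records_path, summary_path) {
  stopifnot(inherits(result, "benchmark_result"))
  utils::write.table(result$records, records_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  out <- list(schema_version = IO_SCHEMA_VERSION, seed = result$seed,
              config = list(scenarios = result$scenarios,
                            methods = result$methods,
                            n_replicates = result$n_replicates,
                            train_fraction = result$train_fraction),
              summary = result$summary)
  jsonlite::write_json(out, summary_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(summary_path)
}
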