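#' Feature Z-score
#'
#' The suite's unit of discrepancy: the absolute difference between a
#' model's feature value and the experimental mean, in units of the
#' experimental standard deviation.
#'
#' @param model_value feature value measured on the model.
#' @param mean experimental mean.
#' @param sd experimental standard deviation, must be > 0.
#' @param feature_key optional label used in error messages.
#' @return non-negative numeric Z-score.
#' @examples
#' zscore(1.50, 1.23, 0.096)   # AP half-width 2 SD off -> 2.8125
#' @export
zscore <- function(model_value, mean, sd, feature_key = "feature") {
  if (!is.finite(sd) || sd <= 0)
    hv_stop("hippoval_invalid_observation",
            "invalid observation for '%s': sd must be > 0 (got %s)",
            feature_key, format(sd))
  abs(model_value - mean) / sd
}

#' Construct a single feature score
#'
#' @param feature_key unique feature label (feature name plus stimulus
#'   context, e.g. `"AP_amplitude@0.15"`).
#' @param model_value model feature value, `NA` when unevaluable.
#' @param mean,sd experimental target; `sd` must be positive.
#' @param evaluated `FALSE` when the feature could not be extracted (e.g. a
#'   spiking feature on a spikeless trace); the Z-score is then undefined
#'   and the feature is only counted among the attempted ones.
#' @param note free-form annotation carried into the log file.
#' @return a one-row `data.frame` with columns `feature_key`,
#'   `model_value`, `mean`, `sd`, `z`, `evaluated`, `note`.
#' @export
feature_score <- function(feature_key, model_value, mean, sd,
                          evaluated = TRUE, note = "") {
  if (evaluated && !is.finite(model_value)) evaluated <- FALSE
  z <- if (evaluated) zscore(model_value, mean, sd, feature_key) else NA_real_
  data.frame(feature_key = feature_key,
             model_value = if (evaluated) model_value else NA_real_,
             mean = mean, sd = sd, z = z, evaluated = evaluated,
             note = note, stringsAsFactors = FALSE)
}

bind_scores <- function(scores) {
  if (is.data.frame(scores)) return(scores)
  do.call(rbind, scores)
}

#' Aggregate feature scores into a final score
#'
#' Averages (or sums) the Z-scores of the evaluated features; unevaluable
#' features are ignored here but remain counted in `n_attempted` of the
#' enclosing [test_result()].
#'
#' @param scores a data.frame of feature scores (rows from
#'   [feature_score()]) or a list of such rows.
#' @param mode `"mean"` (default for all tests) or `"sum"`.
#' @return numeric aggregate.  With zero evaluated features a classed
#'   error `hippoval_degenerate_score` is signalled for the calling test
#'   to handle (each test defines its own degenerate-case policy).
#' @export
aggregate_scores <- function(scores, mode = c("mean", "sum")) {
  mode <- match.arg(mode)
  df <- bind_scores(scores)
  z <- df$z[df$evaluated]
  if (length(z) == 0)
    hv_stop("hippoval_degenerate_score",
            "no feature could be evaluated; degenerate result")
  if (mode == "mean") base::mean(z) else sum(z)
}

#' Assemble a test result
#'
#' @param test_name name of the validation test.
#' @param feature_scores data.frame of feature scores ([feature_score()]).
#' @param penalty non-negative additive penalty (test-specific rules).
#' @param mode aggregation mode passed to [aggregate_scores()].
#' @param final_override when non-NULL, used as the final score verbatim
#'   (the depolarization-block test sets 100 for models that never block).
#' @param classification_notes free-form notes (e.g. strong/weak
#'   propagation verdict, excluded dendritic locations).
#' @param seed the seed governing any randomness in the test run.
#' @param config_echo list echoing the configuration used, for provenance.
#' @return object of class `hippo_test_result`.
#' @export
test_result <- function(test_name, feature_scores, penalty = 0,
                        mode = "mean", final_override = NULL,
                        classification_notes = "", seed = NA_integer_,
                        config_echo = list()) {
  fs <- bind_scores(feature_scores)
  final <- if (!is.null(final_override)) final_override
           else aggregate_scores(fs, mode) + penalty
  structure(list(
    test_name = test_name,
    feature_scores = fs,
    penalty = penalty,
    final_score = final,
    n_evaluated = sum(fs$evaluated),
    n_attempted = nrow(fs),
    classification_notes = classification_notes,
    seed = seed,
    config_echo = config_echo,
    artifact_paths = character(0)
  ), class = "hippo_test_result")
}

#' @export
print.hippo_test_result <- function(x, ...) {
  cat(sprintf("<%s> final score %.6g (penalty %.6g), %d/%d features evaluated\n",
              x$test_name, x$final_score, x$penalty,
              x$n_evaluated, x$n_attempted))
  if (nzchar(x$classification_notes))
    cat(" notes:", x$classification_notes, "\n")
  invisible(x)
}

#' Persist a test result to disk
#'
#' Writes a machine-readable JSON result file plus a plain-text log that
#' states the final score on its own line and lists every feature that
#' could not be evaluated.  Reloading the JSON with [load_result()]
#' reproduces the result.
#'
#' @param result a [test_result()].
#' @param out_dir writable output directory (created if absent).
#' @param prefix file-name prefix, default the test name.
#' @return character vector of the file paths written (JSON first).
#' @export
persist_result <- function(result, out_dir, prefix = result$test_name) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) hv_stop("hippoval_io_error", "cannot create directory '%s'", out_dir)
  }
  if (file.access(out_dir, 2) != 0)
    hv_stop("hippoval_io_error", "directory '%s' is not writable", out_dir)
  json_path <- file.path(out_dir, paste0(prefix, "_result.json"))
  log_path <- file.path(out_dir, paste0(prefix, "_log.txt"))

  payload <- list(
    test_name = result$test_name,
    final_score = result$final_score,
    penalty = result$penalty,
    feature_scores = result$feature_scores,
    n_evaluated = result$n_evaluated,
    n_attempted = result$n_attempted,
    classification_notes = result$classification_notes,
    seed = result$seed,
    config_echo = result$config_echo
  )
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       na = "null", null = "null", dataframe = "rows")

  unev <- result$feature_scores$feature_key[!result$feature_scores$evaluated]
  lines <- c(
    sprintf("test: %s", result$test_name),
    sprintf("final score: %.15g", result$final_score),
    sprintf("penalty: %.15g", result$penalty),
    sprintf("features evaluated: %d of %d attempted",
            result$n_evaluated, result$n_attempted),
    if (nzchar(result$classification_notes))
      sprintf("notes: %s", result$classification_notes),
    if (length(unev)) "features that could not be evaluated:",
    sprintf("  %s", unev)
  )
  writeLines(lines, log_path)
  paths <- c(json_path, log_path)
  invisible(paths)
}

#' Reload a persisted test result
#'
#' @param json_path path to a `*_result.json` written by
#'   [persist_result()].
#' @return a `hippo_test_result` equal to the persisted one.
#' @export
load_result <- function(json_path) {
  p <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  fs <- p$feature_scores
  fs$model_value <- as.numeric(fs$model_value)
  fs$z <- as.numeric(fs$z)
  fs$note <- as.character(fs$note)
  structure(list(
    test_name = p$test_name,
    feature_scores = fs,
    penalty = as.numeric(p$penalty),
    final_score = as.numeric(p$final_score),
    n_evaluated = as.integer(p$n_evaluated),
    n_attempted = as.integer(p$n_attempted),
    classification_notes = p$classification_notes,
    seed = if (is.null(p$seed)) NA_integer_ else p$seed,
    config_echo = as.list(p$config_echo),
    artifact_paths = character(0)
  ), class = "hippo_test_result")
}
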