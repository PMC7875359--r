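# Observation files: JSON containers of experimental feature means and
# standard deviations, one schema per test (documented in the README and
# methods vignette).  Validation enumerates schema violations instead of
# silently coercing.

.hv_tests <- c("somatic-features", "depol-block", "bap",
               "psp-attenuation", "oblique-integration")

.oblique_features <- c("threshold", "prox_threshold", "dist_threshold",
                       "nonlin_at_th", "suprath_nonlin", "peak_deriv",
                       "peak_amp", "time_to_peak", "async_nonlin")

as_observation <- function(x, test = NULL) {
  if (is.character(x) && length(x) == 1) read_observation(x, test) else x
}

#' Read an observation file
#'
#' For oblique-integration files that report standard errors (`se_*` keys
#' plus `n_cells`), the SE values are converted to standard deviations
#' (`sd = se * sqrt(n_cells)`) on loading.
#'
#' @param path path to a JSON observation file.
#' @param test optional test name (`"somatic-features"`, `"depol-block"`,
#'   `"bap"`, `"psp-attenuation"` or `"oblique-integration"`); enables
#'   test-specific post-processing.
#' @return named list mirroring the file, with any SE fields converted.
#' @export
read_observation <- function(path, test = NULL) {
  if (!file.exists(path))
    hv_stop("hippoval_io_error", "observation file '%s' not found", path)
  obs <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(test, "oblique-integration")) {
    se_keys <- grep("^se_", names(obs), value = TRUE)
    if (length(se_keys)) {
      n <- obs$n_cells
      if (is.null(n))
        hv_stop("hippoval_invalid_observation",
                "oblique observation has SE fields but no n_cells for SE->SD conversion")
      for (k in se_keys) {
        obs[[sub("^se_", "std_", k)]] <- obs[[k]] * sqrt(n)
        obs[[k]] <- NULL
      }
      attr(obs, "note") <- sprintf(
        "SE values converted to standard deviation (sd = se * sqrt(%d))", n)
    }
  }
  obs
}

.check_entry <- function(e, key, violations) {
  if (!is.list(e) || is.null(e$mean) || is.null(e$std))
    return(c(violations, sprintf("'%s': missing mean or std", key)))
  if (!is.finite(e$std) || e$std <= 0)
    return(c(violations, sprintf("'%s': std must be > 0 (got %s)",
                                 key, format(e$std))))
  violations
}

#' Validate an observation file against a test's schema
#'
#' @param path path to a JSON observation file.
#' @param test one of the five test names (see [run_validation()]).
#' @return list with `valid` (logical), `violations` (character) and
#'   `notes` (character, e.g. the SE-to-SD conversion flag for oblique
#'   files).
#' @export
validate_observation <- function(path, test) {
  test <- match.arg(test, .hv_tests)
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  violations <- character(0); notes <- character(0)
  reg <- feature_registry()$name

  if (test == "somatic-features") {
    for (f in names(raw)) {
      if (!(f %in% reg)) {
        violations <- c(violations,
                        sprintf("'%s': not a registry feature", f))
        next
      }
      if (!is.list(raw[[f]]) || is.null(names(raw[[f]]))) {
        violations <- c(violations,
                        sprintf("'%s': expected amplitude-keyed entries", f))
        next
      }
      for (a in names(raw[[f]])) {
        if (is.na(suppressWarnings(as.numeric(a))))
          violations <- c(violations,
                          sprintf("'%s' amplitude label '%s' is not numeric", f, a))
        violations <- .check_entry(raw[[f]][[a]], paste0(f, "@", a), violations)
      }
    }
    if (!length(raw)) violations <- c(violations, "no features in file")
  } else if (test == "depol-block") {
    for (k in c("mean_Ith", "Ith_std", "mean_Veq", "Veq_std"))
      if (is.null(raw[[k]]))
        violations <- c(violations, sprintf("missing key '%s'", k))
    for (k in c("Ith_std", "Veq_std"))
      if (!is.null(raw[[k]]) && raw[[k]] <= 0)
        violations <- c(violations, sprintf("'%s' must be > 0", k))
  } else if (test == "bap") {
    pat <- "^(AP1|APlast)_amp_[0-9]+(_strong|_weak)?$"
    bad <- setdiff(names(raw), grep(pat, names(raw), value = TRUE))
    for (k in bad)
      violations <- c(violations, sprintf("unrecognized key '%s'", k))
    for (k in grep(pat, names(raw), value = TRUE))
      violations <- .check_entry(raw[[k]], k, violations)
    if (!any(grepl("^AP1_amp_", names(raw))))
      violations <- c(violations, "no AP1_amp_<distance> entries")
  } else if (test == "psp-attenuation") {
    means <- grep("^mean_attenuation_soma/dend_[0-9]+_um$", names(raw),
                  value = TRUE)
    if (!length(means))
      violations <- c(violations, "no mean_attenuation_soma/dend_<d>_um keys")
    for (m in means) {
      s <- sub("^mean_", "std_", m)
      if (is.null(raw[[s]]))
        violations <- c(violations, sprintf("missing '%s'", s))
      else if (raw[[s]] <= 0)
        violations <- c(violations, sprintf("'%s' must be > 0", s))
    }
  } else if (test == "oblique-integration") {
    has_se <- any(grepl("^se_", names(raw)))
    if (has_se) {
      if (is.null(raw$n_cells))
        violations <- c(violations, "SE fields present but n_cells missing")
      else
        notes <- c(notes,
                   "SE fields present; converted to SD on loading (sd = se * sqrt(n_cells))")
    }
    for (f in .oblique_features) {
      m <- paste0("mean_", f)
      s <- paste0("std_", f); se <- paste0("se_", f)
      if (is.null(raw[[m]]))
        violations <- c(violations, sprintf("missing '%s'", m))
      if (is.null(raw[[s]]) && is.null(raw[[se]]))
        violations <- c(violations, sprintf("missing '%s' (or '%s')", s, se))
      else if (!is.null(raw[[s]]) && raw[[s]] <= 0)
        violations <- c(violations, sprintf("'%s' must be > 0", s))
    }
  }
  list(valid = length(violations) == 0, violations = violations, notes = notes)
}
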