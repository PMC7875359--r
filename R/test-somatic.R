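#' The Somatic Features Test
#'
#' Injects step currents of the amplitudes named in the observation into
#' the soma, extracts every observed feature from the voltage response at
#' each amplitude, and Z-scores the evaluable ones.  Vector features are
#' averaged over action potentials, with the first element dropped for
#' features derived from the AP begin point.  Features that cannot be
#' evaluated (e.g. spiking features at amplitudes where the model does
#' not fire) are excluded from the average but counted among the
#' attempted features and listed in the log file.
#'
#' @param model a model providing the `step_current` capability.
#' @param observation path to, or parsed list of, a somatic observation:
#'   `{feature: {amplitude_label: {"mean": m, "std": s}}}` with
#'   registry feature names and amplitude labels in nA.
#' @param protocol list with `delay`, `duration`, `tstop` (ms) and
#'   optionally `amplitudes` (nA); when `amplitudes` is given every
#'   observation label must match one of them.
#' @param spike_threshold AP detection threshold, mV.
#' @return a [test_result()]; the final score is the mean Z-score over
#'   the evaluated features.
#' @export
run_somatic_features_test <- function(model, observation,
                                      protocol = list(delay = 500,
                                                      duration = 1000,
                                                      tstop = 1700),
                                      spike_threshold = -20) {
  require_capability(model, "step_current", "the somatic features test")
  obs <- as_observation(observation, "somatic-features")
  if (!length(obs))
    hv_stop("hippoval_invalid_observation", "empty somatic observation")

  labels <- sort(unique(unlist(lapply(obs, names))))
  amps <- as.numeric(labels)
  if (anyNA(amps))
    hv_stop("hippoval_invalid_observation",
            "non-numeric amplitude label in observation: %s",
            paste(labels[is.na(amps)], collapse = ", "))
  if (!is.null(protocol$amplitudes)) {
    missing <- labels[vapply(amps, function(a)
      !any(abs(protocol$amplitudes - a) < 1e-9), logical(1))]
    if (length(missing))
      hv_stop("hippoval_invalid_observation",
              "observation amplitudes not in protocol: %s",
              paste(missing, collapse = ", "))
  }

  traces <- setNames(lapply(amps, function(a) {
    step_current_response(model, a, protocol$delay, protocol$duration,
                          protocol$tstop)$soma
  }), labels)

  scores <- list()
  for (f in names(obs)) {
    for (lab in names(obs[[f]])) {
      e <- obs[[f]][[lab]]
      fv <- extract_feature(traces[[lab]], f, spike_threshold)
      key <- paste0(f, "@", lab)
      scores[[key]] <- feature_score(
        key, fv$scalar, e$mean, e$std, evaluated = fv$evaluable,
        note = if (fv$evaluable) "" else "could not be evaluated")
    }
  }
  test_result("somatic_features", scores, mode = "mean",
              config_echo = list(protocol = protocol,
                                 spike_threshold = spike_threshold))
}
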