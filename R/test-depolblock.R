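#' The Depolarization Block Test
#'
#' Stimulates the soma with 1000 ms square current pulses from 0 to
#' 1.6 nA in 0.05 nA steps and counts the action potentials per
#' amplitude.  Three features are evaluated against the experimental
#' threshold current `I_th` and equilibrium potential `V_eq`:
#'
#' * `I_maxNumAP` — the lowest amplitude at which the model fires the
#'   maximal number of APs;
#' * `I_below_depol_block` — the amplitude one step below the lowest
#'   amplitude at which the model enters depolarization block (defined as
#'   firing no AP during the last 100 ms of the stimulus, at an amplitude
#'   above `I_maxNumAP`);
#' * `V_eq` — the mean membrane potential over the last 100 ms of the
#'   first genuinely blocking trace, searched upward from one step above
#'   `I_maxNumAP` (skipping traces that still spike late).
#'
#' The final score is the mean of the three Z-scores plus a penalty of 10
#' per examined step separating `I_maxNumAP` from `I_below_depol_block`
#' (equivalently 200 times their difference in nA).  A model that never
#' enters depolarization block receives a final score of 100.
#'
#' @param model a model providing the `step_current` capability.
#' @param observation path or list with `mean_Ith`, `Ith_std`,
#'   `mean_Veq`, `Veq_std`.
#' @param config list with `amplitudes` (default `seq(0, 1.6, 0.05)` nA),
#'   `delay`, `duration`, `tstop` (ms), `spike_threshold` (mV).
#' @return a [test_result()].
#' @export
run_depol_block_test <- function(model, observation, config = list()) {
  require_capability(model, "step_current", "the depolarization block test")
  cfg <- modifyList(list(amplitudes = seq(0, 1.6, by = 0.05), delay = 500,
                         duration = 1000, tstop = 1700,
                         spike_threshold = -20), config)
  obs <- as_observation(observation, "depol-block")
  for (k in c("mean_Ith", "Ith_std", "mean_Veq", "Veq_std"))
    if (is.null(obs[[k]]))
      hv_stop("hippoval_invalid_observation",
              "depolarization block observation lacks '%s'", k)

  amps <- sort(cfg$amplitudes)
  step <- if (length(amps) > 1) stats::median(diff(amps)) else 0.05
  end <- cfg$delay + cfg$duration

  traces <- lapply(amps, function(a)
    step_current_response(model, a, cfg$delay, cfg$duration, cfg$tstop)$soma)
  peaks <- lapply(traces, function(tr)
    detect_spikes(tr, cfg$spike_threshold)$peak_time)
  counts <- vapply(peaks, function(pt)
    sum(pt >= cfg$delay & pt <= end), numeric(1))
  silent_late <- vapply(peaks, function(pt)
    !any(pt >= end - 100 & pt <= end), logical(1))

  i_max <- which.max(counts)               # lowest amplitude with max count
  I_maxNumAP <- amps[i_max]
  block_idx <- which(seq_along(amps) > i_max & silent_late)
  block_detected <- i_max < length(amps) && length(block_idx) > 0

  echo <- list(amplitudes = amps, delay = cfg$delay, duration = cfg$duration,
               tstop = cfg$tstop, spike_threshold = cfg$spike_threshold)

  if (!block_detected) {
    scores <- rbind(
      feature_score("I_maxNumAP", I_maxNumAP, obs$mean_Ith, obs$Ith_std),
      feature_score("I_below_depol_block", NA_real_, obs$mean_Ith,
                    obs$Ith_std, evaluated = FALSE,
                    note = "model did not enter depolarization block"),
      feature_score("V_eq", NA_real_, obs$mean_Veq, obs$Veq_std,
                    evaluated = FALSE,
                    note = "model did not enter depolarization block"))
    return(test_result("depol_block", scores, penalty = 0,
                       final_override = 100,
                       classification_notes = "no depolarization block detected; final score set to 100",
                       config_echo = echo))
  }

  ib <- block_idx[1]
  I_below <- amps[ib - 1L]
  n_steps <- round(abs(I_maxNumAP - I_below) / step)
  penalty <- 10 * n_steps

  # V_eq: start one step above I_maxNumAP and iterate upward past traces
  # that still fire during the last 100 ms
  veq <- NA_real_; veq_amp <- NA_real_
  for (j in seq(i_max + 1L, length(amps))) {
    if (silent_late[j]) {
      veq <- tw_mean(traces[[j]], end - 100, end)
      veq_amp <- amps[j]
      break
    }
  }

  scores <- rbind(
    feature_score("I_maxNumAP", I_maxNumAP, obs$mean_Ith, obs$Ith_std),
    feature_score("I_below_depol_block", I_below, obs$mean_Ith, obs$Ith_std),
    feature_score("V_eq", veq, obs$mean_Veq, obs$Veq_std,
                  evaluated = is.finite(veq),
                  note = if (is.finite(veq))
                    sprintf("extracted at %.6g nA", veq_amp) else
                    "no blocking trace found for V_eq"))
  test_result("depol_block", scores, penalty = penalty,
              classification_notes = sprintf(
                "depolarization block above %.6g nA; I_maxNumAP = %.6g nA, I_below_depol_block = %.6g nA (%d step(s) apart)",
                amps[ib], I_maxNumAP, I_below, n_steps),
              config_echo = echo)
}
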