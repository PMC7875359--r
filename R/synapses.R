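#' Default synaptic parameters
#'
#' The default synapse used by the oblique integration workflow: a
#' double-exponential AMPA conductance plus an NMDA conductance with
#' Jahr-Stevens magnesium-block voltage dependence.  The NMDA time
#' constants are temperature-corrected (Q10) values and are stored already
#' corrected; the Q10 factors are recorded for provenance only.
#'
#' @param ampa_tau1 AMPA rise time constant, ms (default 0.1).
#' @param ampa_tau2 AMPA decay time constant, ms (default 2.0).
#' @param nmda_tau_rise NMDA rise time constant, ms (default 3.3).
#' @param nmda_tau_decay NMDA decay time constant, ms (default 102.38).
#' @param ampa_nmda_ratio ratio of AMPA to NMDA peak conductance
#'   (default 2.0).
#' @param reversal synaptic reversal potential, mV (default 0).
#' @param mg_conc extracellular magnesium concentration, mM (default 1).
#' @param q10_rise,q10_decay Q10 factors of the NMDA rise and decay time
#'   constants (2.2 and 1.7; provenance only, never re-applied).
#' @return object of class `synapse_params`.
#' @export
synapse_params <- function(ampa_tau1 = 0.1, ampa_tau2 = 2.0,
                           nmda_tau_rise = 3.3, nmda_tau_decay = 102.38,
                           ampa_nmda_ratio = 2.0, reversal = 0,
                           mg_conc = 1, q10_rise = 2.2, q10_decay = 1.7) {
  if (!(ampa_tau2 > ampa_tau1 && ampa_tau1 > 0))
    hv_stop("hippoval_parameter_error", "need ampa_tau2 > ampa_tau1 > 0")
  if (!(nmda_tau_decay > nmda_tau_rise && nmda_tau_rise > 0))
    hv_stop("hippoval_parameter_error", "need nmda_tau_decay > nmda_tau_rise > 0")
  if (ampa_nmda_ratio <= 0)
    hv_stop("hippoval_parameter_error", "ampa_nmda_ratio must be > 0")
  if (mg_conc < 0)
    hv_stop("hippoval_parameter_error", "mg_conc must be >= 0")
  structure(list(ampa_tau1 = ampa_tau1, ampa_tau2 = ampa_tau2,
                 nmda_tau_rise = nmda_tau_rise, nmda_tau_decay = nmda_tau_decay,
                 ampa_nmda_ratio = ampa_nmda_ratio, reversal = reversal,
                 mg_conc = mg_conc, q10_rise = q10_rise, q10_decay = q10_decay),
            class = "synapse_params")
}

#' Synaptic weight from a target EPSC amplitude
#'
#' With the synaptic reversal potential at 0 mV the driving force at rest
#' equals -Vm, so the weight (peak conductance, uS) reproducing a target
#' EPSC amplitude is `-epsc_amp / vm`.
#'
#' @param epsc_amp target EPSC amplitude, nA.
#' @param vm resting membrane potential, mV; must be negative.
#' @return positive synaptic weight.
#' @export
psp_weight_from_epsc <- function(epsc_amp, vm) {
  if (!is.finite(vm) || vm >= 0)
    hv_stop("hippoval_calibration_error",
            "resting Vm must be negative (got %g mV); driving force undefined",
            vm)
  -epsc_amp / vm
}

#' NMDA magnesium block (Jahr-Stevens)
#'
#' Fraction of NMDA conductance unblocked at membrane potential `v`:
#' `1 / (1 + (mg_conc / 3.57) * exp(-0.062 * v))`.  Strictly increasing
#' in `v`, tends to 1 with depolarization and equals 1 at any voltage
#' when magnesium is absent.
#'
#' @param v membrane potential, mV.
#' @param mg_conc magnesium concentration, mM (default 1).
#' @return unblocked fraction in (0, 1].
#' @export
nmda_block <- function(v, mg_conc = 1) {
  if (mg_conc < 0)
    hv_stop("hippoval_parameter_error", "mg_conc must be >= 0")
  1 / (1 + (mg_conc / 3.57) * exp(-0.062 * v))
}

#' Normalized double-exponential conductance waveform
#'
#' `g(t) = N * (exp(-t/tau2) - exp(-t/tau1))` for `t >= 0` (0 before),
#' with `N` chosen so that the peak equals 1.  The peak occurs at
#' `t* = tau1*tau2/(tau2-tau1) * log(tau2/tau1)`.
#'
#' @param t time in ms (vectorized).
#' @param tau1 rise time constant, ms.
#' @param tau2 decay time constant, ms; must exceed `tau1`.
#' @return conductance values in `[0, 1]`.
#' @export
conductance_waveform <- function(t, tau1, tau2) {
  if (!(tau2 > tau1 && tau1 > 0))
    hv_stop("hippoval_parameter_error", "need tau2 > tau1 > 0")
  tp <- tau1 * tau2 / (tau2 - tau1) * log(tau2 / tau1)
  N <- 1 / (exp(-tp / tau2) - exp(-tp / tau1))
  ifelse(t < 0, 0, N * (exp(-t / tau2) - exp(-t / tau1)))
}

#' Calibration configuration for the oblique integration workflow
#'
#' @param c_minmax search interval `(low, high)` for the synaptic weight.
#' @param c_step_start initial search step (kept for interface
#'   compatibility; the bisection narrows the bracket from `c_minmax`).
#' @param c_step_stop minimum bracket width; the search stops, and the
#'   postcondition is verified, once the bracket is narrower than this.
#' @param target_count number of synchronous inputs that must first elicit
#'   a dendritic spike (default 5).
#' @param sync_interval inter-input interval for synchronous activation,
#'   ms (default 0.1).
#' @param async_interval inter-input interval for asynchronous activation,
#'   ms (default 2).
#' @param spike_threshold dendritic (and somatic) spike detection
#'   threshold, mV (default -20).
#' @param stim_delay onset of the first input, ms.
#' @param tstop simulated time per run, ms.
#' @return object of class `calibration_config`.
#' @export
calibration_config <- function(c_minmax = c(1e-4, 1.0), c_step_start = NULL,
                               c_step_stop = 1e-6, target_count = 5,
                               sync_interval = 0.1, async_interval = 2.0,
                               spike_threshold = -20,
                               stim_delay = 150, tstop = 400) {
  if (!(c_minmax[1] < c_minmax[2]))
    hv_stop("hippoval_parameter_error", "c_minmax low must be < high")
  if (c_step_stop <= 0)
    hv_stop("hippoval_parameter_error", "c_step_stop must be > 0")
  if (target_count < 2)
    hv_stop("hippoval_parameter_error", "target_count must be >= 2")
  structure(list(c_minmax = c_minmax,
                 c_step_start = c_step_start %||% diff(c_minmax) / 2,
                 c_step_stop = c_step_stop, target_count = target_count,
                 sync_interval = sync_interval, async_interval = async_interval,
                 spike_threshold = spike_threshold,
                 stim_delay = stim_delay, tstop = tstop),
            class = "calibration_config")
}

#' Calibrate the synaptic weight for the dendritic-spike threshold
#'
#' Bisects the weight interval `cfg$c_minmax` so that activating
#' `cfg$target_count` synchronous inputs at the location first elicits a
#' detected dendritic spike while `target_count - 1` inputs do not.  After
#' the bracket collapses below `cfg$c_step_stop` the postcondition is
#' verified by re-simulation at both input counts.  Locations where the
#' threshold dendritic spike also triggers a somatic action potential, or
#' where no dendritic spike can be evoked at the top of the interval, are
#' excluded from further analysis.
#'
#' @param model a model providing the synaptic activation capability.
#' @param location a location row (see [select_locations_by_distance()]).
#' @param cfg a [calibration_config()].
#' @return object of class `oblique_calibration`: list with `status`
#'   (`"ok"` or `"excluded"`), `weight` (NA when excluded), `note` and
#'   `n_iterations`.
#' @export
calibrate_oblique_weight <- function(model, location, cfg = calibration_config()) {
  require_capability(model, "synaptic_activation", "oblique weight calibration")

  run <- function(n, w) synaptic_response(model, location, weight = w,
                                          count = n,
                                          interval = cfg$sync_interval,
                                          tstop = cfg$tstop,
                                          delay = cfg$stim_delay)
  dspike <- function(tr) nrow(detect_spikes(tr$dendrite, cfg$spike_threshold)) > 0
  sspike <- function(tr) nrow(detect_spikes(tr$soma, cfg$spike_threshold)) > 0

  lo <- cfg$c_minmax[1]; hi <- cfg$c_minmax[2]
  if (!dspike(run(cfg$target_count, hi)))
    return(structure(list(status = "excluded", weight = NA_real_,
                          note = "no dendritic spike can be evoked at the top of the search interval",
                          n_iterations = 1L),
                     class = "oblique_calibration"))
  it <- 0L
  while (hi - lo > cfg$c_step_stop) {
    it <- it + 1L
    mid <- (lo + hi) / 2
    if (dspike(run(cfg$target_count, mid))) hi <- mid else lo <- mid
    if (it > 200L) break
  }
  w <- hi
  ok_at <- dspike(run(cfg$target_count, w))
  ok_below <- !dspike(run(cfg$target_count - 1L, w))
  if (!ok_at || !ok_below)
    return(structure(list(status = "excluded", weight = NA_real_,
                          note = sprintf(
                            "calibration postcondition failed (spike at %d inputs: %s, at %d inputs: %s)",
                            cfg$target_count, ok_at, cfg$target_count - 1L, !ok_below),
                          n_iterations = it),
                     class = "oblique_calibration"))
  if (sspike(run(cfg$target_count, w)))
    return(structure(list(status = "excluded", weight = NA_real_,
                          note = "threshold dendritic spike triggers a somatic action potential",
                          n_iterations = it),
                     class = "oblique_calibration"))
  structure(list(status = "ok", weight = w, note = "", n_iterations = it),
            class = "oblique_calibration")
}
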