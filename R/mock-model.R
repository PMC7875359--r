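# Deterministic phenomenological model backend.  Every capability call is
# a pure function of (parameters, protocol): no ODEs are solved, traces
# are rendered in closed form, and repeated calls are byte-identical.
# The parameter family spans all branches of every test: non-spiking,
# regular spiking, genuine depolarization block, "cheating" block (AP
# amplitudes shrinking below the detection threshold while the membrane
# never settles), strong/weak bAP propagation, linear and supralinear
# dendrites.

#' Parameters of the mock model backend
#'
#' @param v_rest resting potential, mV.
#' @param r_in input resistance, MOhm (deflection = amplitude * r_in).
#' @param tau_m membrane time constant, ms.
#' @param sag_fraction relative size of the sag overshoot in `[0, 1)`;
#'   the steady/peak deflection ratio (sag_ratio2) is about
#'   `1/(1+sag_fraction)`.
#' @param sag_onset time into the stimulus at which the sag overshoot
#'   starts to decay, ms (`NA` = `5*tau_m`, i.e. once charging is
#'   complete).
#' @param sag_tau_decay decay time constant of the sag overshoot, ms.
#' @param depol_cap ceiling on the depolarizing subthreshold deflection,
#'   mV; keeps the inter-spike baseline below the spike detection
#'   threshold at strong currents (hyperpolarizing responses are not
#'   capped).
#' @param rheobase lowest amplitude that elicits spikes, nA.
#' @param fi_slope firing-rate gain above rheobase, Hz/nA.
#' @param fi_rollover `NULL`, or `list(I_start, slope_down, floor)`: above
#'   `I_start` the rate declines at `slope_down` Hz/nA (never below
#'   `floor`), so the spike count peaks before any block.
#' @param latency_base,latency_gain first-spike latency,
#'   `latency_base / (1 + latency_gain*(I - rheobase))` ms.
#' @param ap_peak somatic AP peak, mV (absolute).
#' @param ap_rise,ap_fall rise/fall times of the stereotyped triangular AP
#'   waveform, ms.
#' @param block `list(enabled, I_block, t_block, v_eq, max_spikes, cheat,
#'   cheat_peak)`: for amplitudes >= `I_block` the cell fires at most
#'   `max_spikes` APs, firing ceases at `t_block` ms into the stimulus
#'   and the membrane settles at `v_eq`; with `cheat = TRUE` the membrane
#'   never settles but AP peaks after `t_block` shrink to `cheat_peak`
#'   (below the detection threshold) instead.
#' @param bap_profile `list(A0, plateau, lambda, last_ap_scale)`:
#'   dendritic AP amplitude `plateau + (A0-plateau)*exp(-d/lambda)` at
#'   path distance `d`; `A0 = NA` defaults to the somatic AP amplitude;
#'   the last AP of a train is additionally scaled by `last_ap_scale`.
#' @param psp_lambda dendrite-to-soma EPSP attenuation length constant, um.
#' @param somatic_coupling proximal soma/dendrite transfer ratio; the
#'   somatic EPSP is `somatic_coupling * exp(-d/psp_lambda)` times the
#'   local one.
#' @param dendrite `list(unitary_epsp, spike_threshold_weight, spike_amp,
#'   spike_coupling_scale, sync_cutoff, dspike_latency, dspike_rise,
#'   dspike_fall, somatic_ap_on_dspike)`: the local EPSP is
#'   `count * weight * unitary_epsp` mV (linear superposition); a
#'   dendritic spike of amplitude `spike_amp` fires iff the inputs are
#'   synchronous (interval <= `sync_cutoff` ms) and
#'   `count * weight >= spike_threshold_weight`; only
#'   `spike_coupling_scale` of the spike component (on top of the
#'   distance-dependent EPSP transfer) reaches the soma; `NULL` disables
#'   dendritic spikes entirely (a perfectly linear dendrite).
#' @param syn_tau1,syn_tau2 local EPSP kernel time constants, ms.
#' @param dt default sampling step, ms (0.025).
#' @param v_init,celsius simulation settings echoed by
#'   [simulation_settings()].
#' @return list of class `mock_params`.
#' @export
mock_params <- function(v_rest = -70, r_in = 60, tau_m = 20,
                        sag_fraction = 0.25, sag_onset = NA,
                        sag_tau_decay = 150, depol_cap = 15,
                        rheobase = 0.1, fi_slope = 30, fi_rollover = NULL,
                        latency_base = 8, latency_gain = 4,
                        ap_peak = 35, ap_rise = 0.6, ap_fall = 1.4,
                        block = list(enabled = FALSE, I_block = NA,
                                     t_block = 400, v_eq = -42,
                                     max_spikes = 5,
                                     cheat = FALSE, cheat_peak = -35),
                        bap_profile = list(A0 = NA, plateau = 45,
                                           lambda = 150, last_ap_scale = 1),
                        psp_lambda = 200, somatic_coupling = 0.8,
                        dendrite = list(unitary_epsp = 10,
                                        spike_threshold_weight = 0.5,
                                        spike_amp = 55,
                                        spike_coupling_scale = 0.08,
                                        sync_cutoff = 0.5,
                                        dspike_latency = 1, dspike_rise = 1,
                                        dspike_fall = 3,
                                        somatic_ap_on_dspike = FALSE),
                        syn_tau1 = 0.5, syn_tau2 = 5,
                        dt = 0.025, v_init = v_rest, celsius = "34") {
  p <- as.list(environment())
  defaults <- list(
    block = eval(formals(mock_params)$block),
    bap_profile = eval(formals(mock_params)$bap_profile),
    dendrite = eval(formals(mock_params)$dendrite))
  for (nm in names(defaults))
    if (!is.null(p[[nm]])) p[[nm]] <- modifyList(defaults[[nm]], p[[nm]])
  stopifnot(p$tau_m > 0, p$fi_slope >= 0, p$psp_lambda > 0,
            p$sag_fraction >= 0, p$sag_fraction < 1)
  class(p) <- "mock_params"
  p
}

#' Construct a mock model
#'
#' @param params a [mock_params()] list.
#' @param morphology a `morph_tree` (default: [generate_morphology()] of
#'   the default synthetic spec).
#' @param min_apical_distance threshold for the apical-point search used
#'   to classify the morphology.
#' @return object of class `mock_model` implementing the full capability
#'   contract.
#' @export
mock_model <- function(params = mock_params(), morphology = NULL,
                       min_apical_distance = 100) {
  if (is.null(morphology)) morphology <- generate_morphology()
  cls <- classify_apical(morphology,
                         find_apical_points(morphology, min_apical_distance))
  structure(list(params = params, tree = morphology, classification = cls),
            class = c("mock_model", "hippo_model"))
}

#' Load a mock model from a JSON parameter file
#'
#' The file may contain a `params` object (any subset of [mock_params()]
#' fields) and a `morphology` object (any subset of [morphology_spec()]
#' fields); omitted fields take their defaults.
#'
#' @param path path to the JSON file.
#' @return a [mock_model()].
#' @export
mock_model_from_file <- function(path) {
  if (!file.exists(path))
    hv_stop("hippoval_io_error", "model file '%s' not found", path)
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- do.call(mock_params, as.list(spec$params))
  morph <- generate_morphology(do.call(morphology_spec,
                                       as.list(spec$morphology)))
  mock_model(params, morph)
}

#' @export
capabilities.mock_model <- function(model)
  c("step_current", "synaptic_activation", "morphology")

#' @export
simulation_settings.mock_model <- function(model)
  list(v_init = model$params$v_init, celsius = model$params$celsius,
       dt = model$params$dt)

#' @export
model_morphology.mock_model <- function(model)
  list(tree = model$tree, classification = model$classification)

#' @export
print.mock_model <- function(x, ...) {
  cat(sprintf("<mock_model> v_rest %g mV, rheobase %g nA, f-I slope %g Hz/nA, block %s\n",
              x$params$v_rest, x$params$rheobase, x$params$fi_slope,
              if (isTRUE(x$params$block$enabled)) "enabled" else "disabled"))
  invisible(x)
}

# spike times of the mock f-I mechanism (before any block truncation)
mock_spike_times <- function(p, I, delay, duration) {
  if (I < p$rheobase || p$fi_slope <= 0) return(numeric(0))
  rate <- p$fi_slope * (I - p$rheobase)
  ro <- p$fi_rollover
  if (!is.null(ro) && I > ro$I_start) {
    rate <- p$fi_slope * (ro$I_start - p$rheobase) -
      ro$slope_down * (I - ro$I_start)
    rate <- max(rate, ro$floor %||% 2)
  }
  n <- floor(rate * duration / 1000)
  if (n < 1) return(numeric(0))
  isi <- 1000 / rate
  lat <- p$latency_base / (1 + p$latency_gain * (I - p$rheobase))
  times <- delay + lat + (seq_len(n) - 1) * isi
  times[times <= delay + duration]
}

# blend a triangular AP reaching `peak_abs` into the baseline vector
.render_spike <- function(v, t, ts, peak_abs, rise, fall) {
  i <- which(t >= ts & t <= ts + rise + fall)
  if (!length(i)) return(v)
  frac <- ifelse(t[i] <= ts + rise, (t[i] - ts) / rise,
                 pmax(0, 1 - (t[i] - ts - rise) / fall))
  v[i] <- v[i] + (peak_abs - v[i]) * frac
  v
}

.mock_subthreshold <- function(p, t, I, delay, duration) {
  v <- rep(p$v_rest, length(t))
  S <- I * p$r_in
  s <- t - delay
  onset <- if (is.na(p$sag_onset)) 5 * p$tau_m else p$sag_onset
  defl <- function(s) {
    d <- S * (1 - exp(-s / p$tau_m)) *
      (1 + p$sag_fraction * exp(-pmax(0, s - onset) / p$sag_tau_decay))
    if (S > 0) pmin(d, p$depol_cap) else d
  }
  instim <- s >= 0 & s <= duration
  v[instim] <- p$v_rest + defl(s[instim])
  post <- s > duration
  if (any(post))
    v[post] <- p$v_rest + defl(duration) * exp(-(s[post] - duration) / p$tau_m)
  v
}

#' @export
step_current_response.mock_model <- function(model, amplitude, delay,
                                             duration, tstop, sites = "soma",
                                             dt = NULL) {
  p <- model$params
  dt <- dt %||% p$dt
  t <- seq(0, tstop, by = dt)
  if (is.character(sites)) sites <- as.list(sites)
  if (is.data.frame(sites)) sites <- split(sites, seq_len(nrow(sites)))
  else if (!is.null(sites$path_distance)) sites <- list(sites)

  blocking <- isTRUE(p$block$enabled) && !is.na(p$block$I_block) &&
    amplitude >= p$block$I_block
  times <- mock_spike_times(p, amplitude, delay, duration)
  tb <- delay + min(p$block$t_block, duration)
  if (blocking && !isTRUE(p$block$cheat))
    times <- head(times[times < tb], p$block$max_spikes %||% 5)

  sub <- .mock_subthreshold(p, t, amplitude, delay, duration)
  if (blocking && !isTRUE(p$block$cheat)) {
    end <- delay + duration
    settle <- t >= tb & t <= end
    v_tb <- sub[which(settle)[1]]
    sub[settle] <- p$block$v_eq + (v_tb - p$block$v_eq) *
      exp(-(t[settle] - tb) / 5)
    post <- t > end
    sub[post] <- p$v_rest + (p$block$v_eq - p$v_rest) *
      exp(-(t[post] - end) / p$tau_m)
  }

  A0 <- p$bap_profile$A0
  if (is.na(A0)) A0 <- p$ap_peak - p$v_rest

  out <- lapply(seq_along(sites), function(k) {
    site <- sites[[k]]
    somatic <- is.character(site) && identical(site, "soma")
    v <- sub
    d <- if (somatic) 0 else site$path_distance
    amp_d <- p$bap_profile$plateau +
      (A0 - p$bap_profile$plateau) * exp(-d / p$bap_profile$lambda)
    for (j in seq_along(times)) {
      ts <- times[j]
      cheat_now <- blocking && isTRUE(p$block$cheat) && ts >= tb
      if (somatic) {
        peak <- if (cheat_now) p$block$cheat_peak else p$ap_peak
      } else {
        a <- amp_d
        if (j == length(times)) a <- a * p$bap_profile$last_ap_scale
        if (cheat_now) a <- a * 0.2
        base <- sub[which.min(abs(t - ts))]
        peak <- base + a
      }
      v <- .render_spike(v, t, ts, peak, p$ap_rise, p$ap_fall)
    }
    label <- if (somatic) "soma"
             else (site$label %||% sprintf("dend_%.6g", d))
    voltage_trace(t, v, stim_delay = delay, stim_duration = duration,
                  stim_amplitude = amplitude, recording_site = label)
  })
  names(out) <- vapply(out, `[[`, "", "recording_site")
  out
}

#' @export
synaptic_response.mock_model <- function(model, location, weight, count,
                                         interval, tstop, delay = 150,
                                         dt = NULL) {
  p <- model$params
  dt <- dt %||% p$dt
  t <- seq(0, tstop, by = dt)
  d <- location$path_distance
  dend <- p$dendrite

  depol <- numeric(length(t))
  if (count > 0) {
    A_unit <- weight * (dend$unitary_epsp %||% 10)
    for (k in 0:(count - 1))
      depol <- depol + A_unit *
        conductance_waveform(t - (delay + k * interval), p$syn_tau1, p$syn_tau2)
  }
  fire <- !is.null(dend$spike_threshold_weight) && count > 0 &&
    interval <= dend$sync_cutoff &&
    count * weight >= dend$spike_threshold_weight
  spike_comp <- numeric(length(t))
  if (fire) {
    ts <- delay + (count - 1) * interval + dend$dspike_latency
    s <- t - ts
    tri <- ifelse(s < 0 | s > dend$dspike_rise + dend$dspike_fall, 0,
                  ifelse(s <= dend$dspike_rise, s / dend$dspike_rise,
                         pmax(0, 1 - (s - dend$dspike_rise) / dend$dspike_fall)))
    spike_comp <- dend$spike_amp * tri
  }
  factor <- p$somatic_coupling * exp(-d / p$psp_lambda)
  stim_dur <- if (count > 0) (count - 1) * interval else 0
  dend_tr <- voltage_trace(t, p$v_rest + depol + spike_comp,
                           stim_delay = delay,
                           stim_duration = stim_dur,
                           stim_amplitude = weight * count,
                           recording_site = location$label %||%
                             sprintf("dend_%.6g", d))
  vs <- p$v_rest + factor *
    (depol + (dend$spike_coupling_scale %||% 1) * spike_comp)
  if (fire && isTRUE(dend$somatic_ap_on_dspike)) {
    ts <- delay + (count - 1) * interval + dend$dspike_latency + 1
    vs <- .render_spike(vs, t, ts, 30, 0.5, 1.5)
  }
  soma_tr <- voltage_trace(t, vs, stim_delay = delay,
                           stim_duration = stim_dur,
                           stim_amplitude = weight * count,
                           recording_site = "soma")
  list(soma = soma_tr, dendrite = dend_tr)
}
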