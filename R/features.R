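# Electrophysiological feature registry.
#
# Each entry documents its exact formula and windowing.  Names are
# compatible with the widely used eFEL naming so observation files written
# against that library's vocabulary work unchanged.  Vector features
# produce one element per action potential; entries flagged
# `begin_dependent` derive from the AP begin point, which is often
# mis-detected on the first AP of a train, so the first element is dropped
# before averaging (see average_vector_feature).

# -- window helpers ---------------------------------------------------------

.f_voltage_base <- function(trace) {
  d <- trace$stim_delay
  if (d > 0) tw_mean(trace, 0.9 * d, d)
  else tw_mean(trace, trace$t[1], trace$t[1] + 0.1 * diff(range(trace$t)))
}

.f_ss_stimend <- function(trace) {
  e <- stim_end(trace)
  tw_mean(trace, e - 0.1 * trace$stim_duration, e)
}

.f_min_v <- function(trace) {
  sel <- trace$t >= trace$stim_delay & trace$t <= stim_end(trace)
  min(trace$v[sel])
}

# level-crossing times on the rise and fall of one spike; frac = 0 gives
# the width at the AP begin voltage, frac = 0.5 the half-amplitude width
.spike_level_times <- function(trace, spikes, i, frac) {
  sp <- spikes[i, ]
  L <- sp$begin_voltage + frac * (sp$peak_voltage - sp$begin_voltage)
  t <- trace$t; v <- trace$v; n <- length(v)
  rise <- NA_real_
  if (sp$begin_idx < sp$peak_idx) {
    idx <- (sp$begin_idx + 1L):sp$peak_idx
    hit <- idx[v[idx] >= L & v[idx - 1L] < L]
    if (length(hit)) {
      i1 <- hit[1]
      rise <- t[i1 - 1L] + (L - v[i1 - 1L]) / (v[i1] - v[i1 - 1L]) * (t[i1] - t[i1 - 1L])
    } else if (v[sp$begin_idx] >= L) rise <- sp$begin_time
  } else rise <- sp$begin_time
  fall <- NA_real_
  stop_idx <- if (i < nrow(spikes)) spikes$begin_idx[i + 1L] else n
  if (sp$peak_idx < stop_idx) {
    idx <- (sp$peak_idx + 1L):stop_idx
    hit <- idx[v[idx] <= L & v[idx - 1L] > L]
    if (length(hit)) {
      i1 <- hit[1]
      fall <- t[i1 - 1L] + (L - v[i1 - 1L]) / (v[i1] - v[i1 - 1L]) * (t[i1] - t[i1 - 1L])
    }
  }
  c(rise = rise, fall = fall)
}

.per_spike <- function(trace, spikes, fn) {
  if (nrow(spikes) == 0) return(numeric(0))
  vapply(seq_len(nrow(spikes)), function(i) fn(i), numeric(1))
}

.ahp_min <- function(trace, spikes, i, from_ms, to_ms) {
  t0 <- spikes$peak_time[i] + from_ms
  t1 <- spikes$peak_time[i] + to_ms
  if (i < nrow(spikes)) t1 <- min(t1, spikes$begin_time[i + 1L])
  t1 <- min(t1, trace$t[length(trace$t)])
  if (t1 <= t0) return(NA_real_)
  sel <- trace$t >= t0 & trace$t <= t1
  if (!any(sel)) NA_real_ else min(trace$v[sel])
}

# -- registry ---------------------------------------------------------------

.hv_entry <- function(units, vector, begin_dependent, needs_spikes, formula, fn) {
  list(units = units, vector = vector, begin_dependent = begin_dependent,
       needs_spikes = needs_spikes, formula = formula, fn = fn)
}

.hv_registry <- local({
  r <- list()

  r$voltage_base <- .hv_entry("mV", FALSE, FALSE, FALSE,
    "time-weighted mean V over [0.9*stim_delay, stim_delay]",
    function(trace, spikes) .f_voltage_base(trace))

  r$steady_state_voltage <- .hv_entry("mV", FALSE, FALSE, FALSE,
    "time-weighted mean V from stimulus end to end of trace",
    function(trace, spikes) {
      e <- stim_end(trace); tl <- trace$t[length(trace$t)]
      if (tl - e < 1e-9) return(NA_real_)
      tw_mean(trace, e, tl)
    })

  r$steady_state_voltage_stimend <- .hv_entry("mV", FALSE, FALSE, FALSE,
    "time-weighted mean V over the last 10% of the stimulus",
    function(trace, spikes) .f_ss_stimend(trace))

  r$voltage_deflection <- .hv_entry("mV", FALSE, FALSE, FALSE,
    "steady_state_voltage_stimend - voltage_base",
    function(trace, spikes) .f_ss_stimend(trace) - .f_voltage_base(trace))

  r$minimum_voltage <- .hv_entry("mV", FALSE, FALSE, FALSE,
    "minimum V during the stimulus window",
    function(trace, spikes) .f_min_v(trace))

  r$sag_amplitude <- .hv_entry("mV", FALSE, FALSE, FALSE,
    "steady_state_voltage_stimend - minimum_voltage",
    function(trace, spikes) .f_ss_stimend(trace) - .f_min_v(trace))

  r$sag_ratio2 <- .hv_entry("", FALSE, FALSE, FALSE,
    "(voltage_base - steady_state_voltage_stimend) / (voltage_base - minimum_voltage)",
    function(trace, spikes) {
      vb <- .f_voltage_base(trace); mv <- .f_min_v(trace)
      if (abs(vb - mv) < 1e-12) return(NA_real_)
      (vb - .f_ss_stimend(trace)) / (vb - mv)
    })

  r$spikecount <- .hv_entry("", FALSE, FALSE, FALSE,
    "number of detected action potentials",
    function(trace, spikes) nrow(spikes))

  r$mean_frequency <- .hv_entry("Hz", FALSE, FALSE, TRUE,
    "1000 * spikecount / stim_duration",
    function(trace, spikes) {
      if (trace$stim_duration <= 0) return(NA_real_)
      1000 * nrow(spikes) / trace$stim_duration
    })

  r$ISI_values <- .hv_entry("ms", TRUE, FALSE, TRUE,
    "differences between consecutive AP peak times",
    function(trace, spikes) if (nrow(spikes) < 2) numeric(0) else diff(spikes$peak_time))

  isi_pick <- function(which) function(trace, spikes) {
    isi <- if (nrow(spikes) < 2) numeric(0) else diff(spikes$peak_time)
    idx <- switch(which, first = 1L, second = 2L, last = length(isi))
    if (length(isi) < idx || idx < 1L) NA_real_ else 1000 / isi[idx]
  }
  r$inv_first_ISI <- .hv_entry("Hz", FALSE, FALSE, TRUE,
    "1000 / first inter-spike interval", isi_pick("first"))
  r$inv_second_ISI <- .hv_entry("Hz", FALSE, FALSE, TRUE,
    "1000 / second inter-spike interval", isi_pick("second"))
  r$inv_last_ISI <- .hv_entry("Hz", FALSE, FALSE, TRUE,
    "1000 / last inter-spike interval", isi_pick("last"))

  r$time_to_first_spike <- .hv_entry("ms", FALSE, FALSE, TRUE,
    "first AP peak time - stim_delay",
    function(trace, spikes) spikes$peak_time[1] - trace$stim_delay)
  r$inv_time_to_first_spike <- .hv_entry("Hz", FALSE, FALSE, TRUE,
    "1000 / time_to_first_spike",
    function(trace, spikes) 1000 / (spikes$peak_time[1] - trace$stim_delay))
  r$time_to_last_spike <- .hv_entry("ms", FALSE, FALSE, TRUE,
    "last AP peak time - stim_delay",
    function(trace, spikes) spikes$peak_time[nrow(spikes)] - trace$stim_delay)

  r$AP_begin_time <- .hv_entry("ms", TRUE, TRUE, TRUE,
    "per AP: begin time from the rising-phase derivative criterion",
    function(trace, spikes) spikes$begin_time)
  r$AP_begin_voltage <- .hv_entry("mV", TRUE, TRUE, TRUE,
    "per AP: voltage at the begin point",
    function(trace, spikes) spikes$begin_voltage)

  r$AP_amplitude <- .hv_entry("mV", TRUE, TRUE, TRUE,
    "per AP: peak voltage - begin voltage",
    function(trace, spikes) spikes$peak_voltage - spikes$begin_voltage)

  r$AP_amplitude_from_voltagebase <- .hv_entry("mV", TRUE, FALSE, TRUE,
    "per AP: peak voltage - voltage_base",
    function(trace, spikes) spikes$peak_voltage - .f_voltage_base(trace))

  r$AP2_amp <- .hv_entry("mV", FALSE, FALSE, TRUE,
    "second AP: peak voltage - begin voltage",
    function(trace, spikes) {
      if (nrow(spikes) < 2) NA_real_
      else spikes$peak_voltage[2] - spikes$begin_voltage[2]
    })

  r$APlast_amp <- .hv_entry("mV", FALSE, FALSE, TRUE,
    "last AP: peak voltage - voltage_base",
    function(trace, spikes) spikes$peak_voltage[nrow(spikes)] - .f_voltage_base(trace))

  r$AP_width <- .hv_entry("ms", TRUE, TRUE, TRUE,
    "per AP: time above the begin voltage (interpolated crossings)",
    function(trace, spikes) .per_spike(trace, spikes, function(i) {
      ct <- .spike_level_times(trace, spikes, i, 0)
      ct["fall"] - ct["rise"]
    }))

  r$AP_duration_half_width <- .hv_entry("ms", TRUE, TRUE, TRUE,
    "per AP: time above begin voltage + half amplitude",
    function(trace, spikes) .per_spike(trace, spikes, function(i) {
      ct <- .spike_level_times(trace, spikes, i, 0.5)
      ct["fall"] - ct["rise"]
    }))

  r$AP_rise_time <- .hv_entry("ms", TRUE, TRUE, TRUE,
    "per AP: peak time - begin time",
    function(trace, spikes) spikes$peak_time - spikes$begin_time)

  r$AP_rise_rate <- .hv_entry("V/s", TRUE, TRUE, TRUE,
    "per AP: (peak V - begin V) / (peak t - begin t)",
    function(trace, spikes) {
      dt <- spikes$peak_time - spikes$begin_time
      ifelse(dt > 0, (spikes$peak_voltage - spikes$begin_voltage) / dt, NA_real_)
    })

  r$AP_fall_time <- .hv_entry("ms", TRUE, TRUE, TRUE,
    "per AP: time from peak back down to the begin voltage",
    function(trace, spikes) .per_spike(trace, spikes, function(i) {
      ct <- .spike_level_times(trace, spikes, i, 0)
      ct["fall"] - spikes$peak_time[i]
    }))

  r$AP_fall_rate <- .hv_entry("V/s", TRUE, TRUE, TRUE,
    "per AP: (begin V - peak V) / fall time (negative)",
    function(trace, spikes) .per_spike(trace, spikes, function(i) {
      ct <- .spike_level_times(trace, spikes, i, 0)
      ft <- ct["fall"] - spikes$peak_time[i]
      if (!is.finite(ft) || ft <= 0) NA_real_
      else (spikes$begin_voltage[i] - spikes$peak_voltage[i]) / ft
    }))

  r$AHP_depth_fast <- .hv_entry("mV", TRUE, FALSE, TRUE,
    "per AP: voltage_base - min V within 5 ms after the peak",
    function(trace, spikes) {
      vb <- .f_voltage_base(trace)
      .per_spike(trace, spikes, function(i) {
        m <- .ahp_min(trace, spikes, i, 0, 5)
        if (is.na(m)) NA_real_ else vb - m
      })
    })

  r$AHP_depth_slow <- .hv_entry("mV", TRUE, FALSE, TRUE,
    "per AP: voltage_base - min V in [5, 20] ms after the peak",
    function(trace, spikes) {
      vb <- .f_voltage_base(trace)
      .per_spike(trace, spikes, function(i) {
        m <- .ahp_min(trace, spikes, i, 5, 20)
        if (is.na(m)) NA_real_ else vb - m
      })
    })

  r
})

#' The supported feature registry
#'
#' @return data.frame with one row per supported feature: `name`, `units`,
#'   `vector` (one value per AP), `begin_dependent` (first vector element
#'   dropped before averaging), `formula`.
#' @export
feature_registry <- function() {
  data.frame(
    name = names(.hv_registry),
    units = vapply(.hv_registry, `[[`, "", "units"),
    vector = vapply(.hv_registry, `[[`, TRUE, "vector"),
    begin_dependent = vapply(.hv_registry, `[[`, TRUE, "begin_dependent"),
    formula = vapply(.hv_registry, `[[`, "", "formula"),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Average a vector feature with the first-AP exclusion rule
#'
#' Spiking features are extracted per action potential; the value a test
#' uses is the mean of the vector.  For features derived from the AP begin
#' point (flagged `begin_dependent` in [feature_registry()]) the first
#' element is dropped before averaging, because the begin point of the
#' first AP of a train is frequently mis-detected.  Non-finite elements
#' (truncated last spikes etc.) are dropped too.
#'
#' @param feature_key registry feature name.
#' @param raw numeric vector of per-AP values.
#' @return the mean, or `NA_real_` when nothing remains after exclusion
#'   (the feature is then unevaluable).
#' @export
average_vector_feature <- function(feature_key, raw) {
  entry <- .hv_registry[[feature_key]]
  if (is.null(entry))
    hv_stop("hippoval_registry_error", "unknown feature '%s'", feature_key)
  if (entry$begin_dependent && length(raw) >= 1) raw <- raw[-1]
  raw <- raw[is.finite(raw)]
  if (length(raw) == 0) NA_real_ else mean(raw)
}

#' Extract one feature from a voltage trace
#'
#' @param trace a [voltage_trace()].
#' @param feature_key name of a registry feature ([feature_registry()]).
#' @param spike_threshold detection threshold passed to [detect_spikes()].
#' @return object of class `hippo_feature`: `feature_key`, `raw` (per-AP
#'   vector for vector features), `scalar` (post-averaging value),
#'   `units`, `evaluable`.  Spiking features on spikeless traces are
#'   flagged unevaluable, never reported as zero.
#' @export
extract_feature <- function(trace, feature_key, spike_threshold = -20) {
  entry <- .hv_registry[[feature_key]]
  if (is.null(entry))
    hv_stop("hippoval_registry_error", "unknown feature '%s'", feature_key)
  spikes <- detect_spikes(trace, threshold = spike_threshold)
  if (entry$needs_spikes && nrow(spikes) == 0) {
    raw <- numeric(0); scalar <- NA_real_
  } else {
    raw <- entry$fn(trace, spikes)
    scalar <- if (entry$vector) average_vector_feature(feature_key, raw)
              else as.numeric(raw)[1]
  }
  structure(list(feature_key = feature_key, raw = raw, scalar = scalar,
                 units = entry$units,
                 evaluable = is.finite(scalar)),
            class = "hippo_feature")
}

#' @export
print.hippo_feature <- function(x, ...) {
  cat(sprintf("<feature %s> %s %s%s\n", x$feature_key,
              if (x$evaluable) format(x$scalar) else "unevaluable",
              x$units,
              if (length(x$raw) > 1) sprintf(" (from %d APs)", length(x$raw)) else ""))
  invisible(x)
}
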