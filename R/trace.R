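#' Voltage trace container
#'
#' The universal currency between models and tests: a sampled somatic or
#' dendritic membrane-potential time series together with the stimulus
#' metadata the feature extractors need.
#'
#' @param t time points in ms, strictly increasing, length >= 2.  Sampling
#'   need not be uniform; all window statistics downstream are
#'   time-weighted.
#' @param v membrane potential in mV, same length as `t`.
#' @param stim_delay stimulus onset in ms (>= 0).
#' @param stim_duration stimulus duration in ms.
#' @param stim_amplitude stimulus amplitude in nA.
#' @param recording_site free-form location label (e.g. `"soma"`,
#'   `"trunk_150"`).
#' @return An object of class `voltage_trace`.
#' @examples
#' tr <- voltage_trace(seq(0, 100, 0.1), rep(-70, 1001),
#'                     stim_delay = 10, stim_duration = 50)
#' resting_vm(tr)
#' @export
voltage_trace <- function(t, v, stim_delay = 0, stim_duration = 0,
                          stim_amplitude = 0, recording_site = "soma") {
  t <- as.numeric(t); v <- as.numeric(v)
  if (length(t) != length(v) || length(t) < 2)
    hv_stop("hippoval_trace_error", "t and v must have equal length >= 2")
  if (any(diff(t) <= 0))
    hv_stop("hippoval_trace_error", "t must be strictly increasing")
  if (stim_delay < 0)
    hv_stop("hippoval_trace_error", "stim_delay must be >= 0")
  if (stim_delay + stim_duration > t[length(t)] + 1e-9)
    hv_stop("hippoval_trace_error",
            "stimulus window [%g, %g] extends past end of trace (%g ms)",
            stim_delay, stim_delay + stim_duration, t[length(t)])
  structure(list(t = t, v = v, stim_delay = stim_delay,
                 stim_duration = stim_duration,
                 stim_amplitude = stim_amplitude,
                 recording_site = recording_site),
            class = "voltage_trace")
}

#' @export
print.voltage_trace <- function(x, ...) {
  cat(sprintf(
    "<voltage_trace> %s: %d samples over %.6g ms, stim %.6g nA at [%.6g, %.6g] ms\n",
    x$recording_site, length(x$t), x$t[length(x$t)] - x$t[1],
    x$stim_amplitude, x$stim_delay, x$stim_delay + x$stim_duration))
  invisible(x)
}

stim_end <- function(trace) trace$stim_delay + trace$stim_duration

# Trapezoid (time-weighted) mean of v over [t0, t1], interpolating the
# window edges so the result is robust to non-uniform sampling.
tw_mean <- function(trace, t0, t1) {
  t <- trace$t; v <- trace$v
  t0 <- max(t0, t[1]); t1 <- min(t1, t[length(t)])
  if (t1 <= t0) hv_stop("hippoval_trace_error", "empty averaging window")
  inside <- t > t0 & t < t1
  tt <- c(t0, t[inside], t1)
  vv <- c(approx(t, v, t0)$y, v[inside], approx(t, v, t1)$y)
  dt <- diff(tt)
  sum(dt * (head(vv, -1) + tail(vv, -1)) / 2) / (t1 - t0)
}

# Linear interpolation of the trace voltage at a single time point.
v_at <- function(trace, time) approx(trace$t, trace$v, time, rule = 2)$y

# Maximum voltage within [t0, t1] (sample-based; traces are densely sampled).
max_in_window <- function(trace, t0, t1) {
  sel <- trace$t >= t0 & trace$t <= t1
  if (!any(sel)) hv_stop("hippoval_trace_error", "empty window [%g, %g]", t0, t1)
  max(trace$v[sel])
}

#' Resting membrane potential from a baseline trace
#'
#' Time-weighted mean of the membrane potential over the final 10% of the
#' trace.  Used by the PSP attenuation workflow on a zero-weight run before
#' converting the target EPSC amplitude into a synaptic weight.
#'
#' @param trace a [voltage_trace()] recorded with synaptic weight 0.
#' @return resting potential in mV.
#' @export
resting_vm <- function(trace) {
  if (length(trace$t) < 10)
    hv_stop("hippoval_trace_error",
            "trace too short (%d samples) to estimate resting Vm",
            length(trace$t))
  tl <- trace$t[length(trace$t)]
  tw_mean(trace, tl - 0.1 * (tl - trace$t[1]), tl)
}

# element-wise difference of two traces on the same time base
trace_subtract <- function(a, b) {
  if (length(a$t) != length(b$t) || max(abs(a$t - b$t)) > 1e-9)
    hv_stop("hippoval_trace_error", "traces are not on the same time base")
  out <- a
  out$v <- a$v - b$v
  out
}
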