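#' Detect somatic action potentials in a voltage trace
#'
#' One spike event is reported per upward crossing of the detection
#' threshold.  The spike begin point is located on the rising phase by a
#' derivative criterion: the first sample of the maximal contiguous run of
#' slopes `dV/dt >= deriv_threshold` (V/s) that ends at the threshold
#' crossing.  If that run is shorter than `min_rise_samples` the crossing
#' sample itself is used as the begin point.
#'
#' @param trace a [voltage_trace()].
#' @param threshold spike detection threshold in mV (default -20, the
#'   value used throughout the suite and overridable per test).
#' @param deriv_threshold rising-phase slope criterion in V/s (= mV/ms).
#' @param min_rise_samples minimum sustained-rise run length in samples.
#' @return data.frame with one row per spike: `begin_time`,
#'   `begin_voltage`, `peak_time`, `peak_voltage` plus internal sample
#'   indices `begin_idx`, `peak_idx`, `end_idx` (first sample back below
#'   threshold).  Zero rows when no spike crosses the threshold.
#' @export
detect_spikes <- function(trace, threshold = -20, deriv_threshold = 10,
                          min_rise_samples = 3) {
  t <- trace$t; v <- trace$v; n <- length(v)
  crossings <- which(v[-1] >= threshold & v[-n] < threshold) + 1L
  empty <- data.frame(begin_time = numeric(0), begin_voltage = numeric(0),
                      peak_time = numeric(0), peak_voltage = numeric(0),
                      begin_idx = integer(0), peak_idx = integer(0),
                      end_idx = integer(0))
  if (v[1] >= threshold) {
    # trace starts above threshold: count the initial excursion as a spike
    crossings <- c(1L, crossings)
  }
  if (!length(crossings)) return(empty)
  dvdt <- diff(v) / diff(t)
  prev_end <- 1L
  rows <- vector("list", length(crossings))
  for (k in seq_along(crossings)) {
    ci <- crossings[k]
    j <- ci
    while (j < n && v[j] >= threshold) j <- j + 1L
    seg <- ci:max(ci, j - 1L)
    pk <- seg[which.max(v[seg])]
    b <- ci
    while (b - 1L > prev_end && dvdt[b - 1L] >= deriv_threshold) b <- b - 1L
    if (ci - b < min_rise_samples && ci - b > 0 &&
        any(dvdt[b:(ci - 1L)] < deriv_threshold)) b <- ci
    rows[[k]] <- data.frame(begin_time = t[b], begin_voltage = v[b],
                            peak_time = t[pk], peak_voltage = v[pk],
                            begin_idx = b, peak_idx = pk, end_idx = j)
    prev_end <- j
  }
  do.call(rbind, rows)
}
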