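#' Find the current amplitude giving a 10-20 Hz spike train
#'
#' Applies increasing step currents (0 to 1 nA in 0.1 nA steps by
#' default), counts spikes, and selects the amplitude whose firing rate
#' lies in the 10-20 Hz band, preferring the one closest to 15 Hz.  If
#' the rate jumps over the band between two consecutive amplitudes, a
#' binary search on the bracketing interval is used.  Errors out on
#' spontaneous spiking (spikes at 0 nA) or when the rate never reaches
#' 10 Hz.
#'
#' @param model a model providing the `step_current` capability.
#' @param config list with `amplitudes` (nA), `delay`, `duration`,
#'   `tstop` (ms), `spike_threshold` (mV), `band` (Hz), `target_rate`
#'   (Hz), `max_bisect`.
#' @return list with `amplitude` (nA), `rate` (Hz), and the scanned
#'   `amplitudes`/`rates`.
#' @export
find_bap_amplitude <- function(model, config = list()) {
  require_capability(model, "step_current", "the bAP amplitude search")
  cfg <- modifyList(list(amplitudes = seq(0, 1, by = 0.1), delay = 500,
                         duration = 1000, tstop = 1700,
                         spike_threshold = -20, band = c(10, 20),
                         target_rate = 15, max_bisect = 30), config)
  rate_at <- function(a) {
    tr <- step_current_response(model, a, cfg$delay, cfg$duration,
                                cfg$tstop)$soma
    pt <- detect_spikes(tr, cfg$spike_threshold)$peak_time
    1000 * sum(pt >= cfg$delay & pt <= cfg$delay + cfg$duration) / cfg$duration
  }
  amps <- sort(cfg$amplitudes)
  rates <- vapply(amps, rate_at, numeric(1))
  if (any(abs(amps) < 1e-12) && rates[which(abs(amps) < 1e-12)[1]] > 0)
    hv_stop("hippoval_protocol_error",
            "spontaneous spiking: the model fires with no injected current")
  if (max(rates) < cfg$band[1])
    hv_stop("hippoval_protocol_error",
            "firing rate does not reach %g Hz even at %g nA (max %.3g Hz)",
            cfg$band[1], max(amps), max(rates))
  in_band <- which(rates >= cfg$band[1] & rates <= cfg$band[2])
  if (length(in_band)) {
    best <- in_band[which.min(abs(rates[in_band] - cfg$target_rate))]
    return(list(amplitude = amps[best], rate = rates[best],
                amplitudes = amps, rates = rates))
  }
  jump <- which(rates[-length(rates)] < cfg$band[1] &
                rates[-1] > cfg$band[2])
  if (!length(jump))
    hv_stop("hippoval_protocol_error",
            "no amplitude with firing rate in [%g, %g] Hz and no bracketing jump",
            cfg$band[1], cfg$band[2])
  lo <- amps[jump[1]]; hi <- amps[jump[1] + 1L]
  for (i in seq_len(cfg$max_bisect)) {
    mid <- (lo + hi) / 2
    r <- rate_at(mid)
    if (r >= cfg$band[1] && r <= cfg$band[2])
      return(list(amplitude = mid, rate = r, amplitudes = amps, rates = rates))
    if (r < cfg$band[1]) lo <- mid else hi <- mid
  }
  hv_stop("hippoval_protocol_error",
          "binary search failed to find a firing rate in [%g, %g] Hz",
          cfg$band[1], cfg$band[2])
}

#' Back-propagating AP amplitude at a dendritic location
#'
#' Somatic spike detection defines the measurement windows; no threshold
#' is applied to the dendritic trace, which the back-propagating signal
#' may never bring above a fixed detection level at distal sites.  The
#' amplitude of the chosen AP is the maximum of the dendritic voltage in
#' the window from the somatic AP begin time to the next somatic AP begin
#' (for the last AP, one preceding inter-begin interval wide), minus the
#' dendritic voltage 1 ms before the somatic AP begin.
#'
#' @param somatic,dendritic [voltage_trace()] objects from the same run.
#' @param which `"first"` or `"last"` AP of the train.
#' @param spike_threshold somatic detection threshold, mV.
#' @return amplitude in mV, or `NA_real_` when the somatic trace has
#'   fewer than two spikes (unevaluable).
#' @export
extract_bap_amplitude <- function(somatic, dendritic,
                                  which = c("first", "last"),
                                  spike_threshold = -20) {
  which <- match.arg(which)
  sp <- detect_spikes(somatic, spike_threshold)
  n <- nrow(sp)
  if (n < 2) return(NA_real_)
  i <- if (which == "first") 1L else n
  t0 <- sp$begin_time[i]
  t1 <- if (i < n) sp$begin_time[i + 1L]
        else t0 + (sp$begin_time[n] - sp$begin_time[n - 1L])
  max_in_window(dendritic, t0, min(t1, dendritic$t[length(dendritic$t)])) -
    v_at(dendritic, t0 - 1)
}

#' The Back-propagating AP Test
#'
#' Finds the amplitude giving a spike train nearest 15 Hz
#' ([find_bap_amplitude()]), records the somatic and trunk voltage
#' responses at locations 50/150/250/350 +/- 20 um from the soma, and
#' averages the first- and last-AP back-propagating amplitudes over each
#' distance range.  Where the observation distinguishes strongly and
#' weakly propagating cells, the model is classified by whichever
#' first-AP target at the most distal evaluable range it matches with
#' the smaller Z-score, and scored against that class.  Ranges with no
#' suitable trunk location are skipped with a note.
#'
#' @param model a model providing `step_current` and `morphology`.
#' @param observation path or list with keys `AP1_amp_<d>` /
#'   `APlast_amp_<d>` (plain or with `_strong` / `_weak` suffixes), each
#'   `{"mean": m, "std": s}`.
#' @param config list with `distances` (um), `tolerance` (um),
#'   `seg_resolution` (um) and the [find_bap_amplitude()] settings.
#' @return a [test_result()]; final score is the mean Z-score over the
#'   evaluable range features.
#' @export
run_bap_test <- function(model, observation, config = list()) {
  require_capability(model, "step_current", "the back-propagating AP test")
  require_capability(model, "morphology", "the back-propagating AP test")
  cfg <- modifyList(list(distances = c(50, 150, 250, 350), tolerance = 20,
                         seg_resolution = 10, delay = 500, duration = 1000,
                         tstop = 1700, spike_threshold = -20), config)
  obs <- as_observation(observation, "bap")

  search <- find_bap_amplitude(model, cfg)
  morph <- model_morphology(model)
  ranges <- lapply(cfg$distances, function(d) c(d, cfg$tolerance))
  locs <- select_locations_by_distance(morph$tree,
                                       morph$classification$trunk,
                                       ranges, cfg$seg_resolution)

  sites <- list()
  for (rn in names(locs)) {
    lr <- locs[[rn]]
    if (is.null(lr) || nrow(lr) == 0) next
    for (i in seq_len(nrow(lr))) {
      s <- as.list(lr[i, ])
      s$label <- sprintf("r%s_%d", rn, i)
      sites[[s$label]] <- s
    }
  }
  if (!length(sites))
    hv_stop("hippoval_test_error",
            "no trunk location found in any distance range")

  traces <- step_current_response(model, search$amplitude, cfg$delay,
                                  cfg$duration, cfg$tstop,
                                  sites = c(list("soma"), unname(sites)))
  soma_tr <- traces$soma

  range_mean <- function(rn, which) {
    labs <- names(sites)[startsWith(names(sites), paste0("r", rn, "_"))]
    if (!length(labs)) return(NA_real_)
    vals <- vapply(labs, function(l)
      extract_bap_amplitude(soma_tr, traces[[l]], which,
                            cfg$spike_threshold), numeric(1))
    if (all(!is.finite(vals))) NA_real_ else mean(vals[is.finite(vals)])
  }
  dists <- cfg$distances
  ap1 <- setNames(vapply(as.character(dists), range_mean,
                         numeric(1), which = "first"), dists)
  aplast <- setNames(vapply(as.character(dists), range_mean,
                            numeric(1), which = "last"), dists)

  # strong/weak classification on the most distal evaluable range whose
  # observation has both class variants of the first-AP amplitude
  class_chosen <- ""
  cls_note <- "observation does not distinguish strong/weak propagation"
  for (d in rev(dists)) {
    ks <- sprintf("AP1_amp_%d_strong", d); kw <- sprintf("AP1_amp_%d_weak", d)
    if (!is.null(obs[[ks]]) && !is.null(obs[[kw]]) &&
        is.finite(ap1[[as.character(d)]])) {
      zs <- zscore(ap1[[as.character(d)]], obs[[ks]]$mean, obs[[ks]]$std, ks)
      zw <- zscore(ap1[[as.character(d)]], obs[[kw]]$mean, obs[[kw]]$std, kw)
      class_chosen <- if (zs <= zw) "strong" else "weak"
      cls_note <- sprintf(
        "classified as %sly propagating at %d um (z_strong = %.4g, z_weak = %.4g)",
        class_chosen, d, zs, zw)
      break
    }
  }

  scores <- list()
  for (d in dists) {
    for (feat in c("AP1", "APlast")) {
      base_key <- sprintf("%s_amp_%d", feat, d)
      entry <- obs[[base_key]]
      used_key <- base_key
      if (is.null(entry) && nzchar(class_chosen)) {
        used_key <- sprintf("%s_%s", base_key, class_chosen)
        entry <- obs[[used_key]]
      }
      if (is.null(entry)) next  # distance not in the observation
      val <- (if (feat == "AP1") ap1 else aplast)[[as.character(d)]]
      scores[[used_key]] <- feature_score(
        used_key, val, entry$mean, entry$std,
        evaluated = is.finite(val),
        note = if (is.finite(val)) "" else
          "no suitable trunk location in this distance range")
    }
  }
  if (!length(scores))
    hv_stop("hippoval_test_error",
            "observation contains no feature matching the configured distances")

  test_result("bap", scores, mode = "mean",
              classification_notes = sprintf(
                "%s; stimulus %.6g nA at %.6g Hz", cls_note,
                search$amplitude, search$rate),
              config_echo = list(distances = cfg$distances,
                                 tolerance = cfg$tolerance,
                                 amplitude = search$amplitude,
                                 rate = search$rate))
}
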