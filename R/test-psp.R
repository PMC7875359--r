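#' The PSP Attenuation Test
#'
#' Measures how much an EPSP attenuates on its way from the apical trunk
#' to the soma.  Dendritic input locations are drawn at random from the
#' trunk with probability proportional to segment length (between 50 and
#' 350 um from the soma; a fixed seed makes the selection reproducible).
#' At each location a zero-weight baseline run yields the resting
#' potential, from which the synaptic weight reproducing the target EPSC
#' amplitude is computed (`weight = -EPSC_amp / Vm`, reversal at 0 mV).
#' The baseline is subtracted from the stimulated traces and the
#' attenuation is the somatic peak depolarization divided by the
#' dendritic one.  Attenuations are averaged over the distance ranges
#' 100/200/300 +/- 50 um and Z-scored; the final score is their mean.
#'
#' @param model a model providing `synaptic_activation` and `morphology`.
#' @param observation path or list with keys
#'   `mean_attenuation_soma/dend_<d>_um` and `std_attenuation_soma/dend_<d>_um`.
#' @param config list with `distances` (um), `tolerance` (um),
#'   `num_of_dend_locations`, `seed`, `epsc_amp` (nA), `tau1`, `tau2`
#'   (ms, EPSC shape, echoed for provenance), `delay`, `tstop` (ms),
#'   `seg_resolution` (um).
#' @return a [test_result()] with the seed recorded.
#' @export
run_psp_attenuation_test <- function(model, observation, config = list()) {
  require_capability(model, "synaptic_activation", "the PSP attenuation test")
  require_capability(model, "morphology", "the PSP attenuation test")
  cfg <- modifyList(list(distances = c(100, 200, 300), tolerance = 50,
                         num_of_dend_locations = 15, seed = 1,
                         epsc_amp = 0.2, tau1 = 0.5, tau2 = 3,
                         delay = 150, tstop = 400, seg_resolution = 10),
                    config)
  obs <- as_observation(observation, "psp-attenuation")

  bounds <- c(min(cfg$distances) - cfg$tolerance,
              max(cfg$distances) + cfg$tolerance)
  morph <- model_morphology(model)
  locs <- sample_random_trunk_locations(morph$tree,
                                        morph$classification$trunk,
                                        n = cfg$num_of_dend_locations,
                                        seed = cfg$seed, bounds = bounds,
                                        seg_resolution = cfg$seg_resolution)

  atts <- numeric(nrow(locs)); notes <- character(nrow(locs))
  for (i in seq_len(nrow(locs))) {
    loc <- as.list(locs[i, ])
    loc$label <- sprintf("loc_%d", i)
    baseline <- synaptic_response(model, loc, weight = 0, count = 1,
                                  interval = 0, tstop = cfg$tstop,
                                  delay = cfg$delay)
    vm <- resting_vm(baseline$soma)
    w <- psp_weight_from_epsc(cfg$epsc_amp, vm)
    stim <- synaptic_response(model, loc, weight = w, count = 1,
                              interval = 0, tstop = cfg$tstop,
                              delay = cfg$delay)
    dep_soma <- trace_subtract(stim$soma, baseline$soma)
    dep_dend <- trace_subtract(stim$dendrite, baseline$dendrite)
    pk_d <- max(dep_dend$v)
    if (pk_d <= 0) {
      atts[i] <- NA_real_
      notes[i] <- "no dendritic depolarization"
    } else atts[i] <- max(dep_soma$v) / pk_d
  }

  scores <- list()
  for (d in cfg$distances) {
    mk <- sprintf("mean_attenuation_soma/dend_%d_um", d)
    sk <- sprintf("std_attenuation_soma/dend_%d_um", d)
    if (is.null(obs[[mk]]) || is.null(obs[[sk]]))
      hv_stop("hippoval_invalid_observation",
              "PSP observation lacks '%s' / '%s'", mk, sk)
    in_range <- is.finite(atts) &
      locs$path_distance >= d - cfg$tolerance &
      locs$path_distance <= d + cfg$tolerance
    val <- if (any(in_range)) mean(atts[in_range]) else NA_real_
    key <- sprintf("attenuation_soma/dend_%d_um", d)
    scores[[key]] <- feature_score(
      key, val, obs[[mk]], obs[[sk]], evaluated = is.finite(val),
      note = if (is.finite(val))
        sprintf("%d location(s)", sum(in_range)) else
        "no sampled location in this distance range")
  }
  test_result("psp_attenuation", scores, mode = "mean", seed = cfg$seed,
              classification_notes = paste(notes[nzchar(notes)],
                                           collapse = "; "),
              config_echo = cfg[c("distances", "tolerance",
                                  "num_of_dend_locations", "seed",
                                  "epsc_amp", "tau1", "tau2")])
}
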