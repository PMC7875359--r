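# The Oblique Integration Test: dendrite selection, per-location
# input-output protocol, the nine integration features, and scoring.

#' Select oblique dendrites eligible for the integration protocol
#'
#' Eligible obliques are terminal sections (no child sections) whose
#' origin lies at most `max_dist` um (path distance) from the soma.  If
#' none qualifies, the distance limit is increased in 15 um steps, but
#' never beyond 190 um; if still none qualifies a selection error is
#' raised.
#'
#' @param tree a `morph_tree`.
#' @param classification an `apical_classification`.
#' @param max_dist initial distance limit, um (default 120).
#' @param extend_step,extend_max extension step and hard cap, um.
#' @return list with `sections` (section ids) and `limit_used` (um).
#' @export
select_oblique_dendrites <- function(tree, classification, max_dist = 120,
                                     extend_step = 15, extend_max = 190) {
  secs <- tree$sections
  obl <- secs[secs$section_id %in% classification$oblique & secs$terminal, ]
  limit <- max_dist
  repeat {
    hit <- obl$section_id[obl$dist_start <= limit]
    if (length(hit))
      return(list(sections = hit, limit_used = limit))
    if (limit >= extend_max)
      hv_stop("hippoval_selection_error",
              "no eligible oblique dendrite found up to %g um from the soma",
              extend_max)
    limit <- min(limit + extend_step, extend_max)
  }
}

# nine integration features measured at one calibrated location.
# The linear baseline for n inputs is the peak of the unitary somatic
# depolarization shifted by the inter-input interval and summed n times.
oblique_location_features <- function(model, loc, weight, cfg) {
  target <- cfg$target_count
  run <- function(n, interval) synaptic_response(
    model, loc, weight = weight, count = n, interval = interval,
    tstop = cfg$tstop, delay = cfg$stim_delay)

  sync <- lapply(0:(target + 1), run, interval = cfg$sync_interval)
  async <- lapply(0:(target + 1), run, interval = cfg$async_interval)
  base_s <- sync[[1]]$soma; base_a <- async[[1]]$soma

  dep <- function(runs, n) runs[[n + 1]]$soma$v - base_s$v
  t <- base_s$t

  spike_n <- NA_integer_
  for (n in seq_len(target + 1))
    if (nrow(detect_spikes(sync[[n + 1]]$dendrite, cfg$spike_threshold))) {
      spike_n <- n; break
    }
  if (is.na(spike_n)) return(NULL)

  linpred <- function(n, interval, udep) {
    acc <- numeric(length(t))
    for (k in 0:(n - 1))
      acc <- acc + approx(t, udep, t - k * interval, rule = 2)$y
    max(acc)
  }
  u_sync <- dep(sync, 1)
  u_async <- async[[2]]$soma$v - base_a$v

  d_th <- dep(sync, spike_n)
  lp_th <- linpred(spike_n, cfg$sync_interval, u_sync)
  dvdt <- diff(sync[[spike_n + 1]]$soma$v) / diff(t)
  d_async <- async[[spike_n + 1]]$soma$v - base_a$v

  list(
    threshold = lp_th,
    nonlin_at_th = 100 * max(d_th) / lp_th,
    suprath_nonlin = 100 * max(dep(sync, spike_n + 1)) /
      linpred(spike_n + 1, cfg$sync_interval, u_sync),
    peak_deriv = max(dvdt),
    peak_amp = max(d_th),
    time_to_peak = t[which.max(d_th)] - cfg$stim_delay,
    async_nonlin = 100 * max(d_async) /
      linpred(spike_n, cfg$async_interval, u_async),
    spike_n = spike_n
  )
}

#' The Oblique Integration Test
#'
#' Evaluates the integration of clustered synaptic inputs on radial
#' oblique dendrites.  For each eligible oblique
#' ([select_oblique_dendrites()]) a proximal and a distal location are
#' examined.  At each location the synaptic weight is calibrated by
#' binary search so that the first dendritic spike occurs at exactly
#' `cfg$target_count` (default 5) synchronous inputs
#' ([calibrate_oblique_weight()]); locations where the threshold spike
#' triggers a somatic AP, or where no dendritic spike can be evoked, are
#' excluded and listed in the notes.  An increasing number of inputs is
#' then delivered synchronously (0.1 ms apart) and asynchronously (2 ms
#' apart), and nine features are computed per location and averaged:
#' dendritic-spike voltage threshold (the expected — linear-sum — somatic
#' depolarization at the first spiking input count), its proximal-only
#' and distal-only variants, degree of nonlinearity at threshold and one
#' input above it, peak somatic dV/dt at threshold, somatic EPSP peak
#' amplitude and time to peak at threshold, and the asynchronous degree
#' of nonlinearity.  The final score is the mean Z-score over the nine
#' features.
#'
#' @param model a model providing `synaptic_activation` and `morphology`.
#' @param observation path or list with `mean_<f>` / `std_<f>` (or
#'   `se_<f>` plus `n_cells`) for the nine features `threshold`,
#'   `prox_threshold`, `dist_threshold`, `nonlin_at_th`,
#'   `suprath_nonlin`, `peak_deriv`, `peak_amp`, `time_to_peak`,
#'   `async_nonlin`.
#' @param cfg a [calibration_config()].
#' @param config list with `max_dist` (um, default 120), `prox_arc`,
#'   `dist_arc` (arc positions of the proximal/distal test locations).
#' @return a [test_result()].
#' @export
run_oblique_integration_test <- function(model, observation,
                                         cfg = calibration_config(),
                                         config = list()) {
  require_capability(model, "synaptic_activation", "the oblique integration test")
  require_capability(model, "morphology", "the oblique integration test")
  opt <- modifyList(list(max_dist = 120, prox_arc = 0.3, dist_arc = 0.7),
                    config)
  obs <- as_observation(observation, "oblique-integration")

  morph <- model_morphology(model)
  sel <- select_oblique_dendrites(morph$tree, morph$classification,
                                  opt$max_dist)

  locs <- list()
  for (sid in sel$sections) {
    sec <- morph$tree$sections[morph$tree$sections$section_id == sid, ]
    for (kind in c("prox", "dist")) {
      arc <- if (kind == "prox") opt$prox_arc else opt$dist_arc
      locs[[paste0("sec", sid, "_", kind)]] <- list(
        section_id = sid, arc = arc,
        path_distance = sec$dist_start + arc * sec$length,
        label = paste0("sec", sid, "_", kind), kind = kind)
    }
  }

  feats <- list(); excluded <- character(0)
  for (loc in locs) {
    cal <- calibrate_oblique_weight(model, loc, cfg)
    if (cal$status != "ok") {
      excluded <- c(excluded, sprintf("%s: %s", loc$label, cal$note))
      next
    }
    f <- oblique_location_features(model, loc, cal$weight, cfg)
    if (is.null(f)) {
      excluded <- c(excluded,
                    sprintf("%s: no dendritic spike after calibration",
                            loc$label))
      next
    }
    f$kind <- loc$kind
    feats[[loc$label]] <- f
  }
  if (!length(feats))
    hv_stop("hippoval_test_error",
            "no oblique location could be calibrated (%s)",
            paste(excluded, collapse = "; "))

  colmean <- function(name, kind = NULL) {
    v <- vapply(feats, function(f) {
      if (!is.null(kind) && f$kind != kind) return(NA_real_)
      f[[name]]
    }, numeric(1))
    if (all(!is.finite(v))) NA_real_ else mean(v[is.finite(v)])
  }
  model_vals <- c(
    threshold = colmean("threshold"),
    prox_threshold = colmean("threshold", "prox"),
    dist_threshold = colmean("threshold", "dist"),
    nonlin_at_th = colmean("nonlin_at_th"),
    suprath_nonlin = colmean("suprath_nonlin"),
    peak_deriv = colmean("peak_deriv"),
    peak_amp = colmean("peak_amp"),
    time_to_peak = colmean("time_to_peak"),
    async_nonlin = colmean("async_nonlin"))

  scores <- list()
  for (f in names(model_vals)) {
    m <- obs[[paste0("mean_", f)]]; s <- obs[[paste0("std_", f)]]
    if (is.null(m) || is.null(s))
      hv_stop("hippoval_invalid_observation",
              "oblique observation lacks mean_%s / std_%s", f, f)
    scores[[f]] <- feature_score(
      f, model_vals[[f]], m, s, evaluated = is.finite(model_vals[[f]]),
      note = if (is.finite(model_vals[[f]])) "" else
        "no calibrated location of the required kind")
  }
  notes <- sprintf("%d/%d locations calibrated (limit %g um)%s",
                   length(feats), length(locs), sel$limit_used,
                   if (length(excluded))
                     paste0("; excluded: ", paste(excluded, collapse = "; "))
                   else "")
  test_result("oblique_integration", scores, mode = "mean",
              classification_notes = notes,
              config_echo = list(c_minmax = cfg$c_minmax,
                                 c_step_stop = cfg$c_step_stop,
                                 target_count = cfg$target_count,
                                 sync_interval = cfg$sync_interval,
                                 async_interval = cfg$async_interval,
                                 max_dist = opt$max_dist,
                                 limit_used = sel$limit_used))
}
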