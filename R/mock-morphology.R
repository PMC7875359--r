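# Synthetic SWC morphology generator: a parametric CA1-like pyramidal
# cell (soma, apical trunk with radial oblique side branches, distal tuft,
# basal dendrites) used as the suite's fixture factory.  Geometry is
# rendered deterministically; the seed only drives the optional
# coordinate jitter.

#' Specification of a synthetic morphology
#'
#' @param trunk_length apical trunk length, um.
#' @param node_step spacing of consecutive SWC nodes, um.
#' @param soma_radius soma radius, um.
#' @param oblique_distances path distances (from the soma) at which
#'   oblique side branches attach to the trunk, um.
#' @param oblique_lengths length of each oblique (recycled), um.
#' @param tuft_branches number of tuft branches arising at the distal
#'   trunk bifurcation (the apical point); 0 leaves an unbranched trunk.
#' @param tuft_length length of each tuft branch, um.
#' @param proximal_bifurcation_at `NULL`, or a depth (um) at which the
#'   trunk splits into two sub-trunks that each run the full
#'   `trunk_length` and carry their own tuft — the multi-apical-point
#'   scenario.
#' @param basal_count,basal_length number and length of basal dendrites.
#' @param jitter_sd standard deviation of the optional x/z coordinate
#'   jitter, um (0 = none).
#' @param seed RNG seed for the jitter.
#' @return list of class `morphology_spec`.
#' @export
morphology_spec <- function(trunk_length = 420, node_step = 10,
                            soma_radius = 6,
                            oblique_distances = c(60, 90, 110),
                            oblique_lengths = 60,
                            tuft_branches = 2, tuft_length = 150,
                            proximal_bifurcation_at = NULL,
                            basal_count = 2, basal_length = 80,
                            jitter_sd = 0, seed = 1) {
  spec <- as.list(environment())
  if (trunk_length <= 0 || node_step <= 0)
    hv_stop("hippoval_generation_error", "lengths and node_step must be > 0")
  if (length(oblique_distances) &&
      any(oblique_distances <= 0 | oblique_distances >= trunk_length))
    hv_stop("hippoval_generation_error",
            "oblique attachment distances must lie inside the trunk")
  if (!is.null(proximal_bifurcation_at) &&
      (proximal_bifurcation_at <= 0 || proximal_bifurcation_at >= trunk_length))
    hv_stop("hippoval_generation_error",
            "proximal bifurcation depth must lie inside the trunk")
  class(spec) <- "morphology_spec"
  spec
}

#' Generate a synthetic morphology
#'
#' @param spec a [morphology_spec()].
#' @param swc_path optional path; when given, the morphology is also
#'   written as a standard SWC file.
#' @return a `morph_tree` (see [build_morph_tree()]).
#' @export
generate_morphology <- function(spec = morphology_spec(), swc_path = NULL) {
  rows <- list()
  nid <- 0L
  add_node <- function(type, x, y, z, radius, parent) {
    nid <<- nid + 1L
    rows[[nid]] <<- data.frame(id = nid, type = type, x = x, y = y, z = z,
                               radius = radius, parent = parent)
    nid
  }
  # straight chain of nodes from (but excluding) the parent node position
  add_chain <- function(parent, from, dir, len, type, radius = 1) {
    n_seg <- max(1L, ceiling(len / spec$node_step))
    step <- len / n_seg
    last <- parent
    for (k in seq_len(n_seg)) {
      pos <- from + dir * (k * step)
      last <- add_node(type, pos[1], pos[2], pos[3], radius, last)
    }
    last
  }
  soma <- add_node("soma", 0, 0, 0, spec$soma_radius, -1L)

  ob_len <- rep_len(spec$oblique_lengths,
                    max(1L, length(spec$oblique_distances)))
  grow_trunk <- function(parent, from, tilt, dist_offset) {
    # trunk with obliques at the specified path distances, then a tuft
    dirs <- c(tilt, 1, 0); dirs <- dirs / sqrt(sum(dirs^2))
    marks <- sort(spec$oblique_distances[spec$oblique_distances > dist_offset])
    pos <- from; last <- parent; travelled <- dist_offset; side <- 1
    for (i in seq_along(marks)) {
      seg <- marks[i] - travelled
      last <- add_chain(last, pos, dirs, seg, "apical")
      pos <- pos + dirs * seg; travelled <- marks[i]
      odir <- c(side, 0, 0.2 * side); odir <- odir / sqrt(sum(odir^2))
      add_chain(last, pos, odir,
                ob_len[match(marks[i], spec$oblique_distances)], "apical")
      side <- -side
    }
    last <- add_chain(last, pos, dirs, spec$trunk_length - travelled, "apical")
    pos <- from + dirs * (spec$trunk_length - dist_offset)
    if (spec$tuft_branches > 0) {
      for (b in seq_len(spec$tuft_branches)) {
        ang <- pi / 6 * (b - (spec$tuft_branches + 1) / 2)
        tdir <- c(sin(ang) + tilt, cos(ang), 0)
        tdir <- tdir / sqrt(sum(tdir^2))
        add_chain(last, pos, tdir, spec$tuft_length, "apical")
      }
    }
    invisible(last)
  }

  if (is.null(spec$proximal_bifurcation_at)) {
    grow_trunk(soma, c(0, 0, 0), tilt = 0, dist_offset = 0)
  } else {
    up <- c(0, 1, 0)
    stem <- add_chain(soma, c(0, 0, 0), up, spec$proximal_bifurcation_at,
                      "apical")
    base <- c(0, spec$proximal_bifurcation_at, 0)
    grow_trunk(stem, base, tilt = 0.35,
               dist_offset = spec$proximal_bifurcation_at)
    grow_trunk(stem, base, tilt = -0.35,
               dist_offset = spec$proximal_bifurcation_at)
  }
  if (spec$basal_count > 0) {
    for (b in seq_len(spec$basal_count)) {
      ang <- pi / 4 * (b - (spec$basal_count + 1) / 2)
      bdir <- c(sin(ang), -cos(ang), 0); bdir <- bdir / sqrt(sum(bdir^2))
      add_chain(soma, c(0, 0, 0), bdir, spec$basal_length, "basal")
    }
  }
  nodes <- do.call(rbind, rows)
  if (spec$jitter_sd > 0) {
    nodes <- withr::with_seed(spec$seed, {
      ns <- nodes$type != "soma"
      nodes$x[ns] <- nodes$x[ns] + stats::rnorm(sum(ns), 0, spec$jitter_sd)
      nodes$z[ns] <- nodes$z[ns] + stats::rnorm(sum(ns), 0, spec$jitter_sd)
      nodes
    })
  }
  tree <- build_morph_tree(nodes)
  if (!is.null(swc_path)) write_swc(tree, swc_path)
  tree
}
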