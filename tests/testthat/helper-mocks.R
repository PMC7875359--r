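# shared helpers: fixture paths, canonical mock configurations, and the
# independent oracles used by the property suites

hv_ext <- function(f) system.file("extdata", f, package = "hippoval")

# a mock with zero rheobase and the textbook 30 Hz/nA f-I curve
mock_fi30 <- function(...) mock_model(mock_params(rheobase = 0, ...))

# engineered so the spike count peaks at 0.4 nA while block sets in at
# 0.5 nA: I_maxNumAP and I_below_depol_block end up one 0.05 nA step apart
mock_one_step_penalty <- function() {
  mock_model(mock_params(
    rheobase = 0, fi_slope = 30,
    fi_rollover = list(I_start = 0.4, slope_down = 20, floor = 10),
    block = list(enabled = TRUE, I_block = 0.5)))
}

# independent linear interpolation of a trace voltage
v_at_oracle <- function(trace, time) stats::approx(trace$t, trace$v, time)$y

# brute-force spike counter: scan every sample pair for upward crossings
oracle_spike_count <- function(v, threshold) {
  n <- 0L
  above <- v[1] >= threshold
  for (i in seq_along(v)[-1]) {
    if (!above && v[i] >= threshold) n <- n + 1L
    above <- v[i] >= threshold
  }
  if (v[1] >= threshold) n <- n + 1L
  n
}

# independent LCA of a node-id set via root-path intersection
oracle_lca <- function(tree, ids) {
  root_path <- function(id) {
    r <- match(id, tree$nodes$id)
    path <- integer(0)
    while (!is.na(r)) { path <- c(tree$nodes$id[r], path); r <- tree$parent_idx[r] }
    path
  }
  paths <- lapply(ids, root_path)
  common <- Reduce(intersect, paths)
  common[length(common)]
}

# independent re-implementation of the multi-apical-point recursion, built
# on the path-intersection LCA and explicit descendant sets
oracle_apical_points <- function(tree, min_distance = 100,
                                 tuft_fraction = 0.6) {
  nd <- tree$nodes
  is_terminal <- lengths(tree$children) == 0L
  term <- nd$id[nd$type == "apical" & is_terminal]
  dmax <- max(nd$path_dist[match(term, nd$id)])
  term <- term[nd$path_dist[match(term, nd$id)] >= tuft_fraction * dmax]
  descendants <- function(id) {
    out <- integer(0); stack <- tree$children[[match(id, nd$id)]]
    while (length(stack)) {
      i <- stack[1]; stack <- stack[-1]
      out <- c(out, nd$id[i]); stack <- c(stack, tree$children[[i]])
    }
    out
  }
  rec <- function(ids) {
    a <- oracle_lca(tree, ids)
    if (nd$path_dist[match(a, nd$id)] >= min_distance) return(a)
    kids <- nd$id[tree$children[[match(a, nd$id)]]]
    if (length(ids) == 1L || !length(kids)) return(a)
    groups <- lapply(kids, function(k) intersect(ids, c(k, descendants(k))))
    groups <- groups[lengths(groups) > 0]
    if (length(groups) == 1L) return(a)
    unlist(lapply(groups, rec))
  }
  sort(unique(rec(term)))
}

# random synthetic morphology spec under a fixed seed
random_morph_spec <- function(seed) {
  withr::with_seed(seed, {
    trunk <- sample(seq(200, 480, by = 20), 1)
    n_ob <- sample(0:3, 1)
    ob <- if (n_ob > 0) sort(sample(seq(30, trunk - 40, by = 10), n_ob))
          else numeric(0)
    morphology_spec(
      trunk_length = trunk,
      oblique_distances = ob,
      oblique_lengths = sample(seq(30, 80, by = 10), max(1, n_ob),
                               replace = TRUE),
      tuft_branches = sample(2:3, 1),
      tuft_length = sample(seq(80, 180, by = 20), 1),
      proximal_bifurcation_at = if (runif(1) < 0.4)
        sample(seq(20, 80, by = 10), 1) else NULL)
  })
}

# random voltage trace with a known number of stereotyped spikes
random_spike_trace <- function(seed, dt = 0.2) {
  withr::with_seed(seed, {
    tstop <- 500
    t <- seq(0, tstop, by = dt)
    v <- -70 + stats::rnorm(length(t), 0, 1.5)
    n_sp <- sample(0:8, 1)
    if (n_sp > 0) {
      ts <- sort(sample(seq(50, tstop - 20, by = 10), n_sp))
      for (s in ts) {
        idx <- which(t >= s & t <= s + 3)
        frac <- ifelse(t[idx] <= s + 1, (t[idx] - s), 1 - (t[idx] - s - 1) / 2)
        v[idx] <- pmax(v[idx], -70 + 105 * pmax(frac, 0))
      }
    }
    voltage_trace(t, v, stim_delay = 20, stim_duration = tstop - 40)
  })
}
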