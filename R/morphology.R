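# SWC morphology handling: reading/writing, section building, path
# distances, and the location machinery used by the dendritic tests.
#
# Conventions (documented in the methods vignette):
#  * path distance is measured from the soma root node centre along the
#    3D polyline; soma extent is ignored (all soma nodes sit at 0 um);
#  * a "section" is a maximal unbranched chain of same-type nodes;
#  * arc_position runs in [0, 1] from the proximal to the distal end of a
#    section;
#  * for location selection, sections are discretised into resolution
#    segments of at most `seg_resolution` um (default 10) and locations
#    sit at segment midpoints.

.swc_types <- c(`1` = "soma", `2` = "axon", `3` = "basal", `4` = "apical")

#' Read an SWC morphology file
#'
#' Parses the standard 7-column SWC format and builds a rooted tree with
#' typed sections.  SWC type codes are mapped 1 = soma, 2 = axon,
#' 3 = basal dendrite, 4 = apical dendrite (other codes become
#' `"other"`).
#'
#' @param path path to an SWC file.
#' @return an object of class `morph_tree`; see [build_morph_tree()].
#' @export
read_swc <- function(path) {
  if (!file.exists(path))
    hv_stop("hippoval_io_error", "SWC file '%s' not found", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  fields <- strsplit(trimws(lines[keep]), "\\s+")
  lineno <- which(keep)
  bad <- which(lengths(fields) != 7)
  if (length(bad))
    hv_stop("hippoval_swc_error", "SWC line %d: expected 7 columns, got %d",
            lineno[bad[1]], lengths(fields)[bad[1]])
  m <- matrix(as.numeric(unlist(fields)), ncol = 7, byrow = TRUE)
  if (anyNA(m))
    hv_stop("hippoval_swc_error", "SWC line %d: non-numeric field",
            lineno[which(rowSums(is.na(m)) > 0)[1]])
  nodes <- data.frame(id = as.integer(m[, 1]),
                      type = unname(.swc_types[as.character(as.integer(m[, 2]))]),
                      x = m[, 3], y = m[, 4], z = m[, 5], radius = m[, 6],
                      parent = as.integer(m[, 7]),
                      stringsAsFactors = FALSE)
  nodes$type[is.na(nodes$type)] <- "other"
  build_morph_tree(nodes, src_lines = lineno)
}

#' Build a morphology tree from a node table
#'
#' Validates the node table (unique ids, exactly one soma root, parents
#' defined before children — which also rules out cycles) and derives the
#' section decomposition and per-node path distances from the soma.
#'
#' @param nodes data.frame with columns `id`, `type` (one of soma, axon,
#'   basal, apical, other), `x`, `y`, `z`, `radius`, `parent` (-1 for the
#'   root).
#' @param src_lines optional original file line numbers for error
#'   messages.
#' @return object of class `morph_tree` with elements `nodes` (the table
#'   plus `path_dist`), `children` (list indexed like `nodes`),
#'   `sections` (data.frame: `section_id`, `type`, `parent_section`,
#'   `attach_node`, `dist_start`, `length`, `terminal`) and
#'   `section_nodes` (list of node row-indices per section).
#' @export
build_morph_tree <- function(nodes, src_lines = seq_len(nrow(nodes))) {
  n <- nrow(nodes)
  if (n < 1) hv_stop("hippoval_swc_error", "empty morphology")
  if (anyDuplicated(nodes$id))
    hv_stop("hippoval_swc_error", "duplicate node id %d",
            nodes$id[anyDuplicated(nodes$id)])
  idx <- setNames(seq_len(n), nodes$id)
  roots <- which(nodes$parent == -1L)
  if (length(roots) != 1)
    hv_stop("hippoval_swc_error", "expected exactly one root node, found %d",
            length(roots))
  if (nodes$type[roots] != "soma")
    hv_stop("hippoval_swc_error", "root node (id %d) must be of soma type",
            nodes$id[roots])
  parent_idx <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    p <- nodes$parent[i]
    if (p == -1L) next
    pi <- idx[as.character(p)]
    if (is.na(pi))
      hv_stop("hippoval_swc_error",
              "line %d: node %d references undefined parent %d",
              src_lines[i], nodes$id[i], p)
    if (pi >= i)
      hv_stop("hippoval_swc_error",
              "line %d: parent %d of node %d is not defined before it",
              src_lines[i], p, nodes$id[i])
    parent_idx[i] <- pi
  }
  children <- vector("list", n)
  for (i in seq_len(n)) if (!is.na(parent_idx[i]))
    children[[parent_idx[i]]] <- c(children[[parent_idx[i]]], i)

  path_dist <- numeric(n)
  for (i in seq_len(n)) {
    if (nodes$type[i] == "soma") { path_dist[i] <- 0; next }
    pi <- parent_idx[i]
    seg <- sqrt((nodes$x[i] - nodes$x[pi])^2 + (nodes$y[i] - nodes$y[pi])^2 +
                (nodes$z[i] - nodes$z[pi])^2)
    path_dist[i] <- path_dist[pi] + seg
  }
  nodes$path_dist <- path_dist

  # section decomposition: a node opens a new section when its parent is
  # the root, a branch point, of a different type, or absent
  n_children <- lengths(children)
  starts <- vapply(seq_len(n), function(i) {
    pi <- parent_idx[i]
    is.na(pi) || n_children[pi] != 1L || nodes$type[pi] != nodes$type[i]
  }, logical(1))

  sec_nodes <- list(); sec_rows <- list()
  node_section <- rep(NA_integer_, n)
  sid <- 0L
  for (s in which(starts)) {
    sid <- sid + 1L
    chain <- s
    while (n_children[chain[length(chain)]] == 1L) {
      nxt <- children[[chain[length(chain)]]]
      if (starts[nxt]) break
      chain <- c(chain, nxt)
    }
    node_section[chain] <- sid
    pi <- parent_idx[s]
    len <- if (is.na(pi)) {
      if (length(chain) > 1)
        sum(sqrt(diff(nodes$x[chain])^2 + diff(nodes$y[chain])^2 +
                 diff(nodes$z[chain])^2)) else 0
    } else path_dist[chain[length(chain)]] - path_dist[pi]
    sec_nodes[[sid]] <- chain
    sec_rows[[sid]] <- data.frame(
      section_id = sid, type = nodes$type[s],
      attach_node = if (is.na(pi)) NA_integer_ else pi,
      dist_start = if (is.na(pi)) 0 else path_dist[pi],
      length = len,
      terminal = n_children[chain[length(chain)]] == 0L)
  }
  sections <- do.call(rbind, sec_rows)
  sections$parent_section <- vapply(seq_len(nrow(sections)), function(k) {
    a <- sections$attach_node[k]
    if (is.na(a)) NA_integer_ else node_section[a]
  }, integer(1))

  structure(list(nodes = nodes, parent_idx = parent_idx, children = children,
                 sections = sections, section_nodes = sec_nodes,
                 node_section = node_section),
            class = "morph_tree")
}

#' @export
print.morph_tree <- function(x, ...) {
  tab <- table(x$sections$type)
  cat(sprintf("<morph_tree> %d nodes, %d sections (%s)\n",
              nrow(x$nodes), nrow(x$sections),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Write a morphology to an SWC file
#'
#' @param tree a `morph_tree`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(tree, path) {
  type_code <- c(soma = 1L, axon = 2L, basal = 3L, apical = 4L, other = 5L)
  nd <- tree$nodes
  lines <- sprintf("%d %d %.6f %.6f %.6f %.6f %d",
                   nd$id, type_code[nd$type], nd$x, nd$y, nd$z, nd$radius,
                   nd$parent)
  writeLines(c("# SWC generated by hippoval", lines), path)
  invisible(path)
}

# row index <-> node id helpers
.node_row <- function(tree, id) {
  r <- match(id, tree$nodes$id)
  if (anyNA(r)) hv_stop("hippoval_swc_error", "unknown node id")
  r
}

node_depth <- function(tree, row) {
  d <- 0L
  while (!is.na(tree$parent_idx[row])) { row <- tree$parent_idx[row]; d <- d + 1L }
  d
}

# lowest common ancestor of a set of node row-indices
lca_rows <- function(tree, rows) {
  cur <- rows[1]
  for (b in rows[-1]) {
    a <- cur
    da <- node_depth(tree, a); db <- node_depth(tree, b)
    while (da > db) { a <- tree$parent_idx[a]; da <- da - 1L }
    while (db > da) { b <- tree$parent_idx[b]; db <- db - 1L }
    while (a != b) { a <- tree$parent_idx[a]; b <- tree$parent_idx[b] }
    cur <- a
  }
  cur
}

#' Find the apical point(s) of a morphology
#'
#' Starting from the tuft endpoints — the uppermost apical terminals,
#' operationalized as those whose path distance is at least
#' `tuft_fraction` of the most distal apical terminal's — the common
#' ancestor of all of them is located.  If its path distance from the
#' soma is below `min_distance` (i.e. the trunk bifurcates proximally)
#' the search is repeated on each child subtree of that ancestor, and the
#' union of the apical points found there is returned.  A subtree with no
#' bifurcation above it contributes its terminal-side ancestor as-is.
#'
#' @param tree a `morph_tree` with apical nodes.
#' @param min_distance acceptance threshold in um (default 100) below
#'   which a candidate apical point is considered a proximal trunk
#'   bifurcation and recursed through.
#' @param tuft_fraction fraction (default 0.6) of the maximal apical
#'   terminal path distance above which a terminal counts as a tuft
#'   endpoint; side-branch (oblique) terminals fall below it and do not
#'   seed the search.
#' @return integer vector of node ids.
#' @export
find_apical_points <- function(tree, min_distance = 100,
                               tuft_fraction = 0.6) {
  apical <- which(tree$nodes$type == "apical")
  if (!length(apical))
    hv_stop("hippoval_classification_error", "morphology has no apical nodes")
  terminals <- apical[lengths(tree$children[apical]) == 0L]
  if (!length(terminals))
    hv_stop("hippoval_classification_error", "apical arbor has no terminal points")
  dmax <- max(tree$nodes$path_dist[terminals])
  terminals <- terminals[tree$nodes$path_dist[terminals] >=
                           tuft_fraction * dmax]

  recurse <- function(term_rows) {
    a <- lca_rows(tree, term_rows)
    if (tree$nodes$path_dist[a] >= min_distance) return(a)
    if (length(term_rows) == 1L || length(tree$children[[a]]) == 0L)
      return(a)  # unbranched subtree: terminal-side ancestor as-is
    # split terminals by which child subtree of `a` they belong to
    branch_of <- vapply(term_rows, function(r) {
      while (!is.na(tree$parent_idx[r]) && tree$parent_idx[r] != a)
        r <- tree$parent_idx[r]
      r
    }, integer(1))
    groups <- split(term_rows, branch_of)
    if (length(groups) == 1L) return(a)
    unlist(lapply(groups, recurse), use.names = FALSE)
  }
  rows <- sort(unique(recurse(terminals)))
  tree$nodes$id[rows]
}

#' Classify the apical arbor into trunk, oblique and tuft sections
#'
#' Trunk sections lie on the root path of an apical point; tuft sections
#' are apical sections distal to an apical point; every other apical
#' section (side branches of the trunk) is an oblique dendrite.
#'
#' @param tree a `morph_tree`.
#' @param apical_points node ids from [find_apical_points()].
#' @return object of class `apical_classification`: list with
#'   `apical_points` (node ids) and disjoint section-id vectors `trunk`,
#'   `oblique`, `tuft` whose union is the apical arbor.
#' @export
classify_apical <- function(tree, apical_points) {
  if (!length(apical_points))
    hv_stop("hippoval_classification_error", "no apical points supplied")
  ap_rows <- .node_row(tree, apical_points)
  n <- nrow(tree$nodes)
  on_trunk <- rep(FALSE, n)
  for (r in ap_rows) {
    while (!is.na(r) && tree$nodes$type[r] == "apical") {
      on_trunk[r] <- TRUE
      r <- tree$parent_idx[r]
    }
  }
  in_tuft <- rep(FALSE, n)
  for (r in ap_rows) {
    stack <- tree$children[[r]]
    while (length(stack)) {
      i <- stack[[1]]; stack <- stack[-1]
      if (tree$nodes$type[i] == "apical") {
        in_tuft[i] <- TRUE
        stack <- c(stack, tree$children[[i]])
      }
    }
  }
  apical_secs <- which(tree$sections$type == "apical")
  last_node <- vapply(tree$section_nodes[apical_secs],
                      function(ch) ch[length(ch)], integer(1))
  cls <- ifelse(in_tuft[last_node], "tuft",
                ifelse(on_trunk[last_node], "trunk", "oblique"))
  structure(list(apical_points = apical_points,
                 trunk = apical_secs[cls == "trunk"],
                 oblique = apical_secs[cls == "oblique"],
                 tuft = apical_secs[cls == "tuft"]),
            class = "apical_classification")
}

#' @export
print.apical_classification <- function(x, ...) {
  cat(sprintf("<apical_classification> %d apical point(s); trunk %d, oblique %d, tuft %d sections\n",
              length(x$apical_points), length(x$trunk), length(x$oblique),
              length(x$tuft)))
  invisible(x)
}

# discretise a section into resolution segments; returns midpoints
section_segments <- function(tree, section_id, seg_resolution = 10) {
  sec <- tree$sections[tree$sections$section_id == section_id, ]
  if (nrow(sec) != 1)
    hv_stop("hippoval_swc_error", "unknown section id %s", section_id)
  L <- sec$length
  if (L <= 0)
    return(data.frame(section_id = integer(0), arc = numeric(0),
                      path_distance = numeric(0), seg_length = numeric(0)))
  m <- max(1L, ceiling(L / seg_resolution))
  arc <- (seq_len(m) - 0.5) / m
  data.frame(section_id = section_id, arc = arc,
             path_distance = sec$dist_start + arc * L,
             seg_length = L / m)
}

#' Locations on listed sections within distance ranges
#'
#' Sections are discretised into segments of at most `seg_resolution` um;
#' the midpoint of every segment whose path distance from the soma lies in
#' `[center - tol, center + tol]` (both ends inclusive) becomes a
#' candidate location.
#'
#' @param tree a `morph_tree`.
#' @param sections integer vector of section ids to scan (e.g. the trunk
#'   list of an [classify_apical()] result).
#' @param ranges list of `c(center, tolerance)` pairs in um, or a 2-column
#'   matrix/data.frame.
#' @param seg_resolution segment resolution in um.
#' @return named list (names = range centers) of data.frames with columns
#'   `section_id`, `arc`, `path_distance`, `seg_length`.  Ranges with no
#'   eligible segment are returned empty; the calling test decides policy.
#' @export
select_locations_by_distance <- function(tree, sections, ranges,
                                         seg_resolution = 10) {
  if (is.matrix(ranges) || is.data.frame(ranges))
    ranges <- lapply(seq_len(nrow(ranges)), function(i) as.numeric(ranges[i, ]))
  segs <- do.call(rbind, lapply(sections, section_segments, tree = tree,
                                seg_resolution = seg_resolution))
  out <- lapply(ranges, function(r) {
    if (is.null(segs) || nrow(segs) == 0) return(segs)
    segs[segs$path_distance >= r[1] - r[2] &
         segs$path_distance <= r[1] + r[2], , drop = FALSE]
  })
  names(out) <- vapply(ranges, function(r) format(r[1]), "")
  out
}

#' Random trunk locations with length-proportional sampling
#'
#' Draws `n` distinct resolution segments from the listed sections, each
#' with probability proportional to its length; segments outside
#' `bounds` or already drawn trigger a redraw.  When `n` meets or exceeds
#' the number of eligible segments, all of them are returned.
#'
#' @param tree a `morph_tree`.
#' @param sections trunk section ids.
#' @param n number of locations requested.
#' @param seed RNG seed; a fixed seed yields an identical selection.
#' @param bounds inclusive path-distance bounds in um (default 50-350).
#' @param seg_resolution segment resolution in um.
#' @return data.frame of locations (`section_id`, `arc`, `path_distance`,
#'   `seg_length`), in draw order.
#' @export
sample_random_trunk_locations <- function(tree, sections, n, seed,
                                          bounds = c(50, 350),
                                          seg_resolution = 10) {
  if (n < 1) hv_stop("hippoval_selection_error", "n must be >= 1")
  segs <- do.call(rbind, lapply(sections, section_segments, tree = tree,
                                seg_resolution = seg_resolution))
  if (!is.null(segs))
    segs <- segs[segs$path_distance >= bounds[1] &
                 segs$path_distance <= bounds[2], , drop = FALSE]
  if (is.null(segs) || nrow(segs) == 0)
    hv_stop("hippoval_selection_error",
            "no eligible segment in [%g, %g] um on the listed sections",
            bounds[1], bounds[2])
  if (n >= nrow(segs)) return(segs)
  chosen <- withr::with_seed(seed, {
    picked <- integer(0)
    while (length(picked) < n) {
      i <- sample.int(nrow(segs), 1L, prob = segs$seg_length)
      if (!(i %in% picked)) picked <- c(picked, i)
    }
    picked
  })
  segs[chosen, , drop = FALSE]
}
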