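# SWC handling, apical classification, location selection and sampling

test_that("a hand-written SWC parses into the expected tree", {
  f <- withr::local_tempfile(lines = c(
    "# toy cell",
    "1 1 0 0 0 6 -1",
    "2 4 0 10 0 1 1",
    "3 4 0 20 0 1 2",
    "4 4 0 30 0 1 3",
    "5 4 0 40 0 1 4"))
  tree <- read_swc(f)
  expect_equal(nrow(tree$nodes), 5)
  expect_equal(sum(tree$sections$type == "apical"), 1)
  expect_equal(tree$nodes$path_dist[5], 40)
})

test_that("malformed SWC files fail with the offending line identified", {
  f <- withr::local_tempfile(lines = c(
    "1 1 0 0 0 6 -1",
    "2 4 0 10 0 1 9"))   # undefined parent
  err <- expect_error(read_swc(f), class = "hippoval_swc_error")
  expect_match(conditionMessage(err), "line 2")
  f2 <- withr::local_tempfile(lines = c("1 3 0 0 0 6 -1"))  # non-soma root
  expect_error(read_swc(f2), class = "hippoval_swc_error")
  f3 <- withr::local_tempfile(lines = c(
    "1 1 0 0 0 6 -1",
    "1 4 0 10 0 1 1"))   # duplicate id
  expect_error(read_swc(f3), class = "hippoval_swc_error")
})

test_that("write -> read round-trips a generated morphology", {
  tree <- generate_morphology()
  f <- withr::local_tempfile(fileext = ".swc")
  write_swc(tree, f)
  tree2 <- read_swc(f)
  expect_equal(tree2$nodes$x, tree$nodes$x, tolerance = 1e-6)
  expect_equal(tree2$nodes$parent, tree$nodes$parent)
  expect_equal(tree2$nodes$type, tree$nodes$type)
  expect_equal(tree2$sections$length, tree$sections$length, tolerance = 1e-6)
  expect_equal(tree2$nodes$path_dist, tree$nodes$path_dist, tolerance = 1e-6)
})

test_that("path distance is additive and invariant under node re-labelling", {
  tree <- generate_morphology()
  # additivity: distance of a section end = section start + section length
  secs <- tree$sections[tree$sections$type != "soma", ]
  for (k in seq_len(nrow(secs))) {
    ch <- tree$section_nodes[[secs$section_id[k]]]
    expect_equal(tree$nodes$path_dist[ch[length(ch)]],
                 secs$dist_start[k] + secs$length[k], tolerance = 1e-9)
  }
  # relabel ids (order preserved): distances unchanged
  nd <- tree$nodes[, c("id", "type", "x", "y", "z", "radius", "parent")]
  nd$id <- nd$id * 10L + 3L
  nd$parent <- ifelse(nd$parent == -1L, -1L, nd$parent * 10L + 3L)
  tree3 <- build_morph_tree(nd)
  expect_equal(tree3$nodes$path_dist, tree$nodes$path_dist)
})

test_that("apical point search handles single, multiple and degenerate cases", {
  # unbranched trunk with one distal bifurcation: a single apical point
  t1 <- generate_morphology(morphology_spec(trunk_length = 300,
                                            oblique_distances = numeric(0)))
  ap1 <- find_apical_points(t1, 100)
  expect_length(ap1, 1)
  expect_equal(t1$nodes$path_dist[match(ap1, t1$nodes$id)], 300)

  # proximal trunk bifurcation: both distal bifurcations are found
  t2 <- generate_morphology(morphology_spec(proximal_bifurcation_at = 30))
  ap2 <- find_apical_points(t2, 100)
  expect_length(ap2, 2)
  expect_true(all(t2$nodes$path_dist[match(ap2, t2$nodes$id)] >= 100))

  # unbranched arbor with a single terminal: the terminal is returned
  t3 <- generate_morphology(morphology_spec(trunk_length = 80,
                                            oblique_distances = numeric(0),
                                            tuft_branches = 0))
  ap3 <- find_apical_points(t3, 100)
  expect_length(ap3, 1)
  expect_equal(t3$nodes$path_dist[match(ap3, t3$nodes$id)], 80)
})

test_that("apical points match the independent LCA oracle on random trees", {
  for (seed in 1:25) {
    tree <- generate_morphology(random_morph_spec(seed))
    got <- sort(find_apical_points(tree, 100))
    want <- oracle_apical_points(tree, 100)
    expect_equal(got, want, info = sprintf("seed %d", seed))
  }
})

test_that("classification partitions the apical arbor", {
  for (seed in c(1, 5, 9, 13)) {
    tree <- generate_morphology(random_morph_spec(seed))
    cls <- classify_apical(tree, find_apical_points(tree, 100))
    all_apical <- tree$sections$section_id[tree$sections$type == "apical"]
    expect_setequal(c(cls$trunk, cls$oblique, cls$tuft), all_apical)
    expect_length(intersect(cls$trunk, cls$oblique), 0)
    expect_length(intersect(cls$trunk, cls$tuft), 0)
    expect_length(intersect(cls$oblique, cls$tuft), 0)
    # every tuft section's root path passes through an apical point
    ap_rows <- match(cls$apical_points, tree$nodes$id)
    for (sid in cls$tuft) {
      r <- tree$section_nodes[[sid]][1]
      path <- integer(0)
      while (!is.na(r)) { path <- c(path, r); r <- tree$parent_idx[r] }
      expect_true(any(ap_rows %in% path))
    }
  }
})

test_that("trunk without side branches yields no obliques; terminal apical point yields no tuft", {
  t1 <- generate_morphology(morphology_spec(oblique_distances = numeric(0)))
  cls1 <- classify_apical(t1, find_apical_points(t1, 100))
  expect_length(cls1$oblique, 0)
  t2 <- generate_morphology(morphology_spec(trunk_length = 200,
                                            oblique_distances = numeric(0),
                                            tuft_branches = 0))
  cls2 <- classify_apical(t2, find_apical_points(t2, 100))
  expect_length(cls2$tuft, 0)
})

test_that("distance-range selection matches an exhaustive scan", {
  tree <- generate_morphology(morphology_spec(oblique_distances = numeric(0)))
  cls <- classify_apical(tree, find_apical_points(tree, 100))
  ranges <- list(c(50, 20), c(150, 20), c(250, 20), c(350, 20))
  locs <- select_locations_by_distance(tree, cls$trunk, ranges, 10)
  for (rn in names(locs)) {
    r <- as.numeric(rn)
    # 10 um segments in a +/- 20 um window: 4 +/- 1 midpoints
    expect_gte(nrow(locs[[rn]]), 3)
    expect_lte(nrow(locs[[rn]]), 5)
    expect_true(all(locs[[rn]]$path_distance >= r - 20 &
                    locs[[rn]]$path_distance <= r + 20))
  }
  # a section fully proximal to every range
  proximal <- tree$sections$section_id[tree$sections$dist_start == 0 &
                                       tree$sections$type == "apical"][1]
  short <- select_locations_by_distance(
    tree, proximal, list(c(800, 20)), 10)
  expect_equal(nrow(short[["800"]]), 0)
})

test_that("coarse segmentation can leave the 50 um range empty on a long first section", {
  # 102.66 um first section resolved into 2 segments at 25.67 and 77 um
  n <- 4
  step <- 102.66 / n
  nd <- data.frame(id = 1:(n + 1),
                   type = c("soma", rep("apical", n)),
                   x = 0, y = c(0, step * (1:n)), z = 0, radius = 1,
                   parent = c(-1L, 1:n))
  tree <- build_morph_tree(nd)
  locs <- select_locations_by_distance(tree, tree$sections$section_id[2],
                                       list(c(50, 20)),
                                       seg_resolution = 51.33)
  expect_equal(nrow(locs[["50"]]), 0)
  # finer segmentation does find locations there
  locs10 <- select_locations_by_distance(tree, tree$sections$section_id[2],
                                         list(c(50, 20)),
                                         seg_resolution = 10)
  expect_gt(nrow(locs10[["50"]]), 0)
})

test_that("random trunk sampling is deterministic, length-weighted, and exhaustive when n is large", {
  tree <- generate_morphology()
  cls <- classify_apical(tree, find_apical_points(tree, 100))
  a <- sample_random_trunk_locations(tree, cls$trunk, 5, seed = 11)
  b <- sample_random_trunk_locations(tree, cls$trunk, 5, seed = 11)
  expect_identical(a, b)
  expect_equal(nrow(a), 5)
  expect_true(all(a$path_distance >= 50 & a$path_distance <= 350))

  # n exceeding the eligible segments returns all of them
  all_segs <- sample_random_trunk_locations(tree, cls$trunk, 10000, seed = 1)
  expect_lt(nrow(all_segs), 10000)
  expect_true(all(!duplicated(all_segs[c("section_id", "arc")])))

  # two segments of 100 and 50 um drawn with probability 2:1
  nd <- data.frame(id = 1:4, type = c("soma", rep("apical", 3)),
                   x = c(0, 0, 0, 50), y = c(0, 100, 200, 100), z = 0,
                   radius = 1, parent = c(-1L, 1L, 2L, 2L))
  t2 <- build_morph_tree(nd)
  secs <- t2$sections$section_id[t2$sections$type == "apical" &
                                 t2$sections$dist_start == 100]
  expect_setequal(t2$sections$length[match(secs, t2$sections$section_id)],
                  c(100, 50))
  secs <- secs[order(-t2$sections$length[match(secs, t2$sections$section_id)])]
  draws <- vapply(1:3000, function(s)
    sample_random_trunk_locations(t2, secs, 1, seed = s,
                                  bounds = c(0, 400),
                                  seg_resolution = 500)$section_id,
    numeric(1))
  n1 <- sum(draws == secs[1])
  se <- sqrt(3000 * (2 / 3) * (1 / 3))
  expect_lt(abs(n1 - 2000), 3 * se)

  expect_error(sample_random_trunk_locations(tree, cls$trunk, 3, seed = 1,
                                             bounds = c(5000, 6000)),
               class = "hippoval_selection_error")
})
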