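test_that("cable length sums Euclidean edges and respects subsets", {
  chain <- make_chain_skeleton(rbind(c(0, 0, 0), c(3, 4, 0)))
  expect_equal(cable_length(chain), 5.0)
  expect_equal(cable_length(make_chain_skeleton(matrix(0, 1, 3))), 0.0)
  # Y-shaped tree: trunk 5, daughters 12 and 8
  nd <- data.frame(node_id = 1:4,
                   x = c(0, 3, 3, 3), y = c(0, 4, 16, 4), z = c(0, 0, 0, 8),
                   radius = 0.4, parent_id = c(NA, 1L, 2L, 2L),
                   compartment = "dendrite_basal")
  y <- skeleton(nd, "y")
  expect_equal(cable_length(y), 25.0)
  expect_equal(cable_length(y, c(2L, 3L)), 12.0)
  expect_error(cable_length(y, c(1L, 3L)), "disconnected")
  # additivity over the two daughter paths plus trunk
  expect_equal(cable_length(y, c(1L, 2L)) + cable_length(y, c(2L, 3L)) +
                 cable_length(y, c(2L, 4L)), 25.0)
})

test_that("fragment sampling traces the target length with truncation flags", {
  den <- make_line_dendrite(100)
  frs <- sample_fragments(den, target_length_um = 10, n = 5, seed = 3)
  full <- Filter(function(f) !f$truncated, frs)
  for (f in full) expect_equal(f$path_length, 10.0)
  for (f in frs)
    expect_true(f$truncated || abs(f$path_length - 10) < 1e-9)
  # deterministic under the seed
  frs2 <- sample_fragments(den, target_length_um = 10, n = 5, seed = 3)
  expect_identical(lapply(frs, `[[`, "node_ids"),
                   lapply(frs2, `[[`, "node_ids"))
  # a start 4 um from the tip gives a 4 um truncated fragment
  f <- fragment_from_nodes(den, 97:101, truncated = TRUE)
  expect_equal(f$path_length, 4.0)
  expect_true(f$truncated)
  soma_only <- make_chain_skeleton(matrix(0, 1, 3), compartment = "soma")
  expect_error(sample_fragments(soma_only, n = 1), "dendritic cable")
})

test_that("branch traversal rules follow the thicker daughter or stop", {
  nd <- data.frame(node_id = 1:5,
                   x = c(0, 5, 10, 10, 6), y = c(0, 0, 4, -4, 0) * 0 +
                     c(0, 0, 3, -3, 0), z = 0,
                   radius = c(0.4, 0.4, 0.6, 0.2, 0.2),
                   parent_id = c(NA, 1L, 2L, 2L, NA)[1:5],
                   compartment = "dendrite_basal")
  nd$parent_id <- c(NA, 1L, 2L, 2L, 3L)
  y <- skeleton(nd, "y2")
  # start from the root: traverse_branch picks node 3 (thicker)
  fr <- sample_fragments(y, target_length_um = 50, n = 1, seed = 1)
  # regardless of random start, paths never include the thin daughter 4
  # when they pass the branch
  frs <- lapply(1:6, function(s)
    sample_fragments(y, target_length_um = 50, n = 1, seed = s)[[1]])
  for (f in frs)
    if (2L %in% f$node_ids && length(f$node_ids) > 2)
      expect_false(4L %in% f$node_ids)
  stopped <- sample_fragments(y, target_length_um = 50, n = 4, seed = 2,
                              rule = "stop_at_branch")
  for (f in stopped) expect_false(all(c(3L, 4L) %in% f$node_ids))
})

test_that("fragment densities are exactly count over actual length", {
  den <- make_line_dendrite(10)
  syn <- make_synapses(den, c(2L, 4L, 6L, 8L, 10L))
  ds <- new_dataset(list(den), synapses = syn)
  fr <- fragment_from_nodes(den, den$nodes$node_id)
  rec <- fragment_density(fr, ds, "spine")
  expect_equal(rec$density, 0.5)
  # truncated 4 um fragment with 2 synapses -> 0.5/um
  fr4 <- fragment_from_nodes(den, 1:5, truncated = TRUE)
  syn2 <- make_synapses(den, c(2L, 4L))
  ds2 <- new_dataset(list(den), synapses = syn2)
  expect_equal(fragment_density(fr4, ds2, "spine")$density, 0.5)
  # splitting a fragment and pooling counts/lengths reproduces the whole
  left <- fragment_density(fragment_from_nodes(den, 1:6), ds, "spine")
  right <- fragment_density(fragment_from_nodes(den, 7:11), ds, "spine")
  pooled <- (left$count + right$count) /
    (left$path_length + right$path_length +
       cable_length(den, 6:7))  # the connecting edge
  expect_equal(pooled, rec$density)
  # filopodia density
  fil <- data.frame(filopodium_id = "f1", post_cell_id = den$cell_id,
                    base_node_id = 5L, length = 2.0)
  ds3 <- new_dataset(list(den), filopodia = fil)
  expect_equal(filopodia_density(fr, ds3)$density, 0.1)
  expect_equal(filopodia_density(fr, ds)$density, 0)
})

test_that("fragment diameter is twice the mean node radius", {
  den <- make_line_dendrite(10, radius = 0.4)
  expect_equal(fragment_diameter(fragment_from_nodes(den, 1:11)), 0.8)
  den2 <- make_chain_skeleton(cbind(0:1, 0, 0), radii = c(0.3, 0.5))
  expect_equal(fragment_diameter(fragment_from_nodes(den2, 1:2)), 0.8)
  taper <- make_chain_skeleton(cbind(0:10, 0, 0),
                               radii = seq(0.5, 0.2, length.out = 11))
  d <- fragment_diameter(fragment_from_nodes(taper, 1:11))
  expect_gte(d, 2 * 0.2)
  expect_lte(d, 2 * 0.5)
})

test_that("spine-to-shaft distance is a point-to-polyline distance in nm", {
  den <- make_line_dendrite(20)
  on_cable <- make_synapses(den, 5L)
  expect_equal(spine_branch_distance(on_cable[1, ], den), 0)
  off <- on_cable
  off$y <- 1.107
  expect_equal(spine_branch_distance(off[1, ], den), 1107)
  expect_gte(spine_branch_distance(off[1, ], den), 0)
  # invariant under a rigid rotation of skeleton and synapse together
  th <- 0.83
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  rot_nodes <- den$nodes
  xyz <- as.matrix(rot_nodes[, c("x", "y", "z")]) %*% t(R)
  rot_nodes[, c("x", "y", "z")] <- xyz
  rot_den <- skeleton(rot_nodes, "rot")
  rot_syn <- off
  rot_syn[, c("x", "y", "z")] <-
    as.numeric(R %*% c(off$x, off$y, off$z))
  expect_equal(spine_branch_distance(rot_syn[1, ], rot_den), 1107,
               tolerance = 1e-9)
  shaft <- on_cable
  shaft$target_class <- "shaft"
  expect_error(spine_branch_distance(shaft[1, ], den), "spine")
})

test_that("bulk 2D density counts qualifying synapses per FOV area", {
  ev <- data.frame(fov = rep(1L, 11),
                   vesicle_count = c(rep(12L, 9), 2L, 3L))
  res <- bulk_2d_density(ev, 20)
  expect_equal(res$per_fov$count, 9L)
  expect_equal(res$mean, 0.45)
  # adding sub-threshold distractors never changes the estimate
  more <- rbind(ev, data.frame(fov = 1L, vesicle_count = rep(1L, 50)))
  expect_equal(bulk_2d_density(more, 20)$mean, res$mean)
  # all-empty FOVs
  none <- bulk_2d_density(ev[0, ], 20, n_fov = 4)
  expect_equal(none$mean, 0)
  expect_equal(none$sem, 0)
  expect_error(bulk_2d_density(ev, 0), "positive")
})

test_that("bulk 2D density recovers a simulated density", {
  reps <- vapply(derive_seeds(31, 300), function(s) {
    ev <- generate_fov_counts(0.465, n_fov = 4, fov_area_um2 = 20, seed = s)
    bulk_2d_density(ev, 20, n_fov = 4)$mean
  }, numeric(1))
  ms <- mean_sem(reps)
  expect_lt(abs(ms$mean - 0.465), 3 * ms$sem)
})

test_that("filopodia density on synthetic adult data is near its tiny rate", {
  p105 <- load_profile("mouse_V1_L23_p105")
  seeds <- derive_seeds(32, 400)
  dens <- vapply(seq_len(400), function(i) {
    d <- generate_dendrite(p105, 10, seed = seeds[i])
    sk <- d$skeletons[[1]]
    filopodia_density(fragment_from_nodes(sk, sk$nodes$node_id), d)$density
  }, numeric(1))
  ms <- mean_sem(dens)
  expect_lt(abs(ms$mean - p105$filopodia_rate), 3 * max(ms$sem, 1e-3))
})
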