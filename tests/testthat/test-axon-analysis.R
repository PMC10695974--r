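# straight axon with synapses at chosen arc positions/targets
make_axon_dataset <- function(length_um, syn_nodes, targets,
                              axon_id = "ax1", radii = 0.25) {
  n <- round(length_um) + 1
  pts <- cbind(seq(0, length_um, length.out = n), 0, 0)
  ax <- make_chain_skeleton(pts, radii = radii, compartment = "axon",
                            skeleton_id = axon_id)
  syn <- if (length(syn_nodes) > 0) {
    pos <- ax$nodes[match(syn_nodes, ax$nodes$node_id), ]
    data.frame(synapse_id = paste0(axon_id, "_s", seq_along(syn_nodes)),
               pre_axon_id = axon_id, post_cell_id = NA_character_,
               post_node_id = syn_nodes,
               target_class = targets,
               x = pos$x, y = pos$y, z = pos$z)
  } else NULL
  if (is.null(syn)) new_dataset(list(ax))
  else new_dataset(list(ax), synapses = syn)
}

test_that("axon trace stats compute frequencies per actual cable", {
  ds <- make_axon_dataset(10, c(2L, 3L, 4L, 5L, 6L, 7L, 8L),
                          rep("spine", 7))
  st <- axon_trace_stats(ds$skeletons[[1]], ds)
  expect_equal(st$synapses_per_um, 0.7)
  expect_equal(st$branches_per_um, 0)
  expect_equal(st$branch_count, 0L)
  # adding a synapse strictly increases the frequency
  ds2 <- make_axon_dataset(10, c(2L, 3L, 4L, 5L, 6L, 7L, 8L, 9L),
                           rep("spine", 8))
  st2 <- axon_trace_stats(ds2$skeletons[[1]], ds2)
  expect_gt(st2$synapses_per_um, st$synapses_per_um)
})

test_that("classification requires additional synapses and a spine target", {
  # seed synapse at node 2 plus additional targets along the trace
  ds <- make_axon_dataset(20, c(2L, 6L, 10L, 14L),
                          c("shaft", "shaft", "shaft", "spine"))
  expect_equal(
    as.character(classify_axon(ds$skeletons[[1]], ds,
                               seed_synapse_id = "ax1_s1")),
    "excitatory")
  ds2 <- make_axon_dataset(20, c(2L, 6L, 10L, 14L),
                           c("shaft", "shaft", "shaft", "shaft"))
  expect_equal(
    as.character(classify_axon(ds2$skeletons[[1]], ds2,
                               seed_synapse_id = "ax1_s1")),
    "unclassified")
  # too few additional synapses: unclassified with the insufficiency flag
  ds3 <- make_axon_dataset(20, c(2L, 6L), c("shaft", "spine"))
  out <- classify_axon(ds3$skeletons[[1]], ds3, seed_synapse_id = "ax1_s1")
  expect_equal(as.character(out), "unclassified")
  expect_true(attr(out, "insufficient"))
})

test_that("classification is invariant to the order of non-spine synapses", {
  others <- c("shaft", "soma", "shaft")
  for (perm in list(c(1, 2, 3), c(3, 1, 2), c(2, 3, 1))) {
    tg <- c("shaft", others[perm], "spine")
    ds <- make_axon_dataset(30, c(2L, 6L, 10L, 14L, 18L), tg)
    expect_equal(
      as.character(classify_axon(ds$skeletons[[1]], ds,
                                 seed_synapse_id = "ax1_s1")),
      "excitatory")
  }
})

test_that("shaft input composition recovers the generator fraction", {
  p <- load_profile("mouse_V1_L23_p105")
  # all-inhibitory axon population -> fraction 0
  seeds <- derive_seeds(71, 40)
  parts <- lapply(seq_len(40), function(i)
    generate_axon(p, 60, seed = seeds[i], axon_id = sprintf("in%02d", i),
                  id_start = (i - 1L) * 10000L + 1L, excitatory = FALSE))
  ds0 <- combine_datasets(parts)
  r0 <- shaft_input_composition(ds0, n_sample = 30, seed = 1)
  expect_equal(r0$fraction_excitatory, 0)
  # fixed seed -> identical sample
  r0b <- shaft_input_composition(ds0, n_sample = 30, seed = 1)
  expect_identical(r0, r0b)
  expect_error(shaft_input_composition(ds0, n_sample = 1e5), "required")
  # mixture at the profile fraction: mean over replicates within 3 se
  seeds2 <- derive_seeds(72, 150)
  parts2 <- lapply(seq_len(150), function(i) {
    exc <- withr::with_seed(seeds2[i] + 1L, stats::runif(1) < 0.24)
    generate_axon(p, 60, seed = seeds2[i], axon_id = sprintf("mx%03d", i),
                  id_start = (i - 1L) * 10000L + 1L, excitatory = exc)
  })
  dsm <- combine_datasets(parts2)
  fracs <- vapply(derive_seeds(73, 40), function(s)
    shaft_input_composition(dsm, n_sample = 30, seed = s)$fraction_excitatory,
    numeric(1))
  # replicates share the axon pool, so compare against the pool's own
  # shaft-weighted excitatory fraction
  cells <- vapply(dsm$skeletons, function(s) s$cell_id, character(1))
  exc_cells <- cells[vapply(dsm$skeletons, function(s)
    s$cell_class == "excitatory", logical(1))]
  shaft <- dsm$synapses[dsm$synapses$target_class == "shaft", ]
  pool_frac <- mean(shaft$pre_axon_id %in% exc_cells)
  expect_lt(abs(mean(fracs) - pool_frac), 0.05)
  # and the pool fraction itself sits near the generator's 0.24 target
  expect_lt(abs(pool_frac - 0.24), 3 * sqrt(0.24 * 0.76 / 150))
})

test_that("bulb detection needs both swelling and clustered mitochondria", {
  ds <- make_axon_dataset(20, integer(0), character(0))
  expect_identical(detect_retraction_bulbs(ds$skeletons[[1]], ds), integer(0))
  # swollen terminal without mitochondria is not a bulb
  ax <- ds$skeletons[[1]]
  tip <- max(ax$nodes$node_id)
  ax$nodes$radius[ax$nodes$node_id == tip] <- 1.0
  ds$skeletons[[1]] <- ax
  expect_identical(detect_retraction_bulbs(ax, ds), integer(0))
  # with clustered mitochondria it is
  ds$mitochondria <- data.frame(mito_id = paste0("m", 1:3),
                                host_skeleton_id = ax$skeleton_id,
                                volume = 5e7, start_node_id = tip,
                                end_node_id = tip)
  expect_identical(detect_retraction_bulbs(ax, ds), tip)
  # lowering the radius threshold never removes a detection
  expect_identical(detect_retraction_bulbs(ax, ds, radius_factor = 1.5), tip)
  # raising it beyond the swelling removes it
  expect_identical(detect_retraction_bulbs(ax, ds, radius_factor = 10),
                   integer(0))
})

test_that("false-positive bulb rate on bulb-free axons is under 2%", {
  p <- load_profile("mouse_V1_L23_p523")
  seeds <- derive_seeds(74, 300)
  fp <- vapply(seq_len(300), function(i) {
    d <- generate_axon(p, 60, seed = seeds[i], axon_id = "a")
    length(detect_retraction_bulbs(d$skeletons[[1]], d)) > 0
  }, logical(1))
  expect_lt(mean(fp), 0.02)
  # sensitivity on bulb-bearing axons is 100%
  hit <- vapply(derive_seeds(75, 50), function(s) {
    d <- generate_axon(p, 60, seed = s, with_retraction_bulb = TRUE,
                       axon_id = "a")
    identical(detect_retraction_bulbs(d$skeletons[[1]], d),
              d$metadata$bulb_node)
  }, logical(1))
  expect_true(all(hit))
})
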