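p105 <- load_profile("mouse_V1_L23_p105")
p14 <- load_profile("mouse_V1_L23_p14")

test_that("fixed seeds make generation deterministic", {
  a <- generate_dataset(p105, n_dendrites = 3, n_somata = 2, n_axons = 2,
                        seed = 123)
  b <- generate_dataset(p105, n_dendrites = 3, n_somata = 2, n_axons = 2,
                        seed = 123)
  expect_identical(a, b)
  c <- generate_dataset(p105, n_dendrites = 3, n_somata = 2, n_axons = 2,
                        seed = 124)
  expect_false(identical(a$synapses, c$synapses))
})

test_that("generated datasets always pass validation", {
  for (nm in c("mouse_V1_L23_p6", "mouse_V1_L23_p105",
               "primate_V1_L23_p7")) {
    ds <- generate_dataset(nm, n_dendrites = 4, n_somata = 2, n_axons = 2,
                           seed = 11, bulb_fraction = 0.5)
    expect_equal(nrow(validate_dataset(ds)), 0L, info = nm)
  }
})

test_that("zero rates yield zero annotations", {
  quiet <- age_profile("mouse", "V1", "L23", 99,
                       spine_rate = 0, shaft_rate = 0, filopodia_rate = 0,
                       soma_synapse_mean = 0, axons_per_soma_mean = 0,
                       axon_synapse_rate = 0, axon_branch_rate = 0,
                       bouton_volume_mean = 0.1, vesicle_count_mean = 10,
                       psd_logmean = 11, psd_logsd = 0.5,
                       mito_density_mean = 1000, mito_synapse_corr = 0,
                       excitatory_shaft_fraction = 0.24)
  for (s in 1:5) {
    d <- generate_dendrite(quiet, 50, seed = s)
    expect_equal(nrow(d$synapses), 0L)
    expect_equal(nrow(d$filopodia), 0L)
    som <- generate_soma(quiet, seed = s)
    expect_equal(nrow(som$synapses), 0L)
    ax <- generate_axon(quiet, 50, seed = s)
    expect_equal(nrow(ax$synapses), 0L)
    expect_length(branch_nodes(ax$skeletons[[1]]), 0L)
  }
  expect_error(generate_dendrite(quiet, -3), "positive")
})

test_that("dendrite generator recovers the spine rate at fragment scale", {
  seeds <- derive_seeds(101, 200)
  dens <- vapply(seq_len(200), function(i) {
    d <- generate_dendrite(p105, 10, seed = seeds[i])
    sk <- d$skeletons[[1]]
    fragment_density(fragment_from_nodes(sk, sk$nodes$node_id),
                     d, "spine")$density
  }, numeric(1))
  ms <- mean_sem(dens)
  expect_lt(abs(ms$mean - p105$spine_rate), 3 * ms$sem)
})

test_that("soma generator recovers innervation means and conserves counts", {
  seeds <- derive_seeds(102, 300)
  tot <- ax <- numeric(300)
  for (i in seq_len(300)) {
    d <- generate_soma(p105, seed = seeds[i], cell_id = "c")
    p <- soma_profile("c", d)
    expect_equal(sum(p$per_axon_counts), p$total_soma_synapses)
    tot[i] <- p$total_soma_synapses
    ax[i] <- p$innervating_axons
  }
  ms_t <- mean_sem(tot)
  ms_a <- mean_sem(ax)
  expect_lt(abs(ms_t$mean - p105$soma_synapse_mean), 3 * ms_t$sem)
  expect_lt(abs(ms_a$mean - p105$axons_per_soma_mean), 3 * ms_a$sem)
})

test_that("axon generator recovers synapse and branch frequencies", {
  pr7 <- load_profile("primate_V1_L23_p7")
  seeds <- derive_seeds(103, 150)
  st <- t(vapply(seq_len(150), function(i) {
    d <- generate_axon(pr7, 100, seed = seeds[i], axon_id = "a")
    s <- axon_trace_stats(d$skeletons[[1]], d)
    c(s$synapses_per_um, s$branches_per_um)
  }, numeric(2)))
  ms_s <- mean_sem(st[, 1])
  ms_b <- mean_sem(st[, 2])
  expect_lt(abs(ms_s$mean - pr7$axon_synapse_rate), 3 * ms_s$sem)
  expect_lt(abs(ms_b$mean - pr7$axon_branch_rate), 3 * ms_b$sem)
})

test_that("FOV generator matches the Poisson mean and distractor rules", {
  ev <- generate_fov_counts(0, n_fov = 10, seed = 1)
  expect_equal(nrow(ev), 0L)
  # all-distractor events are all excluded by the vesicle criterion
  ev <- generate_fov_counts(0.465, n_fov = 4, fov_area_um2 = 20,
                            distractor_fraction = 1, seed = 2)
  expect_true(all(ev$vesicle_count < 5))
  expect_equal(bulk_2d_density(ev, 20, n_fov = 4)$mean, 0)
  # qualifying total ~ Poisson(density * area * n_fov)
  tots <- vapply(derive_seeds(104, 400), function(s) {
    ev <- generate_fov_counts(0.465, n_fov = 4, fov_area_um2 = 20, seed = s)
    sum(ev$vesicle_count >= 5)
  }, numeric(1))
  ms <- mean_sem(tots)
  expect_lt(abs(ms$mean - 0.465 * 20 * 4), 3 * ms$sem)
})

test_that("mitochondria generator hits the density mean and correlation", {
  ds <- generate_dataset(p105, n_dendrites = 300, seed = 201,
                         apical_fraction = 0.5)
  tab <- mito_dendrite_table(ds)
  expect_true(all(tab$total_mito_volume > 0))
  ms <- mean_sem(tab$mito_density)
  expect_lt(abs(ms$mean - p105$mito_density_mean), 3 * ms$sem)
  r_basal <- coverage_synapse_correlation(tab, "basal")$r
  expect_gt(r_basal, p105$mito_synapse_corr - 0.12)
  expect_lt(r_basal, p105$mito_synapse_corr + 0.12)
  # apical compartments target zero correlation
  r_apical <- coverage_synapse_correlation(tab, "apical")$r
  expect_lt(abs(r_apical), 0.15)
  # infeasible correlation target
  expect_error(generate_mitochondria(ds, p105, seed = 1, target_corr = 1.5),
               "infeasible")
})

test_that("retraction-bulb generation closes the loop with the detector", {
  pr75 <- load_profile("primate_V1_L23_p75")
  for (s in derive_seeds(105, 10)) {
    d <- generate_axon(pr75, 80, with_retraction_bulb = TRUE, seed = s)
    flagged <- detect_retraction_bulbs(d$skeletons[[1]], d)
    expect_identical(flagged, d$metadata$bulb_node)
  }
})
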