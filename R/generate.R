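#' @title Synthetic annotation-data generators
#' @name synthetic_data
#' @description
#' Generators that emulate the per-age measurement structure of
#' skeleton-plus-annotation datasets: homogeneous Poisson placement of
#' spine/shaft synapses and filopodia along dendritic cable, Poisson
#' somatic innervation partitioned over distinct axons, branched axons
#' with Poisson synapse and branch frequencies, log-normal synapse sizes,
#' and mitochondria whose coverage is correlated with synapse density at
#' a target Pearson r. Each generator is deterministic given its seed:
#' the same (profile, seed) pair reproduces the same dataset byte for
#' byte. Sub-streams of composite generators are derived with
#' [derive_seeds()].
NULL

#' Derive reproducible sub-seeds from a master seed
#'
#' Sub-seeds are drawn by `sample.int` from a dedicated RNG stream seeded
#' with `seed`, so composite generators can hand independent deterministic
#' streams to their parts.
#'
#' @param seed master integer seed.
#' @param n number of sub-seeds.
#' @return integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed),
                   sample.int(.Machine$integer.max - 1L, n))
}

# log-normal draws with a prescribed arithmetic mean and coefficient of
# variation; used for bouton volumes and mitochondrion sizes
rlnorm_mean_cv <- function(n, mean, cv) {
  if (mean <= 0) return(rep(0, n))
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

# shifted Poisson: support {1, 2, ...}, mean = `mean` (>= 1)
rshifted_pois <- function(n, mean) {
  1L + stats::rpois(n, max(mean - 1, 0))
}

bouton_radius_from_volume <- function(volume_um3) {
  (3 * volume_um3 / (4 * pi))^(1 / 3)
}

# unit vector orthogonal to v, uniformly random in its plane
random_perpendicular <- function(v) {
  v <- v / sqrt(sum(v^2))
  a <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * v) * v
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(v[2] * e1[3] - v[3] * e1[2],
          v[3] * e1[1] - v[1] * e1[3],
          v[1] * e1[2] - v[2] * e1[1])
  th <- stats::runif(1, 0, 2 * pi)
  cos(th) * e1 + sin(th) * e2
}

# random direction mildly jittered around `dir`
jitter_direction <- function(dir, sd = 0.15) {
  d <- dir + stats::rnorm(3, 0, sd)
  d / sqrt(sum(d^2))
}

random_unit_vector <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-8) return(v / n)
  }
}

# draw the standard synapse size/geometry marks for n synapses
draw_synapse_marks <- function(n, profile) {
  vol <- rlnorm_mean_cv(n, profile$bouton_volume_mean, 0.4)
  list(psd_area = stats::rlnorm(n, profile$psd_logmean, profile$psd_logsd),
       vesicle_count = rshifted_pois(n, profile$vesicle_count_mean),
       bouton_radius = bouton_radius_from_volume(vol),
       vesicle_cloud_size = stats::rlnorm(n, profile$vesicle_cloud_logmean,
                                          profile$vesicle_cloud_logsd))
}

#' Generate a dendrite with Poisson-placed annotations
#'
#' Builds an unbranched dendritic polyline of the requested cable length
#' and places spine synapses, shaft synapses and filopodia along it as
#' independent homogeneous Poisson processes at the profile rates. Spine
#' synapse positions are offset perpendicularly from the shaft by the
#' profile's mean spine length; shaft synapses are flagged as made by an
#' excitatory axon with probability `excitatory_shaft_fraction`. PSD
#' areas and vesicle-cloud sizes are log-normal; vesicle counts are
#' shifted Poisson; bouton radii derive from log-normal bouton volumes
#' with the profile mean.
#'
#' @param profile an [age_profile()].
#' @param length_um cable length, um (> 0).
#' @param compartment `"dendrite_basal"` or `"dendrite_apical"`.
#' @param seed integer seed.
#' @param cell_id identifier of the (synthetic) parent cell.
#' @param id_start first node id to use.
#' @param node_spacing_um polyline node spacing.
#' @return a `dataset` with one skeleton and its annotations;
#'   `metadata$axons_complete` is `FALSE` (presynaptic axons are stubs).
#' @export
generate_dendrite <- function(profile, length_um = 10,
                              compartment = "dendrite_basal",
                              seed = 1L, cell_id = "den1",
                              id_start = 1L, node_spacing_um = 0.5) {
  stopifnot(inherits(profile, "age_profile"))
  if (!is.finite(length_um) || length_um <= 0)
    stop("length_um must be positive")
  compartment <- match.arg(compartment, DENDRITE_COMPARTMENTS)
  withr::with_seed(as.integer(seed), {
    n_steps <- max(1L, round(length_um / node_spacing_um))
    spacing <- length_um / n_steps
    dirs <- matrix(0, n_steps, 3)
    d <- random_unit_vector()
    for (i in seq_len(n_steps)) {
      d <- jitter_direction(d, 0.1)
      dirs[i, ] <- d
    }
    pos <- rbind(c(0, 0, 0), apply(dirs * spacing, 2, cumsum))
    n_nodes <- n_steps + 1L
    ids <- seq.int(id_start, length.out = n_nodes)
    radius <- pmax(stats::rnorm(n_nodes, profile$dendrite_radius_um, 0.04),
                   0.08)
    nodes <- data.frame(node_id = ids, x = pos[, 1], y = pos[, 2],
                        z = pos[, 3], radius = radius,
                        parent_id = c(NA_integer_, ids[-n_nodes]),
                        compartment = compartment)
    skel <- skeleton(nodes, skeleton_id = cell_id, cell_id = cell_id,
                     cell_class = "excitatory")

    arc_to_row <- function(u) pmin(pmax(round(u / spacing) + 1L, 1L), n_nodes)
    node_dir <- function(row) dirs[pmin(pmax(row - 1L, 1L), n_steps), ,
                                   drop = FALSE]

    n_spine <- stats::rpois(1, profile$spine_rate * length_um)
    n_shaft <- stats::rpois(1, profile$shaft_rate * length_um)
    n_filo <- stats::rpois(1, profile$filopodia_rate * length_um)

    syn <- empty_synapses()
    if (n_spine + n_shaft > 0) {
      rows_sp <- arc_to_row(stats::runif(n_spine, 0, length_um))
      rows_sh <- arc_to_row(stats::runif(n_shaft, 0, length_um))
      # spine heads sit off the shaft at the spine-length offset
      off_len <- pmax(stats::rnorm(n_spine, profile$spine_offset_um, 0.12),
                      0.1)
      sp_pos <- t(vapply(seq_len(n_spine), function(i) {
        r <- rows_sp[i]
        as.numeric(pos[r, ]) + off_len[i] * random_perpendicular(node_dir(r)[1, ])
      }, numeric(3)))
      if (n_spine == 0L) sp_pos <- matrix(numeric(0), 0, 3)
      rows_all <- c(rows_sp, rows_sh)
      n_syn <- n_spine + n_shaft
      marks <- draw_synapse_marks(n_syn, profile)
      xyz <- rbind(sp_pos, pos[rows_sh, , drop = FALSE])
      syn <- data.frame(
        synapse_id = paste0(cell_id, "_s", seq_len(n_syn)),
        pre_axon_id = paste0(cell_id, "_ax", seq_len(n_syn)),
        post_cell_id = cell_id,
        post_node_id = ids[rows_all],
        target_class = rep(c("spine", "shaft"), c(n_spine, n_shaft)),
        x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
        psd_area = marks$psd_area,
        vesicle_count = marks$vesicle_count,
        bouton_radius = marks$bouton_radius,
        vesicle_cloud_size = marks$vesicle_cloud_size,
        pre_excitatory = c(rep(TRUE, n_spine),
                           stats::runif(n_shaft) <
                             profile$excitatory_shaft_fraction))
    }
    fil <- empty_filopodia()
    if (n_filo > 0) {
      rows_f <- arc_to_row(stats::runif(n_filo, 0, length_um))
      fil <- data.frame(
        filopodium_id = paste0(cell_id, "_f", seq_len(n_filo)),
        post_cell_id = cell_id,
        base_node_id = ids[rows_f],
        length = rlnorm_mean_cv(n_filo, 2.5, 0.4))
    }
    new_dataset(skeletons = list(skel), synapses = syn, filopodia = fil,
                metadata = list(species = profile$species,
                                region = profile$region,
                                layer = profile$layer,
                                age_days = profile$age_days,
                                profile = profile$name,
                                seed = as.integer(seed),
                                axons_complete = FALSE))
  })
}

#' Generate a soma with multi-axon somatic innervation
#'
#' The number of distinct innervating axons is Poisson with the profile
#' mean; each axon contributes `1 + Poisson(m - 1)` synapses where `m` is
#' `soma_synapse_mean / axons_per_soma_mean`, so the expected total
#' somatic synapse count equals `soma_synapse_mean`. Synapses are placed
#' on the soma sphere surface with bouton radii drawn from the bouton
#' volume distribution.
#'
#' @inheritParams generate_dendrite
#' @return a `dataset` with a one-node soma skeleton; its cell id is
#'   listed under `metadata$complete_somata`.
#' @export
generate_soma <- function(profile, seed = 1L, cell_id = "soma1",
                          id_start = 1L) {
  stopifnot(inherits(profile, "age_profile"))
  withr::with_seed(as.integer(seed), {
    r <- profile$soma_radius_um
    nodes <- data.frame(node_id = as.integer(id_start), x = 0, y = 0, z = 0,
                        radius = r, parent_id = NA_integer_,
                        compartment = "soma")
    skel <- skeleton(nodes, skeleton_id = cell_id, cell_id = cell_id,
                     cell_class = "excitatory")
    n_axons <- stats::rpois(1, profile$axons_per_soma_mean)
    syn <- empty_synapses()
    if (n_axons > 0) {
      per_axon_mean <- if (profile$axons_per_soma_mean > 0)
        profile$soma_synapse_mean / profile$axons_per_soma_mean else 1
      counts <- rshifted_pois(n_axons, per_axon_mean)
      n_syn <- sum(counts)
      axon_of <- rep(seq_len(n_axons), counts)
      # uniform points on the soma sphere
      u <- matrix(stats::rnorm(3 * n_syn), ncol = 3)
      u <- u / sqrt(rowSums(u^2))
      marks <- draw_synapse_marks(n_syn, profile)
      syn <- data.frame(
        synapse_id = paste0(cell_id, "_s", seq_len(n_syn)),
        pre_axon_id = paste0(cell_id, "_ax", axon_of),
        post_cell_id = cell_id,
        post_node_id = as.integer(id_start),
        target_class = "soma",
        x = r * u[, 1], y = r * u[, 2], z = r * u[, 3],
        psd_area = marks$psd_area,
        vesicle_count = marks$vesicle_count,
        bouton_radius = marks$bouton_radius,
        vesicle_cloud_size = marks$vesicle_cloud_size,
        pre_excitatory = FALSE)
    }
    new_dataset(skeletons = list(skel), synapses = syn,
                metadata = list(species = profile$species,
                                region = profile$region,
                                layer = profile$layer,
                                age_days = profile$age_days,
                                profile = profile$name,
                                seed = as.integer(seed),
                                axons_complete = FALSE,
                                complete_somata = cell_id))
  })
}

#' Generate an axon with branches, output synapses and optional
#' retraction bulb
#'
#' The axon grows as a tree of fixed total cable length: branch events
#' are Poisson at `axon_branch_rate` per um and each converts the current
#' tip into a branch point with two daughters, so the realized branch
#' count divided by cable length is an unbiased estimate of the rate.
#' Output synapses are Poisson at `axon_synapse_rate` per um with
#' spine/shaft/soma targets (spine-rich when `excitatory`). With
#' `with_retraction_bulb`, one terminal node is swollen to
#' `bulb_radius_factor` times the median axon radius and at least
#' `n_bulb_mitos` mitochondria are clustered at it.
#'
#' @inheritParams generate_dendrite
#' @param axon_id identifier for the axon (used as cell id).
#' @param with_retraction_bulb add a terminal retraction bulb.
#' @param excitatory latent class; excitatory axons target spines
#'   predominantly, non-excitatory axons target shafts and somata only.
#' @param bulb_radius_factor terminal swelling relative to the median
#'   axon radius.
#' @param n_bulb_mitos mitochondria packed into the bulb.
#' @return a `dataset` with one axon skeleton, its output synapses
#'   (postsynaptic partners are external, `post_cell_id = NA`) and any
#'   bulb mitochondria.
#' @export
generate_axon <- function(profile, length_um = 100,
                          with_retraction_bulb = FALSE, seed = 1L,
                          axon_id = "axon1", id_start = 1L,
                          excitatory = TRUE, node_spacing_um = 1,
                          bulb_radius_factor = 3, n_bulb_mitos = 5) {
  stopifnot(inherits(profile, "age_profile"))
  if (!is.finite(length_um) || length_um <= 0)
    stop("length_um must be positive")
  withr::with_seed(as.integer(seed), {
    total_steps <- max(2L, round(length_um / node_spacing_um))
    spacing <- length_um / total_steps
    n_branch <- stats::rpois(1, profile$axon_branch_rate * length_um)
    n_branch <- min(n_branch, (total_steps - 1L) %/% 2L)
    branch_at <- sort(sample.int(total_steps - 1L, n_branch))

    ids <- seq.int(id_start, length.out = total_steps + 1L)
    xs <- ys <- zs <- numeric(total_steps + 1L)
    parent <- rep(NA_integer_, total_steps + 1L)
    # tips: list of (row index of tip node, direction)
    tips <- list(list(row = 1L, dir = random_unit_vector()))
    next_row <- 2L
    used <- 0L
    bi <- 1L
    creation_arc <- numeric(total_steps + 1L)  # cable length when node added
    while (used < total_steps) {
      branching <- bi <= length(branch_at) && branch_at[bi] <= used &&
        (total_steps - used) >= 2L
      ti <- sample.int(length(tips), 1L)
      tip <- tips[[ti]]
      if (branching) {
        # the tip node becomes a branch point with two daughters
        for (k in 1:2) {
          d <- jitter_direction(tip$dir, 0.5)
          r <- next_row
          parent[r] <- ids[tip$row]
          xs[r] <- xs[tip$row] + spacing * d[1]
          ys[r] <- ys[tip$row] + spacing * d[2]
          zs[r] <- zs[tip$row] + spacing * d[3]
          used <- used + 1L
          creation_arc[r] <- used * spacing
          tips[[if (k == 1) ti else length(tips) + 1L]] <-
            list(row = r, dir = d)
          next_row <- next_row + 1L
        }
        bi <- bi + 1L
      } else {
        d <- jitter_direction(tip$dir, 0.12)
        r <- next_row
        parent[r] <- ids[tip$row]
        xs[r] <- xs[tip$row] + spacing * d[1]
        ys[r] <- ys[tip$row] + spacing * d[2]
        zs[r] <- zs[tip$row] + spacing * d[3]
        used <- used + 1L
        creation_arc[r] <- used * spacing
        tips[[ti]] <- list(row = r, dir = d)
        next_row <- next_row + 1L
      }
    }
    n_nodes <- next_row - 1L
    radius <- pmax(stats::rnorm(n_nodes, profile$axon_radius_um, 0.03), 0.08)
    nodes <- data.frame(node_id = ids[seq_len(n_nodes)],
                        x = xs[seq_len(n_nodes)], y = ys[seq_len(n_nodes)],
                        z = zs[seq_len(n_nodes)],
                        radius = radius,
                        parent_id = parent[seq_len(n_nodes)],
                        compartment = "axon")
    mito <- empty_mitochondria()
    bulb_node <- NA_integer_
    if (with_retraction_bulb) {
      tip_rows <- which(!nodes$node_id %in% nodes$parent_id)
      bulb_row <- sample(tip_rows, 1L)
      nodes$radius[bulb_row] <- bulb_radius_factor *
        stats::median(nodes$radius[-bulb_row])
      bulb_node <- nodes$node_id[bulb_row]
      mito <- data.frame(
        mito_id = paste0(axon_id, "_m", seq_len(n_bulb_mitos)),
        host_skeleton_id = axon_id,
        volume = rlnorm_mean_cv(n_bulb_mitos, 5e7, 0.3),
        start_node_id = bulb_node, end_node_id = bulb_node)
    }
    skel <- skeleton(nodes, skeleton_id = axon_id, cell_id = axon_id,
                     cell_class = if (excitatory) "excitatory"
                                  else "unclassified")

    n_syn <- stats::rpois(1, profile$axon_synapse_rate * length_um)
    syn <- empty_synapses()
    if (n_syn > 0) {
      u <- stats::runif(n_syn, 0, length_um)
      # map arc position at placement to the node added at that length
      rows <- vapply(u, function(ui) {
        which.min(abs(creation_arc[seq_len(n_nodes)] - ui))
      }, integer(1))
      probs <- if (excitatory) c(spine = 0.65, shaft = 0.25, soma = 0.10)
               else c(spine = 0, shaft = 0.5, soma = 0.5)
      target <- sample(names(probs), n_syn, replace = TRUE, prob = probs)
      marks <- draw_synapse_marks(n_syn, profile)
      syn <- data.frame(
        synapse_id = paste0(axon_id, "_s", seq_len(n_syn)),
        pre_axon_id = axon_id,
        post_cell_id = NA_character_,
        post_node_id = nodes$node_id[rows],
        target_class = target,
        x = nodes$x[rows], y = nodes$y[rows], z = nodes$z[rows],
        psd_area = marks$psd_area,
        vesicle_count = marks$vesicle_count,
        bouton_radius = marks$bouton_radius,
        vesicle_cloud_size = marks$vesicle_cloud_size,
        pre_excitatory = excitatory)
    }
    new_dataset(skeletons = list(skel), synapses = syn,
                mitochondria = mito,
                metadata = list(species = profile$species,
                                region = profile$region,
                                layer = profile$layer,
                                age_days = profile$age_days,
                                profile = profile$name,
                                seed = as.integer(seed),
                                axons_complete = FALSE,
                                bulb_node = bulb_node))
  })
}

#' Generate per-field-of-view synapse counts for bulk 2D density
#'
#' Synapse events per field of view (FOV) are Poisson with mean
#' `density_per_um2 * fov_area_um2`. Each event is independently
#' sub-threshold (fewer than 5 vesicles, a distractor excluded by the
#' bulk density criterion) with probability `distractor_fraction`;
#' qualifying events get at least 5 vesicles.
#'
#' @param density_per_um2 true 2D synapse density.
#' @param n_fov number of fields of view (>= 1).
#' @param fov_area_um2 FOV area (> 0).
#' @param distractor_fraction probability an event is sub-threshold.
#' @param vesicle_mean mean vesicle count of qualifying events.
#' @param seed integer seed.
#' @return data.frame with one row per synapse event: `fov`,
#'   `vesicle_count`.
#' @export
generate_fov_counts <- function(density_per_um2, n_fov = 4,
                                fov_area_um2 = 20,
                                distractor_fraction = 0,
                                vesicle_mean = 30, seed = 1L) {
  if (n_fov < 1) stop("n_fov must be >= 1")
  if (fov_area_um2 <= 0) stop("fov_area_um2 must be positive")
  if (density_per_um2 < 0) stop("density_per_um2 must be >= 0")
  withr::with_seed(as.integer(seed), {
    n <- stats::rpois(n_fov, density_per_um2 * fov_area_um2)
    fov <- rep(seq_len(n_fov), n)
    total <- sum(n)
    sub <- stats::runif(total) < distractor_fraction
    vc <- integer(total)
    vc[sub] <- sample(0:4, sum(sub), replace = TRUE)
    vc[!sub] <- 5L + stats::rpois(sum(!sub), max(vesicle_mean - 5, 0))
    data.frame(fov = fov, vesicle_count = vc)
  })
}

#' Generate mitochondria over a collection of dendrites
#'
#' Per-dendrite mitochondria density (total volume per cable length, nm2)
#' follows `a + b * spine_density + noise`, with slope and noise solved so
#' that the mean density matches `mito_density_mean` and the
#' across-dendrite Pearson correlation with spine-synapse density matches
#' `mito_synapse_corr` for basal dendrites (apical dendrites use target
#' correlation 0). The total volume is split into instances around
#' `mean_mito_size_um3`.
#'
#' @param dendrites a `dataset` of generated dendrites with their
#'   synapses.
#' @param profile an [age_profile()].
#' @param seed integer seed.
#' @param target_corr override the profile correlation target (checked to
#'   lie in `[-1, 1]`).
#' @return data.frame of mitochondrion instances (`mito_id`,
#'   `host_skeleton_id`, `volume` nm3, `start_node_id`, `end_node_id`).
#' @export
generate_mitochondria <- function(dendrites, profile, seed = 1L,
                                  target_corr = NULL) {
  stopifnot(inherits(dendrites, "dataset"), inherits(profile, "age_profile"))
  withr::with_seed(as.integer(seed), {
    skels <- Filter(function(s) any(s$nodes$compartment %in%
                                    DENDRITE_COMPARTMENTS),
                    dendrites$skeletons)
    if (length(skels) == 0L) return(empty_mitochondria())
    comp <- vapply(skels, function(s) {
      names(which.max(table(s$nodes$compartment)))
    }, character(1))
    len <- vapply(skels, cable_length, numeric(1))
    sdens <- vapply(skels, function(s) {
      n <- sum(dendrites$synapses$post_cell_id == s$cell_id &
               dendrites$synapses$target_class == "spine", na.rm = TRUE)
      n / cable_length(s)
    }, numeric(1))
    out <- list()
    for (cp in unique(comp)) {
      i <- which(comp == cp)
      r <- if (!is.null(target_corr)) target_corr
           else if (cp == "dendrite_basal") profile$mito_synapse_corr else 0
      if (abs(r) > 1) stop("infeasible correlation target |r| > 1")
      m <- profile$mito_density_mean
      sd_d <- profile$mito_density_cv * m
      sd_s <- stats::sd(sdens[i])
      b <- if (length(i) >= 2 && !is.na(sd_s) && sd_s > 0) r * sd_d / sd_s
           else 0
      a <- m - b * mean(sdens[i])
      dens <- a + b * sdens[i] +
        stats::rnorm(length(i), 0, sd_d * sqrt(max(1 - r^2, 0)))
      dens <- pmax(dens, 0.01 * m)
      vol_tot <- dens * len[i] * 1000  # nm3 = nm2 * (um cable -> nm)
      for (k in seq_along(i)) {
        s <- skels[[i[k]]]
        cnt <- max(1L, round(vol_tot[k] / (profile$mean_mito_size_um3 * 1e9)))
        w <- stats::rgamma(cnt, shape = 6)
        vols <- vol_tot[k] * w / sum(w)
        span <- matrix(sample(s$nodes$node_id, 2L * cnt, replace = TRUE),
                       ncol = 2)
        out[[length(out) + 1L]] <- data.frame(
          mito_id = paste0(s$skeleton_id, "_m", seq_len(cnt)),
          host_skeleton_id = s$skeleton_id,
          volume = vols,
          start_node_id = pmin(span[, 1], span[, 2]),
          end_node_id = pmax(span[, 1], span[, 2]))
      }
    }
    do.call(rbind, out)
  })
}

#' Generate a full synthetic dataset for one age profile
#'
#' Assembles dendrites (with mitochondria), somata and axons generated
#' from one profile into a single `dataset` with globally unique node and
#' annotation identifiers. Deterministic given `seed`; component
#' sub-seeds come from [derive_seeds()].
#'
#' @param profile an [age_profile()] or bundled profile name.
#' @param n_dendrites,n_somata,n_axons component counts.
#' @param seed integer master seed.
#' @param dendrite_length_um,axon_length_um component cable lengths.
#' @param apical_fraction fraction of dendrites labelled apical (the rest
#'   are basal).
#' @param bulb_fraction fraction of axons generated with a retraction
#'   bulb.
#' @param prefix string prepended to all cell ids.
#' @return a `dataset`.
#' @export
generate_dataset <- function(profile, n_dendrites = 0, n_somata = 0,
                             n_axons = 0, seed = 1L,
                             dendrite_length_um = 10,
                             axon_length_um = 100,
                             apical_fraction = 0.5, bulb_fraction = 0,
                             prefix = "") {
  if (is.character(profile)) profile <- load_profile(profile)
  stopifnot(inherits(profile, "age_profile"))
  total <- n_dendrites + n_somata + n_axons
  if (total == 0L) stop("nothing to generate: all component counts are zero")
  seeds <- derive_seeds(seed, total + 1L)
  parts <- vector("list", total)
  k <- 0L
  n_apical <- round(n_dendrites * apical_fraction)
  for (i in seq_len(n_dendrites)) {
    k <- k + 1L
    parts[[k]] <- generate_dendrite(
      profile, length_um = dendrite_length_um,
      compartment = if (i <= n_apical) "dendrite_apical" else "dendrite_basal",
      seed = seeds[k], cell_id = sprintf("%sden%04d", prefix, i),
      id_start = (k - 1L) * 100000L + 1L)
  }
  for (i in seq_len(n_somata)) {
    k <- k + 1L
    parts[[k]] <- generate_soma(profile, seed = seeds[k],
                                cell_id = sprintf("%ssoma%04d", prefix, i),
                                id_start = (k - 1L) * 100000L + 1L)
  }
  n_bulb <- round(n_axons * bulb_fraction)
  for (i in seq_len(n_axons)) {
    k <- k + 1L
    parts[[k]] <- generate_axon(profile, length_um = axon_length_um,
                                with_retraction_bulb = i <= n_bulb,
                                seed = seeds[k],
                                axon_id = sprintf("%saxon%04d", prefix, i),
                                id_start = (k - 1L) * 100000L + 1L)
  }
  ds <- combine_datasets(parts)
  if (n_dendrites > 0) {
    mito <- generate_mitochondria(ds, profile, seed = seeds[total + 1L])
    ds$mitochondria <- rbind(ds$mitochondria, mito)
  }
  ds$metadata <- list(species = profile$species, region = profile$region,
                      layer = profile$layer, age_days = profile$age_days,
                      profile = profile$name, seed = as.integer(seed),
                      axons_complete = FALSE,
                      complete_somata = unlist(lapply(
                        parts, function(p) p$metadata$complete_somata)))
  ds
}
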