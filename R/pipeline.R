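#' @title Pipeline orchestration
#' @name pipeline
#' @description
#' Reproducible simulate -> measure -> compare runs over a set of age
#' profiles: per-dataset measurement CSVs, pairwise comparison JSONs
#' with star-style significance annotations, an age-series summary table
#' (mean +/- sem per age and metric) and a machine-readable manifest
#' carrying every seed. The run is deterministic under a fixed config.
NULL

#' Build a run configuration
#'
#' @param profiles character vector of bundled profile names (or profile
#'   JSON paths).
#' @param n_dendrites,n_somata,n_axons per-profile component counts.
#' @param seed master seed; per-profile seeds are derived with
#'   [derive_seeds()].
#' @param fragment_length_um,n_fragments dendrite fragment sampling
#'   parameters.
#' @param comparisons list of 2-element character vectors naming profile
#'   pairs to compare (default: adjacent profiles in `profiles`).
#' @param out_dir output directory.
#' @return list of class `run_config`.
#' @export
run_config <- function(profiles, n_dendrites = 20, n_somata = 8,
                       n_axons = 20, seed = 1L, fragment_length_um = 10,
                       n_fragments = 20, comparisons = NULL,
                       out_dir = tempfile("isochron_run_")) {
  if (length(profiles) == 0L) stop("config lists no profiles")
  if (n_dendrites + n_somata + n_axons == 0L)
    stop("config would generate zero datasets: all component counts are zero")
  bundled <- tryCatch(list_profiles(), error = function(e) character(0))
  for (p in profiles)
    if (!file.exists(p) && !p %in% bundled)
      stop("unknown profile '", p, "'; bundled profiles: ",
           paste(bundled, collapse = ", "))
  if (is.null(comparisons) && length(profiles) >= 2)
    comparisons <- Map(c, profiles[-length(profiles)], profiles[-1])
  structure(list(profiles = profiles, n_dendrites = n_dendrites,
                 n_somata = n_somata, n_axons = n_axons,
                 seed = as.integer(seed),
                 fragment_length_um = fragment_length_um,
                 n_fragments = n_fragments,
                 comparisons = comparisons, out_dir = out_dir),
            class = "run_config")
}

#' Read a run configuration from YAML or JSON
#' @param path config file; fields as in [run_config()].
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(cfg$comparisons) && is.data.frame(cfg$comparisons))
    cfg$comparisons <- split(as.matrix(cfg$comparisons),
                             seq_len(nrow(cfg$comparisons)))
  do.call(run_config, cfg)
}

measure_profile_dataset <- function(ds, cfg, seed) {
  dends <- Filter(function(s) any(s$nodes$compartment %in%
                                  DENDRITE_COMPARTMENTS), ds$skeletons)
  # each generated dendrite is one traced fragment of the target length
  dens <- list()
  for (i in seq_len(min(length(dends), cfg$n_fragments))) {
    fr <- fragment_from_nodes(dends[[i]], dends[[i]]$nodes$node_id,
                              truncated = cable_length(dends[[i]]) <
                                cfg$fragment_length_um - 1e-6)
    dens[[i]] <- density_record(fr, ds)
  }
  dens <- do.call(rbind, dens)
  somas <- soma_profile_table(ds)
  axons <- Filter(function(s) any(s$nodes$compartment == "axon"),
                  ds$skeletons)
  axst <- if (length(axons) > 0)
    do.call(rbind, lapply(axons, function(a) axon_trace_stats(a, ds)))
  else NULL
  mito <- if (length(dends) > 0 && nrow(ds$mitochondria) > 0)
    mito_dendrite_table(ds)
  else NULL
  list(densities = dens, somas = somas, axons = axst, mito = mito)
}

#' Run the full simulate/measure/compare pipeline
#'
#' For each profile in the config: generates a dataset, writes its
#' bundle and measurement CSVs; then runs the configured pairwise
#' comparisons (two-tailed Mann-Whitney U on fragment spine densities
#' and per-soma synapse counts), writes an age-series summary table and
#' a manifest with all seeds.
#'
#' @param config a [run_config()] or path to a YAML/JSON config.
#' @param quiet suppress progress messages.
#' @return (invisibly) list with `summary` (data.frame), `comparisons`
#'   (list), `out_dir`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  cfg <- config
  say <- function(...) if (!quiet) message(...)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- derive_seeds(cfg$seed, 2L * length(cfg$profiles))
  measured <- list()
  summary_rows <- list()
  for (i in seq_along(cfg$profiles)) {
    pname <- cfg$profiles[i]
    prof <- load_profile(pname)
    say("[simulate] ", pname, " seed=", seeds[i])
    ds <- generate_dataset(prof,
                           n_dendrites = cfg$n_dendrites,
                           n_somata = cfg$n_somata,
                           n_axons = cfg$n_axons, seed = seeds[i])
    pdir <- file.path(cfg$out_dir, prof$name)
    write_dataset(ds, file.path(pdir, "dataset"))
    say("[measure] ", pname)
    m <- measure_profile_dataset(ds, cfg, seeds[length(cfg$profiles) + i])
    utils::write.csv(m$densities, file.path(pdir, "densities.csv"),
                     row.names = FALSE)
    utils::write.csv(m$somas, file.path(pdir, "soma_profiles.csv"),
                     row.names = FALSE)
    if (!is.null(m$axons))
      utils::write.csv(m$axons, file.path(pdir, "axon_stats.csv"),
                       row.names = FALSE)
    if (!is.null(m$mito))
      utils::write.csv(m$mito, file.path(pdir, "mito.csv"),
                       row.names = FALSE)
    ntr <- sum(m$densities$truncated)
    if (ntr > 0) say("[measure] ", pname, ": ", ntr, " truncated fragment(s)")
    measured[[prof$name]] <- m
    ms_sp <- mean_sem(m$densities$spine_density)
    ms_sh <- mean_sem(m$densities$shaft_density)
    ms_fl <- mean_sem(m$densities$filopodia_density)
    ms_so <- if (nrow(m$somas) > 0) mean_sem(m$somas$total_soma_synapses)
             else list(mean = NA, sem = NA)
    ms_ax <- if (nrow(m$somas) > 0) mean_sem(m$somas$innervating_axons)
             else list(mean = NA, sem = NA)
    ms_sy <- if (!is.null(m$axons)) mean_sem(m$axons$synapses_per_um)
             else list(mean = NA, sem = NA)
    ms_br <- if (!is.null(m$axons)) mean_sem(m$axons$branches_per_um)
             else list(mean = NA, sem = NA)
    summary_rows[[i]] <- data.frame(
      profile = prof$name, species = prof$species, age_days = prof$age_days,
      spine_density_mean = ms_sp$mean, spine_density_sem = ms_sp$sem,
      shaft_density_mean = ms_sh$mean, shaft_density_sem = ms_sh$sem,
      filopodia_density_mean = ms_fl$mean, filopodia_density_sem = ms_fl$sem,
      soma_synapses_mean = ms_so$mean, soma_synapses_sem = ms_so$sem,
      axons_per_soma_mean = ms_ax$mean, axons_per_soma_sem = ms_ax$sem,
      axon_synapses_per_um_mean = ms_sy$mean,
      axon_synapses_per_um_sem = ms_sy$sem,
      axon_branches_per_um_mean = ms_br$mean,
      axon_branches_per_um_sem = ms_br$sem)
  }
  summary <- do.call(rbind, summary_rows)
  summary <- summary[order(summary$species, summary$age_days), ]
  utils::write.csv(summary, file.path(cfg$out_dir, "age_series_summary.csv"),
                   row.names = FALSE)
  comparisons <- list()
  for (pair in cfg$comparisons) {
    a <- load_profile(pair[1])$name
    b <- load_profile(pair[2])$name
    say("[compare] ", a, " vs ", b)
    cmp <- list()
    for (metric in c("spine_density", "shaft_density")) {
      t <- mann_whitney_u(measured[[a]]$densities[[metric]],
                          measured[[b]]$densities[[metric]])
      cmp[[metric]] <- list(U = t$statistic_U, p = t$p_two_tailed,
                            significance = significance_stars(t$p_two_tailed),
                            method = t$method,
                            mean_a = t$mean_sem_a$mean,
                            sem_a = t$mean_sem_a$sem,
                            mean_b = t$mean_sem_b$mean,
                            sem_b = t$mean_sem_b$sem)
    }
    if (nrow(measured[[a]]$somas) > 0 && nrow(measured[[b]]$somas) > 0) {
      t <- mann_whitney_u(measured[[a]]$somas$total_soma_synapses,
                          measured[[b]]$somas$total_soma_synapses)
      cmp$soma_synapses <- list(U = t$statistic_U, p = t$p_two_tailed,
                                significance = significance_stars(t$p_two_tailed),
                                method = t$method,
                                mean_a = t$mean_sem_a$mean,
                                sem_a = t$mean_sem_a$sem,
                                mean_b = t$mean_sem_b$mean,
                                sem_b = t$mean_sem_b$sem)
    }
    key <- paste0(a, "_vs_", b)
    comparisons[[key]] <- cmp
    jsonlite::write_json(cmp,
                         file.path(cfg$out_dir, paste0(key, ".json")),
                         auto_unbox = TRUE, digits = NA)
  }
  cfg_record <- unclass(cfg)
  cfg_record$out_dir <- NULL  # location is not part of the run identity
  manifest <- list(package_version = as.character(utils::packageVersion("isochron")),
                   r_version = paste(R.version$major, R.version$minor,
                                     sep = "."),
                   master_seed = cfg$seed,
                   profile_seeds = stats::setNames(
                     as.list(seeds[seq_along(cfg$profiles)]), cfg$profiles),
                   config = cfg_record)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(summary = summary, comparisons = comparisons,
                 out_dir = cfg$out_dir))
}
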