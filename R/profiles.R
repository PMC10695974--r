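#' Age profiles: per-age generator parameter sets
#'
#' An age profile names one (species, region, layer, postnatal day)
#' condition and carries the mean rates and distribution parameters the
#' synthetic generators draw from: spine/shaft/filopodia densities along
#' dendritic cable (per um), somatic innervation means (synapses and
#' distinct axons per soma), axonal synapse and branch frequencies,
#' bouton volume and vesicle-count means, log-normal PSD-area parameters
#' (log nm2), mitochondria density (nm2 = nm3 of mitochondrion per nm of
#' cable) and the target Pearson correlation between mitochondria
#' coverage and synapse density in basal dendrites.
#'
#' Bundled profiles (see [list_profiles()]) encode the measured means for
#' mouse V1 L2/3 at postnatal days 6, 14, 36, 105 and 523 and macaque V1
#' L2/3 at days 7, 75 and 3000.
#'
#' @param species `"mouse"` or `"primate"`.
#' @param region `"V1"` or `"S1"`.
#' @param layer `"L23"` or `"L4"`.
#' @param age_days postnatal day.
#' @param spine_rate,shaft_rate,filopodia_rate densities per um of
#'   dendritic cable.
#' @param soma_synapse_mean mean somatic synapses per soma.
#' @param axons_per_soma_mean mean distinct innervating axons per soma.
#' @param axon_synapse_rate,axon_branch_rate per um of axonal cable.
#' @param bouton_volume_mean um3.
#' @param vesicle_count_mean vesicles per bouton.
#' @param psd_logmean,psd_logsd log-normal parameters of PSD area (log nm2).
#' @param mito_density_mean nm2 (mitochondrial nm3 per nm of cable).
#' @param mito_synapse_corr target Pearson r between mitochondria density
#'   and spine-synapse density across basal dendrites, in `[-1, 1]`.
#' @param excitatory_shaft_fraction proportion of shaft synapses made by
#'   excitatory axons.
#' @param ... optional extras with defaults: `spine_offset_um` (mean
#'   spine length, i.e. synapse-to-shaft distance), `soma_radius_um`,
#'   `dendrite_radius_um`, `axon_radius_um`, `mean_mito_size_um3`,
#'   `mito_density_cv`, `vesicle_cloud_logmean`, `vesicle_cloud_logsd`,
#'   `name`.
#' @return object of class `age_profile`.
#' @export
age_profile <- function(species, region, layer, age_days,
                        spine_rate, shaft_rate, filopodia_rate,
                        soma_synapse_mean, axons_per_soma_mean,
                        axon_synapse_rate, axon_branch_rate,
                        bouton_volume_mean, vesicle_count_mean,
                        psd_logmean, psd_logsd,
                        mito_density_mean, mito_synapse_corr,
                        excitatory_shaft_fraction, ...) {
  extras <- list(...)
  p <- list(species = match.arg(species, c("mouse", "primate")),
            region = match.arg(region, c("V1", "S1")),
            layer = match.arg(layer, c("L23", "L4")),
            age_days = as.integer(age_days),
            spine_rate = spine_rate, shaft_rate = shaft_rate,
            filopodia_rate = filopodia_rate,
            soma_synapse_mean = soma_synapse_mean,
            axons_per_soma_mean = axons_per_soma_mean,
            axon_synapse_rate = axon_synapse_rate,
            axon_branch_rate = axon_branch_rate,
            bouton_volume_mean = bouton_volume_mean,
            vesicle_count_mean = vesicle_count_mean,
            psd_logmean = psd_logmean, psd_logsd = psd_logsd,
            mito_density_mean = mito_density_mean,
            mito_synapse_corr = mito_synapse_corr,
            excitatory_shaft_fraction = excitatory_shaft_fraction)
  defaults <- list(spine_offset_um = 1.1, soma_radius_um = 7.5,
                   dendrite_radius_um = 0.35, axon_radius_um = 0.25,
                   mean_mito_size_um3 = 0.05, mito_density_cv = 0.3,
                   vesicle_cloud_logmean = log(2e7) - 0.125,
                   vesicle_cloud_logsd = 0.5,
                   name = paste0(p$species, "_", p$region, "_", p$layer,
                                 "_p", p$age_days))
  for (k in names(defaults))
    p[[k]] <- extras[[k]] %||% defaults[[k]]
  rates <- c("spine_rate", "shaft_rate", "filopodia_rate",
             "soma_synapse_mean", "axons_per_soma_mean",
             "axon_synapse_rate", "axon_branch_rate",
             "bouton_volume_mean", "vesicle_count_mean",
             "mito_density_mean")
  for (k in rates)
    if (!is.finite(p[[k]]) || p[[k]] < 0)
      stop("profile field ", k, " must be a non-negative number")
  if (p$excitatory_shaft_fraction < 0 || p$excitatory_shaft_fraction > 1)
    stop("excitatory_shaft_fraction must lie in [0, 1]")
  if (abs(p$mito_synapse_corr) > 1)
    stop("mito_synapse_corr must lie in [-1, 1]")
  if (p$psd_logsd <= 0) stop("psd_logsd must be positive")
  structure(p, class = "age_profile")
}

#' @export
print.age_profile <- function(x, ...) {
  cat(sprintf("<age_profile %s> spine %.3g/um, shaft %.3g/um, soma %.3g syn / %.3g axons\n",
              x$name, x$spine_rate, x$shaft_rate, x$soma_synapse_mean,
              x$axons_per_soma_mean))
  invisible(x)
}

profile_dir <- function() {
  system.file("extdata", "profiles", package = "isochron", mustWork = TRUE)
}

#' List bundled age-profile names
#' @return character vector of names accepted by [load_profile()].
#' @export
list_profiles <- function() {
  sort(sub("\\.json$", "", list.files(profile_dir(), pattern = "\\.json$")))
}

#' Load a bundled or on-disk age profile
#'
#' @param name a bundled profile name (see [list_profiles()]) or a path
#'   to a profile JSON file.
#' @return an [age_profile()].
#' @export
load_profile <- function(name) {
  path <- if (file.exists(name)) name
          else file.path(profile_dir(), paste0(name, ".json"))
  if (!file.exists(path))
    stop("unknown profile '", name, "'; bundled profiles: ",
         paste(list_profiles(), collapse = ", "))
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(age_profile, p)
}
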