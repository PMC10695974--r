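#' @title Somatic innervation analysis
#' @name innervation
#' @description
#' Per-soma tallies of somatic synapses grouped by distinct presynaptic
#' axon, bouton sphere geometry, and the fraction of the soma surface
#' occupied by postsynaptic densities. Only cells whose soma is fully
#' contained in the reconstructed volume (listed in
#' `metadata$complete_somata`) are admissible, since partial somata
#' undercount synapses.
NULL

#' Somatic innervation profile of one cell
#'
#' Counts synapses with `target_class == "soma"` on the cell and groups
#' them by presynaptic axon id.
#'
#' @param cell_id the postsynaptic cell.
#' @param dataset a `dataset` whose `metadata$complete_somata` contains
#'   `cell_id`.
#' @return object of class `soma_innervation_profile`:
#'   `cell_id`, `total_soma_synapses`, `innervating_axons`,
#'   `per_axon_counts` (named integer vector), `mean_bouton_volume`
#'   (um3, `NA` if no radii), `psd_occupancy_fraction` (`NA` unless
#'   computed via [psd_occupancy()]).
#' @export
soma_profile <- function(cell_id, dataset) {
  complete <- dataset$metadata$complete_somata
  if (!cell_id %in% complete)
    stop("soma of cell '", cell_id, "' is not flagged as fully contained; ",
         "per-soma counts require a complete soma")
  syn <- dataset$synapses
  syn <- syn[!is.na(syn$post_cell_id) & syn$post_cell_id == cell_id &
             syn$target_class == "soma", , drop = FALSE]
  per_axon <- if (nrow(syn) > 0) {
    tab <- table(syn$pre_axon_id)
    stats::setNames(as.integer(tab), names(tab))
  } else stats::setNames(integer(0), character(0))
  mbv <- if (nrow(syn) > 0 && any(!is.na(syn$bouton_radius)))
    mean((4 / 3) * pi * syn$bouton_radius^3, na.rm = TRUE)
  else NA_real_
  structure(list(cell_id = cell_id,
                 total_soma_synapses = nrow(syn),
                 innervating_axons = length(per_axon),
                 per_axon_counts = per_axon,
                 mean_bouton_volume = mbv,
                 psd_occupancy_fraction = NA_real_),
            class = "soma_innervation_profile")
}

#' @export
print.soma_innervation_profile <- function(x, ...) {
  cat(sprintf("<soma %s> %d synapses from %d axons, mean bouton %.3g um3\n",
              x$cell_id, x$total_soma_synapses, x$innervating_axons,
              x$mean_bouton_volume))
  invisible(x)
}

#' Soma profiles for every complete soma in a dataset
#' @param dataset a `dataset`.
#' @return data.frame with one row per complete soma: `cell_id`,
#'   `total_soma_synapses`, `innervating_axons`, `mean_bouton_volume`.
#' @export
soma_profile_table <- function(dataset) {
  cells <- dataset$metadata$complete_somata
  if (length(cells) == 0L)
    return(data.frame(cell_id = character(0),
                      total_soma_synapses = integer(0),
                      innervating_axons = integer(0),
                      mean_bouton_volume = numeric(0)))
  do.call(rbind, lapply(cells, function(cid) {
    p <- soma_profile(cid, dataset)
    data.frame(cell_id = p$cell_id,
               total_soma_synapses = p$total_soma_synapses,
               innervating_axons = p$innervating_axons,
               mean_bouton_volume = p$mean_bouton_volume)
  }))
}

#' Bouton sphere geometry
#'
#' Surface area `4 * pi * r^2` and volume `(4/3) * pi * r^3` of the
#' sphere fitted to a bouton.
#'
#' @param radius_um bouton radius (um, > 0); vectorized.
#' @return list with `surface_area` (um2) and `volume` (um3).
#' @export
bouton_geometry <- function(radius_um) {
  if (any(!is.finite(radius_um) | radius_um <= 0))
    stop("bouton radius must be positive")
  list(surface_area = 4 * pi * radius_um^2,
       volume = (4 / 3) * pi * radius_um^3)
}

#' PSD occupancy of the soma surface
#'
#' Sum of PSD areas of somatic synapses over the soma sphere surface.
#' Values above 1 are reported clipped to 1 with a warning.
#'
#' @param cell_id the postsynaptic cell.
#' @param dataset a `dataset`.
#' @param soma_radius_um soma sphere radius (um); defaults to the radius
#'   of the cell's soma node.
#' @return proportion in `[0, 1]`.
#' @export
psd_occupancy <- function(cell_id, dataset, soma_radius_um = NULL) {
  syn <- dataset$synapses
  syn <- syn[!is.na(syn$post_cell_id) & syn$post_cell_id == cell_id &
             syn$target_class == "soma", , drop = FALSE]
  if (nrow(syn) == 0L) return(0)
  missing <- syn$synapse_id[is.na(syn$psd_area)]
  if (length(missing) > 0L)
    stop("somatic synapses without psd_area: ",
         paste(missing, collapse = ", "))
  if (is.null(soma_radius_um)) {
    skel <- NULL
    for (s in dataset$skeletons)
      if (s$cell_id == cell_id && any(s$nodes$compartment == "soma"))
        skel <- s
    if (is.null(skel)) stop("no soma node found for cell '", cell_id, "'")
    soma_radius_um <- max(skel$nodes$radius[skel$nodes$compartment == "soma"])
  }
  surface_nm2 <- 4 * pi * (soma_radius_um * 1000)^2
  frac <- sum(syn$psd_area) / surface_nm2
  if (frac > 1) {
    warning("PSD occupancy exceeds 1; reporting clipped value")
    frac <- 1
  }
  frac
}
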