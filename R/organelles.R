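#' @title Mitochondria morphometry
#' @name organelles
#' @description
#' Per-dendrite mitochondria coverage: total mitochondrial volume per
#' cable length (reported in nm2 = nm3 per nm, the unit the source
#' measurements print), instance counts and mean sizes, paired with the
#' dendrite's spine-synapse density for correlation analysis split by
#' dendritic compartment. Mitochondria belong to a dendrite through
#' their host-skeleton span; partial spans count their full volume.
NULL

#' Mitochondria coverage record of one dendrite
#'
#' @param dendrite a dendritic [skeleton()].
#' @param dataset a `dataset` with mitochondria and synapses.
#' @return one-row data.frame: `skeleton_id`, `compartment`,
#'   `cable_length` (um), `mito_count`, `total_mito_volume` (nm3),
#'   `mito_density` (nm2, volume over cable length in nm),
#'   `mean_mito_size` (um3, `NA` when no mitochondria),
#'   `synapse_density` (spine synapses per um).
#' @export
mito_dendrite_record <- function(dendrite, dataset) {
  len <- cable_length(dendrite)
  if (len <= 0)
    stop("dendrite '", dendrite$skeleton_id, "' has zero cable length")
  mito <- dataset$mitochondria
  mito <- mito[mito$host_skeleton_id == dendrite$skeleton_id, , drop = FALSE]
  tot <- sum(mito$volume)
  nsyn <- sum(dataset$synapses$post_cell_id == dendrite$cell_id &
              dataset$synapses$target_class == "spine", na.rm = TRUE)
  comp_tab <- table(dendrite$nodes$compartment)
  data.frame(skeleton_id = dendrite$skeleton_id,
             compartment = names(which.max(comp_tab)),
             cable_length = len,
             mito_count = nrow(mito),
             total_mito_volume = tot,
             mito_density = tot / (len * 1000),
             mean_mito_size = if (nrow(mito) > 0) mean(mito$volume) / 1e9
                              else NA_real_,
             synapse_density = nsyn / len)
}

#' Coverage records for all dendrites in a dataset
#' @param dataset a `dataset`.
#' @return data.frame of [mito_dendrite_record()] rows.
#' @export
mito_dendrite_table <- function(dataset) {
  dends <- Filter(function(s) any(s$nodes$compartment %in%
                                  DENDRITE_COMPARTMENTS),
                  dataset$skeletons)
  if (length(dends) == 0L)
    stop("dataset has no dendritic skeletons")
  do.call(rbind, lapply(dends, function(s) {
    r <- mito_dendrite_record(s, dataset)
    rownames(r) <- NULL
    r
  }))
}

#' Correlation between mitochondria coverage and synapse density
#'
#' Pearson correlation of `mito_density` with `synapse_density` across
#' dendrites, with the two-sided p-value from the t reference
#' distribution, optionally restricted to one dendritic compartment.
#'
#' @param records data.frame of [mito_dendrite_record()] rows.
#' @param compartment_filter `"combined"` (default), `"apical"` or
#'   `"basal"`.
#' @return list with `r`, `p_value`, `n`.
#' @export
coverage_synapse_correlation <- function(records,
                                         compartment_filter = c("combined",
                                                                "apical",
                                                                "basal")) {
  compartment_filter <- match.arg(compartment_filter)
  if (compartment_filter != "combined") {
    want <- paste0("dendrite_", compartment_filter)
    records <- records[records$compartment == want, , drop = FALSE]
  }
  if (nrow(records) < 3)
    stop("need at least 3 records after filtering, have ", nrow(records))
  res <- pearson(records$mito_density, records$synapse_density)
  list(r = res$r, p_value = res$p_value, n = nrow(records))
}
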