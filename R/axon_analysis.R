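#' @title Axon-centric analysis
#' @name axon_analysis
#' @description
#' Per-axon synapse and branch frequencies, the excitatory-axon
#' classification rule (an axon is called excitatory when, after a seed
#' bouton, at least a minimum number of additional synapses can be
#' examined and any of them targets a dendritic spine), the composition
#' of shaft inputs, and detection of terminal retraction bulbs (swollen
#' axon endings packed with mitochondria, the anatomical signature of
#' branch-specific axon withdrawal).
NULL

axon_synapses <- function(axon, dataset) {
  syn <- dataset$synapses
  syn[!is.na(syn$pre_axon_id) & syn$pre_axon_id == axon$cell_id, ,
      drop = FALSE]
}

#' Synapse and branch frequencies of one axon
#'
#' @param axon an axon [skeleton()].
#' @param dataset a `dataset` containing the axon's output synapses
#'   (rows with `pre_axon_id` equal to the axon's cell id).
#' @return one-row data.frame: `axon_id`, `cable_length` (um),
#'   `synapse_count`, `branch_count`, `synapses_per_um`,
#'   `branches_per_um`, `classification`, `n_bulb_terminals`.
#' @export
axon_trace_stats <- function(axon, dataset) {
  len <- cable_length(axon)
  if (len <= 0) stop("axon '", axon$skeleton_id, "' has zero cable length")
  syn <- axon_synapses(axon, dataset)
  bc <- length(branch_nodes(axon))
  cls <- tryCatch(classify_axon(axon, dataset), error = function(e) "unclassified")
  bulbs <- detect_retraction_bulbs(axon, dataset)
  data.frame(axon_id = axon$cell_id, cable_length = len,
             synapse_count = nrow(syn), branch_count = bc,
             synapses_per_um = nrow(syn) / len,
             branches_per_um = bc / len,
             classification = as.character(cls),
             n_bulb_terminals = length(bulbs))
}

#' Classify an axon as excitatory from its synapse targets
#'
#' Starting from a seed synapse, the axon's remaining synapses are
#' examined in trace order (along-cable distance from the seed, nearest
#' first). If fewer than `min_additional` additional synapses exist the
#' axon stays `"unclassified"` with attribute `insufficient = TRUE`;
#' otherwise it is `"excitatory"` as soon as any examined synapse
#' targets a dendritic spine, else `"unclassified"` (the rule never
#' licenses an inhibitory call).
#'
#' @param axon an axon [skeleton()].
#' @param dataset a `dataset` with the axon's synapses.
#' @param min_additional minimum number of additional synapses required
#'   to attempt classification (default 3).
#' @param seed_synapse_id synapse id of the seed bouton; default is the
#'   synapse closest to the axon root.
#' @return `"excitatory"` or `"unclassified"` (with attribute
#'   `insufficient` when too few synapses were available).
#' @export
classify_axon <- function(axon, dataset, min_additional = 3,
                          seed_synapse_id = NULL) {
  syn <- axon_synapses(axon, dataset)
  if (nrow(syn) == 0L) stop("axon '", axon$cell_id, "' has no seed synapse")
  root <- axon$nodes$node_id[is.na(axon$nodes$parent_id)]
  if (is.null(seed_synapse_id)) {
    droot <- node_path_distances(axon, root)
    seed_synapse_id <- syn$synapse_id[
      which.min(droot[as.character(syn$post_node_id)])]
  }
  seed <- syn[syn$synapse_id == seed_synapse_id, , drop = FALSE]
  if (nrow(seed) != 1L) stop("seed synapse not found on axon")
  extra <- syn[syn$synapse_id != seed_synapse_id, , drop = FALSE]
  if (nrow(extra) < min_additional) {
    out <- "unclassified"
    attr(out, "insufficient") <- TRUE
    return(out)
  }
  d <- node_path_distances(axon, seed$post_node_id)
  ord <- order(d[as.character(extra$post_node_id)])
  targets <- extra$target_class[ord]
  if (any(targets == "spine")) "excitatory" else "unclassified"
}

#' Fraction of shaft inputs made by excitatory axons
#'
#' Samples shaft boutons (without replacement) whose presynaptic axon is
#' reconstructed in the dataset, classifies each axon with
#' [classify_axon()] seeded at the sampled bouton, and returns the
#' excitatory fraction among classifiable axons.
#'
#' @param dataset a `dataset` containing axon skeletons and synapses.
#' @param n_sample number of shaft boutons to sample (default 30).
#' @param seed integer seed.
#' @param min_additional passed to [classify_axon()].
#' @return list with `fraction_excitatory`, `n_classifiable`,
#'   `n_sampled`.
#' @export
shaft_input_composition <- function(dataset, n_sample = 30, seed = 1L,
                                    min_additional = 3) {
  cells <- vapply(dataset$skeletons, function(s) s$cell_id, character(1))
  syn <- dataset$synapses
  shaft <- syn[syn$target_class == "shaft" &
               !is.na(syn$pre_axon_id) & syn$pre_axon_id %in% cells, ,
               drop = FALSE]
  if (nrow(shaft) < n_sample)
    stop("only ", nrow(shaft), " shaft synapses with reconstructed axons; ",
         n_sample, " required")
  withr::with_seed(as.integer(seed), {
    pick <- shaft[sample.int(nrow(shaft), n_sample), , drop = FALSE]
    cls <- vapply(seq_len(n_sample), function(i) {
      axon <- dataset$skeletons[[which(cells == pick$pre_axon_id[i])[1]]]
      out <- classify_axon(axon, dataset, min_additional = min_additional,
                           seed_synapse_id = pick$synapse_id[i])
      if (isTRUE(attr(out, "insufficient"))) NA_character_
      else as.character(out)
    }, character(1))
  })
  classifiable <- cls[!is.na(cls)]
  list(fraction_excitatory = if (length(classifiable) > 0)
         mean(classifiable == "excitatory") else NA_real_,
       n_classifiable = length(classifiable),
       n_sampled = n_sample)
}

#' Detect terminal retraction bulbs on an axon
#'
#' A terminal node is flagged when its radius is at least
#' `radius_factor` times the median radius of the axon's non-terminal
#' nodes and at least `min_bulb_mitos` mitochondria lie within the
#' terminal swelling (both span endpoints within `span_um` of the
#' terminal along the cable). Detection is branch-specific: other
#' branches of the same axon are unaffected.
#'
#' @param axon an axon [skeleton()].
#' @param dataset a `dataset` with mitochondria hosted on the axon.
#' @param radius_factor swelling threshold relative to the median
#'   non-terminal radius (default 2).
#' @param min_bulb_mitos minimum clustered mitochondria (default 3).
#' @param span_um how far along the cable from the terminal a
#'   mitochondrion may lie and still count as inside the bulb.
#' @return integer vector of flagged terminal node ids (possibly empty).
#' @export
detect_retraction_bulbs <- function(axon, dataset, radius_factor = 2,
                                    min_bulb_mitos = 3, span_um = 2) {
  terms <- terminal_nodes(axon)
  nd <- axon$nodes
  nonterm <- nd$radius[!nd$node_id %in% terms]
  if (length(nonterm) == 0L) return(integer(0))
  med <- stats::median(nonterm)
  mito <- dataset$mitochondria
  mito <- mito[mito$host_skeleton_id == axon$skeleton_id, , drop = FALSE]
  flagged <- integer(0)
  for (t in terms) {
    r <- nd$radius[match(t, nd$node_id)]
    if (r < radius_factor * med) next
    if (nrow(mito) == 0L) next
    d <- node_path_distances(axon, t)
    inside <- d[as.character(mito$start_node_id)] <= span_um &
              d[as.character(mito$end_node_id)] <= span_um
    if (sum(inside, na.rm = TRUE) >= min_bulb_mitos)
      flagged <- c(flagged, t)
  }
  flagged
}
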