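#' @title Dendrite morphometry
#' @name morphometry
#' @description
#' Fragment-based dendrite measurements: random ~10 um fragments sampled
#' along the dendritic tree, per-fragment spine/shaft/filopodia densities
#' (count over actual path length), fragment diameter (twice the mean
#' node radius, the skeleton proxy for calliper measurements), spine
#' head-to-shaft distances, and bulk 2D synapse density from
#' field-of-view counts with the >= 5 vesicle inclusion criterion.
NULL

#' Construct a dendrite fragment from an explicit node path
#'
#' The nodes must form a connected path (or subtree) of the skeleton.
#'
#' @param skel a [skeleton()].
#' @param node_ids nodes making up the fragment, in path order.
#' @param truncated flag marking fragments cut short at a tip.
#' @return object of class `dendrite_fragment` with fields
#'   `skeleton_id`, `cell_id`, `node_ids`, `path_length` (um),
#'   `diameter` (um), `compartment`, `truncated`.
#' @export
fragment_from_nodes <- function(skel, node_ids, truncated = FALSE) {
  node_ids <- as.integer(node_ids)
  plen <- cable_length(skel, node_ids)
  nd <- skel$nodes[match(node_ids, skel$nodes$node_id), , drop = FALSE]
  comp_tab <- table(nd$compartment)
  structure(list(skeleton_id = skel$skeleton_id, cell_id = skel$cell_id,
                 node_ids = node_ids, path_length = plen,
                 diameter = 2 * mean(nd$radius),
                 compartment = names(which.max(comp_tab)),
                 truncated = isTRUE(truncated)),
            class = "dendrite_fragment")
}

#' @export
print.dendrite_fragment <- function(x, ...) {
  cat(sprintf("<fragment on %s> %.2f um, %d nodes, diameter %.2f um%s\n",
              x$skeleton_id, x$path_length, length(x$node_ids), x$diameter,
              if (x$truncated) " (truncated)" else ""))
  invisible(x)
}

#' Sample random dendrite fragments from a skeleton
#'
#' Start nodes are sampled without replacement among dendritic nodes;
#' each fragment is traced tipward along the tree until the target
#' length. At branch points the default rule (`"traverse_branch"`)
#' follows the thicker daughter; `"stop_at_branch"` ends the fragment
#' there. Fragments ending early (at a tip or a stopping branch) are
#' flagged truncated and their actual length is used as the density
#' denominator.
#'
#' @param skel a [skeleton()] with dendritic cable.
#' @param target_length_um fragment length to trace (default 10).
#' @param n number of fragments.
#' @param seed integer seed.
#' @param rule `"traverse_branch"` or `"stop_at_branch"`.
#' @return list of [fragment_from_nodes()] fragments.
#' @export
sample_fragments <- function(skel, target_length_um = 10, n = 1, seed = 1L,
                             rule = c("traverse_branch", "stop_at_branch")) {
  rule <- match.arg(rule)
  nd <- skel$nodes
  dend_ids <- nd$node_id[nd$compartment %in% DENDRITE_COMPARTMENTS]
  if (length(dend_ids) == 0L)
    stop("skeleton '", skel$skeleton_id, "' has no dendritic cable")
  children <- skeleton_children(nd)
  elen <- edge_lengths(nd)
  withr::with_seed(as.integer(seed), {
    starts <- sample(dend_ids, min(n, length(dend_ids)))
    lapply(starts, function(s) {
      path <- s
      len <- 0
      cur <- s
      truncated <- FALSE
      repeat {
        kids <- children[[as.character(cur)]]
        kids <- kids[nd$compartment[match(kids, nd$node_id)] %in%
                     DENDRITE_COMPARTMENTS]
        if (length(kids) == 0L) { truncated <- len < target_length_um; break }
        if (length(kids) > 1L && rule == "stop_at_branch") {
          truncated <- len < target_length_um
          break
        }
        nxt <- if (length(kids) == 1L) kids else {
          kids[which.max(nd$radius[match(kids, nd$node_id)])]
        }
        len <- len + elen[match(nxt, nd$node_id)]
        path <- c(path, nxt)
        cur <- nxt
        if (len >= target_length_um) break
      }
      fragment_from_nodes(skel, path, truncated = truncated)
    })
  })
}

#' Per-fragment annotation density
#'
#' Counts annotations assigned (by `post_node_id`) to nodes on the
#' fragment path and divides by the actual path length, exactly
#' `count / path_length`.
#'
#' @param fragment a [fragment_from_nodes()] fragment.
#' @param dataset a `dataset` holding the annotations.
#' @param annotation_class `"spine"`, `"shaft"`, `"soma"` or
#'   `"filopodia"`.
#' @return one-row data.frame: `skeleton_id`, `annotation_class`,
#'   `count`, `path_length`, `density`, `truncated`.
#' @export
fragment_density <- function(fragment, dataset,
                             annotation_class = c("spine", "shaft", "soma",
                                                  "filopodia")) {
  annotation_class <- match.arg(annotation_class)
  count <- if (annotation_class == "filopodia") {
    sum(dataset$filopodia$post_cell_id == fragment$cell_id &
        dataset$filopodia$base_node_id %in% fragment$node_ids, na.rm = TRUE)
  } else {
    sum(dataset$synapses$post_cell_id == fragment$cell_id &
        dataset$synapses$target_class == annotation_class &
        dataset$synapses$post_node_id %in% fragment$node_ids, na.rm = TRUE)
  }
  if (fragment$path_length <= 0)
    stop("fragment has zero path length")
  data.frame(skeleton_id = fragment$skeleton_id,
             annotation_class = annotation_class,
             count = count, path_length = fragment$path_length,
             density = count / fragment$path_length,
             truncated = fragment$truncated)
}

#' Filopodia density on a fragment
#'
#' Convenience wrapper around [fragment_density()] counting
#' filopodium annotations per um.
#' @inheritParams fragment_density
#' @return one-row data.frame as in [fragment_density()].
#' @export
filopodia_density <- function(fragment, dataset) {
  fragment_density(fragment, dataset, "filopodia")
}

#' Fragment diameter
#'
#' Twice the mean node radius along the path: the skeleton proxy for a
#' calliper diameter averaged over orthogonal views.
#' @param fragment a [fragment_from_nodes()] fragment.
#' @return diameter in um.
#' @export
fragment_diameter <- function(fragment) fragment$diameter

#' All three densities of a fragment in one record
#'
#' @inheritParams fragment_density
#' @return one-row data.frame with `spine_density`, `shaft_density`,
#'   `filopodia_density` (per um), the counts behind each, path length,
#'   diameter and compartment.
#' @export
density_record <- function(fragment, dataset) {
  sp <- fragment_density(fragment, dataset, "spine")
  sh <- fragment_density(fragment, dataset, "shaft")
  fl <- fragment_density(fragment, dataset, "filopodia")
  data.frame(skeleton_id = fragment$skeleton_id,
             compartment = fragment$compartment,
             path_length = fragment$path_length,
             diameter = fragment$diameter,
             truncated = fragment$truncated,
             spine_count = sp$count, spine_density = sp$density,
             shaft_count = sh$count, shaft_density = sh$density,
             filopodia_count = fl$count, filopodia_density = fl$density)
}

#' Distance from a spine synapse to the dendritic shaft
#'
#' Euclidean distance from the synapse position to the nearest point on
#' the dendritic cable polyline of the skeleton, reported in nanometres.
#'
#' @param synapse one-row synapse data.frame with `target_class`
#'   `"spine"` and position columns `x`, `y`, `z` (um).
#' @param skel the postsynaptic [skeleton()].
#' @return distance in nm (>= 0).
#' @export
spine_branch_distance <- function(synapse, skel) {
  if (nrow(synapse) != 1L) stop("expected exactly one synapse row")
  if (!identical(synapse$target_class, "spine"))
    stop("spine_branch_distance is defined for spine synapses only")
  nd <- skel$nodes
  dend <- nd$compartment %in% DENDRITE_COMPARTMENTS
  p <- c(synapse$x, synapse$y, synapse$z)
  best <- Inf
  idx <- which(!is.na(nd$parent_id))
  for (i in idx) {
    j <- match(nd$parent_id[i], nd$node_id)
    if (!dend[i] && !dend[j]) next
    a <- c(nd$x[j], nd$y[j], nd$z[j])
    b <- c(nd$x[i], nd$y[i], nd$z[i])
    ab <- b - a
    denom <- sum(ab^2)
    t <- if (denom == 0) 0 else max(0, min(1, sum((p - a) * ab) / denom))
    q <- a + t * ab
    best <- min(best, sqrt(sum((p - q)^2)))
  }
  if (!is.finite(best)) {
    # single-node dendrite: distance to the node itself
    i <- which(dend)
    if (length(i) == 0L) stop("skeleton has no dendritic cable")
    best <- min(sqrt((nd$x[i] - p[1])^2 + (nd$y[i] - p[2])^2 +
                     (nd$z[i] - p[3])^2))
  }
  best * 1000
}

#' Bulk 2D synapse density from field-of-view counts
#'
#' Counts synapse events with at least `min_vesicles` vesicles per FOV
#' and divides by the FOV area; sub-threshold distractors are excluded.
#'
#' @param fov_events data.frame with columns `fov` and `vesicle_count`
#'   (one row per synapse event), as produced by
#'   [generate_fov_counts()]. FOVs with zero events must still appear in
#'   `levels` of `fov` or be implied by `n_fov`.
#' @param fov_area_um2 FOV area in um2 (> 0).
#' @param min_vesicles inclusion criterion (default 5).
#' @param n_fov total number of FOVs (defaults to `max(fov)`); FOVs
#'   without qualifying events count as zero.
#' @return list with `per_fov` (data.frame `fov`, `count`, `density`),
#'   `mean` and `sem` of the per-FOV densities.
#' @export
bulk_2d_density <- function(fov_events, fov_area_um2, min_vesicles = 5,
                            n_fov = NULL) {
  if (fov_area_um2 <= 0) stop("fov_area_um2 must be positive")
  if (is.null(n_fov))
    n_fov <- if (nrow(fov_events) > 0) max(fov_events$fov) else 1L
  qual <- fov_events[fov_events$vesicle_count >= min_vesicles, , drop = FALSE]
  counts <- tabulate(qual$fov, nbins = n_fov)
  dens <- counts / fov_area_um2
  ms <- mean_sem(dens)
  list(per_fov = data.frame(fov = seq_len(n_fov), count = counts,
                            density = dens),
       mean = ms$mean, sem = ms$sem)
}
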