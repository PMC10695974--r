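#' @title Neuron skeletons
#' @name skeleton
#' @description
#' A skeleton is a rooted tree of 3D nodes, the standard reduced
#' representation of a reconstructed neurite. Each node carries a position
#' (micrometres), a radius (micrometres) and a compartment label; edges are
#' implied by parent pointers. All per-micron densities in this package are
#' normalized by cable length measured on these trees.
NULL

#' Compartment labels recognized on skeleton nodes
#' @export
COMPARTMENTS <- c("soma", "dendrite_apical", "dendrite_basal", "axon",
                  "filopodium")

#' Compartments counted as dendritic cable
#' @export
DENDRITE_COMPARTMENTS <- c("dendrite_apical", "dendrite_basal")

#' Construct a skeleton
#'
#' @param nodes data.frame with columns `node_id` (integer, unique),
#'   `x`, `y`, `z` (numeric, um), `radius` (numeric, um, > 0),
#'   `parent_id` (integer, `NA` for the root) and `compartment`
#'   (one of [COMPARTMENTS]).
#' @param skeleton_id,cell_id character identifiers.
#' @param cell_class one of `"excitatory"`, `"inhibitory"`, `"unclassified"`.
#' @param validate run [validate_skeleton()] (default `TRUE`).
#' @return an object of class `skeleton`.
#' @export
skeleton <- function(nodes, skeleton_id, cell_id = skeleton_id,
                     cell_class = "unclassified", validate = TRUE) {
  required <- c("node_id", "x", "y", "z", "radius", "parent_id", "compartment")
  missing <- setdiff(required, names(nodes))
  if (length(missing) > 0L)
    stop("skeleton nodes missing columns: ", paste(missing, collapse = ", "))
  nodes <- as.data.frame(nodes)[required]
  nodes$node_id <- as.integer(nodes$node_id)
  nodes$parent_id <- as.integer(nodes$parent_id)
  nodes$compartment <- as.character(nodes$compartment)
  cell_class <- match.arg(cell_class,
                          c("excitatory", "inhibitory", "unclassified"))
  obj <- structure(list(skeleton_id = as.character(skeleton_id),
                        cell_id = as.character(cell_id),
                        cell_class = cell_class,
                        nodes = nodes),
                   class = "skeleton")
  if (validate) validate_skeleton(obj)
  obj
}

#' Validate skeleton invariants
#'
#' Checks unique node ids, positive radii, resolvable parent references,
#' exactly one root and acyclicity (tree property).
#'
#' @param skel a [skeleton()].
#' @return the skeleton, invisibly; errors name the offending `node_id`.
#' @export
validate_skeleton <- function(skel) {
  nd <- skel$nodes
  if (nrow(nd) == 0L) stop("skeleton '", skel$skeleton_id, "' has no nodes")
  dup <- nd$node_id[duplicated(nd$node_id)]
  if (length(dup) > 0L)
    stop("skeleton '", skel$skeleton_id, "': duplicate node_id ",
         paste(unique(dup), collapse = ", "))
  bad_r <- nd$node_id[!is.finite(nd$radius) | nd$radius <= 0]
  if (length(bad_r) > 0L)
    stop("skeleton '", skel$skeleton_id, "': non-positive radius at node_id ",
         paste(bad_r, collapse = ", "))
  bad_c <- unique(nd$compartment[!nd$compartment %in% COMPARTMENTS])
  if (length(bad_c) > 0L)
    stop("skeleton '", skel$skeleton_id, "': unknown compartment ",
         paste(bad_c, collapse = ", "))
  is_root <- is.na(nd$parent_id)
  if (sum(is_root) != 1L)
    stop("skeleton '", skel$skeleton_id, "' must have exactly one root, found ",
         sum(is_root))
  dangling <- nd$node_id[!is_root & !(nd$parent_id %in% nd$node_id)]
  if (length(dangling) > 0L)
    stop("skeleton '", skel$skeleton_id, "': node ", paste(dangling, collapse = ", "),
         " references an absent parent")
  # reachability from the root == acyclic connected tree (n-1 edges hold here)
  reached <- nodes_reachable_from(nd, nd$node_id[is_root])
  if (length(reached) != nrow(nd)) {
    off <- setdiff(nd$node_id, reached)
    stop("skeleton '", skel$skeleton_id, "': cycle or disconnected nodes ",
         paste(off, collapse = ", "))
  }
  invisible(skel)
}

#' @export
print.skeleton <- function(x, ...) {
  cat(sprintf("<skeleton %s> cell %s (%s): %d nodes, %.2f um cable\n",
              x$skeleton_id, x$cell_id, x$cell_class, nrow(x$nodes),
              cable_length(x)))
  invisible(x)
}

# children list keyed by node_id (as character); internal
skeleton_children <- function(nodes) {
  kids <- nodes$node_id[!is.na(nodes$parent_id)]
  split(kids, as.character(nodes$parent_id[!is.na(nodes$parent_id)]))
}

# breadth-first sweep down the tree from `start` ids; returns reached node_ids
nodes_reachable_from <- function(nodes, start) {
  children <- skeleton_children(nodes)
  reached <- integer(0)
  frontier <- start
  while (length(frontier) > 0L) {
    reached <- c(reached, frontier)
    frontier <- unlist(children[as.character(frontier)], use.names = FALSE)
    if (length(reached) > nrow(nodes)) break  # defensive: cycle guard
  }
  reached
}

# length of the edge from each node to its parent (0 for root); internal
edge_lengths <- function(nodes) {
  idx <- match(nodes$parent_id, nodes$node_id)
  len <- sqrt((nodes$x - nodes$x[idx])^2 +
              (nodes$y - nodes$y[idx])^2 +
              (nodes$z - nodes$z[idx])^2)
  len[is.na(nodes$parent_id)] <- 0
  len
}

#' Cable length of a skeleton or a connected node subset
#'
#' Sum of Euclidean edge lengths, the denominator of every per-micron
#' density in the package.
#'
#' @param skel a [skeleton()].
#' @param node_ids optional integer vector restricting to the induced
#'   subtree; must be connected within the skeleton.
#' @return length in micrometres.
#' @export
cable_length <- function(skel, node_ids = NULL) {
  nd <- skel$nodes
  if (is.null(node_ids)) {
    return(sum(edge_lengths(nd)))
  }
  node_ids <- as.integer(node_ids)
  if (!all(node_ids %in% nd$node_id))
    stop("node subset contains ids absent from skeleton")
  sub <- nd[nd$node_id %in% node_ids, , drop = FALSE]
  # edges internal to the subset
  keep <- !is.na(sub$parent_id) & sub$parent_id %in% node_ids
  # connectivity of the induced subgraph: one local root, rest reachable
  sub2 <- sub
  sub2$parent_id[!keep] <- NA_integer_
  roots <- sub2$node_id[is.na(sub2$parent_id)]
  if (length(roots) != 1L ||
      length(nodes_reachable_from(sub2, roots)) != nrow(sub2))
    stop("node subset is disconnected")
  sum(edge_lengths(sub)[keep])
}

#' Path distances from one node along the tree
#'
#' Undirected geodesic (along-cable) distance from `from_id` to every node,
#' in micrometres.
#'
#' @param skel a [skeleton()].
#' @param from_id a node_id present in the skeleton.
#' @return named numeric vector, names are node_ids.
#' @export
node_path_distances <- function(skel, from_id) {
  nd <- skel$nodes
  from_id <- as.integer(from_id)
  if (!from_id %in% nd$node_id) stop("from_id not in skeleton")
  elen <- edge_lengths(nd)
  children <- skeleton_children(nd)
  idx <- match(nd$node_id, nd$node_id)  # identity, for clarity
  dist <- stats::setNames(rep(NA_real_, nrow(nd)), as.character(nd$node_id))
  dist[as.character(from_id)] <- 0
  frontier <- from_id
  while (length(frontier) > 0L) {
    nxt <- integer(0)
    for (v in frontier) {
      vi <- match(v, nd$node_id)
      nb <- c(children[[as.character(v)]],
              if (!is.na(nd$parent_id[vi])) nd$parent_id[vi])
      for (w in nb) {
        if (is.na(dist[as.character(w)])) {
          wi <- match(w, nd$node_id)
          # edge length between v and w: stored on the child side
          el <- if (!is.na(nd$parent_id[wi]) && nd$parent_id[wi] == v)
            elen[wi] else elen[vi]
          dist[as.character(w)] <- dist[as.character(v)] + el
          nxt <- c(nxt, w)
        }
      }
    }
    frontier <- nxt
  }
  dist
}

#' Terminal (tip) nodes of a skeleton
#' @param skel a [skeleton()].
#' @return integer vector of node_ids with no children.
#' @export
terminal_nodes <- function(skel) {
  nd <- skel$nodes
  setdiff(nd$node_id, nd$parent_id[!is.na(nd$parent_id)])
}

#' Branch-point nodes of a skeleton
#' @param skel a [skeleton()].
#' @return integer vector of node_ids with two or more children.
#' @export
branch_nodes <- function(skel) {
  nd <- skel$nodes
  tab <- table(nd$parent_id[!is.na(nd$parent_id)])
  as.integer(names(tab)[tab >= 2L])
}
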