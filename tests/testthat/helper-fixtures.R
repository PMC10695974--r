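# shared fixtures and independent oracles, built in code

# straight chain skeleton through the given points
make_chain_skeleton <- function(points, radii = 0.4,
                                compartment = "dendrite_basal",
                                skeleton_id = "chain", id_start = 1L) {
  n <- nrow(points)
  ids <- seq.int(id_start, length.out = n)
  skeleton(data.frame(node_id = ids,
                      x = points[, 1], y = points[, 2], z = points[, 3],
                      radius = rep_len(radii, n),
                      parent_id = c(NA_integer_, ids[-n]),
                      compartment = rep_len(compartment, n)),
           skeleton_id = skeleton_id, cell_id = skeleton_id)
}

# unbranched dendrite along +x with unit node spacing
make_line_dendrite <- function(length_um, skeleton_id = "line",
                               radius = 0.4, spacing = 1) {
  n <- round(length_um / spacing)
  pts <- cbind(seq(0, length_um, length.out = n + 1), 0, 0)
  make_chain_skeleton(pts, radii = radius, skeleton_id = skeleton_id)
}

# synapse rows on the given nodes of a skeleton
make_synapses <- function(skel, node_ids, target_class = "spine",
                          pre_axon_id = NULL, id_prefix = "s", ...) {
  n <- length(node_ids)
  extra <- list(...)
  pos <- skel$nodes[match(node_ids, skel$nodes$node_id), ]
  df <- data.frame(synapse_id = paste0(id_prefix, seq_len(n)),
                   pre_axon_id = pre_axon_id %||%
                     paste0(id_prefix, "_ax", seq_len(n)),
                   post_cell_id = skel$cell_id,
                   post_node_id = node_ids,
                   target_class = rep_len(target_class, n),
                   x = pos$x, y = pos$y, z = pos$z)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent Mann-Whitney oracle: full enumeration over all labelings,
# U from plain ranks (inputs tie-free), two-tailed by doubled smaller tail
brute_force_mw <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  u_of <- function(x, y) {
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  u_obs <- u_of(a, b)
  idx <- utils::combn(length(pooled), n1)
  us <- apply(idx, 2, function(i) u_of(pooled[i], pooled[-i]))
  p_lo <- mean(us <= u_obs + 1e-9)
  p_hi <- mean(us >= u_obs - 1e-9)
  list(u = u_obs, p = min(1, 2 * min(p_lo, p_hi)))
}
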