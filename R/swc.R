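#' Default SWC type-code mapping
#'
#' Standard SWC integer codes to compartment labels: 1 soma, 2 axon,
#' 3 basal dendrite, 4 apical dendrite, 5 filopodium. Override by passing
#' a named vector (names = codes) to [read_swc()].
#' @export
swc_compartment_map <- function() {
  c("1" = "soma", "2" = "axon", "3" = "dendrite_basal",
    "4" = "dendrite_apical", "5" = "filopodium")
}

#' Read skeletons from an SWC file
#'
#' Standard whitespace-delimited 7-column SWC
#' (`id type x y z radius parent`, parent `-1` at roots, `#` comments).
#' A file may hold several trees; one [skeleton()] is returned per root.
#'
#' @param path file path.
#' @param compartment_map named character vector mapping SWC type codes to
#'   compartment labels; default [swc_compartment_map()].
#' @param default_compartment label used, with a warning, for type codes
#'   absent from the map.
#' @param cell_class passed to each resulting skeleton.
#' @return list of [skeleton()] objects (possibly empty).
#' @export
read_swc <- function(path, compartment_map = swc_compartment_map(),
                     default_compartment = "dendrite_basal",
                     cell_class = "unclassified") {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) return(list())
  fields <- strsplit(lines, "[[:space:]]+")
  bad <- which(lengths(fields) != 7L)
  if (length(bad) > 0L)
    stop("SWC line ", bad[1], " does not have 7 columns")
  m <- matrix(as.numeric(unlist(fields)), ncol = 7L, byrow = TRUE)
  nodes <- data.frame(node_id = as.integer(m[, 1]),
                      type = as.integer(m[, 2]),
                      x = m[, 3], y = m[, 4], z = m[, 5],
                      radius = m[, 6],
                      parent_id = as.integer(m[, 7]))
  nodes$parent_id[nodes$parent_id == -1L] <- NA_integer_
  comp <- unname(compartment_map[as.character(nodes$type)])
  unknown <- unique(nodes$type[is.na(comp)])
  if (length(unknown) > 0L) {
    warning("SWC type code(s) ", paste(unknown, collapse = ", "),
            " not in compartment_map; using '", default_compartment, "'")
    comp[is.na(comp)] <- default_compartment
  }
  nodes$compartment <- comp
  nodes$type <- NULL
  if (anyDuplicated(nodes$node_id))
    stop("duplicate node_id in SWC file: ",
         paste(unique(nodes$node_id[duplicated(nodes$node_id)]), collapse = ", "))
  dang <- nodes$node_id[!is.na(nodes$parent_id) &
                        !(nodes$parent_id %in% nodes$node_id)]
  if (length(dang) > 0L)
    stop("SWC node ", paste(dang, collapse = ", "),
         " references an absent parent")
  # split into connected components, one skeleton per root
  roots <- nodes$node_id[is.na(nodes$parent_id)]
  if (length(roots) == 0L)
    stop("SWC file has no root node (cycle): every node has a parent")
  base <- tools::file_path_sans_ext(basename(path))
  out <- vector("list", length(roots))
  for (i in seq_along(roots)) {
    ids <- nodes_reachable_from(nodes, roots[i])
    sid <- if (length(roots) == 1L) base else paste0(base, "_", roots[i])
    out[[i]] <- skeleton(nodes[nodes$node_id %in% ids, , drop = FALSE],
                         skeleton_id = sid, cell_id = sid,
                         cell_class = cell_class)
  }
  claimed <- unlist(lapply(out, function(s) s$nodes$node_id))
  leftover <- setdiff(nodes$node_id, claimed)
  if (length(leftover) > 0L)
    stop("SWC node ", paste(leftover, collapse = ", "),
         " lies on a cycle (unreachable from any root)")
  out
}

#' Write skeletons to an SWC file
#'
#' One line per node, ordered by `node_id`, roots written with parent `-1`.
#' Node ids must be unique across all skeletons written to one file.
#'
#' @param skeletons a [skeleton()] or list of skeletons.
#' @param path output file path.
#' @param compartment_map as in [read_swc()]; inverted to produce type codes.
#' @return `path`, invisibly.
#' @export
write_swc <- function(skeletons, path,
                      compartment_map = swc_compartment_map()) {
  if (inherits(skeletons, "skeleton")) skeletons <- list(skeletons)
  inv <- stats::setNames(as.integer(names(compartment_map)),
                         unname(compartment_map))
  header <- c("# SWC skeleton export",
              paste0("# columns: id type x y z radius parent"))
  rows <- character(0)
  all_ids <- integer(0)
  for (skel in skeletons) {
    nd <- skel$nodes
    if (anyDuplicated(nd$node_id))
      stop("skeleton '", skel$skeleton_id, "' has duplicate node_ids")
    all_ids <- c(all_ids, nd$node_id)
    nd <- nd[order(nd$node_id), , drop = FALSE]
    type <- inv[nd$compartment]
    if (anyNA(type))
      stop("compartment without an SWC type code: ",
           paste(unique(nd$compartment[is.na(type)]), collapse = ", "))
    parent <- ifelse(is.na(nd$parent_id), -1L, nd$parent_id)
    rows <- c(rows, sprintf("%d %d %.9g %.9g %.9g %.9g %d",
                            nd$node_id, type, nd$x, nd$y, nd$z,
                            nd$radius, parent))
  }
  if (anyDuplicated(all_ids))
    stop("node_id collision across skeletons written to one SWC file: ",
         paste(unique(all_ids[duplicated(all_ids)]), collapse = ", "))
  writeLines(c(header, rows), path)
  invisible(path)
}
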