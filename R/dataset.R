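#' @title Annotation tables and the dataset bundle
#' @name dataset
#' @description
#' Annotations are flat data.frames keyed to skeletons: synapses (one row
#' per synaptic contact with presynaptic axon id, postsynaptic cell and
#' nearest skeleton node, target class spine/shaft/soma, PSD area in nm2,
#' vesicle count, bouton radius in um), filopodia (protrusions with no
#' postsynaptic structure) and mitochondria (volume in nm3 plus a cable
#' span on the host skeleton). A `dataset` bundles skeletons and
#' annotation tables with metadata.
NULL

#' Permitted synapse target classes
#' @export
TARGET_CLASSES <- c("spine", "shaft", "soma")

synapse_columns <- c("synapse_id", "pre_axon_id", "post_cell_id",
                     "post_node_id", "target_class", "x", "y", "z",
                     "psd_area", "vesicle_count", "bouton_radius",
                     "vesicle_cloud_size", "pre_excitatory")
filopodia_columns <- c("filopodium_id", "post_cell_id", "base_node_id",
                       "length")
mito_columns <- c("mito_id", "host_skeleton_id", "volume",
                  "start_node_id", "end_node_id")

empty_synapses <- function() {
  data.frame(synapse_id = character(0), pre_axon_id = character(0),
             post_cell_id = character(0), post_node_id = integer(0),
             target_class = character(0), x = numeric(0), y = numeric(0),
             z = numeric(0), psd_area = numeric(0),
             vesicle_count = integer(0), bouton_radius = numeric(0),
             vesicle_cloud_size = numeric(0), pre_excitatory = logical(0))
}
empty_filopodia <- function() {
  data.frame(filopodium_id = character(0), post_cell_id = character(0),
             base_node_id = integer(0), length = numeric(0))
}
empty_mitochondria <- function() {
  data.frame(mito_id = character(0), host_skeleton_id = character(0),
             volume = numeric(0), start_node_id = integer(0),
             end_node_id = integer(0))
}

coerce_annotation <- function(df, template, what) {
  df <- as.data.frame(df)
  for (col in names(template)) {
    if (!col %in% names(df)) {
      df[[col]] <- template[[col]][NA_integer_][rep(1L, nrow(df))]
    } else {
      df[[col]] <- switch(class(template[[col]])[1],
                          character = as.character(df[[col]]),
                          integer = as.integer(df[[col]]),
                          numeric = as.numeric(df[[col]]),
                          logical = as.logical(df[[col]]))
    }
  }
  df[names(template)]
}

#' Assemble a dataset bundle
#'
#' @param skeletons list of [skeleton()] objects.
#' @param synapses,filopodia,mitochondria annotation data.frames (missing
#'   optional columns are filled with `NA`).
#' @param metadata named list; recognized fields include `species`,
#'   `region`, `layer`, `age_days`, `seed`, `profile`,
#'   `complete_somata` (cell ids whose soma is fully contained) and
#'   `axons_complete` (logical; are presynaptic axon ids expected to
#'   resolve to skeletons in the bundle).
#' @return object of class `dataset`.
#' @export
new_dataset <- function(skeletons = list(), synapses = empty_synapses(),
                        filopodia = empty_filopodia(),
                        mitochondria = empty_mitochondria(),
                        metadata = list()) {
  if (inherits(skeletons, "skeleton")) skeletons <- list(skeletons)
  synapses <- coerce_annotation(synapses, empty_synapses(), "synapses")
  bad <- setdiff(unique(synapses$target_class[!is.na(synapses$target_class)]),
                 TARGET_CLASSES)
  if (length(bad) > 0L)
    stop("unknown target_class '", paste(bad, collapse = "', '"),
         "'; permitted values: ", paste(TARGET_CLASSES, collapse = ", "))
  filopodia <- coerce_annotation(filopodia, empty_filopodia(), "filopodia")
  mitochondria <- coerce_annotation(mitochondria, empty_mitochondria(),
                                    "mitochondria")
  names(skeletons) <- vapply(skeletons, function(s) s$skeleton_id, character(1))
  structure(list(skeletons = skeletons, synapses = synapses,
                 filopodia = filopodia, mitochondria = mitochondria,
                 metadata = metadata),
            class = "dataset")
}

#' @export
print.dataset <- function(x, ...) {
  cat(sprintf("<dataset> %d skeletons, %d synapses, %d filopodia, %d mitochondria\n",
              length(x$skeletons), nrow(x$synapses), nrow(x$filopodia),
              nrow(x$mitochondria)))
  if (!is.null(x$metadata$profile))
    cat("  profile:", x$metadata$profile,
        " seed:", x$metadata$seed %||% NA, "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Concatenate datasets
#'
#' Skeleton and annotation ids must not collide; metadata is taken from
#' the first dataset.
#' @param ... `dataset` objects.
#' @return a merged `dataset`.
#' @export
combine_datasets <- function(...) {
  ds <- list(...)
  if (length(ds) == 1L && !inherits(ds[[1]], "dataset")) ds <- ds[[1]]
  skels <- do.call(c, lapply(ds, function(d) d$skeletons))
  if (anyDuplicated(names(skels)))
    stop("skeleton_id collision when combining datasets")
  new_dataset(skeletons = skels,
              synapses = do.call(rbind, lapply(ds, function(d) d$synapses)),
              filopodia = do.call(rbind, lapply(ds, function(d) d$filopodia)),
              mitochondria = do.call(rbind, lapply(ds, function(d) d$mitochondria)),
              metadata = {
                md <- ds[[1]]$metadata
                md$complete_somata <- unique(unlist(
                  lapply(ds, function(d) d$metadata$complete_somata)))
                md
              })
}

#' Read annotation CSVs
#'
#' Column headers are the field names documented in [dataset]; optional
#' columns may be absent. Unknown `target_class` strings error, listing
#' the permitted values.
#'
#' @param synapse_csv path to the synapse table (required).
#' @param filopodia_csv,mito_csv optional paths.
#' @return a `dataset` with empty skeleton list.
#' @export
read_annotations <- function(synapse_csv, filopodia_csv = NULL,
                             mito_csv = NULL) {
  syn <- utils::read.csv(synapse_csv, stringsAsFactors = FALSE)
  fil <- if (!is.null(filopodia_csv))
    utils::read.csv(filopodia_csv, stringsAsFactors = FALSE)
  else empty_filopodia()
  mit <- if (!is.null(mito_csv))
    utils::read.csv(mito_csv, stringsAsFactors = FALSE)
  else empty_mitochondria()
  new_dataset(skeletons = list(), synapses = syn, filopodia = fil,
              mitochondria = mit)
}

#' Validate a dataset; report, do not modify
#'
#' Checks that annotation references resolve against the bundled
#' skeletons and that values are in range. Presynaptic axon ids are
#' checked only when `metadata$axons_complete` is `TRUE`, since axons
#' commonly leave the reconstructed volume.
#'
#' @param dataset a `dataset`.
#' @return data.frame with columns `component`, `id`, `message`;
#'   zero rows when the dataset is fully consistent.
#' @export
validate_dataset <- function(dataset) {
  findings <- list()
  note <- function(component, id, message) {
    findings[[length(findings) + 1L]] <<-
      data.frame(component = component, id = as.character(id),
                 message = message)
  }
  cell_ids <- vapply(dataset$skeletons, function(s) s$cell_id, character(1))
  skel_of_cell <- function(cid) {
    hit <- which(cell_ids == cid)
    if (length(hit) == 0L) NULL else dataset$skeletons[[hit[1]]]
  }
  syn <- dataset$synapses
  for (i in seq_len(nrow(syn))) {
    s <- syn[i, ]
    if (!is.na(s$target_class) && !s$target_class %in% TARGET_CLASSES)
      note("synapse", s$synapse_id, paste0("unknown target_class ", s$target_class))
    # NA post_cell_id marks a postsynaptic partner outside the volume
    if (!is.na(s$post_cell_id)) {
      sk <- skel_of_cell(s$post_cell_id)
      if (is.null(sk)) {
        note("synapse", s$synapse_id,
             paste0("post_cell_id ", s$post_cell_id, " not in dataset"))
      } else if (!is.na(s$post_node_id) &&
                 !s$post_node_id %in% sk$nodes$node_id) {
        note("synapse", s$synapse_id,
             paste0("post_node_id ", s$post_node_id, " not on skeleton"))
      }
    }
    if (!is.na(s$psd_area) && s$psd_area <= 0)
      note("synapse", s$synapse_id, "non-positive psd_area")
    if (!is.na(s$bouton_radius) && s$bouton_radius <= 0)
      note("synapse", s$synapse_id, "non-positive bouton_radius")
    if (!is.na(s$vesicle_count) && s$vesicle_count < 0)
      note("synapse", s$synapse_id, "negative vesicle_count")
    if (isTRUE(dataset$metadata$axons_complete) &&
        !is.na(s$pre_axon_id) && is.null(skel_of_cell(s$pre_axon_id)))
      note("synapse", s$synapse_id,
           paste0("pre_axon_id ", s$pre_axon_id, " not in dataset"))
  }
  fil <- dataset$filopodia
  for (i in seq_len(nrow(fil))) {
    f <- fil[i, ]
    sk <- skel_of_cell(f$post_cell_id)
    if (is.null(sk)) {
      note("filopodium", f$filopodium_id,
           paste0("post_cell_id ", f$post_cell_id, " not in dataset"))
    } else if (!is.na(f$base_node_id) && !f$base_node_id %in% sk$nodes$node_id) {
      note("filopodium", f$filopodium_id, "base_node_id not on skeleton")
    }
    if (!is.na(f$length) && f$length <= 0)
      note("filopodium", f$filopodium_id, "non-positive length")
  }
  mit <- dataset$mitochondria
  skel_ids <- names(dataset$skeletons)
  for (i in seq_len(nrow(mit))) {
    m <- mit[i, ]
    if (!m$host_skeleton_id %in% skel_ids) {
      note("mitochondrion", m$mito_id,
           paste0("host_skeleton_id ", m$host_skeleton_id, " not in dataset"))
    } else {
      sk <- dataset$skeletons[[m$host_skeleton_id]]
      if (!is.na(m$start_node_id) && !m$start_node_id %in% sk$nodes$node_id)
        note("mitochondrion", m$mito_id, "start_node_id not on host skeleton")
      if (!is.na(m$end_node_id) && !m$end_node_id %in% sk$nodes$node_id)
        note("mitochondrion", m$mito_id, "end_node_id not on host skeleton")
    }
    if (!is.na(m$volume) && m$volume <= 0)
      note("mitochondrion", m$mito_id, "non-positive volume")
  }
  if (length(findings) == 0L)
    data.frame(component = character(0), id = character(0),
               message = character(0))
  else do.call(rbind, findings)
}

#' Write a dataset bundle to a directory
#'
#' Layout: `skeletons.swc`, `synapses.csv`, `filopodia.csv`,
#' `mitochondria.csv`, `metadata.json`.
#'
#' @param dataset a `dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_swc(dataset$skeletons, file.path(dir, "skeletons.swc"))
  utils::write.csv(dataset$synapses, file.path(dir, "synapses.csv"),
                   row.names = FALSE)
  utils::write.csv(dataset$filopodia, file.path(dir, "filopodia.csv"),
                   row.names = FALSE)
  utils::write.csv(dataset$mitochondria, file.path(dir, "mitochondria.csv"),
                   row.names = FALSE)
  md <- dataset$metadata
  # node ids are unique across a bundle, so the root node re-identifies
  # each skeleton on read
  md$skeleton_index <- data.frame(
    skeleton_id = names(dataset$skeletons),
    cell_id = vapply(dataset$skeletons, function(s) s$cell_id, character(1)),
    cell_class = vapply(dataset$skeletons, function(s) s$cell_class,
                        character(1)),
    root_node_id = vapply(dataset$skeletons, function(s) {
      s$nodes$node_id[is.na(s$nodes$parent_id)][1]
    }, integer(1)),
    row.names = NULL)
  jsonlite::write_json(md, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a dataset bundle written by [write_dataset()]
#' @param dir bundle directory.
#' @return a `dataset`.
#' @export
read_dataset <- function(dir) {
  md <- jsonlite::read_json(file.path(dir, "metadata.json"),
                            simplifyVector = TRUE)
  skels <- read_swc(file.path(dir, "skeletons.swc"))
  idx <- md$skeleton_index
  if (!is.null(idx)) {
    for (i in seq_along(skels)) {
      root <- skels[[i]]$nodes$node_id[is.na(skels[[i]]$nodes$parent_id)][1]
      hit <- which(idx$root_node_id == root)
      if (length(hit) == 1L) {
        skels[[i]]$skeleton_id <- idx$skeleton_id[hit]
        skels[[i]]$cell_id <- idx$cell_id[hit]
        skels[[i]]$cell_class <- idx$cell_class[hit]
      }
    }
  }
  new_dataset(
    skeletons = skels,
    synapses = utils::read.csv(file.path(dir, "synapses.csv"),
                               stringsAsFactors = FALSE),
    filopodia = utils::read.csv(file.path(dir, "filopodia.csv"),
                                stringsAsFactors = FALSE),
    mitochondria = utils::read.csv(file.path(dir, "mitochondria.csv"),
                                   stringsAsFactors = FALSE),
    metadata = md[setdiff(names(md), "skeleton_index")])
}
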