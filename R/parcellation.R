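# Subsystem atlas: integer-labelled volume plus a label -> subsystem mapping.
# Masks are mutually exclusive by construction (one label per voxel), matching
# the three non-overlapping DMN subsystems (MT, Core, FT).

#' Build a subsystem atlas from a labelled volume
#'
#' Retains only the labels named in `mapping`; every other label is treated as
#' background (0). Each mapped label must occur in the volume.
#'
#' @param labels A `volume3d` with integer label values (0 = background).
#' @param mapping Named integer vector or two-column data frame
#'   (`label`, `subsystem`) mapping label IDs to subsystem names, e.g.
#'   `c("15" = "MT", "16" = "Core", "17" = "FT")` or
#'   `data.frame(label = c(15,16,17), subsystem = c("MT","Core","FT"))`.
#' @return A `subsystem_atlas`: list with `labels` (integer array), `grid`,
#'   and `mapping` (data frame label/subsystem).
#' @export
build_atlas <- function(labels, mapping) {
  if (!inherits(labels, "volume3d")) stop("build_atlas: 'labels' must be a volume3d")
  map <- normalize_mapping(mapping)
  if (nrow(map) == 0L) stop("build_atlas: empty mapping (configuration error)")
  lab <- labels$values
  lab[is.na(lab)] <- 0
  if (max(abs(lab - round(lab))) > 1e-8)
    stop("build_atlas: label volume is not integer-valued")
  lab <- array(as.integer(round(lab)), dim = dim(lab))
  present <- unique(as.vector(lab))
  missing <- setdiff(map$label, present)
  if (length(missing))
    stop("build_atlas: mapped label(s) absent from volume: ",
         paste(missing, collapse = ", "))
  lab[!(lab %in% map$label)] <- 0L
  structure(list(labels = lab, grid = labels$grid, mapping = map),
            class = "subsystem_atlas")
}

normalize_mapping <- function(mapping) {
  if (is.data.frame(mapping)) {
    stopifnot(all(c("label", "subsystem") %in% names(mapping)))
    map <- data.frame(label = as.integer(mapping$label),
                      subsystem = as.character(mapping$subsystem),
                      stringsAsFactors = FALSE)
  } else if (length(mapping)) {
    map <- data.frame(label = as.integer(names(mapping)),
                      subsystem = as.character(unname(mapping)),
                      stringsAsFactors = FALSE)
  } else {
    map <- data.frame(label = integer(0), subsystem = character(0))
  }
  if (anyNA(map$label)) stop("mapping labels must be integers")
  if (anyDuplicated(map$label)) stop("duplicate label in mapping")
  map
}

#' Read a label -> subsystem mapping from TSV or YAML
#'
#' TSV files need columns `label` and `subsystem`; YAML files map label IDs to
#' subsystem names (`15: MT`).
#'
#' @param path File path (`.tsv`/`.txt` or `.yaml`/`.yml`).
#' @return Data frame with columns `label`, `subsystem`.
#' @export
read_label_mapping <- function(path) {
  if (!file.exists(path)) stop("read_label_mapping: file not found: ", path)
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("read_label_mapping: the 'yaml' package is required for YAML input")
    y <- yaml::read_yaml(path)
    normalize_mapping(stats::setNames(as.character(unlist(y)), names(y)))
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    normalize_mapping(tab)
  }
}

#' Subsystem masks of an atlas
#'
#' @param atlas A `subsystem_atlas`.
#' @return Named list of binary `volume3d` masks, one per subsystem.
#' @export
atlas_masks <- function(atlas) {
  stopifnot(inherits(atlas, "subsystem_atlas"))
  out <- lapply(seq_len(nrow(atlas$mapping)), function(i) {
    m <- array(as.numeric(atlas$labels == atlas$mapping$label[i]),
               dim = atlas$grid$shape)
    volume3d(m, atlas$grid, role = "binary")
  })
  stats::setNames(out, atlas$mapping$subsystem)
}

#' Resample an atlas onto a target grid (nearest neighbour)
#'
#' Each target voxel centre is mapped through the two affines into the source
#' voxel lattice and takes the label of the nearest source voxel (background if
#' it falls outside the source field of view). Nearest-neighbour assignment
#' never introduces new label values and preserves mask disjointness.
#'
#' @param atlas A `subsystem_atlas`.
#' @param target A [grid_spec()].
#' @return A `subsystem_atlas` on `target`. Subsystems that end up with zero
#'   voxels trigger a warning.
#' @export
resample_labels <- function(atlas, target) {
  stopifnot(inherits(atlas, "subsystem_atlas"), inherits(target, "grid_spec"))
  sh <- target$shape
  idx <- as.matrix(expand.grid(i = seq_len(sh[1]), j = seq_len(sh[2]),
                               k = seq_len(sh[3])))
  world <- vox_to_world(target, idx)
  src <- round(world_to_vox(atlas$grid, world))
  inside <- src[, 1] >= 1 & src[, 1] <= atlas$grid$shape[1] &
            src[, 2] >= 1 & src[, 2] <= atlas$grid$shape[2] &
            src[, 3] >= 1 & src[, 3] <= atlas$grid$shape[3]
  out <- integer(nrow(src))
  if (any(inside)) {
    s <- src[inside, , drop = FALSE]
    out[inside] <- atlas$labels[cbind(s[, 1], s[, 2], s[, 3])]
  }
  lab <- array(out, dim = sh)
  res <- structure(list(labels = lab, grid = target, mapping = atlas$mapping),
                   class = "subsystem_atlas")
  cnt <- subsystem_voxel_counts(res)
  if (any(cnt == 0))
    warning("resample_labels: subsystem(s) with zero voxels after resampling: ",
            paste(names(cnt)[cnt == 0], collapse = ", "))
  # disjointness is structural (one label per voxel) but asserted post-resample
  stopifnot(sum(cnt) == sum(lab != 0L))
  res
}

#' Voxel counts per subsystem
#'
#' The group-level masks in MNI152 2 mm space used for activation profiling
#' have documented sizes 2,680 (MT), 11,435 (Core) and 12,672 (FT) voxels;
#' this reports the analogous counts for any atlas.
#'
#' @param atlas A `subsystem_atlas`.
#' @return Named integer vector of voxel counts, in mapping order.
#' @export
subsystem_voxel_counts <- function(atlas) {
  stopifnot(inherits(atlas, "subsystem_atlas"))
  cnt <- vapply(atlas$mapping$label,
                function(l) sum(atlas$labels == l), integer(1))
  stats::setNames(cnt, atlas$mapping$subsystem)
}
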