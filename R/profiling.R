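# The core statistic: per participant, condition and subsystem, the percentage
# of voxels whose z passes +tau (activating) or -tau (deactivating). z-maps are
# individual task-vs-implicit-baseline statistic volumes in a common space.

#' Threshold configuration for z-maps
#'
#' @param tau Positive z threshold; 1.96 by default, with 2.3 and 2.6 as the
#'   conventional robustness alternates.
#' @return A `threshold_config`.
#' @export
threshold_config <- function(tau = 1.96) {
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau <= 0)
    stop("threshold_config: 'tau' must be a positive scalar")
  structure(list(tau = tau), class = "threshold_config")
}

#' Binarize a z-map into activation and deactivation masks
#'
#' The boundary is inclusive: a voxel with `z == tau` activates and `z == -tau`
#' deactivates, so no voxel is ever in both masks. Missing voxels are in
#' neither.
#'
#' @param zmap A `volume3d` with role `"zstat"`.
#' @param cfg A [threshold_config()] (or a bare numeric tau).
#' @return List with binary `volume3d` elements `activation` and
#'   `deactivation`.
#' @export
threshold_zmap <- function(zmap, cfg = threshold_config()) {
  stopifnot(inherits(zmap, "volume3d"))
  if (is.numeric(cfg)) cfg <- threshold_config(cfg)
  if (all(is.na(zmap$values)))
    stop("threshold_zmap: all voxels missing (empty map)")
  z <- zmap$values
  act <- array(as.numeric(!is.na(z) & z >= cfg$tau), dim = dim(z))
  deact <- array(as.numeric(!is.na(z) & z <= -cfg$tau), dim = dim(z))
  list(activation = volume3d(act, zmap$grid, role = "binary"),
       deactivation = volume3d(deact, zmap$grid, role = "binary"))
}

#' Per-subsystem percentages of over-threshold voxels
#'
#' For each subsystem mask S, reports `100 * |mask ∩ S| / |S|` for the
#' activation and deactivation masks. The denominator is the full subsystem
#' size; set `denominator_mask` to a per-participant valid-voxel mask to
#' restrict it for real data with partial coverage.
#'
#' @param maps Output of [threshold_zmap()].
#' @param atlas A `subsystem_atlas` on the same grid.
#' @param denominator_mask Optional binary `volume3d` restricting both
#'   numerator and denominator.
#' @return Data frame with columns `subsystem`, `n_subsystem_voxels`,
#'   `pct_activating`, `pct_deactivating`.
#' @export
profile_zmap <- function(maps, atlas, denominator_mask = NULL) {
  stopifnot(inherits(atlas, "subsystem_atlas"))
  assert_same_grid(maps$activation, atlas)
  assert_same_grid(maps$deactivation, atlas)
  keep <- if (is.null(denominator_mask)) TRUE else {
    assert_same_grid(denominator_mask, atlas)
    denominator_mask$values == 1
  }
  act <- maps$activation$values == 1 & keep
  deact <- maps$deactivation$values == 1 & keep
  res <- lapply(seq_len(nrow(atlas$mapping)), function(i) {
    inS <- atlas$labels == atlas$mapping$label[i] & keep
    n <- sum(inS)
    if (n == 0L)
      stop("profile_zmap: subsystem '", atlas$mapping$subsystem[i],
           "' has no voxels (division guard)")
    data.frame(subsystem = atlas$mapping$subsystem[i],
               n_subsystem_voxels = n,
               pct_activating = 100 * sum(act & inS) / n,
               pct_deactivating = 100 * sum(deact & inS) / n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Build the long-format profile table for a collection of z-maps
#'
#' @param zmaps Named list of `volume3d` z-maps; names are
#'   `"<participant>|<condition>"`, or supply a data frame `manifest` with
#'   columns `participant`, `condition` (and optionally `study`) whose rows
#'   parallel `zmaps`.
#' @param atlas A `subsystem_atlas` shared by all maps.
#' @param cfg A [threshold_config()].
#' @param manifest Optional manifest data frame (see above).
#' @param study Study identifier recycled over rows when the manifest lacks
#'   one.
#' @return Data frame with one row per (participant, condition, subsystem),
#'   sorted deterministically, columns `participant`, `study`, `condition`,
#'   `subsystem`, `n_subsystem_voxels`, `pct_activating`, `pct_deactivating`.
#' @export
build_profile_table <- function(zmaps, atlas, cfg = threshold_config(),
                                manifest = NULL, study = "study1") {
  if (is.null(manifest)) {
    if (is.null(names(zmaps)) || any(!grepl("\\|", names(zmaps))))
      stop("build_profile_table: zmaps must be named '<participant>|<condition>' ",
           "or a manifest supplied")
    parts <- strsplit(names(zmaps), "|", fixed = TRUE)
    manifest <- data.frame(participant = vapply(parts, `[`, "", 1),
                           condition = vapply(parts, `[`, "", 2),
                           stringsAsFactors = FALSE)
  }
  if (nrow(manifest) != length(zmaps))
    stop("build_profile_table: manifest rows must parallel zmaps")
  if (is.null(manifest$study)) manifest$study <- study
  key <- paste(manifest$participant, manifest$condition, sep = "|")
  if (anyDuplicated(key))
    stop("build_profile_table: duplicate (participant, condition) input: ",
         key[duplicated(key)][1])
  rows <- lapply(seq_along(zmaps), function(i) {
    prof <- profile_zmap(threshold_zmap(zmaps[[i]], cfg), atlas)
    cbind(manifest[rep(i, nrow(prof)), c("participant", "study", "condition"),
                   drop = FALSE],
          prof, row.names = NULL)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$participant, tab$condition, tab$subsystem), ]
  rownames(tab) <- NULL
  tab
}

#' Write a profile table as TSV
#'
#' UTF-8, tab-delimited, header row; byte-identical for identical inputs.
#'
#' @param table Output of [build_profile_table()].
#' @param path Output path.
#' @export
write_profile_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
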