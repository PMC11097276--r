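# Consensus maps: per-voxel fraction of participants whose binarized map
# includes the voxel; thresholded at 20% to define the "commonly" activated /
# deactivated regions, which intersected with the subsystem masks give the six
# functional-connectivity seeds.

#' Participant-fraction consensus map
#'
#' Voxelwise mean of a stack of binary maps: the fraction of participants whose
#' thresholded map includes each voxel.
#'
#' @param binary_maps List of binary `volume3d`, one per participant, all on
#'   one grid.
#' @return A `volume3d` with role `"fraction"`.
#' @export
consensus_fraction <- function(binary_maps) {
  if (length(binary_maps) < 1L) stop("consensus_fraction: need at least 1 map")
  g <- binary_maps[[1]]$grid
  for (m in binary_maps) {
    if (!inherits(m, "volume3d") || m$role != "binary")
      stop("consensus_fraction: all inputs must be binary volume3d (role error)")
    assert_same_grid(m, binary_maps[[1]])
  }
  acc <- Reduce(`+`, lapply(binary_maps, function(m) {
    v <- m$values
    v[is.na(v)] <- 0
    v
  }))
  volume3d(acc / length(binary_maps), g, role = "fraction")
}

#' Combine per-condition consensus maps
#'
#' Unweighted mean of the per-condition fraction maps, so each condition
#' contributes equally regardless of how many participants its study had
#' (study sizes 29/22/19/26 differ). Set `weights` to the per-condition
#' participant counts for a pooled-count combination instead.
#'
#' @param condition_maps List of fraction `volume3d`, one per condition.
#' @param weights Optional numeric weights (e.g. study Ns); default equal.
#' @return A fraction `volume3d`.
#' @export
combine_conditions <- function(condition_maps, weights = NULL) {
  if (length(condition_maps) < 1L) stop("combine_conditions: need >= 1 map")
  for (m in condition_maps) {
    if (!inherits(m, "volume3d") || m$role != "fraction")
      stop("combine_conditions: inputs must be fraction volume3d")
    assert_same_grid(m, condition_maps[[1]])
  }
  if (is.null(weights)) weights <- rep(1, length(condition_maps))
  stopifnot(length(weights) == length(condition_maps), all(weights > 0))
  w <- weights / sum(weights)
  acc <- Reduce(`+`, Map(function(m, wi) m$values * wi, condition_maps, w))
  volume3d(acc, condition_maps[[1]]$grid, role = "fraction")
}

#' Threshold a consensus map
#'
#' Inclusive at the cutoff: voxels with fraction `>= cutoff` are retained, so a
#' region present in exactly 20% of maps survives the canonical 0.20 cutoff.
#'
#' @param cmap Fraction `volume3d`.
#' @param cutoff Fraction in (0, 1]; 0.20 by default.
#' @return Binary `volume3d`. Warns if the result is empty.
#' @export
threshold_consensus <- function(cmap, cutoff = 0.20) {
  stopifnot(inherits(cmap, "volume3d"))
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0 || cutoff > 1)
    stop("threshold_consensus: cutoff must be in (0, 1] (configuration error)")
  v <- cmap$values
  out <- array(as.numeric(!is.na(v) & v >= cutoff), dim = dim(v))
  if (sum(out) == 0)
    warning("threshold_consensus: no voxel reaches the cutoff (empty map)")
  volume3d(out, cmap$grid, role = "binary")
}

#' Derive the six connectivity seeds
#'
#' Intersects the commonly-activated and commonly-deactivated consensus masks
#' with each subsystem mask: {MT, Core, FT} x {activation, deactivation}.
#' Activation and deactivation seeds of one subsystem may overlap (regions
#' where different voxels, or the same voxels across conditions, both activate
#' and deactivate).
#'
#' @param act_consensus,deact_consensus Binary `volume3d` consensus masks.
#' @param atlas A `subsystem_atlas` on the same grid.
#' @return Named list of six binary `volume3d` seeds,
#'   `"<subsystem>_activation"` / `"<subsystem>_deactivation"`.
#' @export
build_seed_set <- function(act_consensus, deact_consensus, atlas) {
  stopifnot(inherits(atlas, "subsystem_atlas"))
  assert_same_grid(act_consensus, atlas)
  assert_same_grid(deact_consensus, atlas)
  seeds <- list()
  for (i in seq_len(nrow(atlas$mapping))) {
    sys <- atlas$mapping$subsystem[i]
    inS <- atlas$labels == atlas$mapping$label[i]
    for (pol in c("activation", "deactivation")) {
      cons <- if (pol == "activation") act_consensus else deact_consensus
      m <- array(as.numeric(cons$values == 1 & inS), dim = atlas$grid$shape)
      if (sum(m) == 0)
        stop("build_seed_set: empty seed '", sys, "_", pol, "'")
      seeds[[paste(sys, pol, sep = "_")]] <-
        volume3d(m, atlas$grid, role = "binary")
    }
  }
  seeds
}
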