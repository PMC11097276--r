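# Synthetic-data generators: every input the pipeline needs, with recorded
# ground truth, so each stage is testable end to end without any download.
# Generators are pure functions of (spec, seed).

#' Simulation specification
#'
#' Defaults define the study conditions the generators emulate: a 20^3 common
#' grid; three disjoint subsystems (MT smallest, Core and FT larger, echoing
#' the real subsystem size ordering); two task conditions whose planted
#' activation/deactivation fractions reproduce the qualitative pattern of
#' stronger recall-than-reading activation in MT and Core and the strongest
#' deactivation in Core; 9 minutes of rest at TR = 3 s (180 frames); and
#' seed-target coupling of 0.5.
#'
#' @param grid_shape 3-vector of voxels per axis.
#' @param subsystem_sizes Named integer vector (MT, Core, FT block sizes).
#' @param conditions Character vector of task condition names.
#' @param p_act,p_deact Condition x subsystem matrices of planted supra- /
#'   infra-threshold voxel fractions (`p_act + p_deact <= 1` cellwise).
#' @param n_participants Participants per study.
#' @param T_rest,tr Rest-scan length (frames) and repetition time (s).
#' @param beta Seed-target coupling amplitude (signal units per unit latent).
#' @param noise_sd White-noise SD of rest voxel series.
#' @param nuisance_amp Amplitude of the global nuisance component.
#' @param seed RNG seed (mandatory).
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(grid_shape = c(20, 20, 20),
                            subsystem_sizes = c(MT = 200, Core = 800, FT = 900),
                            conditions = c("reading", "recall"),
                            p_act = rbind(reading = c(MT = 0.05, Core = 0.03, FT = 0.15),
                                          recall  = c(MT = 0.15, Core = 0.08, FT = 0.15)),
                            p_deact = rbind(reading = c(MT = 0.10, Core = 0.20, FT = 0.05),
                                            recall  = c(MT = 0.15, Core = 0.25, FT = 0.08)),
                            n_participants = 20, T_rest = 180, tr = 3,
                            beta = 0.5, noise_sd = 1, nuisance_amp = 0.6,
                            seed = 1L) {
  if (is.null(seed)) stop("simulation_spec: rng seed is mandatory")
  stopifnot(length(grid_shape) == 3L, all(subsystem_sizes >= 1),
            sum(subsystem_sizes) <= prod(grid_shape),
            all(p_act >= 0), all(p_deact >= 0), all(p_act + p_deact <= 1),
            all(conditions %in% rownames(p_act)),
            all(conditions %in% rownames(p_deact)),
            all(names(subsystem_sizes) %in% colnames(p_act)),
            n_participants >= 2, T_rest >= 2, tr > 0, is.finite(beta))
  structure(list(grid_shape = as.integer(grid_shape),
                 subsystem_sizes = subsystem_sizes,
                 conditions = conditions, p_act = p_act, p_deact = p_deact,
                 n_participants = as.integer(n_participants),
                 T_rest = as.integer(T_rest), tr = tr, beta = beta,
                 noise_sd = noise_sd, nuisance_amp = nuisance_amp,
                 seed = as.integer(seed)), class = "simulation_spec")
}

#' Synthetic subsystem atlas
#'
#' Three disjoint contiguous blocks (consecutive voxels in array order)
#' labelled MT (1), Core (2), FT (3); the remainder is background. Counts are
#' exact by construction.
#'
#' @param spec A [simulation_spec()].
#' @return A `subsystem_atlas`.
#' @export
make_atlas <- function(spec) {
  sz <- spec$subsystem_sizes
  if (sum(sz) > prod(spec$grid_shape))
    stop("make_atlas: subsystem sizes exceed grid (configuration error)")
  lab <- integer(prod(spec$grid_shape))
  off <- 0L
  for (i in seq_along(sz)) {
    lab[(off + 1):(off + sz[i])] <- i
    off <- off + sz[i]
  }
  vol <- volume3d(array(as.numeric(lab), dim = spec$grid_shape),
                  grid_spec(spec$grid_shape), role = "zstat")
  build_atlas(vol, stats::setNames(names(sz), seq_along(sz)))
}

#' Synthetic stand-in for the reference parcellation
#'
#' A synthetic 91 x 109 x 91 label volume on a 2 mm grid whose three
#' subsystem blocks have exactly the documented MNI152-space subsystem sizes
#' (2,680 MT / 11,435 Core / 12,672 FT voxels). It is a stand-in for the
#' publicly distributed 17-network parcellation — useful for exercising the
#' counting and resampling pathways at realistic dimensions, not a copy of
#' the real atlas.
#'
#' @return A `subsystem_atlas`.
#' @export
make_reference_atlas <- function() {
  shape <- c(91L, 109L, 91L)
  aff <- diag(c(-2, 2, 2, 1))
  aff[1:3, 4] <- c(90, -126, -72)
  sizes <- c(MT = 2680L, Core = 11435L, FT = 12672L)
  lab <- integer(prod(shape))
  off <- 200000L                              # park the blocks mid-volume
  for (i in seq_along(sizes)) {
    lab[(off + 1):(off + sizes[i])] <- i
    off <- off + sizes[i]
  }
  vol <- volume3d(array(as.numeric(lab), dim = shape),
                  grid_spec(shape, aff), role = "zstat")
  build_atlas(vol, stats::setNames(names(sizes), seq_along(sizes)))
}

#' Synthetic participant x condition z-maps with known truth
#'
#' Within each subsystem, a Bernoulli(`p_act`) subset of voxels draws
#' supra-threshold z ~ Normal(3.5, 0.5), a disjoint Bernoulli(`p_deact`)
#' subset draws z ~ Normal(-3.5, 0.5), and everything else (including
#' background) draws Normal(0, 1) — so thresholding at 1.96 retains the
#' planted voxels near-certainly plus the ~2.5% per-direction Gaussian-tail
#' background that real thresholded maps also carry.
#'
#' @param spec A [simulation_spec()].
#' @param atlas Atlas from [make_atlas()] (defaults to `make_atlas(spec)`).
#' @return List: `zmaps` (named `"<participant>|<condition>"`), `truth`
#'   (data frame of realized planted fractions per participant, condition,
#'   subsystem).
#' @export
make_zmaps <- function(spec, atlas = make_atlas(spec)) {
  set.seed(spec$seed)
  nv <- prod(spec$grid_shape)
  labs <- as.vector(atlas$labels)
  zmaps <- list(); truth <- list()
  for (p in seq_len(spec$n_participants)) {
    pid <- sprintf("p%02d", p)
    for (cond in spec$conditions) {
      z <- stats::rnorm(nv, 0, 1)
      for (i in seq_len(nrow(atlas$mapping))) {
        sys <- atlas$mapping$subsystem[i]
        vox <- which(labs == atlas$mapping$label[i])
        u <- stats::runif(length(vox))
        pa <- spec$p_act[cond, sys]
        pd <- spec$p_deact[cond, sys]
        act <- u < pa
        deact <- u >= pa & u < pa + pd
        z[vox[act]] <- stats::rnorm(sum(act), 3.5, 0.5)
        z[vox[deact]] <- stats::rnorm(sum(deact), -3.5, 0.5)
        truth[[length(truth) + 1L]] <- data.frame(
          participant = pid, condition = cond, subsystem = sys,
          frac_act = mean(act), frac_deact = mean(deact),
          stringsAsFactors = FALSE)
      }
      zmaps[[paste(pid, cond, sep = "|")]] <-
        volume3d(array(z, dim = spec$grid_shape), atlas$grid, role = "zstat")
    }
  }
  list(zmaps = zmaps, truth = do.call(rbind, truth))
}

# band-limited unit-variance latent series, one per column
band_limited_latents <- function(T, tr, k, band = c(0.01, 0.1)) {
  Y <- matrix(stats::rnorm(T * k), T, k)
  Y <- fft_bandpass(Y, tr, band)
  sweep(Y, 2, apply(Y, 2, stats::sd), "/")
}

#' Synthetic resting scan with planted coupling and nuisance structure
#'
#' Each seed region gets a latent band-limited (0.01–0.1 Hz) unit-variance
#' signal; its voxels are `beta * latent + noise_sd * white`. A global
#' nuisance component of amplitude `nuisance_amp` is added everywhere, and a
#' background noise ROI (the CompCor stand-in for white matter/CSF) carries
#' the nuisance components at high amplitude. Motion parameters are low-noise
#' with persistent steps planted at `spike_frames` so censoring flags exactly
#' those frames.
#'
#' @param spec A [simulation_spec()].
#' @param atlas Atlas giving the grid and background voxels.
#' @param seeds Named list of binary `volume3d` target regions (defaults to
#'   the subsystem masks).
#' @param spike_frames Frames at which motion spikes are planted.
#' @param gradient_weight Optional `volume3d`; when given, each voxel's
#'   coupling is scaled by its gradient value (for gradient-recovery tests).
#' @return List: `bold` (`volume4d`), `motion` (T x 6), `noise_roi`
#'   (binary `volume3d`), `truth` (latents, spike frames, nuisance series,
#'   coupling amplitude).
#' @export
make_rest <- function(spec, atlas = make_atlas(spec),
                      seeds = atlas_masks(atlas),
                      spike_frames = integer(0), gradient_weight = NULL) {
  set.seed(spec$seed + 1L)
  T <- spec$T_rest; tr <- spec$tr
  nv <- prod(spec$grid_shape)
  lat <- band_limited_latents(T, tr, length(seeds))
  colnames(lat) <- names(seeds)
  Y <- matrix(stats::rnorm(T * nv, 0, spec$noise_sd), T, nv)
  for (i in seq_along(seeds)) {
    vox <- which(as.vector(seeds[[i]]$values) == 1)
    w <- if (is.null(gradient_weight)) rep(1, length(vox))
         else as.vector(gradient_weight$values)[vox]
    Y[, vox] <- Y[, vox] + outer(lat[, i], spec$beta * w)
  }
  nuis <- band_limited_latents(T, tr, 2, band = c(0.01, 0.15))
  Y <- Y + spec$nuisance_amp * nuis[, 1]
  # noise ROI: last background voxels, dominated by the nuisance components
  bg <- which(as.vector(atlas$labels) == 0L)
  roi_vox <- utils::tail(bg, max(50L, ceiling(nv / 50)))
  mix <- matrix(stats::rnorm(2 * length(roi_vox)), 2)
  Y[, roi_vox] <- Y[, roi_vox] + 4 * nuis %*% mix
  roi <- numeric(nv); roi[roi_vox] <- 1
  motion <- cbind(matrix(stats::rnorm(T * 3, 0, 0.005), T, 3),
                  matrix(stats::rnorm(T * 3, 0, 1e-4), T, 3))
  for (f in spike_frames) {
    j <- 1 + (which(spike_frames == f) - 1) %% 3
    motion[f:T, j] <- motion[f:T, j] + 0.8      # persistent step: FD spike at f only
  }
  list(bold = volume4d(array(t(Y), dim = c(spec$grid_shape, T)),
                       atlas$grid, tr = tr),
       motion = motion,
       noise_roi = volume3d(array(roi, dim = spec$grid_shape), atlas$grid,
                            role = "binary"),
       truth = list(latents = lat, spike_frames = spike_frames,
                    nuisance = nuis, beta = spec$beta))
}

#' Synthetic gradient atlas
#'
#' Three smooth, mutually orthogonal, zero-mean, unit-variance fields built by
#' orthogonalizing low-order spatial polynomials of the voxel coordinates
#' within the mask. Deterministic given the spec.
#'
#' @param spec A [simulation_spec()].
#' @param mask Optional binary `volume3d` analysis mask (default: whole grid).
#' @return A `gradient_atlas` with gradients G1, G2, G3.
#' @export
make_gradients <- function(spec, mask = NULL) {
  sh <- spec$grid_shape
  grid <- grid_spec(sh)
  if (is.null(mask))
    mask <- volume3d(array(1, dim = sh), grid, role = "binary")
  co <- as.matrix(expand.grid(x = seq_len(sh[1]), y = seq_len(sh[2]),
                              z = seq_len(sh[3])))
  co <- scale(co)
  B <- cbind(1, co[, 1], co[, 2], co[, 3] + 0.3 * co[, 1] * co[, 2])
  inmask <- as.vector(mask$values) == 1
  Q <- qr.Q(qr(B[inmask, , drop = FALSE]))[, 2:4, drop = FALSE]
  Q <- sweep(Q, 2, apply(Q, 2, stats::sd), "/")
  grads <- lapply(1:3, function(j) {
    v <- rep(NA_real_, nrow(co))
    v[inmask] <- Q[, j]
    volume3d(array(v, dim = sh), grid, role = "gradient")
  })
  names(grads) <- c("G1", "G2", "G3")
  gradient_atlas(grads, mask)
}

#' Synthetic FC maps with planted gradient loadings
#'
#' Builds, for each participant and seed, a map `sum_g a_g * G_g + e` with
#' white noise of SD `noise_sd` and per-subject loading jitter, so the
#' expected spatial correlation with gradient g is
#' `a_g / sqrt(sum(a^2) + noise_sd^2)`.
#'
#' @param atlas_g A [gradient_atlas()].
#' @param loadings Data frame with columns `seed` and one column per gradient
#'   name giving the population loading of that seed on that gradient.
#' @param n Number of participants.
#' @param noise_sd Voxel-noise SD.
#' @param subject_sd SD of the per-subject loading jitter.
#' @return Nested list `maps[[participant]][[seed]]` of `volume3d`.
#' @export
make_fc_maps_with_loadings <- function(atlas_g, loadings, n,
                                       noise_sd = 1, subject_sd = 0.05) {
  gnames <- names(atlas_g$gradients)
  stopifnot(all(c("seed", gnames) %in% names(loadings)))
  sh <- atlas_g$gradients[[1]]$grid$shape
  G <- vapply(atlas_g$gradients, function(g) as.vector(g$values),
              numeric(prod(sh)))
  G[is.na(G)] <- 0
  out <- list()
  for (p in seq_len(n)) {
    pid <- sprintf("p%02d", p)
    out[[pid]] <- list()
    for (i in seq_len(nrow(loadings))) {
      a <- as.numeric(loadings[i, gnames]) +
        stats::rnorm(length(gnames), 0, subject_sd)
      v <- as.vector(G %*% a) + stats::rnorm(prod(sh), 0, noise_sd)
      out[[pid]][[loadings$seed[i]]] <-
        volume3d(array(v, dim = sh), atlas_g$gradients[[1]]$grid,
                 role = "fisherz")
    }
  }
  out
}
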