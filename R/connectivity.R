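# Seed-to-voxel functional connectivity: Fisher-z maps per participant, paired
# contrasts between seeds, and sign-flip permutation cluster-extent inference
# (cluster-forming voxel p < 0.001 two-sided, FWE on maximum cluster size).

#' Fisher z transform of a correlation
#'
#' `atanh(r)`, with `|r| = 1` saturated to `atanh(1 - 1e-7)` so downstream
#' t-tests stay finite.
#'
#' @param r Correlation(s) in `[-1, 1]`.
#' @return Fisher-z value(s).
#' @export
fisher_z <- function(r) {
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE))
    stop("fisher_z: |r| > 1 (domain error)")
  r <- pmax(pmin(r, 1 - 1e-7), -1 + 1e-7)
  atanh(r)
}

#' Mean time series over a seed
#'
#' Unweighted mean over seed voxels per frame.
#'
#' @param bold A `volume4d`.
#' @param seed Binary `volume3d` on the same grid, non-empty.
#' @return Numeric series of length T.
#' @export
seed_mean_timeseries <- function(bold, seed) {
  assert_same_grid(bold, seed)
  if (sum(seed$values == 1, na.rm = TRUE) == 0)
    stop("seed_mean_timeseries: empty seed")
  rowMeans(bold_matrix(bold, seed))
}

#' Whole-brain seed-to-voxel connectivity map
#'
#' Pearson correlation of every voxel's series with the seed mean series,
#' Fisher-z transformed. Zero-variance (degenerate) voxels are missing in the
#' output.
#'
#' @param bold A `volume4d` with at least 3 frames.
#' @param seed Binary `volume3d` seed.
#' @return A `volume3d` with role `"fisherz"`.
#' @export
seed_to_voxel_fc <- function(bold, seed) {
  if (bold$T < 3L) stop("seed_to_voxel_fc: need T >= 3 frames")
  s <- seed_mean_timeseries(bold, seed)
  if (stats::sd(s) == 0) stop("seed_to_voxel_fc: degenerate seed (zero variance)")
  Y <- bold_matrix(bold)
  sdv <- apply(Y, 2, stats::sd)
  r <- rep(NA_real_, ncol(Y))
  ok <- sdv > 0
  r[ok] <- as.numeric(stats::cor(s, Y[, ok, drop = FALSE]))
  z <- rep(NA_real_, length(r))
  z[ok] <- fisher_z(r[ok])
  volume3d(array(z, dim = bold$grid$shape), bold$grid, role = "fisherz")
}

#' Voxelwise paired contrast between two sets of FC maps
#'
#' Paired t statistic of `z_A - z_B` at every voxel across participants;
#' voxels missing in any participant's map propagate as missing.
#'
#' @param maps_a,maps_b Lists of `volume3d` (role `"fisherz"`), parallel by
#'   participant; names, when present, must match.
#' @return List: `tmap` (`volume3d` of t statistics), `diff` (participants x
#'   voxels matrix of differences), `n`.
#' @export
paired_contrast_map <- function(maps_a, maps_b) {
  n <- length(maps_a)
  if (length(maps_b) != n) stop("paired_contrast_map: unequal map counts")
  if (n < 3L) stop("paired_contrast_map: need n >= 3 participants")
  if (!is.null(names(maps_a)) && !is.null(names(maps_b)) &&
      !identical(names(maps_a), names(maps_b)))
    stop("paired_contrast_map: participant pairing mismatch")
  g <- maps_a[[1]]$grid
  for (m in c(maps_a, maps_b)) assert_same_grid(m, maps_a[[1]])
  D <- t(vapply(seq_len(n),
                function(i) as.vector(maps_a[[i]]$values - maps_b[[i]]$values),
                numeric(prod(g$shape))))
  tv <- col_paired_t(D)
  list(tmap = volume3d(array(tv, dim = g$shape), g, role = "zstat"),
       diff = D, n = n)
}

# columnwise one-sample t of an n x V matrix (NA columns propagate)
col_paired_t <- function(D) {
  n <- nrow(D)
  m <- colMeans(D)
  v <- (colSums(D^2) - n * m^2) / (n - 1)
  v[v < 0] <- 0
  t <- m / sqrt(v / n)
  t[v == 0 & m == 0] <- 0
  t
}

#' Label connected clusters (6-connectivity)
#'
#' Face-adjacent connected components of a logical 3-D array.
#'
#' @param supra Logical 3-D array.
#' @return Integer array of cluster labels (0 = background).
#' @export
label_clusters_6 <- function(supra) {
  dm <- dim(supra)
  lab <- array(0L, dm)
  idx <- which(supra)
  if (!length(idx)) return(lab)
  nxt <- 0L
  strides <- c(1L, dm[1], dm[1] * dm[2])
  coord <- arrayInd(idx, dm)
  in_set <- logical(prod(dm)); in_set[idx] <- TRUE
  for (v in idx) {
    if (lab[v] != 0L) next
    nxt <- nxt + 1L
    stack <- v
    lab[v] <- nxt
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      ci <- arrayInd(cur, dm)
      for (ax in 1:3) for (dir in c(-1L, 1L)) {
        nc <- ci
        nc[ax] <- nc[ax] + dir
        if (nc[ax] < 1L || nc[ax] > dm[ax]) next
        nb <- cur + dir * strides[ax]
        if (in_set[nb] && lab[nb] == 0L) {
          lab[nb] <- nxt
          stack <- c(stack, nb)
        }
      }
    }
  }
  lab
}

#' Inference configuration for paired contrasts
#'
#' @param voxel_p Cluster-forming voxel threshold (two-sided), default 0.001.
#' @param cluster_alpha FWE level on cluster size, default 0.05.
#' @param n_contrasts Number of contrasts Bonferroni-corrected over (3 seed
#'   contrasts give the conventional 0.05/3 ≈ 0.017).
#' @param n_permutations Number of sign-flip permutations (>= 100).
#' @param rng_seed Seed for the permutation RNG (mandatory for
#'   reproducibility).
#' @return An `inference_config`.
#' @export
inference_config <- function(voxel_p = 0.001, cluster_alpha = 0.05,
                             n_contrasts = 3, n_permutations = 1000,
                             rng_seed = 1L) {
  stopifnot(voxel_p > 0, voxel_p < 1, n_permutations >= 100, n_contrasts >= 1)
  structure(list(voxel_p = voxel_p, cluster_alpha = cluster_alpha,
                 n_contrasts = n_contrasts,
                 n_permutations = as.integer(n_permutations),
                 rng_seed = as.integer(rng_seed)), class = "inference_config")
}

#' Sign-flip permutation cluster-extent FWE inference
#'
#' Given participants x voxels paired differences, forms clusters of voxels
#' exceeding the two-sided `voxel_p` t threshold (6-connectivity, positive and
#' negative exceedances clustered separately), and compares each observed
#' cluster's size against the permutation null distribution of the maximum
#' cluster size under random sign flips of whole participants:
#' `p_FWE = (1 + #\{perm max >= observed\}) / (1 + n_permutations)`.
#'
#' @param diff Participants x voxels matrix of paired differences (e.g. the
#'   `diff` element of [paired_contrast_map()]).
#' @param shape Grid shape mapping columns of `diff` to 3-D voxels.
#' @param cfg An [inference_config()].
#' @return List: `clusters` (data frame `cluster`, `sign`, `size`, `peak_t`,
#'   `peak_index`, `p_fwe`), `tmap` (observed t values), `null_max` (the
#'   permutation maximum-cluster-size distribution), `t_crit`.
#' @export
permutation_cluster_fwe <- function(diff, shape, cfg = inference_config()) {
  diff <- as.matrix(diff)
  n <- nrow(diff)
  if (ncol(diff) != prod(shape))
    stop("permutation_cluster_fwe: diff columns != prod(shape)")
  nperm <- cfg$n_permutations
  if (n <= 30 && nperm > 2^n) {
    warning("permutation_cluster_fwe: capping permutations at 2^n = ", 2^n)
    nperm <- 2^n
  }
  t_crit <- stats::qt(1 - cfg$voxel_p / 2, df = n - 1)
  miss <- colSums(is.na(diff)) > 0
  D <- diff
  D[, miss] <- 0                            # missing voxels can never enter a cluster
  t_obs <- col_paired_t(D)
  t_obs[miss] <- NA_real_

  max_cluster <- function(tv) {
    mx <- 0L
    for (sgn in c(1, -1)) {
      supra <- array(!is.na(tv) & sgn * tv > t_crit, dim = shape)
      if (!any(supra)) next
      lab <- label_clusters_6(supra)
      mx <- max(mx, max(tabulate(lab[lab > 0L])))
    }
    mx
  }

  # observed clusters, per sign
  clus <- list(); ci <- 0L
  for (sgn in c(1, -1)) {
    supra <- array(!is.na(t_obs) & sgn * t_obs > t_crit, dim = shape)
    if (!any(supra)) next
    lab <- label_clusters_6(supra)
    for (l in seq_len(max(lab))) {
      vox <- which(lab == l)
      if (!length(vox)) next
      ci <- ci + 1L
      pk <- vox[which.max(sgn * t_obs[vox])]
      clus[[ci]] <- data.frame(cluster = ci, sign = sgn, size = length(vox),
                               peak_t = t_obs[pk], peak_index = pk)
    }
  }
  # permutation null of the maximum cluster size (vectorized t over all perms)
  set.seed(cfg$rng_seed)
  S <- matrix(sample(c(-1, 1), nperm * n, replace = TRUE), nperm, n)
  css <- colSums(D^2)
  M <- (S %*% D) / n
  null_max <- integer(nperm)
  for (p in seq_len(nperm)) {
    v <- (css - n * M[p, ]^2) / (n - 1)
    v[v < 1e-300] <- 1e-300
    tv <- M[p, ] / sqrt(v / n)
    tv[miss] <- NA_real_
    null_max[p] <- max_cluster(tv)
  }
  tab <- if (ci > 0) {
    tab <- do.call(rbind, clus)
    tab$p_fwe <- vapply(tab$size,
                        function(sz) (1 + sum(null_max >= sz)) / (1 + nperm),
                        numeric(1))
    tab[order(tab$p_fwe, -tab$size), ]
  } else {
    data.frame(cluster = integer(0), sign = numeric(0), size = integer(0),
               peak_t = numeric(0), peak_index = integer(0), p_fwe = numeric(0))
  }
  rownames(tab) <- NULL
  list(clusters = tab, tmap = t_obs, null_max = null_max, t_crit = t_crit)
}
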