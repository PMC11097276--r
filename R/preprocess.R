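# Resting-state denoising: motion censoring (framewise displacement plus
# global-signal spikes), nuisance/CompCor regression, and bandpass filtering.
# Regression runs before filtering; the residual leakage this order admits is
# bounded by a spectral test in the suite.

#' Denoising configuration
#'
#' @param fd_threshold Framewise-displacement censoring threshold in mm
#'   (0.5 for the resting study; 0.9 is the task-study scrubbing convention).
#' @param global_z_threshold Frames whose z-scored global mean exceeds this
#'   absolute z are censored (default 3).
#' @param n_compcor Number of noise-ROI principal components to regress
#'   (default 5).
#' @param band Passband `(low, high)` in Hz, default `c(0.01, 0.1)`.
#' @param motion_expansion Include first and second temporal derivatives of
#'   the six motion parameters.
#' @param tr Repetition time in seconds, used to validate the band against
#'   Nyquist when supplied.
#' @return A `denoise_config`.
#' @export
denoise_config <- function(fd_threshold = 0.5, global_z_threshold = 3,
                           n_compcor = 5, band = c(0.01, 0.1),
                           motion_expansion = TRUE, tr = NULL) {
  stopifnot(fd_threshold > 0, global_z_threshold > 0, n_compcor >= 0,
            length(band) == 2L)
  if (!(band[1] > 0 && band[1] < band[2]))
    stop("denoise_config: need 0 < low < high")
  if (!is.null(tr) && band[2] >= 1 / (2 * tr))
    stop("denoise_config: high edge must be below Nyquist 1/(2*TR) = ",
         signif(1 / (2 * tr), 4), " Hz")
  structure(list(fd_threshold = fd_threshold,
                 global_z_threshold = global_z_threshold,
                 n_compcor = n_compcor, band = band,
                 motion_expansion = motion_expansion), class = "denoise_config")
}

#' Framewise displacement (Power convention)
#'
#' `FD(t) = sum |Delta translation| + 50 mm * sum |Delta rotation|`, the
#' rotational displacements evaluated on a 50 mm sphere; `FD(1) = 0`.
#'
#' @param motion T x 6 matrix: three translations (mm) then three rotations
#'   (radians), one row per frame.
#' @return Numeric FD series of length T, in mm.
#' @export
framewise_displacement <- function(motion) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6L)
    stop("framewise_displacement: expected 6 motion columns, got ", ncol(motion))
  if (nrow(motion) < 2L) stop("framewise_displacement: need T >= 2 frames")
  d <- abs(diff(motion))
  fd <- rowSums(d[, 1:3, drop = FALSE]) + 50 * rowSums(d[, 4:6, drop = FALSE])
  c(0, fd)
}

#' Read a 6-column motion-parameter text file
#'
#' Whitespace-delimited, one row per frame: three translations in mm, three
#' rotations in radians.
#'
#' @param path File path.
#' @return T x 6 numeric matrix.
#' @export
read_motion_params <- function(path) {
  m <- as.matrix(utils::read.table(path))
  if (ncol(m) != 6L)
    stop("read_motion_params: expected 6 columns in ", path)
  unname(m)
}

#' Censor high-motion / global-signal-spike frames
#'
#' A frame is flagged when `FD > fd_threshold` or its z-scored global signal
#' exceeds `global_z_threshold` in absolute value. Each flagged frame gets one
#' spike regressor (an indicator column), so its influence on the nuisance
#' regression is removed exactly.
#'
#' @param fd FD series (mm), length T.
#' @param gs Global-signal series (mean over in-brain voxels per frame),
#'   length T.
#' @param cfg A [denoise_config()].
#' @return List: `keep` (logical length T), `spikes` (T x n_flagged 0/1
#'   matrix, zero columns when nothing is flagged), `flagged` (frame indices).
#' @export
censor_volumes <- function(fd, gs, cfg = denoise_config()) {
  if (length(fd) != length(gs))
    stop("censor_volumes: fd and gs lengths differ")
  T <- length(fd)
  gz <- if (stats::sd(gs) > 0) (gs - mean(gs)) / stats::sd(gs) else rep(0, T)
  flagged <- which(fd > cfg$fd_threshold | abs(gz) > cfg$global_z_threshold)
  if (length(flagged) == T)
    stop("censor_volumes: every frame flagged (unusable scan)")
  spikes <- matrix(0, T, length(flagged))
  if (length(flagged))
    spikes[cbind(flagged, seq_along(flagged))] <- 1
  colnames(spikes) <- if (length(flagged))
    paste0("spike_", flagged) else character(0)
  list(keep = !(seq_len(T) %in% flagged), spikes = spikes, flagged = flagged)
}

# flatten a volume4d to a T x V matrix over an optional binary mask
bold_matrix <- function(bold, mask = NULL) {
  dm <- dim(bold$series)
  mat <- t(matrix(bold$series, prod(dm[1:3]), dm[4]))
  if (!is.null(mask)) {
    assert_same_grid(bold, mask)
    mat <- mat[, as.vector(mask$values == 1), drop = FALSE]
  }
  mat
}

#' CompCor noise components
#'
#' Voxel series within the noise ROI (white matter + CSF) are linearly
#' detrended and variance-normalized, then the top-k left singular vectors of
#' the T x V matrix are returned: unit-norm component time series, sign fixed
#' so each component's largest-magnitude element is positive.
#'
#' @param bold A `volume4d`.
#' @param noise_roi Binary `volume3d` noise mask (non-empty).
#' @param k Number of components; must satisfy `k <= min(T, |ROI|)`.
#' @return T x k matrix (zero columns when `k = 0`).
#' @export
compcor_components <- function(bold, noise_roi, k = 5) {
  stopifnot(inherits(bold, "volume4d"))
  if (sum(noise_roi$values == 1, na.rm = TRUE) == 0)
    stop("compcor_components: empty noise ROI")
  Y <- bold_matrix(bold, noise_roi)
  T <- nrow(Y)
  if (k > min(T, ncol(Y)))
    stop("compcor_components: k = ", k, " exceeds min(T, |ROI|) = ",
         min(T, ncol(Y)), " (configuration error)")
  if (k == 0) return(matrix(0, T, 0))
  tt <- seq_len(T)
  X <- cbind(1, tt - mean(tt))
  Y <- qr.resid(qr(X), Y)                      # linear detrend per voxel
  sdv <- apply(Y, 2, stats::sd)
  Y <- Y[, sdv > 0, drop = FALSE]
  Y <- sweep(Y, 2, sdv[sdv > 0], "/")          # variance normalization
  sv <- svd(Y, nu = k, nv = 0)
  U <- sv$u
  for (j in seq_len(ncol(U))) {
    i <- which.max(abs(U[, j]))
    if (U[i, j] < 0) U[, j] <- -U[, j]
  }
  colnames(U) <- paste0("compcor_", seq_len(ncol(U)))
  U
}

#' Assemble a confound matrix
#'
#' Columns: six motion parameters, optional first and second derivatives,
#' CompCor components, spike indicators, and a linear drift term. Constant and
#' duplicate columns are dropped.
#'
#' @param motion T x 6 motion matrix (or NULL).
#' @param compcor T x k CompCor matrix (or NULL).
#' @param spikes T x s spike matrix (or NULL).
#' @param motion_expansion Add first/second derivative expansions.
#' @param linear_drift Include a linear trend regressor.
#' @return T x K numeric matrix with column names.
#' @export
build_confounds <- function(motion = NULL, compcor = NULL, spikes = NULL,
                            motion_expansion = TRUE, linear_drift = TRUE) {
  parts <- list()
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    colnames(motion) <- paste0("motion_", 1:6)
    parts$motion <- motion
    if (motion_expansion) {
      d1 <- rbind(0, diff(motion))
      d2 <- rbind(0, diff(d1))
      colnames(d1) <- paste0("motion_d1_", 1:6)
      colnames(d2) <- paste0("motion_d2_", 1:6)
      parts$d1 <- d1; parts$d2 <- d2
    }
  }
  if (!is.null(compcor) && ncol(compcor) > 0) parts$compcor <- compcor
  if (!is.null(spikes) && ncol(spikes) > 0) parts$spikes <- spikes
  X <- do.call(cbind, parts)
  if (is.null(X)) X <- matrix(0, 0, 0)
  if (linear_drift && nrow(X) > 0) {
    tt <- seq_len(nrow(X))
    X <- cbind(X, drift = tt - mean(tt))
  }
  keep <- apply(X, 2, function(col) stats::sd(col) > 0)
  X <- X[, keep, drop = FALSE]
  X[, !duplicated(t(X)), drop = FALSE]
}

#' Regress confounds out of a BOLD series
#'
#' Per-voxel ordinary least squares against `[intercept | confounds]`;
#' residuals are orthogonal to every confound column.
#'
#' @param bold A `volume4d`.
#' @param confounds T x K confound matrix (row count = frames).
#' @return A `volume4d` of residuals.
#' @export
nuisance_regress <- function(bold, confounds) {
  stopifnot(inherits(bold, "volume4d"))
  confounds <- as.matrix(confounds)
  if (nrow(confounds) != bold$T)
    stop("nuisance_regress: confound rows (", nrow(confounds),
         ") != frames (", bold$T, ")")
  X <- cbind(intercept = 1, confounds)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("nuisance_regress: rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  Y <- bold_matrix(bold)
  R <- qr.resid(qx, Y)
  volume4d(array(t(R), dim = dim(bold$series)), bold$grid, tr = bold$tr)
}

#' Bandpass filter a BOLD series
#'
#' Discrete-Fourier mask filter applied per voxel: frequency bins with
#' `low <= f <= high` are retained, all others (including DC) zeroed.
#'
#' @param bold A `volume4d` (TR defines the sampling rate).
#' @param band `(low, high)` in Hz; `high` must be below Nyquist.
#' @return Filtered `volume4d`.
#' @export
bandpass_filter <- function(bold, band = c(0.01, 0.1)) {
  stopifnot(inherits(bold, "volume4d"))
  if (band[1] <= 0 || band[1] >= band[2])
    stop("bandpass_filter: need 0 < low < high")
  nyq <- 1 / (2 * bold$tr)
  if (band[2] >= nyq)
    stop("bandpass_filter: high edge ", band[2], " Hz >= Nyquist ",
         signif(nyq, 4), " Hz (configuration error)")
  R <- fft_bandpass(bold_matrix(bold), bold$tr, band)
  volume4d(array(t(R), dim = dim(bold$series)), bold$grid, tr = bold$tr)
}

# DFT mask filter on a T x V matrix (columns are series)
fft_bandpass <- function(Y, tr, band) {
  T <- nrow(Y)
  freqs <- (seq_len(T) - 1) / (T * tr)
  freqs <- pmin(freqs, 1 / tr - freqs)        # fold to [0, Nyquist]
  keep <- freqs >= band[1] & freqs <= band[2]
  F <- stats::mvfft(Y)
  F[!keep, ] <- 0
  Re(stats::mvfft(F, inverse = TRUE)) / T
}

#' Full denoising chain for one resting scan
#'
#' Censoring (FD + global signal), CompCor, confound regression (motion with
#' derivative expansion, components, spikes, drift), then bandpass. The
#' global-signal spike metric is the z-scored per-frame global mean; no global
#' signal regression is performed.
#'
#' @param bold A `volume4d`.
#' @param motion T x 6 motion matrix.
#' @param noise_roi Binary `volume3d` (white matter + CSF stand-in).
#' @param cfg A [denoise_config()].
#' @return List: `bold` (denoised `volume4d`), `keep` (retained-frame mask),
#'   `confounds` (the design used), `fd` (FD series).
#' @export
denoise_rest <- function(bold, motion, noise_roi, cfg = denoise_config()) {
  fd <- framewise_displacement(motion)
  gs <- rowMeans(bold_matrix(bold))
  cen <- censor_volumes(fd, gs, cfg)
  cc <- compcor_components(bold, noise_roi, cfg$n_compcor)
  X <- build_confounds(motion = motion, compcor = cc, spikes = cen$spikes,
                       motion_expansion = cfg$motion_expansion)
  res <- nuisance_regress(bold, X)
  filt <- bandpass_filter(res, cfg$band)
  list(bold = filt, keep = cen$keep, confounds = X, fd = fd)
}
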