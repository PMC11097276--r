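# Grid-aware volume containers and NIfTI-1 I/O. Every other module operates on
# these; all cross-volume operations refuse mismatched grids.

#' Define a voxel grid
#'
#' A grid is a 3-D voxel lattice together with a 4x4 voxel-to-world affine in
#' millimetres (RAS+ by convention, last row `(0,0,0,1)`).
#'
#' @param shape Integer vector of length 3, voxels per axis (all positive).
#' @param affine 4x4 numeric voxel-to-world matrix; must be invertible.
#' @return An object of class `grid_spec` with elements `shape` and `affine`.
#' @export
grid_spec <- function(shape, affine = diag(4)) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L))
    stop("grid_spec: 'shape' must be 3 positive integers")
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)))
    stop("grid_spec: 'affine' must be a 4x4 matrix")
  if (max(abs(affine[4, ] - c(0, 0, 0, 1))) > 1e-8)
    stop("grid_spec: last affine row must be (0,0,0,1)")
  if (abs(det(affine[1:3, 1:3])) < .Machine$double.eps * 100)
    stop("grid_spec: affine is singular (degenerate grid)")
  structure(list(shape = shape, affine = affine), class = "grid_spec")
}

#' 3-D volume on a grid
#'
#' @param values 3-D numeric array; `NA` marks missing (out-of-brain) voxels.
#' @param grid A [grid_spec()]; defaults to an identity-affine grid matching
#'   `dim(values)`.
#' @param role One of `"zstat"`, `"binary"`, `"fraction"`, `"fisherz"`,
#'   `"gradient"` — what the scalar at each voxel means.
#' @return An object of class `volume3d`.
#' @export
volume3d <- function(values, grid = NULL,
                     role = c("zstat", "binary", "fraction", "fisherz", "gradient")) {
  role <- match.arg(role)
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("volume3d: 'values' must be a 3-D array")
  if (is.null(grid)) grid <- grid_spec(dim(values))
  if (!identical(as.integer(dim(values)), grid$shape))
    stop("volume3d: values shape does not match grid shape")
  v <- values[!is.na(values)]
  if (role == "binary" && length(v) && !all(v %in% c(0, 1)))
    stop("volume3d: binary role requires values in {0,1}")
  if (role == "fraction" && length(v) && (min(v) < 0 || max(v) > 1))
    stop("volume3d: fraction role requires values in [0,1]")
  structure(list(values = values, grid = grid, role = role), class = "volume3d")
}

#' 4-D BOLD volume on a grid
#'
#' @param series 4-D numeric array (x, y, z, frame).
#' @param grid A [grid_spec()] for the spatial dimensions.
#' @param tr Repetition time in seconds (> 0).
#' @return An object of class `volume4d` with `T` frames.
#' @export
volume4d <- function(series, grid = NULL, tr = 1) {
  series <- as.array(series)
  if (length(dim(series)) != 4L)
    stop("volume4d: 'series' must be a 4-D array")
  if (dim(series)[4] < 2L)
    stop("volume4d: need at least 2 frames")
  if (!is.numeric(tr) || length(tr) != 1L || !is.finite(tr) || tr <= 0)
    stop("volume4d: 'tr' must be a positive scalar (seconds)")
  if (is.null(grid)) grid <- grid_spec(dim(series)[1:3])
  if (!identical(as.integer(dim(series)[1:3]), grid$shape))
    stop("volume4d: series spatial shape does not match grid shape")
  structure(list(series = series, grid = grid, tr = tr,
                 T = as.integer(dim(series)[4])), class = "volume4d")
}

#' @export
print.volume3d <- function(x, ...) {
  cat(sprintf("<volume3d %s  %s  missing=%d>\n",
              paste(x$grid$shape, collapse = "x"), x$role,
              sum(is.na(x$values))))
  invisible(x)
}

#' @export
print.volume4d <- function(x, ...) {
  cat(sprintf("<volume4d %s x %d frames  TR=%.3gs>\n",
              paste(x$grid$shape, collapse = "x"), x$T, x$tr))
  invisible(x)
}

#' Read a NIfTI-1 volume
#'
#' 3-D images become [volume3d()] objects (role `"zstat"` unless overridden),
#' 4-D images become [volume4d()] with TR taken from the header's `pixdim[4]`
#' unless `tr` is given. Higher-dimensional images are refused.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param role Value role for 3-D images (see [volume3d()]).
#' @param tr Optional TR override in seconds for 4-D images.
#' @return A `volume3d` or `volume4d`.
#' @export
read_volume <- function(path, role = "zstat", tr = NULL) {
  if (!file.exists(path)) stop("read_volume: file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("read_volume: malformed NIfTI file '",
                                           path, "': ", conditionMessage(e)))
  nd <- length(dim(img))
  aff <- matrix(as.numeric(RNifti::xform(img)), 4, 4)
  if (nd == 3L) {
    volume3d(array(as.numeric(img), dim = dim(img)),
             grid_spec(dim(img), aff), role = role)
  } else if (nd == 4L) {
    if (is.null(tr)) {
      tr <- RNifti::pixdim(img)[4]
      if (!is.finite(tr) || tr <= 0) tr <- 1
    }
    volume4d(array(as.numeric(img), dim = dim(img)),
             grid_spec(dim(img)[1:3], aff), tr = tr)
  } else {
    stop("read_volume: unsupported shape: ", nd, "-D image (need 3 or 4 dims)")
  }
}

#' Write a volume as NIfTI-1
#'
#' Float payloads are written as float32 and round-trip bit-identically;
#' binary-role volumes are written as uint8.
#'
#' @param vol A `volume3d` or `volume4d`.
#' @param path Output path (`.nii` or `.nii.gz`); parent directory must exist.
#' @export
write_volume <- function(vol, path) {
  if (!dir.exists(dirname(path)))
    stop("write_volume: directory does not exist: ", dirname(path))
  voxdims <- sqrt(colSums(vol$grid$affine[1:3, 1:3]^2))
  if (inherits(vol, "volume3d")) {
    dat <- vol$values
    datatype <- if (vol$role == "binary") "uint8" else "float"
    if (vol$role == "binary") dat[is.na(dat)] <- 0
    attr(dat, "pixdim") <- voxdims
    img <- RNifti::asNifti(dat, datatype = datatype, internal = FALSE)
  } else if (inherits(vol, "volume4d")) {
    dat <- vol$series
    attr(dat, "pixdim") <- c(voxdims, vol$tr)
    img <- RNifti::asNifti(dat, datatype = "float", internal = FALSE)
  } else stop("write_volume: not a volume3d/volume4d")
  img <- RNifti::`qform<-`(img, structure(vol$grid$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Assert two volumes share a grid
#'
#' Passes silently iff shapes are equal and affines agree within 1e-4 mm;
#' otherwise raises a grid-mismatch error naming the differing field.
#'
#' @param a,b Volumes or `grid_spec` objects.
#' @export
assert_same_grid <- function(a, b) {
  ga <- if (inherits(a, "grid_spec")) a else a$grid
  gb <- if (inherits(b, "grid_spec")) b else b$grid
  if (!identical(ga$shape, gb$shape))
    stop("grid mismatch: shapes differ (",
         paste(ga$shape, collapse = "x"), " vs ",
         paste(gb$shape, collapse = "x"), ")")
  if (max(abs(ga$affine - gb$affine)) > 1e-4)
    stop("grid mismatch: affines differ by more than 1e-4 mm")
  invisible(TRUE)
}

# voxel (1-based i,j,k) -> world mm, rows of idx are voxels
vox_to_world <- function(grid, idx) {
  idx0 <- cbind(as.matrix(idx) - 1, 1)
  t(grid$affine %*% t(idx0))[, 1:3, drop = FALSE]
}

# world mm -> continuous 1-based voxel coordinates
world_to_vox <- function(grid, xyz) {
  inv <- solve(grid$affine)
  v <- t(inv %*% t(cbind(as.matrix(xyz), 1)))[, 1:3, drop = FALSE]
  v + 1
}
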