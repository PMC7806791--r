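# Core volumetric data model: regular 3-D grids, scalar volumes, and the
# single coordinate convention used throughout the package.
#
# Voxel coordinates are 0-based and continuous; a grid's 4x4 affine maps
# homogeneous voxel coordinates to world coordinates in mm:
#   world = A[1:3,1:3] %*% voxel + A[1:3,4]
# Displacement vectors (see field.R) are always stored in mm in the world
# frame of the grid they are defined on.

#' Construct a sampling grid
#'
#' A grid is the geometric half of a volume: array shape, voxel spacing in
#' mm, and the 4x4 voxel-to-world affine. Volumes, displacement fields and
#' templates all carry one.
#'
#' @param shape integer length-3 array dimensions.
#' @param spacing numeric length-3 voxel size in mm, strictly positive.
#' @param affine 4x4 voxel-to-world matrix; defaults to `diag(spacing)` with
#'   a zero origin.
#' @return An object of class `gm_grid`.
#' @export
gm_grid <- function(shape, spacing = c(1, 1, 1), affine = NULL) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L))
    stop("grid shape must be three positive integers")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("voxel spacing must be strictly positive on all axes")
  if (is.null(affine)) {
    affine <- diag(c(spacing, 1))
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)))
    stop("affine must be a 4x4 matrix")
  structure(list(shape = shape, spacing = spacing, affine = affine),
            class = "gm_grid")
}

#' @export
print.gm_grid <- function(x, ...) {
  cat(sprintf("<gm_grid %s, spacing %s mm>\n",
              paste(x$shape, collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x")))
  invisible(x)
}

grids_equal <- function(a, b, tol = 1e-6) {
  identical(a$shape, b$shape) &&
    max(abs(a$affine - b$affine)) < tol
}

#' Construct a scalar volume
#'
#' @param data 3-D numeric array. NaN/NA voxels are rejected: upstream
#'   conversion problems must be fixed before entering the pipeline.
#' @param spacing,affine grid geometry (see [gm_grid()]).
#' @param modality one of `"T1"`, `"T2"`, `"label"`, `"stat"`, `"logjac"`.
#'   Label volumes must hold non-negative integers and are always
#'   interpolated with nearest-neighbour.
#' @return An object of class `gm_volume` with fields `data`, `spacing`,
#'   `affine`, `modality`.
#' @export
as_volume <- function(data, spacing = c(1, 1, 1), affine = NULL,
                      modality = "T1") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("expected 3-D volume, got ", length(dim(data)), " dimensions")
  n_bad <- sum(!is.finite(data))
  if (n_bad > 0L)
    stop(sprintf("volume contains %d non-finite voxel(s)", n_bad))
  modality <- match.arg(modality, c("T1", "T2", "label", "stat", "logjac"))
  if (modality == "label") {
    if (any(data < 0) || any(data != round(data)))
      stop("label volumes must contain only non-negative integers")
  }
  g <- gm_grid(dim(data), spacing, affine)
  structure(list(data = data, spacing = g$spacing, affine = g$affine,
                 modality = modality),
            class = "gm_volume")
}

#' @export
print.gm_volume <- function(x, ...) {
  cat(sprintf("<gm_volume [%s] %s, spacing %s mm, range [%.4g, %.4g]>\n",
              x$modality, paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' Extract the grid of a volume or displacement field
#' @param x a `gm_volume` or `gm_field`.
#' @return The `gm_grid` the object is defined on.
#' @export
grid_of <- function(x) {
  if (inherits(x, "gm_grid")) return(x)
  if (inherits(x, "gm_volume")) return(gm_grid(dim(x$data), x$spacing, x$affine))
  if (inherits(x, "gm_field")) return(x$reference)
  stop("no grid associated with object of class ", paste(class(x), collapse = "/"))
}

# N x 3 matrix of 0-based voxel index triples in array (column-major) order
grid_index_matrix <- function(grid) {
  n <- grid$shape
  cbind(rep.int(seq_len(n[1]) - 1, n[2] * n[3]),
        rep.int(rep(seq_len(n[2]) - 1, each = n[1]), n[3]),
        rep(seq_len(n[3]) - 1, each = n[1] * n[2]))
}

# N x 3 matrix of world coordinates (mm) of every grid point, array order
grid_world_matrix <- function(grid) {
  idx <- grid_index_matrix(grid)
  w <- idx %*% t(grid$affine[1:3, 1:3])
  w[, 1] <- w[, 1] + grid$affine[1, 4]
  w[, 2] <- w[, 2] + grid$affine[2, 4]
  w[, 3] <- w[, 3] + grid$affine[3, 4]
  w
}

# world (mm, N x 3) -> continuous 0-based voxel coordinates of `grid`
world_to_voxel <- function(world, grid) {
  inv <- solve(grid$affine)
  v <- world %*% t(inv[1:3, 1:3])
  v[, 1] <- v[, 1] + inv[1, 4]
  v[, 2] <- v[, 2] + inv[2, 4]
  v[, 3] <- v[, 3] + inv[3, 4]
  v
}
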