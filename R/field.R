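# Dense displacement fields over a reference grid. Vectors are stored as a
# 4-D array (nx, ny, nz, 3) in mm in the world frame of the reference grid;
# the induced deformation maps x to x + u(x) in world coordinates.

#' Construct a displacement field
#'
#' @param vectors 4-D numeric array `(nx, ny, nz, 3)` of displacement
#'   vectors in mm (world frame of the reference grid).
#' @param reference the `gm_grid` (or grid-bearing object) the field is
#'   defined on; its shape must match `dim(vectors)[1:3]`.
#' @return An object of class `gm_field`.
#' @export
displacement_field <- function(vectors, reference) {
  reference <- grid_of(reference)
  if (!is.array(vectors) || length(dim(vectors)) != 4L ||
      dim(vectors)[4] != 3L)
    stop("vectors must be a (nx, ny, nz, 3) array")
  if (!all(dim(vectors)[1:3] == reference$shape))
    stop("vector grid shape does not match the reference grid")
  if (any(!is.finite(vectors)))
    stop("displacement field contains non-finite components")
  structure(list(vectors = vectors, reference = reference),
            class = "gm_field")
}

#' Zero displacement field on a grid
#' @param reference grid or grid-bearing object.
#' @return A `gm_field` of all-zero vectors (the identity deformation).
#' @export
zero_field <- function(reference) {
  reference <- grid_of(reference)
  displacement_field(array(0, c(reference$shape, 3L)), reference)
}

#' @export
print.gm_field <- function(x, ...) {
  mx <- max(field_norm(x))
  cat(sprintf("<gm_field %s, spacing %s mm, max |u| = %.4g mm>\n",
              paste(x$reference$shape, collapse = "x"),
              paste(signif(x$reference$spacing, 4), collapse = "x"), mx))
  invisible(x)
}

# N x 3 matrix view of the vectors, rows in array order
field_vector_matrix <- function(field) {
  matrix(field$vectors, ncol = 3L)
}

# Euclidean norm of the displacement at every grid point (3-D array, mm)
field_norm <- function(field) {
  v <- field$vectors
  array(sqrt(v[, , , 1]^2 + v[, , , 2]^2 + v[, , , 3]^2),
        field$reference$shape)
}

# max |u| expressed in voxels (against the smallest spacing)
field_max_voxel <- function(field) {
  max(field_norm(field)) / min(field$reference$spacing)
}

# Interpolate a field's vectors at world points (N x 3, mm). Points outside
# the field domain get the zero vector (identity continuation) by default;
# mode = "clamp" extends the boundary values instead (used by the
# fixed-point inversion, which otherwise oscillates at the domain edge).
sample_field <- function(field, world, mode = "fill") {
  vox <- world_to_voxel(world, field$reference)
  cbind(sample_array(field$vectors[, , , 1], vox, mode = mode),
        sample_array(field$vectors[, , , 2], vox, mode = mode),
        sample_array(field$vectors[, , , 3], vox, mode = mode))
}

#' Check that a field induces a diffeomorphism
#'
#' The map `x -> x + u(x)` is only called diffeomorphic when its Jacobian
#' determinant is strictly positive everywhere. Fields that fail are flagged
#' here rather than silently used downstream.
#'
#' @param field a `gm_field`.
#' @return Logical scalar with attribute `min_det`, the smallest Jacobian
#'   determinant found.
#' @export
is_diffeomorphic <- function(field) {
  dets <- jacobian_determinant(field)$data
  structure(min(dets) > 0, min_det = min(dets))
}
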