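# Displacement-field calculus: composition, fixed-point inversion,
# resampling onto a reference grid, and (log-)Jacobian determinant maps.
# The log-Jacobian of the reference-to-native map is the voxel-wise volume
# surrogate the statistical stage analyses: 0 means no local volume change,
# positive means the native structure is larger than the reference.

# d(arr)/d(index) along one axis: 2nd-order central differences in the
# interior, 1st-order one-sided at the boundary faces.
axis_gradient <- function(arr, axis) {
  d <- dim(arr)
  n <- d[axis]
  perm <- c(axis, setdiff(1:3, axis))
  a <- matrix(aperm(arr, perm), nrow = n)
  g <- matrix(0, nrow = n, ncol = ncol(a))
  if (n >= 2L) {
    g[1, ] <- a[2, ] - a[1, ]
    g[n, ] <- a[n, ] - a[n - 1, ]
    if (n >= 3L)
      g[2:(n - 1), ] <- (a[3:n, ] - a[1:(n - 2), ]) / 2
  }
  aperm(array(g, d[perm]), order(perm))
}

#' Compose two displacement fields
#'
#' Returns the field of the composite deformation "apply `g`, then `f`":
#' `(f o g)(x) = g(x) + f(x + g(x))`, with `f` interpolated trilinearly
#' (zero-vector continuation outside its domain). The result lives on
#' `g`'s reference grid.
#'
#' @param f,g `gm_field`s defined over overlapping world regions.
#' @return A `gm_field` on `g`'s reference grid.
#' @export
compose_fields <- function(f, g) {
  stopifnot(inherits(f, "gm_field"), inherits(g, "gm_field"))
  ref <- g$reference
  w <- grid_world_matrix(ref) + field_vector_matrix(g)
  fv <- sample_field(f, w)
  displacement_field(array(field_vector_matrix(g) + fv, c(ref$shape, 3L)),
                     ref)
}

#' Invert a displacement field
#'
#' Fixed-point iteration for the inverse deformation:
#' `u_inv(x) <- -u(x + u_inv(x))`, run until the largest update falls below
#' `tol` (in voxels) or `max_iter` is reached. When the plain iteration
#' starts oscillating (displacement gradients approaching 1), the update is
#' under-relaxed adaptively. The input must induce a diffeomorphism
#' (positive Jacobian determinant) for the inverse to exist.
#'
#' @param field a `gm_field`.
#' @param tol convergence tolerance on the update, in voxels of the
#'   reference grid.
#' @param max_iter maximum number of fixed-point sweeps.
#' @return The inverse `gm_field` on the same reference grid, with
#'   attribute `iterations`.
#' @export
invert_field <- function(field, tol = 0.01, max_iter = 200L) {
  stopifnot(inherits(field, "gm_field"))
  ref <- field$reference
  w0 <- grid_world_matrix(ref)
  vox <- min(ref$spacing)
  v <- matrix(0, nrow(w0), 3L)
  omega <- 1
  delta_prev <- Inf
  for (it in seq_len(max_iter)) {
    target <- -sample_field(field, w0 + v, mode = "clamp")
    vn <- (1 - omega) * v + omega * target
    delta <- max(abs(vn - v)) / vox
    if (delta > delta_prev && omega > 0.25) omega <- omega / 2
    delta_prev <- delta
    v <- vn
    if (delta < tol)
      return(structure(displacement_field(array(v, c(ref$shape, 3L)), ref),
                       iterations = it))
  }
  stop(sprintf(
    "field inversion did not converge in %d iterations (last update %.4g voxels)",
    max_iter, delta))
}

#' Resample a displacement field onto another grid
#'
#' Vectors (mm, world frame) are interpolated componentwise at the world
#' positions of the new reference grid; points outside the source domain
#' get the zero vector.
#'
#' @param field a `gm_field`.
#' @param reference target grid (or grid-bearing object).
#' @return A `gm_field` on `reference`.
#' @export
resample_field <- function(field, reference) {
  reference <- grid_of(reference)
  v <- sample_field(field, grid_world_matrix(reference))
  displacement_field(array(v, c(reference$shape, 3L)), reference)
}

#' Jacobian determinant map of a deformation
#'
#' Per-voxel `det(I + du/dx)` of the map `x -> x + u(x)`, with derivatives
#' of the mm-valued displacements taken with respect to world mm
#' coordinates: central differences in the interior, one-sided at the
#' boundary, chained through the inverse of the grid's direction matrix.
#' Non-positive determinants are returned as-is but flagged with a warning;
#' use [is_diffeomorphic()] to test before trusting a field.
#'
#' @param field a `gm_field`.
#' @param warn warn when non-positive determinants occur.
#' @return A `gm_volume` (modality `"stat"`) of determinants.
#' @export
jacobian_determinant <- function(field, warn = FALSE) {
  stopifnot(inherits(field, "gm_field"))
  ref <- field$reference
  invA3 <- solve(ref$affine[1:3, 1:3])
  # G[[k]][[m]] = d u_k / d index_m
  J <- vector("list", 9L)
  for (k in 1:3) {
    uk <- field$vectors[, , , k]
    gk <- lapply(1:3, function(m) axis_gradient(uk, m))
    for (l in 1:3) {
      acc <- gk[[1]] * invA3[1, l] + gk[[2]] * invA3[2, l] +
        gk[[3]] * invA3[3, l]
      if (k == l) acc <- acc + 1
      J[[(k - 1L) * 3L + l]] <- acc
    }
  }
  F11 <- J[[1]]; F12 <- J[[2]]; F13 <- J[[3]]
  F21 <- J[[4]]; F22 <- J[[5]]; F23 <- J[[6]]
  F31 <- J[[7]]; F32 <- J[[8]]; F33 <- J[[9]]
  det <- F11 * (F22 * F33 - F23 * F32) -
    F12 * (F21 * F33 - F23 * F31) +
    F13 * (F21 * F32 - F22 * F31)
  n_bad <- sum(det <= 0)
  if (warn && n_bad > 0L)
    warning(sprintf("deformation is not diffeomorphic: %d voxel(s) with non-positive Jacobian determinant", n_bad))
  as_volume(det, ref$spacing, ref$affine, modality = "stat")
}

#' Log-Jacobian map of a subject scan in the common reference space
#'
#' Implements the per-scan volume-change computation of the longitudinal
#' TBM pipeline. Both inputs are forward-convention point maps:
#' `subject_field` sends native-space points to the subject's
#' age-appropriate template space (defined on the native/scan grid), and
#' `intertemplate_field` sends age-template points to the common 12-month
#' reference space (zero field for scans already at the reference age).
#' The two are concatenated, normalized by resampling onto the reference
#' grid, and inverted, yielding the reference-to-native map; the returned
#' values are the natural log of its Jacobian determinant. Negative values
#' mean the native structure is smaller than the reference; positive values
#' mean enlargement.
#'
#' @param subject_field `gm_field`, native -> age-template (forward
#'   convention). Registration outputs in resampling convention must first
#'   be passed through [invert_field()].
#' @param intertemplate_field `gm_field`, age-template -> reference, or a
#'   zero field on the reference grid for reference-age scans.
#' @param reference_12m the common reference grid (or grid-bearing object).
#' @param subject_id,visit,age_days optional metadata carried on the map.
#' @param tol,max_iter passed to [invert_field()].
#' @return A `gm_volume` with modality `"logjac"` and attributes
#'   `subject_id`, `visit`, `age_days`.
#' @export
subject_log_jacobian <- function(subject_field, intertemplate_field,
                                 reference_12m, subject_id = NA_character_,
                                 visit = NA_character_, age_days = NA_real_,
                                 tol = 0.01, max_iter = 200L) {
  reference_12m <- grid_of(reference_12m)
  comp <- compose_fields(intertemplate_field, subject_field)
  comp <- resample_field(comp, reference_12m)
  inv <- invert_field(comp, tol = tol, max_iter = max_iter)
  dets <- jacobian_determinant(inv)$data
  n_bad <- sum(dets <= 0)
  if (n_bad > 0L) {
    warning(sprintf("%d voxel(s) with non-positive Jacobian determinant; clamped before log", n_bad))
    dets[dets <= 1e-8] <- 1e-8
  }
  out <- as_volume(log(dets), reference_12m$spacing, reference_12m$affine,
                   modality = "logjac")
  attr(out, "subject_id") <- subject_id
  attr(out, "visit") <- visit
  attr(out, "age_days") <- age_days
  out
}
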