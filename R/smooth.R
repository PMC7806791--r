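# Separable filtering of 3-D arrays: Gaussian smoothing (registration
# regularisers, multi-resolution pyramids) and box sums (local
# cross-correlation windows). Each axis is filtered by a dense band
# operator applied as a matrix product, with kernels renormalised at the
# boundary so constants are preserved.

axis_operator <- function(n, kernel, normalize = TRUE) {
  r <- (length(kernel) - 1L) %/% 2L
  K <- matrix(0, n, n)
  for (j in seq_len(n)) {
    lo <- max(1L, j - r); hi <- min(n, j + r)
    k <- kernel[(lo - j + r + 1L):(hi - j + r + 1L)]
    if (normalize) k <- k / sum(k)
    K[j, lo:hi] <- k
  }
  K
}

apply_axis_operator <- function(arr, K, axis) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  m <- K %*% matrix(a, nrow = d[axis])
  a <- array(m, d[perm])
  aperm(a, order(perm))
}

gauss_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# sigma_vox: scalar or per-axis Gaussian width in voxels; 0 = no smoothing
gauss_smooth_array <- function(arr, sigma_vox) {
  sigma_vox <- rep_len(sigma_vox, 3L)
  for (ax in 1:3) {
    if (sigma_vox[ax] > 0) {
      K <- axis_operator(dim(arr)[ax], gauss_kernel(sigma_vox[ax]))
      arr <- apply_axis_operator(arr, K, ax)
    }
  }
  arr
}

#' Gaussian-smooth a volume
#' @param vol a `gm_volume` (not a label volume).
#' @param sigma_mm Gaussian width in mm (scalar or per-axis); converted to
#'   voxels through the volume spacing.
#' @return Smoothed `gm_volume`.
#' @export
smooth_volume <- function(vol, sigma_mm) {
  stopifnot(inherits(vol, "gm_volume"))
  if (vol$modality == "label") stop("refusing to smooth a label volume")
  sig_vox <- rep_len(sigma_mm, 3L) / vol$spacing
  as_volume(gauss_smooth_array(vol$data, sig_vox), vol$spacing, vol$affine,
            modality = vol$modality)
}

gauss_smooth_field <- function(field, sigma_vox) {
  if (all(sigma_vox <= 0)) return(field)
  v <- field$vectors
  for (k in 1:3) v[, , , k] <- gauss_smooth_array(v[, , , k], sigma_vox)
  displacement_field(v, field$reference)
}

# windowed sums over (2r+1)^3 boxes, truncated (not renormalised) at the
# boundary; window_count_array gives the matching per-voxel window sizes
box_sum_array <- function(arr, radius) {
  if (radius < 1L) return(arr)
  kernel <- rep(1, 2L * radius + 1L)
  for (ax in 1:3) {
    K <- axis_operator(dim(arr)[ax], kernel, normalize = FALSE)
    arr <- apply_axis_operator(arr, K, ax)
  }
  arr
}

window_count_array <- function(shape, radius) {
  box_sum_array(array(1, shape), radius)
}
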