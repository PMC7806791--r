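# Vectorised interpolation of 3-D arrays at arbitrary continuous voxel
# coordinates; the computational kernel behind resample(), warp() and the
# field calculus.

# arr: 3-D array; vox: N x 3 continuous 0-based voxel coordinates.
# Out-of-domain points get `fill`. Trilinear clamps the upper cell so that
# coordinates exactly on the last grid plane are interpolated, not dropped.
sample_array <- function(arr, vox, order = c("trilinear", "nearest"),
                         fill = 0, mode = c("fill", "clamp")) {
  order <- match.arg(order)
  mode <- match.arg(mode)
  n <- dim(arr)
  if (mode == "clamp") {
    for (k in 1:3) vox[, k] <- pmin.int(pmax.int(vox[, k], 0), n[k] - 1)
  }
  inside <- vox[, 1] >= 0 & vox[, 1] <= n[1] - 1 &
    vox[, 2] >= 0 & vox[, 2] <= n[2] - 1 &
    vox[, 3] >= 0 & vox[, 3] <= n[3] - 1
  out <- rep.int(fill, nrow(vox))
  if (!any(inside)) return(out)
  px <- vox[inside, 1]; py <- vox[inside, 2]; pz <- vox[inside, 3]
  if (order == "nearest") {
    ix <- pmin.int(pmax.int(round(px), 0), n[1] - 1)
    iy <- pmin.int(pmax.int(round(py), 0), n[2] - 1)
    iz <- pmin.int(pmax.int(round(pz), 0), n[3] - 1)
    out[inside] <- arr[1 + ix + n[1] * (iy + n[2] * iz)]
    return(out)
  }
  ix <- pmin.int(floor(px), n[1] - 2); ix <- pmax.int(ix, 0)
  iy <- pmin.int(floor(py), n[2] - 2); iy <- pmax.int(iy, 0)
  iz <- pmin.int(floor(pz), n[3] - 2); iz <- pmax.int(iz, 0)
  fx <- px - ix; fy <- py - iy; fz <- pz - iz
  base <- 1 + ix + n[1] * (iy + n[2] * iz)
  dx <- 1L; dy <- n[1]; dz <- n[1] * n[2]
  c000 <- arr[base];           c100 <- arr[base + dx]
  c010 <- arr[base + dy];      c110 <- arr[base + dx + dy]
  c001 <- arr[base + dz];      c101 <- arr[base + dx + dz]
  c011 <- arr[base + dy + dz]; c111 <- arr[base + dx + dy + dz]
  c00 <- c000 + fx * (c100 - c000)
  c10 <- c010 + fx * (c110 - c010)
  c01 <- c001 + fx * (c101 - c001)
  c11 <- c011 + fx * (c111 - c011)
  c0 <- c00 + fy * (c10 - c00)
  c1 <- c01 + fy * (c11 - c01)
  out[inside] <- c0 + fz * (c1 - c0)
  out
}

#' Resample a volume onto a reference grid
#'
#' Intensities are interpolated at the world positions of the reference grid
#' points; voxels falling outside the source domain receive `fill`
#' (0 by default, matching background-dominated phantoms).
#'
#' @param vol a [`gm_volume`][as_volume].
#' @param reference a `gm_grid`, or an object carrying one.
#' @param order `"trilinear"` or `"nearest"`. Label volumes must use
#'   `"nearest"`; requesting trilinear for labels is an error.
#' @param fill out-of-domain fill value.
#' @return A `gm_volume` on the reference grid.
#' @export
resample <- function(vol, reference, order = NULL, fill = 0) {
  stopifnot(inherits(vol, "gm_volume"))
  reference <- grid_of(reference)
  if (is.null(order))
    order <- if (vol$modality == "label") "nearest" else "trilinear"
  order <- match.arg(order, c("trilinear", "nearest"))
  if (vol$modality == "label" && order != "nearest")
    stop("label volumes must be resampled with nearest-neighbour interpolation")
  vox <- world_to_voxel(grid_world_matrix(reference), grid_of(vol))
  vals <- sample_array(vol$data, vox, order = order, fill = fill)
  as_volume(array(vals, reference$shape), reference$spacing, reference$affine,
            modality = vol$modality)
}

#' Warp a volume by a displacement field
#'
#' The output lives on the field's reference grid and satisfies
#' `out(x) = vol(x + u(x))` with the chosen interpolation, where `x` and
#' `u(x)` are world coordinates in mm. This is the resampling convention:
#' the field on a fixed grid pulls intensities back from the moving volume.
#'
#' @inheritParams resample
#' @param field a [`displacement_field`][displacement_field].
#' @return A `gm_volume` on the field's reference grid.
#' @export
warp <- function(vol, field, order = NULL, fill = 0) {
  stopifnot(inherits(vol, "gm_volume"), inherits(field, "gm_field"))
  if (is.null(order))
    order <- if (vol$modality == "label") "nearest" else "trilinear"
  order <- match.arg(order, c("trilinear", "nearest"))
  if (vol$modality == "label" && order != "nearest")
    stop("label volumes must be warped with nearest-neighbour interpolation")
  ref <- field$reference
  w <- grid_world_matrix(ref) + field_vector_matrix(field)
  vox <- world_to_voxel(w, grid_of(vol))
  vals <- sample_array(vol$data, vox, order = order, fill = fill)
  out <- as_volume(array(vals, ref$shape), ref$spacing, ref$affine,
                   modality = vol$modality)
  if (vol$modality == "label") {
    bad <- setdiff(unique(as.vector(out$data)), unique(as.vector(vol$data)))
    if (length(bad) && !all(bad == 0))
      stop("internal error: warped labels outside the input label set")
  }
  out
}
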