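# NIfTI-1 I/O for volumes and displacement fields (via RNifti) and helpers
# for affine text files. Volumes are written in double precision so that
# write -> read round-trips are bit-exact.

rnifti_template <- function(spacing, datatype = 64L) {
  list(pixdim = c(-1, spacing, 0, 0, 0, 0), datatype = datatype)
}

#' Read a 3-D volume from a NIfTI-1 file
#'
#' @param path path to a `.nii` / `.nii.gz` file holding a 3-D image.
#' @param modality modality tag to attach (see [as_volume()]).
#' @return A `gm_volume` with spacing and affine taken from the header and
#'   intensities unchanged.
#' @export
read_volume <- function(path, modality = "T1") {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop("expected 3-D volume, got ", length(dim(img)), "-D image: ", path)
  arr <- array(as.vector(img), dim(img))
  n_bad <- sum(!is.finite(arr))
  if (n_bad > 0L)
    stop(sprintf("volume %s contains %d NaN/non-finite voxel(s)", path, n_bad))
  aff <- unclass(RNifti::xform(img))
  attr(aff, "imagedim") <- NULL
  attr(aff, "code") <- NULL
  as_volume(arr, spacing = RNifti::pixdim(img)[1:3], affine = aff,
            modality = modality)
}

#' Write a volume to a NIfTI-1 file
#'
#' @param vol a `gm_volume`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "gm_volume"))
  img <- RNifti::asNifti(vol$data, rnifti_template(vol$spacing))
  RNifti::`sform<-`(img, structure(vol$affine, code = 2L))
  RNifti::`qform<-`(img, structure(vol$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a displacement field from a 5-D NIfTI-1 file
#'
#' Fields are stored in the de-facto NIfTI dialect for displacement fields:
#' a 5-D image of shape `(nx, ny, nz, 1, 3)` with intent code 1007
#' (vector), components in mm in the world frame of the stored grid.
#'
#' @param path path to the field file.
#' @return A `gm_field`.
#' @export
read_field <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 5L || d[4] != 1L || d[5] != 3L)
    stop("expected a 5-D (nx, ny, nz, 1, 3) displacement field: ", path)
  aff <- unclass(RNifti::xform(img))
  attr(aff, "imagedim") <- NULL
  attr(aff, "code") <- NULL
  ref <- gm_grid(d[1:3], RNifti::pixdim(img)[1:3], aff)
  displacement_field(array(as.vector(img), c(d[1:3], 3L)), ref)
}

#' Write a displacement field to a 5-D NIfTI-1 file
#'
#' @param field a `gm_field`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_field <- function(field, path) {
  stopifnot(inherits(field, "gm_field"))
  ref <- field$reference
  arr <- array(field$vectors, c(ref$shape, 1L, 3L))
  hdr <- rnifti_template(ref$spacing)
  hdr$intent_code <- 1007L
  img <- RNifti::asNifti(arr, hdr)
  RNifti::`sform<-`(img, structure(ref$affine, code = 2L))
  RNifti::`qform<-`(img, structure(ref$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read or write a 4x4 affine transform as whitespace text
#' @param path text file with four rows of four numbers.
#' @return `read_affine`: the 4x4 matrix. `write_affine`: `path`, invisibly.
#' @export
read_affine <- function(path) {
  m <- as.matrix(read.table(path))
  dimnames(m) <- NULL
  if (!all(dim(m) == c(4, 4))) stop("expected a 4x4 matrix in ", path)
  m
}

#' @rdname read_affine
#' @param mat 4x4 matrix.
#' @export
write_affine <- function(mat, path) {
  stopifnot(all(dim(mat) == c(4, 4)))
  utils::write.table(format(mat, digits = 17), path,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read/write a 4-D stack of aligned scalar maps
#'
#' The voxel-wise statistics stage consumes one 3-D map per cohort row,
#' stored as a 4-D NIfTI whose 4th dimension indexes scans in cohort order.
#'
#' @param path NIfTI file path.
#' @return `read_stack`: list with `data` (4-D array) and `grid`.
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L) stop("expected a 4-D stack: ", path)
  aff <- unclass(RNifti::xform(img))
  attr(aff, "imagedim") <- NULL
  attr(aff, "code") <- NULL
  list(data = array(as.vector(img), d),
       grid = gm_grid(d[1:3], RNifti::pixdim(img)[1:3], aff))
}

#' @rdname read_stack
#' @param data 4-D array `(nx, ny, nz, n_scans)`.
#' @param grid `gm_grid` of the first three dimensions.
#' @export
write_stack <- function(data, grid, path) {
  stopifnot(length(dim(data)) == 4L, all(dim(data)[1:3] == grid$shape))
  img <- RNifti::asNifti(data, rnifti_template(grid$spacing))
  RNifti::`sform<-`(img, structure(grid$affine, code = 2L))
  RNifti::`qform<-`(img, structure(grid$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}
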