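# Iterative unbiased average templates per age group. The T1 channel
# drives the registrations; after the last iteration the T2 scans are
# warped through the T1-derived fields and averaged, which guarantees both
# templates live in exactly the same space.

average_volumes <- function(vols, modality) {
  acc <- Reduce(`+`, lapply(vols, `[[`, "data")) / length(vols)
  as_volume(acc, vols[[1]]$spacing, vols[[1]]$affine, modality = modality)
}

#' Build an unbiased average template from a set of scans
#'
#' Each iteration registers every T1 scan to the current average, subtracts
#' the voxel-wise mean of the per-scan deformation fields from each field
#' (the unbiasing step, which drives the average deformation to zero),
#' warps, intensity-normalizes to the current average, and re-averages.
#' After the final iteration the T2 images are warped with the final
#' (unbiased) T1-derived fields and averaged.
#'
#' @param scans list of scans, each a list with elements `t1` and `t2`
#'   (`gm_volume`s). Scans must be affinely pre-aligned to a common
#'   initial space; they are resampled onto the grid of the first scan.
#' @param n_iter number of template iterations (default 4).
#' @param params registration parameters ([syn_params()]); channel weights
#'   are ignored here since only T1 drives the template registrations.
#' @param verbose print progress.
#' @return List with `t1` and `t2` template `gm_volume`s (identical grids),
#'   and `fields`, the final per-scan unbiased fields.
#' @export
build_template <- function(scans, n_iter = 4L, params = syn_params(),
                           verbose = FALSE) {
  if (length(scans) < 2L) stop("template construction needs at least 2 scans")
  if (n_iter < 1L) stop("n_iter must be at least 1")
  ref <- grid_of(scans[[1]]$t1)
  t1s <- lapply(scans, function(s) resample(s$t1, ref))
  t2s <- lapply(scans, function(s) resample(s$t2, ref))
  avg <- average_volumes(t1s, "T1")
  fields <- NULL
  for (it in seq_len(n_iter)) {
    fields <- lapply(t1s, diffeo_register, fixed = avg, params = params)
    mean_vec <- Reduce(`+`, lapply(fields, `[[`, "vectors")) / length(fields)
    fields <- lapply(fields, function(f)
      displacement_field(f$vectors - mean_vec, f$reference))
    warped <- mapply(function(v, f) {
      wv <- warp(v, f)
      normalize_intensity(wv, avg)
    }, t1s, fields, SIMPLIFY = FALSE)
    avg <- average_volumes(warped, "T1")
    if (verbose)
      message(sprintf("template iteration %d: mean residual field %.4g mm",
                      it, max(field_norm(displacement_field(
                        Reduce(`+`, lapply(fields, `[[`, "vectors")) /
                          length(fields), ref)))))
  }
  warped_t2 <- mapply(function(v, f) warp(v, f), t2s, fields,
                      SIMPLIFY = FALSE)
  t2_avg0 <- average_volumes(warped_t2, "T2")
  warped_t2 <- lapply(warped_t2, normalize_intensity, target = t2_avg0)
  t2 <- average_volumes(warped_t2, "T2")
  list(t1 = avg, t2 = t2, fields = fields)
}

#' Register one age template to another
#'
#' Linear (affine) alignment of template `a` onto template `b`, followed by
#' dual-channel diffeomorphic registration. Only the nonlinear field enters
#' the downstream Jacobian analysis; the affine is applied for alignment
#' but returned separately.
#'
#' @param template_a,template_b lists with `t1` and `t2` `gm_volume`s
#'   (moving and fixed respectively; e.g. the 6-month and 12-month
#'   templates).
#' @param params registration parameters for the nonlinear stage.
#' @param similarity affine similarity metric (see [affine_register()]).
#' @return A `gm_field` on `template_b`'s grid (resampling convention, as
#'   [diffeo_register()]), with attribute `affine`, the linear
#'   pre-alignment matrix.
#' @export
register_templates <- function(template_a, template_b,
                               params = syn_params(), similarity = "nmi") {
  ref <- grid_of(template_b$t1)
  A <- affine_register(list(template_a$t1, template_a$t2),
                       list(template_b$t1, template_b$t2),
                       similarity = similarity)
  mv <- list(apply_affine(template_a$t1, A, ref),
             apply_affine(template_a$t2, A, ref))
  u <- diffeo_register(mv, list(template_b$t1, template_b$t2), params)
  attr(u, "affine") <- A
  u
}
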