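# Histogram-based intensity normalization. Each scan's intensity histogram
# is summarised by its decile landmarks (0th, 10th, ..., 100th percentile)
# and mapped to a target histogram by the best (least-squares) linear map
# of the landmark pairs, then clamped to the working range [0, 100].

#' Fit a decile-landmark intensity map
#'
#' Computes the 11 decile landmarks (0th-100th percentile in steps of 10)
#' of source and target over a foreground mask and fits the least-squares
#' linear map of target landmarks on source landmarks.
#'
#' @param source,target `gm_volume`s with comparable anatomy/content.
#' @param mask optional logical array (or `gm_volume` of 0/1) selecting the
#'   voxels whose histograms are matched. Default: `source > 0` and
#'   `target > 0` respectively, so a dominant zero background does not
#'   drive the fit.
#' @return An object of class `gm_decile_map` with fields
#'   `source_deciles`, `target_deciles`, `slope`, `intercept`.
#' @export
fit_decile_map <- function(source, target, mask = NULL) {
  stopifnot(inherits(source, "gm_volume"), inherits(target, "gm_volume"))
  probs <- seq(0, 1, by = 0.1)
  fg <- function(vol) {
    if (!is.null(mask)) {
      m <- if (inherits(mask, "gm_volume")) mask$data != 0 else mask
      vol$data[m]
    } else {
      v <- vol$data[vol$data > 0]
      if (length(v) < 11L) as.vector(vol$data) else v
    }
  }
  src <- quantile(fg(source), probs, names = FALSE, type = 7)
  tgt <- quantile(fg(target), probs, names = FALSE, type = 7)
  if (max(src) - min(src) <= 0)
    stop("source volume is constant within the mask; cannot fit a decile map")
  sxx <- sum((src - mean(src))^2)
  slope <- sum((src - mean(src)) * (tgt - mean(tgt))) / sxx
  if (slope <= 0)
    stop("fitted decile map has non-positive slope; volumes are incompatible")
  intercept <- mean(tgt) - slope * mean(src)
  structure(list(source_deciles = src, target_deciles = tgt,
                 slope = slope, intercept = intercept),
            class = "gm_decile_map")
}

#' @export
print.gm_decile_map <- function(x, ...) {
  cat(sprintf("<gm_decile_map slope %.4g, intercept %.4g>\n",
              x$slope, x$intercept))
  invisible(x)
}

#' Apply a decile map to a volume
#'
#' Intensities become `slope * x + intercept`, clamped to the working
#' normalization range `[0, 100]`.
#'
#' @param vol a `gm_volume`.
#' @param map a `gm_decile_map` from [fit_decile_map()].
#' @param clamp range to clamp to; the standard normalization range by
#'   default.
#' @return The normalized `gm_volume`.
#' @export
apply_decile_map <- function(vol, map, clamp = c(0, 100)) {
  stopifnot(inherits(vol, "gm_volume"), inherits(map, "gm_decile_map"))
  out <- map$slope * vol$data + map$intercept
  out[out < clamp[1]] <- clamp[1]
  out[out > clamp[2]] <- clamp[2]
  as_volume(out, vol$spacing, vol$affine, modality = vol$modality)
}

#' Normalize a scan's intensities to a target volume
#'
#' Convenience wrapper: fit the decile map of `vol` against `target`, then
#' apply it.
#'
#' @inheritParams fit_decile_map
#' @param vol the scan to normalize (also the map's source).
#' @return Normalized `gm_volume`.
#' @export
normalize_intensity <- function(vol, target, mask = NULL) {
  apply_decile_map(vol, fit_decile_map(vol, target, mask))
}
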