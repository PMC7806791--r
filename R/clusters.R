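# Suprathreshold cluster extraction from t-maps and atlas-based labelling:
# connected components of |t| >= threshold, positive and negative signs
# kept separate, reported with size, peak t and (optionally) dominant
# anatomical region and tissue class.

neighbor_offsets <- function(connectivity = 26L) {
  stopifnot(connectivity %in% c(6L, 26L))
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  if (connectivity == 6L) off <- off[rowSums(abs(off)) == 1, , drop = FALSE]
  off
}

# label connected components of a logical 3-D array; 0 = background
label_components <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  off <- neighbor_offsets(connectivity)
  lin_off <- off[, 1] + d[1] * off[, 2] + d[1] * d[2] * off[, 3]
  labels <- array(0L, d)
  seeds <- which(mask)
  next_label <- 0L
  for (s in seq_along(seeds)) {
    v <- seeds[s]
    if (labels[v] != 0L) next
    next_label <- next_label + 1L
    queue <- v
    labels[v] <- next_label
    while (length(queue)) {
      cur <- queue
      queue <- integer(0)
      ci <- arrayInd(cur, d)
      for (k in seq_len(nrow(off))) {
        ni <- ci
        ni[, 1] <- ni[, 1] + off[k, 1]
        ni[, 2] <- ni[, 2] + off[k, 2]
        ni[, 3] <- ni[, 3] + off[k, 3]
        ok <- ni[, 1] >= 1 & ni[, 1] <= d[1] &
          ni[, 2] >= 1 & ni[, 2] <= d[2] &
          ni[, 3] >= 1 & ni[, 3] <= d[3]
        if (!any(ok)) next
        lin <- ni[ok, 1] + d[1] * (ni[ok, 2] - 1L) + d[1] * d[2] * (ni[ok, 3] - 1L)
        new <- lin[mask[lin] & labels[lin] == 0L]
        if (length(new)) {
          labels[new] <- next_label
          queue <- c(queue, new)
        }
      }
      queue <- unique(queue)
    }
  }
  labels
}

#' Extract suprathreshold clusters from a t-map
#'
#' Connected components of `{|t| >= threshold}`, with positive and
#' negative excursions labelled separately so that adjacent blobs of
#' opposite sign never merge. Components smaller than `min_size` are
#' dropped; records are sorted by size, descending. Peak ties break to the
#' lowest linear voxel index.
#'
#' @param tmap a `gm_volume` of t-values (or plain 3-D array).
#' @param threshold positive t-value threshold.
#' @param min_size smallest cluster size kept, in voxels.
#' @param connectivity 26 (default) or 6.
#' @return A data.frame of class `gm_clusters` with columns `cluster_id`,
#'   `size_voxels`, `peak_t`, `peak_x`, `peak_y`, `peak_z` (1-based voxel
#'   indices), `sign`; the member voxel indices of each cluster are kept
#'   in the `members` attribute (list of integer vectors).
#' @export
extract_clusters <- function(tmap, threshold, min_size = 1L,
                             connectivity = 26L) {
  if (threshold <= 0) stop("threshold must be positive")
  tv <- if (inherits(tmap, "gm_volume")) tmap$data else tmap
  stopifnot(length(dim(tv)) == 3L)
  rows <- list()
  members <- list()
  for (sgn in c(1, -1)) {
    mask <- if (sgn > 0) tv >= threshold else tv <= -threshold
    if (!any(mask)) next
    labels <- label_components(mask, connectivity)
    for (lab in seq_len(max(labels))) {
      idx <- which(labels == lab)
      if (length(idx) < min_size) next
      vals <- tv[idx]
      peak_rel <- which(abs(vals) == max(abs(vals)))[1]
      peak_idx <- idx[peak_rel]
      pc <- arrayInd(peak_idx, dim(tv))
      rows[[length(rows) + 1L]] <- data.frame(
        size_voxels = length(idx), peak_t = vals[peak_rel],
        peak_x = pc[1], peak_y = pc[2], peak_z = pc[3],
        sign = if (sgn > 0) "increase" else "decrease")
      members[[length(members) + 1L]] <- idx
    }
  }
  if (!length(rows)) {
    out <- data.frame(cluster_id = integer(0), size_voxels = integer(0),
                      peak_t = numeric(0), peak_x = integer(0),
                      peak_y = integer(0), peak_z = integer(0),
                      sign = character(0))
    attr(out, "members") <- list()
    class(out) <- c("gm_clusters", class(out))
    return(out)
  }
  out <- do.call(rbind, rows)
  ord <- order(-out$size_voxels, -abs(out$peak_t))
  out <- out[ord, , drop = FALSE]
  members <- members[ord]
  out <- cbind(cluster_id = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  attr(out, "members") <- members
  attr(out, "threshold") <- threshold
  class(out) <- c("gm_clusters", class(out))
  out
}

#' Attach atlas region and tissue labels to clusters
#'
#' For each cluster, tabulates the atlas labels of its member voxels and
#' reports the dominant region (all regions with counts are kept in the
#' `region_labels` attribute). When a tissue label volume is supplied
#' (1 = GM, 2 = WM, 0 = other), a cluster is called GM or WM when at least
#' 80% of its voxels share that tissue, otherwise Mixed.
#'
#' @param clusters a `gm_clusters` from [extract_clusters()].
#' @param atlas label `gm_volume` on the same grid as the t-map, with
#'   optional attribute `labels`, a named character vector mapping label
#'   values to region names.
#' @param tissue optional label `gm_volume` (1 = GM, 2 = WM).
#' @return The `gm_clusters` with added `region` (dominant label name) and
#'   `tissue` columns, and a `region_labels` attribute (per-cluster
#'   data.frames of label/voxel-count pairs).
#' @export
label_clusters <- function(clusters, atlas, tissue = NULL) {
  stopifnot(inherits(clusters, "gm_clusters"), inherits(atlas, "gm_volume"))
  if (atlas$modality != "label") stop("atlas must be a label volume")
  members <- attr(clusters, "members")
  lut <- attr(atlas, "labels")
  if (is.null(lut)) lut <- attr(atlas$data, "labels")
  name_of <- function(v) {
    v <- as.character(v)
    if (!is.null(lut) && v %in% names(lut)) unname(lut[v])
    else paste0("label_", v)
  }
  regions <- character(nrow(clusters))
  tissues <- rep(NA_character_, nrow(clusters))
  region_labels <- vector("list", nrow(clusters))
  for (i in seq_len(nrow(clusters))) {
    idx <- members[[i]]
    tab <- sort(table(atlas$data[idx]), decreasing = TRUE)
    region_labels[[i]] <- data.frame(
      label = vapply(names(tab), name_of, character(1)),
      voxels = as.integer(tab), row.names = NULL)
    regions[i] <- region_labels[[i]]$label[1]
    if (!is.null(tissue)) {
      if (!grids_equal(grid_of(tissue), grid_of(atlas)))
        stop("tissue volume grid does not match the atlas grid")
      tt <- tissue$data[idx]
      f_gm <- mean(tt == 1)
      f_wm <- mean(tt == 2)
      tissues[i] <- if (f_gm >= 0.8) "GM" else if (f_wm >= 0.8) "WM"
      else "Mixed"
    }
  }
  clusters$region <- regions
  if (!is.null(tissue)) clusters$tissue <- tissues
  attr(clusters, "region_labels") <- region_labels
  clusters
}

#' Write a cluster report CSV
#'
#' Columns `cluster_id,size_voxels,peak_t,peak_x,peak_y,peak_z,sign` plus
#' `region`/`tissue` when present, and a `significance` star column when
#' the t-value thresholds for FDR 0.10 / 0.05 / 0.01 are supplied
#' (`*`, `**`, `***` respectively).
#'
#' @param clusters a `gm_clusters`.
#' @param path output CSV path.
#' @param fdr_thresholds optional named numeric vector with elements
#'   `"0.1"`, `"0.05"`, `"0.01"` giving the t-thresholds at each rate.
#' @return `path`, invisibly.
#' @export
write_cluster_table <- function(clusters, path, fdr_thresholds = NULL) {
  df <- as.data.frame(clusters)
  if (!is.null(fdr_thresholds)) {
    stars <- vapply(df$peak_t, function(t) {
      a <- abs(t)
      if (!is.null(fdr_thresholds[["0.01"]]) && a >= fdr_thresholds[["0.01"]]) "***"
      else if (!is.null(fdr_thresholds[["0.05"]]) && a >= fdr_thresholds[["0.05"]]) "**"
      else if (!is.null(fdr_thresholds[["0.1"]]) && a >= fdr_thresholds[["0.1"]]) "*"
      else ""
    }, character(1))
    df$significance <- stars
  }
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
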