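# Image registration. Two layers:
#   * affine_register(): 3-stage (translation -> rigid+scale -> full
#     affine) multi-resolution optimisation of NMI (default) or MSE.
#   * diffeo_register(): greedy diffeomorphic registration driven by the
#     gradient of the local (windowed) cross-correlation, summed over one
#     or two image channels, with Gaussian regularisation of the update
#     and total fields and a multi-resolution shrink/smooth schedule.
# The squared local correlation A^2/(B C) drives the update force, so
# edges attract regardless of contrast polarity -- needed when T1/T2
# contrast inverts across age. Registration is fully deterministic.

#' Diffeomorphic registration parameters
#'
#' Defaults follow the standard SyN-style parameterisation for dual-channel
#' infant templates: gradient step 0.25, update/total field smoothing 2.0 /
#' 0.3 voxels, equal T1/T2 channel weights, shrink factors 16/8/4/2/1 with
#' smoothing sigmas 9.44/7.08/4.72/2.36/0 mm. Iteration counts
#' (40/30/20/10/5) and the correlation window radius (2 voxels) are this
#' package's own defaults. Pyramid levels whose shrunken grid would drop
#' below 5 voxels on any axis are skipped automatically.
#'
#' @param gradient_step maximum update magnitude per iteration, in voxels.
#' @param update_sigma_vox Gaussian sigma (voxels) applied to each update
#'   field.
#' @param total_sigma_vox Gaussian sigma (voxels) applied to the
#'   accumulated field after each update.
#' @param channel_weights non-negative weights for the (T1, T2) channels;
#'   must sum to 1.
#' @param shrink_factors positive, non-increasing integer downsampling
#'   factors, one per pyramid level.
#' @param smoothing_sigmas_mm pre-smoothing at each level, in mm (same
#'   length as `shrink_factors`).
#' @param iterations_per_level greedy iterations at each level.
#' @param cc_radius_vox cross-correlation window radius (window edge
#'   `2r + 1` voxels).
#' @return An object of class `gm_reg_params`.
#' @export
syn_params <- function(gradient_step = 0.25,
                       update_sigma_vox = 2.0,
                       total_sigma_vox = 0.3,
                       channel_weights = c(0.5, 0.5),
                       shrink_factors = c(16L, 8L, 4L, 2L, 1L),
                       smoothing_sigmas_mm = c(9.44, 7.08, 4.72, 2.36, 0),
                       iterations_per_level = c(40L, 30L, 20L, 10L, 5L),
                       cc_radius_vox = 2L) {
  if (length(shrink_factors) != length(smoothing_sigmas_mm))
    stop("shrink_factors and smoothing_sigmas_mm must have the same length")
  if (length(iterations_per_level) != length(shrink_factors))
    stop("iterations_per_level must match shrink_factors in length")
  if (any(shrink_factors <= 0) || any(diff(shrink_factors) > 0))
    stop("shrink factors must be positive and non-increasing")
  if (any(channel_weights < 0) ||
      abs(sum(channel_weights) - 1) > 1e-8)
    stop("channel weights must be non-negative and sum to 1")
  if (gradient_step <= 0) stop("gradient_step must be positive")
  structure(list(gradient_step = gradient_step,
                 update_sigma_vox = update_sigma_vox,
                 total_sigma_vox = total_sigma_vox,
                 channel_weights = channel_weights,
                 shrink_factors = as.integer(shrink_factors),
                 smoothing_sigmas_mm = smoothing_sigmas_mm,
                 iterations_per_level = as.integer(iterations_per_level),
                 cc_radius_vox = as.integer(cc_radius_vox)),
            class = "gm_reg_params")
}

as_channel_list <- function(x) {
  if (inherits(x, "gm_volume")) return(list(x))
  stopifnot(is.list(x), all(vapply(x, inherits, logical(1), "gm_volume")))
  x
}

#' Local (windowed) normalized cross-correlation map
#'
#' Per-voxel Pearson correlation of the two images over a cubic
#' `(2 radius + 1)^3` window (truncated at the image boundary). Windows in
#' which either image has zero variance yield 0.
#'
#' @param a,b `gm_volume`s on the same grid.
#' @param radius window radius in voxels.
#' @return A `gm_volume` (modality `"stat"`) with values in `[-1, 1]`.
#' @export
local_cross_correlation <- function(a, b, radius = 2L) {
  stopifnot(inherits(a, "gm_volume"), inherits(b, "gm_volume"))
  if (!grids_equal(grid_of(a), grid_of(b)))
    stop("volumes must share a grid")
  st <- cc_window_stats(a$data, b$data, radius)
  cc <- array(0, dim(a$data))
  ok <- st$B > st$eps & st$C > st$eps
  cc[ok] <- st$A[ok] / sqrt(st$B[ok] * st$C[ok])
  cc[cc > 1] <- 1
  cc[cc < -1] <- -1
  as_volume(cc, a$spacing, a$affine, modality = "stat")
}

# windowed centred moments shared by the CC map and the CC force
cc_window_stats <- function(I, J, radius) {
  N <- window_count_array(dim(I), radius)
  Ibar <- box_sum_array(I, radius) / N
  Jbar <- box_sum_array(J, radius) / N
  A <- box_sum_array(I * J, radius) - N * Ibar * Jbar
  B <- box_sum_array(I * I, radius) - N * Ibar * Ibar
  C <- box_sum_array(J * J, radius) - N * Jbar * Jbar
  B[B < 0] <- 0
  C[C < 0] <- 0
  scale2 <- max(max(B), max(C), .Machine$double.eps)
  list(N = N, Ibar = Ibar, Jbar = Jbar, A = A, B = B, C = C,
       eps = 1e-10 * scale2)
}

# Gradient force of the squared local correlation A^2/(BC) with respect to
# the warped image I, times the spatial gradient of I (world frame).
# Returns list(force = N x 3 matrix, cc2 = mean squared correlation).
# Windows whose variance is a negligible fraction of the image's maximum
# window variance carry no anatomy (residual noise is locally smooth and
# correlates spuriously), so they contribute neither force nor energy.
cc_force <- function(I, J, radius, invA3, var_gate = 1e-3) {
  st <- cc_window_stats(I, J, radius)
  ok <- st$B > var_gate * max(st$B) & st$C > var_gate * max(st$C)
  sc <- array(0, dim(I))
  sc[ok] <- (2 * st$A[ok] / (st$B[ok] * st$C[ok])) *
    ((J[ok] - st$Jbar[ok]) - (st$A[ok] / st$B[ok]) * (I[ok] - st$Ibar[ok]))
  gv <- lapply(1:3, function(m) axis_gradient(I, m))
  force <- matrix(0, length(I), 3L)
  for (l in 1:3) {
    gw <- gv[[1]] * invA3[1, l] + gv[[2]] * invA3[2, l] + gv[[3]] * invA3[3, l]
    force[, l] <- as.vector(sc * gw)
  }
  cc2 <- st$A[ok]^2 / (st$B[ok] * st$C[ok])
  list(force = force, cc2 = if (length(cc2)) mean(cc2) else 0)
}

shrink_grid <- function(grid, factor) {
  if (factor == 1L) return(grid)
  shape <- pmax(as.integer(ceiling(grid$shape / factor)), 1L)
  aff <- grid$affine
  aff[1:3, 1:3] <- aff[1:3, 1:3] * factor
  gm_grid(shape, grid$spacing * factor, aff)
}

shrink_volume <- function(vol, factor, sigma_mm) {
  v <- if (any(sigma_mm > 0)) smooth_volume(vol, sigma_mm) else vol
  if (factor == 1L) return(v)
  resample(v, shrink_grid(grid_of(vol), factor))
}

#' Dual-channel diffeomorphic registration
#'
#' Greedy multi-resolution registration of `moving` onto `fixed`. Both are
#' single volumes or lists of channel volumes (e.g. `list(t1, t2)`); the
#' channel-weighted squared local cross-correlation drives the update. The
#' returned field `u` lives on the fixed grid in resampling convention:
#' `warp(moving, u)` reproduces `fixed`, i.e. `x -> x + u(x)` maps
#' fixed-space points to moving-space sample points. Every accepted update
#' keeps the Jacobian determinant of the induced map strictly positive
#' (updates are halved on violation, and registration aborts if positivity
#' cannot be restored).
#'
#' @param moving,fixed `gm_volume` or list of channel `gm_volume`s; all
#'   channels of one side must share a grid, and the two sides must be
#'   affinely pre-aligned (see [affine_register()]).
#' @param params a [`syn_params()`] object.
#' @param verbose print per-level energy summaries.
#' @return A `gm_field` on the fixed grid with attributes `energy` (list of
#'   per-level `1 - weighted mean CC^2` traces) and `min_jacobian`.
#' @export
diffeo_register <- function(moving, fixed, params = syn_params(),
                            verbose = FALSE) {
  stopifnot(inherits(params, "gm_reg_params"))
  moving <- as_channel_list(moving)
  fixed <- as_channel_list(fixed)
  if (length(moving) != length(fixed))
    stop("moving and fixed must have the same number of channels")
  nch <- length(moving)
  w <- params$channel_weights
  if (nch == 1L) w <- 1
  if (length(w) < nch) stop("channel_weights shorter than channel count")
  w <- w[seq_len(nch)] / sum(w[seq_len(nch)])
  for (ch in seq_len(nch)) {
    if (sd(fixed[[ch]]$data) == 0 || sd(moving[[ch]]$data) == 0)
      stop("degenerate (constant) image in channel ", ch)
  }
  fixed_grid <- grid_of(fixed[[1]])
  levels <- which(vapply(params$shrink_factors, function(s)
    min(ceiling(fixed_grid$shape / s)) >= 5L, logical(1)))
  if (!length(levels)) levels <- length(params$shrink_factors)
  u <- NULL
  energy <- list()
  for (li in levels) {
    s <- params$shrink_factors[li]
    sig <- rep_len(params$smoothing_sigmas_mm[li], 3L)
    g <- shrink_grid(fixed_grid, s)
    fx <- lapply(fixed, shrink_volume, factor = s, sigma_mm = sig)
    mv <- lapply(moving, shrink_volume, factor = s, sigma_mm = sig)
    u <- if (is.null(u)) zero_field(g) else resample_field(u, g)
    # interpolation at the level change can nick the positivity margin;
    # restore it by progressive smoothing before iterating
    sm <- 0.5
    while (min(jacobian_determinant(u)$data) <= 0 && sm <= 4) {
      u <- gauss_smooth_field(u, rep_len(sm, 3L))
      sm <- sm * 2
    }
    invA3 <- solve(g$affine[1:3, 1:3])
    step_mm <- params$gradient_step * min(g$spacing)
    # forces and energy share one evaluation of the warped channels
    state_of <- function(uu) {
      force <- matrix(0, prod(g$shape), 3L)
      cc2 <- 0
      for (ch in seq_len(nch)) {
        Iw <- warp(mv[[ch]], uu)$data
        fc <- cc_force(Iw, fx[[ch]]$data, params$cc_radius_vox, invA3)
        force <- force + w[ch] * fc$force
        cc2 <- cc2 + w[ch] * fc$cc2
      }
      list(force = force, energy = 1 - cc2)
    }
    st <- state_of(u)
    trace <- st$energy
    for (it in seq_len(params$iterations_per_level[li])) {
      if (max(abs(st$force)) == 0) break
      delta <- displacement_field(array(st$force, c(g$shape, 3L)), g)
      delta <- gauss_smooth_field(delta, rep_len(params$update_sigma_vox, 3L))
      # normalise after smoothing so the largest update is gradient_step vox
      fmax <- max(field_norm(delta))
      if (fmax == 0) break
      delta$vectors <- delta$vectors * (step_mm / fmax)
      # accept the largest halved step that keeps the map diffeomorphic
      # and decreases the energy: descent is monotone by construction
      accepted <- FALSE
      for (halving in 0:5) {
        u_try <- displacement_field(u$vectors + delta$vectors, g)
        u_try <- gauss_smooth_field(u_try, rep_len(params$total_sigma_vox, 3L))
        if (min(jacobian_determinant(u_try)$data) > 0) {
          st_try <- state_of(u_try)
          if (st_try$energy < st$energy) {
            u <- u_try
            st <- st_try
            accepted <- TRUE
            break
          }
        }
        delta$vectors <- delta$vectors / 2
      }
      if (!accepted) break  # no admissible descent step: level converged
      trace <- c(trace, st$energy)
    }
    energy[[length(energy) + 1L]] <- trace
    if (verbose)
      message(sprintf("level %d (shrink %d): energy %.4f -> %.4f",
                      li, s, trace[1], trace[length(trace)]))
  }
  if (!grids_equal(u$reference, fixed_grid))
    u <- resample_field(u, fixed_grid)
  attr(u, "energy") <- energy
  attr(u, "min_jacobian") <- min(jacobian_determinant(u)$data)
  u
}

# ---------------------------------------------------------------------------
# Affine pre-alignment

rotation_matrix <- function(theta) {
  cx <- cos(theta[1]); sx <- sin(theta[1])
  cy <- cos(theta[2]); sy <- sin(theta[2])
  cz <- cos(theta[3]); sz <- sin(theta[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
  Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
  Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
  Rz %*% Ry %*% Rx
}

# similarity metrics on paired intensity vectors (lower is better)
metric_mse <- function(a, b) mean((a - b)^2)

metric_nmi <- function(a, b, bins = 32L) {
  ra <- range(a); rb <- range(b)
  if (diff(ra) == 0 || diff(rb) == 0) return(0)
  ia <- pmin.int(1L + floor((a - ra[1]) / diff(ra) * bins), bins)
  ib <- pmin.int(1L + floor((b - rb[1]) / diff(rb) * bins), bins)
  joint <- tabulate(ia + bins * (ib - 1L), bins * bins) / length(a)
  pa <- tabulate(ia, bins) / length(a)
  pb <- tabulate(ib, bins) / length(b)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  hj <- ent(joint)
  if (hj == 0) return(-2)
  -(ent(pa) + ent(pb)) / hj
}

#' Affine registration of (dual-channel) volumes
#'
#' Three-stage multi-resolution optimisation: translation, then rigid plus
#' isotropic scale, then the full affine, each refined over a coarse-to-
#' fine grid schedule with Nelder-Mead. The similarity (normalized mutual
#' information by default, mean squared error optionally) is averaged over
#' channels. Rotations and scaling are parameterised about the world
#' centre of the fixed grid.
#'
#' @param moving,fixed `gm_volume` or list of channel volumes.
#' @param similarity `"nmi"` or `"mse"`.
#' @param shrinks resolution schedule (downsampling factors) used inside
#'   every stage.
#' @param maxit Nelder-Mead iteration cap per stage and level.
#' @return A 4x4 world-to-world matrix `A` mapping fixed-space points to
#'   moving-space points (so `apply_affine(moving, A, fixed)` aligns the
#'   moving image with the fixed one), with attribute `similarity`, the
#'   final metric value.
#' @export
affine_register <- function(moving, fixed, similarity = c("nmi", "mse"),
                            shrinks = c(4L, 2L), maxit = 400L) {
  similarity <- match.arg(similarity)
  metric <- if (similarity == "nmi") metric_nmi else metric_mse
  moving <- as_channel_list(moving)
  fixed <- as_channel_list(fixed)
  nch <- length(moving)
  for (ch in seq_len(nch))
    if (sd(fixed[[ch]]$data) == 0 || sd(moving[[ch]]$data) == 0)
      stop("degenerate (constant) image in channel ", ch)
  fixed_grid <- grid_of(fixed[[1]])
  ctr <- as.vector(fixed_grid$affine %*%
                     c((fixed_grid$shape - 1) / 2, 1))[1:3]
  build_A <- function(M, t) {
    A <- diag(4)
    A[1:3, 1:3] <- M
    A[1:3, 4] <- ctr - M %*% ctr + t
    A
  }
  cost_fn <- function(A, fx_pts, fx_vals, mv) {
    w <- fx_pts %*% t(A[1:3, 1:3])
    w[, 1] <- w[, 1] + A[1, 4]; w[, 2] <- w[, 2] + A[2, 4]
    w[, 3] <- w[, 3] + A[3, 4]
    tot <- 0
    for (ch in seq_len(nch)) {
      vox <- world_to_voxel(w, grid_of(mv[[ch]]))
      vals <- sample_array(mv[[ch]]$data, vox)
      tot <- tot + metric(vals, fx_vals[[ch]])
    }
    tot / nch
  }
  # stage parameterisations: params -> (M, t)
  stages <- list(
    translation = list(
      n = 3L, scale = rep(1, 3),
      make = function(p, M0, t0) list(M = M0, t = t0 + p)),
    rigid_scale = list(
      n = 7L, scale = c(rep(1, 3), rep(0.1, 3), 0.1),
      make = function(p, M0, t0)
        list(M = (exp(p[7]) * rotation_matrix(p[4:6])) %*% M0, t = t0 + p[1:3])),
    affine = list(
      n = 12L, scale = c(rep(1, 3), rep(0.05, 9)),
      make = function(p, M0, t0)
        list(M = (diag(3) + matrix(p[4:12], 3, 3)) %*% M0, t = t0 + p[1:3]))
  )
  M0 <- diag(3); t0 <- c(0, 0, 0)
  val <- NA_real_
  for (stage in stages) {
    for (s in shrinks) {
      g <- shrink_grid(fixed_grid, s)
      fx <- lapply(fixed, shrink_volume, factor = s,
                   sigma_mm = 0.5 * g$spacing)
      mv <- lapply(moving, shrink_volume, factor = 1L,
                   sigma_mm = 0.5 * g$spacing)
      fx_pts <- grid_world_matrix(g)
      fx_vals <- lapply(fx, function(v) as.vector(v$data))
      obj <- function(p) {
        mt <- stage$make(p, M0, t0)
        cost_fn(build_A(mt$M, mt$t), fx_pts, fx_vals, mv)
      }
      # restarted Nelder-Mead: each restart rebuilds the simplex around
      # the incumbent, escaping premature contraction
      best_p <- rep(0, stage$n)
      best_v <- obj(best_p)
      p_cur <- best_p
      for (restart in 1:3) {
        opt <- optim(p_cur, obj, method = "Nelder-Mead",
                     control = list(maxit = maxit, reltol = 1e-10,
                                    parscale = stage$scale))
        p_cur <- opt$par
        if (opt$value < best_v - 1e-9) {
          best_v <- opt$value
          best_p <- opt$par
        } else break
      }
      if (best_v <= obj(rep(0, stage$n))) {
        mt <- stage$make(best_p, M0, t0)
        M0 <- mt$M; t0 <- mt$t
        val <- best_v
      }
    }
  }
  A <- build_A(M0, t0)
  if (abs(det(A[1:3, 1:3])) < 1e-6)
    stop("affine registration produced a singular transform")
  structure(A, similarity = val)
}

#' Apply an affine transform by resampling
#'
#' Samples `vol` at `A %*% x` for every world point `x` of the reference
#' grid, i.e. `A` is the fixed-to-moving (resampling) map returned by
#' [affine_register()].
#'
#' @param vol a `gm_volume`.
#' @param A 4x4 world-to-world matrix.
#' @param reference output grid (or grid-bearing object).
#' @inheritParams resample
#' @return A `gm_volume` on the reference grid.
#' @export
apply_affine <- function(vol, A, reference, order = NULL, fill = 0) {
  reference <- grid_of(reference)
  if (is.null(order))
    order <- if (vol$modality == "label") "nearest" else "trilinear"
  w <- grid_world_matrix(reference)
  w2 <- w %*% t(A[1:3, 1:3])
  w2[, 1] <- w2[, 1] + A[1, 4]; w2[, 2] <- w2[, 2] + A[2, 4]
  w2[, 3] <- w2[, 3] + A[3, 4]
  vox <- world_to_voxel(w2, grid_of(vol))
  vals <- sample_array(vol$data, vox, order = order, fill = fill)
  as_volume(array(vals, reference$shape), reference$spacing,
            reference$affine, modality = vol$modality)
}
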