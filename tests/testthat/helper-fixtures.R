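# Shared fixture builders and independent oracles. Oracles are deliberately
# naive (loops, closed forms, exhaustive enumeration) and never call the
# code paths they check.

ramp_volume <- function(shape = c(9L, 9L, 9L), axis = 1L,
                        spacing = c(1, 1, 1), slope = 1) {
  idx <- slice.index(array(0, shape), axis) - 1L
  as_volume(array(slope * idx, shape), spacing = spacing)
}

noise_volume <- function(shape = c(8L, 8L, 8L), seed = 1L,
                         spacing = c(1, 1, 1)) {
  set.seed(seed)
  as_volume(array(rnorm(prod(shape)), shape), spacing = spacing)
}

# smooth, compactly supported vector field on a cubic grid; max |u| about
# 1.75 voxels at the default amplitudes, diffeomorphic by construction
compact_bump_field <- function(n = 24L, amps = c(1.3, -1.0, 0.7),
                               sigma2 = 40, support_r = 10) {
  g <- gm_grid(c(n, n, n))
  w <- gm_world(g)
  ctr <- (n - 1) / 2
  r2 <- (w[, 1] - ctr)^2 + (w[, 2] - ctr)^2 + (w[, 3] - ctr)^2
  taper <- pmax(0, 1 - (sqrt(r2) / support_r)^4)
  bump <- exp(-r2 / sigma2) * taper
  displacement_field(array(c(amps[1] * bump, amps[2] * bump, amps[3] * bump),
                           c(n, n, n, 3L)), g)
}

gm_world <- function(grid) {
  n <- grid$shape
  idx <- cbind(rep.int(seq_len(n[1]) - 1, n[2] * n[3]),
               rep.int(rep(seq_len(n[2]) - 1, each = n[1]), n[3]),
               rep(seq_len(n[3]) - 1, each = n[1] * n[2]))
  w <- idx %*% t(grid$affine[1:3, 1:3])
  sweep(w, 2, grid$affine[1:3, 4], "+")
}

field_norm_arr <- function(field) {
  v <- field$vectors
  sqrt(v[, , , 1]^2 + v[, , , 2]^2 + v[, , , 3]^2)
}

# windowed Pearson correlation at a single voxel, by direct subsetting
brute_local_cc <- function(a, b, radius, at) {
  d <- dim(a)
  lo <- pmax(at - radius, 1L)
  hi <- pmin(at + radius, d)
  av <- as.vector(a[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]])
  bv <- as.vector(b[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]])
  if (sd(av) == 0 || sd(bv) == 0) return(0)
  suppressWarnings(cor(av, bv))
}

# Benjamini-Hochberg by exhaustive check of every k
brute_bh <- function(p, q) {
  m <- length(p)
  o <- sort(p)
  kmax <- 0L
  for (k in seq_len(m)) if (o[k] <= q * k / m) kmax <- k
  if (kmax == 0L) return(list(p_threshold = 0, reject = rep(FALSE, m)))
  list(p_threshold = o[kmax], reject = p <= o[kmax])
}

# direct evaluation of the marginal Gaussian log-likelihood of the
# two-crossed-random-intercepts model at given parameter values
marginal_loglik <- function(y, X, beta, subject, site,
                            s2_subject, s2_site, s2_resid) {
  n <- length(y)
  Zs <- outer(subject, unique(subject), "==") * 1
  Zt <- outer(site, unique(site), "==") * 1
  V <- s2_subject * tcrossprod(Zs) + s2_site * tcrossprod(Zt) +
    s2_resid * diag(n)
  r <- y - as.vector(X %*% beta)
  ch <- chol(V)
  -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(ch))) +
            sum(backsolve(ch, r, transpose = TRUE)^2))
}

# Jacobian-determinant oracle: same finite-difference stencils, written as
# an independent per-voxel loop over a list of sampled voxels
brute_jacobian_at <- function(field, at) {
  v <- field$vectors
  d <- dim(v)[1:3]
  sp_inv <- solve(field$reference$affine[1:3, 1:3])
  g1 <- function(arr, i, ax) {
    ii <- as.list(i)
    n <- d[ax]
    if (i[ax] == 1L) {
      a <- i; a[ax] <- 2L
      arr[a[1], a[2], a[3]] - arr[i[1], i[2], i[3]]
    } else if (i[ax] == n) {
      a <- i; a[ax] <- n - 1L
      arr[i[1], i[2], i[3]] - arr[a[1], a[2], a[3]]
    } else {
      a <- i; a[ax] <- i[ax] + 1L
      b <- i; b[ax] <- i[ax] - 1L
      (arr[a[1], a[2], a[3]] - arr[b[1], b[2], b[3]]) / 2
    }
  }
  Dvox <- matrix(0, 3, 3)
  for (k in 1:3) for (m in 1:3) Dvox[k, m] <- g1(v[, , , k], at, m)
  det(diag(3) + Dvox %*% sp_inv)
}

# cohort layouts used across statistical tests
small_cohort <- function(n_per_group = c(`HR+` = 8L, `HR-` = 16L, `LR-` = 12L),
                         seed = 1L, dropout = 0) {
  simulate_cohort(sim_config(n_subjects = n_per_group, dropout = dropout),
                  seed = seed)
}

# t5 / FDR study conditions: 8^3 grid, two opposite-sign spheres, ~10.5%
# signal voxels, default scaled-down cohort design
fdr_sim_config <- function() {
  sim_config(grid_shape = c(8L, 8L, 8L),
             signal_regions = list(
               list(center = c(3, 3, 3), radius = 1.8, sign = 1),
               list(center = c(6, 6, 6), radius = 1.8, sign = -1)))
}

# one FDR replicate: simulate, fit voxel-wise, threshold, return the false
# discovery proportion over the pooled model-term maps and the sensitivity
# of the HR+ growth-rate interaction
fdr_replicate <- function(cfg, seed, q = 0.05) {
  co <- simulate_cohort(cfg, seed = seed)
  sim <- simulate_logjac_stack(co, cfg, seed = seed + 100000L)
  vs <- fit_voxelwise(sim$stack, co, model_spec(), grid = sim$grid)
  fdr <- pooled_fdr_threshold(vs, q)
  sigv <- as.vector(sim$truth$signal)
  nv <- length(sigv)
  fp <- 0L; tot <- 0L
  for (nm in setdiff(names(vs$tmaps), vs$derived_maps)) {
    rej <- as.vector(fdr$masks[[nm]])
    isnull <- if (grepl("HR[+]", nm)) sigv == 0
    else if (grepl("HR-", nm)) rep(TRUE, nv)
    else rep(FALSE, nv)
    fp <- fp + sum(rej & isnull)
    tot <- tot + sum(rej)
  }
  sens <- mean(abs(vs$tmaps[["age_c:groupHR+"]]$data[sigv != 0]) >=
                 fdr$t_thresholds[[1]])
  c(fdp = if (tot > 0) fp / tot else 0, sens = sens)
}
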