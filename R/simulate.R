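# Synthetic cohorts, log-Jacobian stacks and growth phantoms. The
# generator reproduces the statistical structure the analysis assumes:
# three visit waves near 6.7 / 12.8 / 25.0 months, three groups with
# group-specific growth trajectories confined to localized signal regions
# of either sign, subject- and site-level random intercepts, a sex effect,
# and (for the imaging phantoms) T1/T2 contrast that inverts across age at
# channel-specific rates.

DAYS_PER_MONTH <- 30.44

#' Simulation configuration
#'
#' Defaults are the package's study conditions: group sizes 20/60/40
#' (HR+/HR-/LR-, mirroring the strong imbalance of large infant-sibling
#' cohorts), visit age means 6.7/12.8/25.0 months with SDs 0.7/0.7/0.9,
#' per-visit dropout 0.28 (three complete visits for ~37% of subjects),
#' sex ratios 85.6/58.3/59.3 percent male, four sites, and a quadratic
#' log-Jacobian growth trajectory (in years since 6 months)
#' `-0.30 + 0.55 t - 0.15 t^2` with an HR+ growth-rate offset of
#' 0.06 / year inside the signal regions. Group effects exist only inside
#' `signal_regions` (two opposite-sign spheres covering ~10% of the
#' default 10^3 grid); elsewhere group and group-by-age effects are zero.
#'
#' @param n_subjects named integer vector of subjects per group.
#' @param visit_mean_months,visit_sd_months per-visit age distributions.
#' @param dropout probability that any given visit is missed (patterns
#'   with zero remaining visits are redrawn).
#' @param n_sites number of acquisition sites (random intercepts).
#' @param sex_pct_male named percent-male per group.
#' @param beta0,beta_age,beta_age2 fixed growth-trajectory coefficients
#'   (age in years since `age_center_days`).
#' @param beta_group,beta_group_age named (HR-, HR+) group offsets at the
#'   centred age and group-by-age slope offsets, applied inside signal
#'   regions multiplied by the region sign.
#' @param beta_sex additive male-sex effect.
#' @param sigma_subject,sigma_site,sigma_resid random-intercept and
#'   residual SDs.
#' @param grid_shape,grid_spacing voxel grid of the simulated maps.
#' @param signal_regions list of `list(center, radius, sign)` spheres in
#'   1-based voxel coordinates.
#' @param age_center_days centre used by the generating model (matches
#'   [model_spec()]).
#' @return An object of class `gm_sim_config`.
#' @export
sim_config <- function(n_subjects = c(`HR+` = 20L, `HR-` = 60L, `LR-` = 40L),
                       visit_mean_months = c(V06 = 6.7, V12 = 12.8, V24 = 25.0),
                       visit_sd_months = c(V06 = 0.7, V12 = 0.7, V24 = 0.9),
                       dropout = 0.28,
                       n_sites = 4L,
                       sex_pct_male = c(`HR+` = 85.6, `HR-` = 58.3,
                                        `LR-` = 59.3),
                       beta0 = -0.30,
                       beta_age = 0.55,
                       beta_age2 = -0.15,
                       beta_group = c(`HR-` = 0, `HR+` = 0),
                       beta_group_age = c(`HR-` = 0, `HR+` = 0.06),
                       beta_sex = 0.02,
                       sigma_subject = 0.05,
                       sigma_site = 0.02,
                       sigma_resid = 0.04,
                       grid_shape = c(10L, 10L, 10L),
                       grid_spacing = c(2, 2, 2),
                       signal_regions = list(
                         list(center = c(3.5, 3.5, 3.5), radius = 2.3,
                              sign = 1),
                         list(center = c(7.5, 7.5, 7.5), radius = 2.3,
                              sign = -1)),
                       age_center_days = 183) {
  stopifnot(length(n_subjects) == 3L,
            all(sort(names(n_subjects)) == sort(GROUP_LEVELS)))
  if (any(c(visit_sd_months, sigma_subject, sigma_site, sigma_resid) < 0))
    stop("SDs and variance parameters must be non-negative")
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  structure(as.list(environment()), class = "gm_sim_config")
}

#' Simulate a longitudinal cohort table
#'
#' Subjects are assigned to groups, sites (round-robin) and sex (Bernoulli
#' with the per-group male percentage); visit ages are drawn
#' Normal(mean, SD) per wave and visits are dropped independently with the
#' configured probability (subjects losing all visits are redrawn).
#' Deterministic given `seed`.
#'
#' @param config a [sim_config()].
#' @param seed integer seed (mandatory: all generators are reproducible).
#' @return A `gm_cohort` data.frame.
#' @export
simulate_cohort <- function(config = sim_config(), seed) {
  stopifnot(inherits(config, "gm_sim_config"))
  if (missing(seed)) stop("seed is mandatory")
  n_tot <- sum(config$n_subjects)
  if (n_tot < 1L) stop("need at least one subject")
  set.seed(seed)
  grp <- rep(GROUP_LEVELS, config$n_subjects[GROUP_LEVELS])
  sid <- seq_len(n_tot)
  subject <- sprintf("S%05d", sid)
  site <- sprintf("site%d", 1L + (sid - 1L) %% config$n_sites)
  sex <- ifelse(runif(n_tot) < config$sex_pct_male[grp] / 100, "M", "F")
  keep <- matrix(runif(3L * n_tot) >= config$dropout, n_tot, 3L)
  # subjects must contribute at least one scan: redraw empty patterns
  repeat {
    empty <- which(rowSums(keep) == 0L)
    if (!length(empty)) break
    keep[empty, ] <- runif(3L * length(empty)) >= config$dropout
  }
  ages <- matrix(rnorm(3L * n_tot,
                       rep(config$visit_mean_months, each = n_tot),
                       rep(config$visit_sd_months, each = n_tot)),
                 n_tot, 3L)
  idx <- which(keep, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  s <- idx[, 1]; v <- idx[, 2]
  as_cohort(data.frame(
    subject_id = subject[s], group = grp[s], sex = sex[s], site = site[s],
    visit = VISIT_LEVELS[v],
    age_days = pmax(1L, as.integer(round(ages[cbind(s, v)] * DAYS_PER_MONTH)))))
}

signal_mask <- function(config) {
  shp <- config$grid_shape
  m <- array(0, shp)
  ix <- grid_index_matrix(gm_grid(shp)) + 1
  for (reg in config$signal_regions) {
    d2 <- (ix[, 1] - reg$center[1])^2 + (ix[, 2] - reg$center[2])^2 +
      (ix[, 3] - reg$center[3])^2
    inside <- d2 <= reg$radius^2
    if (!any(inside)) stop("signal region lies outside the grid")
    m[inside] <- reg$sign
  }
  m
}

#' Simulate a log-Jacobian stack from the generating growth model
#'
#' Every scan's voxel values follow the mixed-effects growth model:
#' fixed quadratic age trajectory plus sex effect everywhere; group and
#' group-by-age effects only inside the configured signal regions (scaled
#' by the region sign); subject and site intercepts drawn once per
#' subject/site; independent Gaussian residuals per voxel and scan.
#'
#' @param cohort a `gm_cohort` (typically from [simulate_cohort()]).
#' @param config the [sim_config()] used to generate it.
#' @param seed integer seed.
#' @return List with `stack` (4-D array, one volume per cohort row),
#'   `grid`, `truth` (list: `signal` signed region array, `beta_group` and
#'   `beta_group_age` true per-voxel coefficient arrays per non-reference
#'   group), and `frame`, the generating covariate frame.
#' @export
simulate_logjac_stack <- function(cohort, config = sim_config(), seed) {
  stopifnot(inherits(cohort, "gm_cohort"), inherits(config, "gm_sim_config"))
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  shp <- config$grid_shape
  nv <- prod(shp)
  n <- nrow(cohort)
  sig <- as.vector(signal_mask(config))
  age <- (cohort$age_days - config$age_center_days) / 365.25
  male <- as.numeric(cohort$sex == "M")
  subjects <- unique(cohort$subject_id)
  sites <- unique(cohort$site)
  b_subj <- setNames(rnorm(length(subjects), 0, config$sigma_subject),
                     subjects)
  b_site <- setNames(rnorm(length(sites), 0, config$sigma_site), sites)
  fixed_base <- config$beta0 + config$beta_age * age +
    config$beta_age2 * age^2 + config$beta_sex * male +
    b_subj[cohort$subject_id] + b_site[cohort$site]
  g_off <- rep(0, n); g_slope <- rep(0, n)
  for (g in names(config$beta_group)) {
    in_g <- cohort$group == g
    g_off[in_g] <- config$beta_group[[g]]
    g_slope[in_g] <- config$beta_group_age[[g]]
  }
  # voxels x scans: base + sign(region) * group terms + residual noise
  M <- matrix(fixed_base, nv, n, byrow = TRUE)
  M <- M + outer(sig, g_off + g_slope * age)
  M <- M + matrix(rnorm(nv * n, 0, config$sigma_resid), nv, n)
  grid <- gm_grid(shp, config$grid_spacing)
  truth_bg <- lapply(config$beta_group, function(b) array(sig * b, shp))
  truth_bga <- lapply(config$beta_group_age, function(b) array(sig * b, shp))
  list(stack = array(M, c(shp, n)), grid = grid,
       truth = list(signal = array(sig, shp), beta_group = truth_bg,
                    beta_group_age = truth_bga),
       frame = data.frame(subject_id = cohort$subject_id, age_c = age,
                          male = male, group = cohort$group,
                          site = cohort$site))
}

# smooth radial profile of the phantom: layered object whose geometry
# scales with growth_factor and whose layer intensities depend on channel
# and age (contrast reversal happens at different ages per channel)
phantom_profile <- function(r, growth_factor, levels, edge = 1.2,
                            shell_r = 16, core_r = 9, band_r = 4.5) {
  radii <- growth_factor * c(band_r, core_r, shell_r)
  edge <- edge * growth_factor  # transitions scale with the object
  s <- function(rr) 1 / (1 + exp((r - rr) / edge))
  # partition of unity over band / core / shell / background
  w_band <- s(radii[1])
  w_core <- s(radii[2]) - w_band
  w_shell <- s(radii[3]) - s(radii[2])
  levels[1] * w_band + levels[2] * w_core + levels[3] * w_shell
}

channel_levels <- function(age_months, channel) {
  # core/shell contrast inverts with age, earlier and faster for T1-like
  # than T2-like intensities; band tracks the core with extra contrast
  x <- if (channel == "T1") (age_months - 9) / 3 else (age_months - 15) / 5
  mix <- 1 / (1 + exp(-x))
  core <- 35 + 45 * mix      # dark -> bright as myelination proceeds
  shell <- 65 - 25 * mix     # bright -> dimmer
  band <- core + 18 * (2 * mix - 1)
  c(band = band, core = core, shell = shell)
}

#' Simulate a two-channel growth phantom
#'
#' Deterministic multi-compartment spherical phantom (inner band, core,
#' outer shell, zero background) whose geometry scales linearly with
#' `growth_factor` — so tissue volume scales with its cube — and whose
#' T1/T2 channel intensities depend on `age_months` such that the
#' core/shell contrast inverts between the 6-month-like and 24-month-like
#' states at different rates per channel. Additive Gaussian noise from
#' `seed`.
#'
#' @param age_months age state controlling the channel contrast.
#' @param growth_factor linear scale of the phantom geometry (> 0).
#' @param grid a `gm_grid` (default 48^3 at 1 mm centred on the phantom).
#' @param noise_sd additive Gaussian noise SD (intensity units).
#' @param seed integer seed for the noise.
#' @return List with `t1` and `t2` `gm_volume`s.
#' @export
simulate_growth_phantom <- function(age_months, growth_factor = 1,
                                    grid = NULL, noise_sd = 1, seed = 1L) {
  if (growth_factor <= 0) stop("growth_factor must be positive")
  if (is.null(grid)) grid <- gm_grid(c(48L, 48L, 48L), c(1, 1, 1))
  w <- grid_world_matrix(grid)
  ctr <- as.vector(grid$affine %*% c((grid$shape - 1) / 2, 1))[1:3]
  r <- sqrt((w[, 1] - ctr[1])^2 + (w[, 2] - ctr[2])^2 + (w[, 3] - ctr[3])^2)
  set.seed(seed)
  out <- lapply(c(T1 = "T1", T2 = "T2"), function(ch) {
    lv <- channel_levels(age_months, ch)
    vals <- phantom_profile(r, growth_factor, lv)
    vals <- vals + rnorm(length(vals), 0, noise_sd)
    as_volume(array(vals, grid$shape), grid$spacing, grid$affine,
              modality = ch)
  })
  structure(list(t1 = out$T1, t2 = out$T2),
            radii_mm = growth_factor * c(band = 4.5, core = 9, shell = 16),
            levels = list(t1 = channel_levels(age_months, "T1"),
                          t2 = channel_levels(age_months, "T2")))
}

#' Deterministic demonstration cohort with published-scale bookkeeping
#'
#' Builds a cohort table whose per-group visit-pattern counts reproduce
#' the demographic structure of a large three-wave infant-sibling study:
#' 56 HR+, 285 HR- and 162 LR- participants (503 in all, 1,088 scans),
#' with the characteristic one/two/three-timepoint splits (18/17/21,
#' 53/122/110 and 39/62/61 respectively). Ages are set to the wave means;
#' sex and site alternate deterministically. Useful for exercising cohort
#' bookkeeping at full scale without any data.
#'
#' @return A `gm_cohort` data.frame (1,088 rows).
#' @export
demo_cohort <- function() {
  # per group: single-visit counts (V06, V12, V24), pair counts
  # (V06+V12, V06+V24, V12+V24), and triple count
  layout <- list(
    `HR+` = list(single = c(5, 4, 9), pairs = c(7, 7, 3), triple = 21),
    `HR-` = list(single = c(20, 2, 31), pairs = c(60, 12, 50), triple = 110),
    `LR-` = list(single = c(24, 5, 10), pairs = c(40, 12, 10), triple = 61))
  pair_sets <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  age_days <- round(c(6.7, 12.8, 25.0) * DAYS_PER_MONTH)
  rows <- list()
  sid <- 0L
  add_subject <- function(group, visits) {
    sid <<- sid + 1L
    subject <- sprintf("D%04d", sid)
    for (v in visits) {
      rows[[length(rows) + 1L]] <<- data.frame(
        subject_id = subject, group = group,
        sex = if (sid %% 2L == 0L) "M" else "F",
        site = sprintf("site%d", 1L + sid %% 4L),
        visit = VISIT_LEVELS[v], age_days = age_days[v])
    }
  }
  for (g in names(layout)) {
    ly <- layout[[g]]
    for (v in 1:3) for (i in seq_len(ly$single[v])) add_subject(g, v)
    for (pp in 1:3) for (i in seq_len(ly$pairs[pp]))
      add_subject(g, pair_sets[[pp]])
    for (i in seq_len(ly$triple)) add_subject(g, 1:3)
  }
  as_cohort(do.call(rbind, rows))
}
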