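test_that("model specifications enforce hierarchy and known terms", {
  expect_error(model_spec(fixed = c("age", "banana")), "unknown fixed")
  expect_error(model_spec(fixed = c("group:age", "group")), "age main")
  expect_error(model_spec(fixed = c("age", "group:age")), "group and age")
  expect_error(model_spec(fixed = c("age", "age3")), "age2")
  expect_error(model_spec(fixed = c("age", "site"),
                          random = c("site_intercept")), "both")
  s <- model_spec()
  expect_identical(s$fixed, c("age", "age2", "group", "group:age", "sex"))
  expect_identical(s$random, c("subject_intercept", "site_intercept"))
  expect_equal(s$age_center_days, 183)
})

test_that("noise-free data are interpolated exactly by the fixed-effects fit", {
  co <- small_cohort(seed = 51)
  fr <- data.frame(age = (co$age_days - 183) / 365.25,
                   male = as.numeric(co$sex == "M"))
  y <- 0.2 + 0.5 * fr$age - 0.1 * fr$age^2 + 0.03 * fr$male
  f <- fit_lmm(y, co, model_spec(fixed = c("age", "age2", "sex"),
                                 random = character(0)))
  expect_equal(unname(f$beta),
               c(0.2, 0.5, -0.1, 0.03), tolerance = 1e-8)
  expect_lt(f$sigma2_resid, 1e-16)
})

test_that("with zero random-effect variance the mixed fit matches ordinary least squares", {
  co <- small_cohort(seed = 52)
  set.seed(52)
  fr <- data.frame(age = (co$age_days - 183) / 365.25,
                   male = as.numeric(co$sex == "M"))
  r <- rnorm(nrow(co), 0, 0.05)
  r <- r - ave(r, co$subject_id)  # zero subject/site variance by construction
  y <- 0.1 + 0.4 * fr$age + 0.05 * fr$male + r
  f_mixed <- fit_lmm(y, co, model_spec(fixed = c("age", "sex")))
  ols <- lm(y ~ fr$age + fr$male)
  expect_equal(unname(f_mixed$beta), unname(coef(ols)), tolerance = 1e-6)
  expect_lt(f_mixed$sigma2_subject, 1e-6)
})

test_that("the returned ML log-likelihood matches a direct marginal Gaussian evaluation", {
  cfg <- sim_config(grid_shape = c(1L, 1L, 1L),
                    signal_regions = list(list(center = c(1, 1, 1),
                                               radius = 1, sign = 1)),
                    beta_group = c(`HR-` = -0.05, `HR+` = 0.08),
                    beta_group_age = c(`HR-` = 0.03, `HR+` = 0.06))
  for (seed in c(61, 62, 63)) {
    co <- simulate_cohort(cfg, seed = seed)
    sim <- simulate_logjac_stack(co, cfg, seed = seed + 10L)
    y <- sim$stack[1, 1, 1, ]
    f <- fit_lmm(y, co, model_spec())
    fr <- data.frame(age_c = (co$age_days - 183) / 365.25,
                     group = factor(co$group, c("LR-", "HR-", "HR+")),
                     sex = factor(co$sex, c("F", "M")))
    X <- model.matrix(~ age_c + I(age_c^2) + group + sex + age_c:group, fr)
    ll <- marginal_loglik(y, X[, names(f$beta)], f$beta,
                          co$subject_id, co$site,
                          f$sigma2_subject, f$sigma2_site, f$sigma2_resid)
    expect_equal(f$loglik, ll, tolerance = 1e-6)
  }
})

test_that("rank-deficient designs fail with the collinear column named", {
  co <- as.data.frame(small_cohort(seed = 53))
  co$sex <- "M"  # sex column collinear with the intercept
  co <- as_cohort(co)
  expect_error(fit_lmm(rnorm(nrow(co)), co,
                       model_spec(fixed = c("age", "sex"))),
               "collinear.*sexM")
})

test_that("likelihood-ratio tests are calibrated and detect strong interactions", {
  co <- small_cohort(c(`HR+` = 12L, `HR-` = 14L, `LR-` = 14L), seed = 54)
  null_spec <- model_spec(fixed = c("age"),
                          random = "subject_intercept")
  full_spec <- model_spec(fixed = c("age", "group"),
                          random = "subject_intercept")
  fr_age <- (co$age_days - 183) / 365.25

  f0 <- fit_lmm(rnorm(nrow(co)), co, null_spec)
  expect_error(lrt(f0, f0), NA)
  self <- lrt(f0, f0)
  expect_equal(self$stat, 0)
  expect_equal(self$p, 1)
  expect_error(lrt(fit_lmm(rnorm(nrow(co)), co, full_spec), f0),
               "not nested")

  # null-true simulation: p-values approximately uniform
  set.seed(55)
  pvals <- replicate(500, {
    b <- rnorm(length(unique(co$subject_id)), 0, 0.05)
    y <- 0.3 * fr_age + b[match(co$subject_id, unique(co$subject_id))] +
      rnorm(nrow(co), 0, 0.05)
    lrt(fit_lmm(y, co, null_spec), fit_lmm(y, co, full_spec))$p
  })
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_lt(unname(ks$statistic), 0.1)
})

test_that("a strong group-by-age signal is overwhelming at the published-scale design", {
  cfg <- sim_config(n_subjects = c(`HR+` = 25L, `HR-` = 75L, `LR-` = 50L),
                    grid_shape = c(1L, 1L, 1L),
                    signal_regions = list(list(center = c(1, 1, 1),
                                               radius = 1, sign = 1)))
  co <- simulate_cohort(cfg, seed = 56)
  sim <- simulate_logjac_stack(co, cfg, seed = 57)
  y <- sim$stack[1, 1, 1, ]
  f_null <- fit_lmm(y, co, model_spec(fixed = c("age", "age2", "group", "sex")))
  f_full <- fit_lmm(y, co, model_spec())
  expect_lt(lrt(f_null, f_full)$p, 1e-6)
})

test_that("voxel-wise fitting at a single voxel reproduces the scalar fit", {
  cfg <- sim_config(grid_shape = c(3L, 3L, 3L),
                    signal_regions = list(list(center = c(2, 2, 2),
                                               radius = 1.2, sign = 1)))
  co <- simulate_cohort(cfg, seed = 58)
  sim <- simulate_logjac_stack(co, cfg, seed = 59)
  mask <- array(FALSE, c(3, 3, 3)); mask[2, 2, 2] <- TRUE
  vs <- fit_voxelwise(sim$stack, co, model_spec(), mask = mask,
                      grid = sim$grid)
  f <- fit_lmm(sim$stack[2, 2, 2, ], co, model_spec())
  expect_equal(unname(vs$beta[1, ]), unname(f$beta), tolerance = 1e-5)
  expect_equal(unname(vs$se[1, ]), unname(f$se), tolerance = 1e-4)
  expect_equal(vs$loglik[1], f$loglik, tolerance = 1e-8)
  expect_equal(vs$df, f$df)
  # t-maps exist for every model term plus the derived pairwise contrast
  expect_setequal(names(vs$tmaps),
                  c("age_c", "I(age_c^2)", "groupHR-", "groupHR+", "sexM",
                    "age_c:groupHR-", "age_c:groupHR+",
                    "group:age HR+ vs HR-"))

  expect_error(fit_voxelwise(sim$stack, co, mask = array(FALSE, c(3, 3, 3))),
               "mask is empty")
  expect_error(fit_voxelwise(sim$stack[, , , 1:5], co), "cohort has")
})

test_that("the peak interaction statistic localizes inside the true signal region", {
  cfg <- sim_config(grid_shape = c(5L, 5L, 5L),
                    signal_regions = list(list(center = c(3, 3, 3),
                                               radius = 1.5, sign = 1)))
  sigv <- array(FALSE, c(5, 5, 5))
  sigv[abs(slice.index(sigv, 1) - 3) <= 1 &
         abs(slice.index(sigv, 2) - 3) <= 1 &
         abs(slice.index(sigv, 3) - 3) <= 1] <- TRUE  # superset of sphere
  hits <- 0L
  for (rep in 1:20) {
    co <- simulate_cohort(cfg, seed = 600 + rep)
    sim <- simulate_logjac_stack(co, cfg, seed = 700 + rep)
    vs <- fit_voxelwise(sim$stack, co, model_spec(), grid = sim$grid)
    tmap <- vs$tmaps[["age_c:groupHR+"]]$data
    peak <- arrayInd(which.max(abs(tmap)), dim(tmap))
    hits <- hits + (sim$truth$signal[peak[1], peak[2], peak[3]] != 0)
  }
  expect_gte(hits, 18L)
})

test_that("forward selection keeps the simplest model on simple data and finds the full structure", {
  simple_keep <- 0L
  full_keep <- 0L
  cfg_simple <- sim_config(n_subjects = c(`HR+` = 10L, `HR-` = 20L,
                                          `LR-` = 15L),
                           grid_shape = c(3L, 3L, 3L), signal_regions = list(),
                           beta_age2 = 0, beta_sex = 0)
  cfg_full <- sim_config(grid_shape = c(3L, 3L, 3L),
                         signal_regions = list(list(center = c(2, 2, 2),
                                                    radius = 5, sign = 1)),
                         beta_group = c(`HR-` = -0.05, `HR+` = 0.08),
                         beta_group_age = c(`HR-` = 0.04, `HR+` = 0.08),
                         beta_sex = 0.05)
  for (rep in 1:10) {
    co <- simulate_cohort(cfg_simple, seed = 800 + rep)
    sim <- simulate_logjac_stack(co, cfg_simple, seed = 900 + rep)
    sel <- forward_select(sim$stack, co)
    simple_keep <- simple_keep + identical(sel$fixed, "age")

    co2 <- simulate_cohort(cfg_full, seed = 1800 + rep)
    sim2 <- simulate_logjac_stack(co2, cfg_full, seed = 1900 + rep)
    sel2 <- forward_select(sim2$stack, co2)
    full_keep <- full_keep +
      identical(sel2$fixed, c("age", "age2", "group", "group:age", "sex"))
  }
  expect_gte(simple_keep, 9L)
  expect_gte(full_keep, 9L)
})

test_that("the selected growth model has the canonical fixed and random structure", {
  cfg <- sim_config(grid_shape = c(3L, 3L, 3L),
                    signal_regions = list(list(center = c(2, 2, 2),
                                               radius = 5, sign = 1)),
                    beta_group = c(`HR-` = -0.05, `HR+` = 0.08),
                    beta_group_age = c(`HR-` = 0.04, `HR+` = 0.08),
                    beta_sex = 0.05)
  co <- simulate_cohort(cfg, seed = 71)
  sim <- simulate_logjac_stack(co, cfg, seed = 72)
  sel <- forward_select(sim$stack, co)
  expect_identical(sel$fixed, c("age", "age2", "group", "group:age", "sex"))
  expect_setequal(sel$random, c("subject_intercept", "site_intercept"))
  expect_s3_class(attr(sel, "trace"), "data.frame")
})

test_that("Benjamini-Hochberg step-up matches its definition", {
  res <- bh_threshold(c(0.01, 0.02, 0.04, 0.20), q = 0.05)
  oracle <- brute_bh(c(0.01, 0.02, 0.04, 0.20), 0.05)
  expect_equal(res$p_threshold, oracle$p_threshold)
  expect_identical(res$reject, oracle$reject)

  all_one <- bh_threshold(rep(1, 10), q = 0.05)
  expect_identical(all_one$n_rejected, 0L)
  expect_error(bh_threshold(numeric(0)), "empty")
  expect_error(bh_threshold(c(0.5, 1.2)), "0, 1")
})

test_that("pooled-FDR thresholding converts the BH p-threshold into consistent t-thresholds", {
  cfg <- sim_config(grid_shape = c(4L, 4L, 4L),
                    signal_regions = list(list(center = c(2, 2, 2),
                                               radius = 1.4, sign = 1)))
  co <- simulate_cohort(cfg, seed = 73)
  sim <- simulate_logjac_stack(co, cfg, seed = 74)
  vs <- fit_voxelwise(sim$stack, co, model_spec(), grid = sim$grid)
  fdr <- pooled_fdr_threshold(vs, q = 0.05)
  expect_true(all(unlist(fdr$t_thresholds) > 0))
  # significance masks agree with the two-sided t <-> p correspondence
  nm <- "age_c:groupHR+"
  expect_identical(fdr$masks[[nm]],
                   abs(vs$tmaps[[nm]]$data) >= fdr$t_thresholds[[nm]])
  expect_equal(fdr$t_thresholds[[nm]],
               qt(1 - fdr$p_threshold / 2, vs$df))

  # nothing significant: +Inf sentinel
  null_vs <- vs
  for (nm2 in names(null_vs$pmaps)) null_vs$pmaps[[nm2]][] <- 1
  fdr0 <- pooled_fdr_threshold(null_vs, q = 0.05)
  expect_identical(fdr0$n_rejected, 0L)
  expect_true(all(!is.finite(unlist(fdr0$t_thresholds))))
  expect_false(any(unlist(fdr0$masks)))
})
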