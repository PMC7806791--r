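test_that("cohort simulation respects dropout, determinism and visit structure", {
  cfg0 <- sim_config(dropout = 0)
  co <- simulate_cohort(cfg0, seed = 91)
  expect_identical(nrow(co), 3L * sum(cfg0$n_subjects))
  expect_true(all(table(co$subject_id) == 3L))

  co_a <- simulate_cohort(sim_config(), seed = 92)
  co_b <- simulate_cohort(sim_config(), seed = 92)
  expect_identical(co_a, co_b)
  co_c <- simulate_cohort(sim_config(), seed = 93)
  expect_false(identical(co_a, co_c))

  # every subject contributes at least one scan even under heavy dropout
  heavy <- simulate_cohort(sim_config(dropout = 0.6), seed = 94)
  expect_identical(length(unique(heavy$subject_id)), sum(sim_config()$n_subjects))
  expect_error(simulate_cohort(sim_config(), ), "seed is mandatory")
})

test_that("simulated visit ages match the configured distributions (law of large numbers)", {
  cfg <- sim_config(n_subjects = c(`HR+` = 3400L, `HR-` = 3300L,
                                   `LR-` = 3300L), dropout = 0)
  co <- simulate_cohort(cfg, seed = 95)
  m6 <- mean(co$age_days[co$visit == "V06"]) / 30.44
  expect_lt(abs(m6 - 6.7), 0.05)
  m24 <- mean(co$age_days[co$visit == "V24"]) / 30.44
  expect_lt(abs(m24 - 25.0), 0.05)
  sd6 <- sd(co$age_days[co$visit == "V06"]) / 30.44
  expect_lt(abs(sd6 - 0.7), 0.05)
})

test_that("the all-zero configuration produces an all-zero stack", {
  cfg <- sim_config(grid_shape = c(4L, 4L, 4L), signal_regions = list(),
                    beta0 = 0, beta_age = 0, beta_age2 = 0, beta_sex = 0,
                    sigma_subject = 0, sigma_site = 0, sigma_resid = 0)
  co <- simulate_cohort(cfg, seed = 96)
  sim <- simulate_logjac_stack(co, cfg, seed = 97)
  expect_identical(unique(as.vector(sim$stack)), 0)
})

test_that("the voxel-wise group-by-age slope difference matches the configured effect", {
  cfg <- sim_config(n_subjects = c(`HR+` = 70L, `HR-` = 70L, `LR-` = 60L),
                    grid_shape = c(4L, 4L, 4L), dropout = 0,
                    signal_regions = list(list(center = c(2, 2, 2),
                                               radius = 1.4, sign = 1)))
  co <- simulate_cohort(cfg, seed = 98)
  sim <- simulate_logjac_stack(co, cfg, seed = 99)
  age <- (co$age_days - 183) / 365.25
  M <- matrix(sim$stack, 64)  # voxels x scans
  hr <- which(co$group == "HR+"); lr <- which(co$group == "LR-")
  sig_idx <- which(sim$truth$signal != 0)
  diffs <- sapply(sig_idx, function(v)
    coef(lm(M[v, hr] ~ age[hr]))[2] - coef(lm(M[v, lr] ~ age[lr]))[2])
  expect_lt(abs(mean(diffs) - cfg$beta_group_age[["HR+"]]), 0.02)
  # no group-by-age difference outside the signal regions
  null_idx <- which(sim$truth$signal == 0)[1:10]
  diffs0 <- sapply(null_idx, function(v)
    coef(lm(M[v, hr] ~ age[hr]))[2] - coef(lm(M[v, lr] ~ age[lr]))[2])
  expect_lt(abs(mean(diffs0)), 0.02)
})

test_that("repeated measures correlate within subject and moments match closed form", {
  cfg <- sim_config(grid_shape = c(3L, 3L, 3L), dropout = 0,
                    signal_regions = list())
  co <- simulate_cohort(cfg, seed = 100)
  sim <- simulate_logjac_stack(co, cfg, seed = 101)
  age <- (co$age_days - 183) / 365.25
  male <- as.numeric(co$sex == "M")
  fixed <- cfg$beta0 + cfg$beta_age * age + cfg$beta_age2 * age^2 +
    cfg$beta_sex * male
  resid <- sweep(matrix(sim$stack, 27), 2, fixed)
  # marginal variance = sigma_subject^2 + sigma_site^2 + sigma_resid^2
  expect_equal(mean(resid^2),
               cfg$sigma_subject^2 + cfg$sigma_site^2 + cfg$sigma_resid^2,
               tolerance = 0.15)
  # within-subject pairs share the subject intercept
  v1 <- which(co$visit == "V06"); v2 <- which(co$visit == "V12")
  same <- match(co$subject_id[v1], co$subject_id[v2])
  within <- cor(resid[1, v1], resid[1, v2[same]])
  scramble <- cor(resid[1, v1], resid[1, sample(v2[same])])
  expect_gt(within, scramble)
  expect_gt(within, 0.3)
})

test_that("phantom geometry scales with growth and contrast with age, independently", {
  g <- gm_grid(c(48L, 48L, 48L))
  p25a <- simulate_growth_phantom(25, 1.0, grid = g, noise_sd = 0, seed = 1)
  p25b <- simulate_growth_phantom(25, 1.1, grid = g, noise_sd = 0, seed = 1)
  p6 <- simulate_growth_phantom(6.7, 1.0, grid = g, noise_sd = 0, seed = 1)

  # same growth at two ages: identical compartment radii, different levels
  expect_identical(attr(p25a, "radii_mm"), attr(p6, "radii_mm"))
  expect_gt(max(abs(p25a$t1$data - p6$t1$data)), 10)
  # 10% linear growth scales radii linearly ...
  expect_equal(unname(attr(p25b, "radii_mm") / attr(p25a, "radii_mm")),
               rep(1.1, 3))
  # ... and bright-core volume by 1.1^3 within voxelization error
  lv <- attr(p25a, "levels")$t1
  thr <- (lv[["core"]] + lv[["shell"]]) / 2
  ratio <- sum(p25b$t1$data > thr) / sum(p25a$t1$data > thr)
  expect_equal(ratio, 1.1^3, tolerance = 0.03)

  # T1 and T2 core/shell contrast inverts across age, at different ages
  contrast <- function(ph) {
    lvl <- attr(ph, "levels")
    c(t1 = lvl$t1[["core"]] - lvl$t1[["shell"]],
      t2 = lvl$t2[["core"]] - lvl$t2[["shell"]])
  }
  expect_true(all(contrast(p6) < 0))
  expect_true(all(contrast(p25a) > 0))
  mid <- contrast(simulate_growth_phantom(11, 1, grid = g, noise_sd = 0,
                                          seed = 1))
  expect_true(mid[["t1"]] > 0 && mid[["t2"]] < 0)  # T1 flips first

  expect_error(simulate_growth_phantom(12, growth_factor = 0), "positive")
})

test_that("the demo cohort reproduces the published demographic structure per group", {
  co <- demo_cohort()
  s <- cohort_summary(co)
  expect_identical(s$n_scans, 1088L)
  expect_identical(s$n_participants, 503L)
  expect_identical(unname(as.vector(s$participants_by_group)),
                   c(162L, 285L, 56L))  # LR-, HR-, HR+
  tab <- s$scans_by_group_visit
  expect_identical(unname(tab["HR+", ]), c(40L, 35L, 40L))
  expect_identical(unname(tab["HR-", ]), c(202L, 222L, 203L))
  expect_identical(unname(tab["LR-", ]), c(137L, 116L, 93L))
  # one/two/three-timepoint participants: 110/201/192
  n_tp <- table(table(co$subject_id))
  expect_identical(unname(as.vector(n_tp)), c(110L, 201L, 192L))
})
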