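# Phantoms for registration tests: 32^3 at 1.5 mm so the default published
# parameter semantics apply at desk scale with a shortened pyramid.
reg_grid <- gm_grid(c(32L, 32L, 32L), c(1.5, 1.5, 1.5))
reg_params <- syn_params(shrink_factors = c(4L, 2L, 1L),
                         smoothing_sigmas_mm = c(4.72, 2.36, 0),
                         iterations_per_level = c(30L, 20L, 10L))

test_that("default registration parameters carry the published values", {
  p <- syn_params()
  expect_equal(p$gradient_step, 0.25)
  expect_equal(p$update_sigma_vox, 2.0)
  expect_equal(p$total_sigma_vox, 0.3)
  expect_equal(p$channel_weights, c(0.5, 0.5))
  expect_equal(p$shrink_factors, c(16L, 8L, 4L, 2L, 1L))
  expect_equal(p$smoothing_sigmas_mm, c(9.44, 7.08, 4.72, 2.36, 0))
})

test_that("parameter invariants are enforced", {
  expect_error(syn_params(shrink_factors = c(2L, 4L),
                          smoothing_sigmas_mm = c(1, 0),
                          iterations_per_level = c(5L, 5L)),
               "non-increasing")
  expect_error(syn_params(channel_weights = c(0.7, 0.5)), "sum to 1")
  expect_error(syn_params(shrink_factors = c(4L, 2L),
                          smoothing_sigmas_mm = c(1)), "same length")
  expect_error(syn_params(gradient_step = 0), "positive")
})

test_that("local cross-correlation is 1 on self, -1 on negation, and matches a brute-force oracle", {
  a <- noise_volume(c(7L, 7L, 7L), seed = 31)
  cc_self <- local_cross_correlation(a, a, 1L)
  expect_true(all(abs(cc_self$data - 1) < 1e-10))
  neg <- as_volume(-a$data)
  expect_true(all(abs(local_cross_correlation(a, neg, 1L)$data + 1) < 1e-10))

  b <- noise_volume(c(7L, 7L, 7L), seed = 32)
  cc <- local_cross_correlation(a, b, 2L)
  set.seed(33)
  for (i in 1:20) {
    at <- sample(1:7, 3, replace = TRUE)
    expect_equal(cc$data[at[1], at[2], at[3]],
                 brute_local_cc(a$data, b$data, 2L, at), tolerance = 1e-10)
  }
  # zero-variance windows yield 0
  flat <- as_volume(array(2, c(7L, 7L, 7L)))
  expect_equal(unique(as.vector(local_cross_correlation(flat, a, 1L)$data)), 0)
})

test_that("affine registration recovers identity, translation and isotropic scale", {
  ph <- simulate_growth_phantom(12.8, 1.0, grid = reg_grid, seed = 41)
  fx <- list(ph$t1, ph$t2)

  A_id <- affine_register(fx, fx)
  expect_lt(max(abs(A_id - diag(4))), 1e-3)

  shifted_aff <- reg_grid$affine
  shifted_aff[2, 4] <- shifted_aff[2, 4] + 4
  mv_t <- lapply(fx, function(v) as_volume(v$data, v$spacing, shifted_aff,
                                           modality = v$modality))
  A_t <- affine_register(mv_t, fx)
  expect_lt(abs(A_t[2, 4] - 4), 0.5)
  expect_lt(max(abs(A_t[1:3, 1:3] - diag(3))), 0.05)

  ctr <- as.vector(reg_grid$affine %*% c((reg_grid$shape - 1) / 2, 1))[1:3]
  S <- diag(4); S[1:3, 1:3] <- diag(3) / 1.1
  S[1:3, 4] <- ctr - ctr / 1.1
  mv_s <- lapply(fx, function(v) {
    out <- apply_affine(v, S, reg_grid)
    out$modality <- v$modality
    out
  })
  A_s <- affine_register(mv_s, fx)
  expect_equal(det(A_s[1:3, 1:3])^(1 / 3), 1.1, tolerance = 0.02)
})

test_that("degenerate constant images are rejected by both registrations", {
  flat <- as_volume(array(1, c(16L, 16L, 16L)))
  ph <- simulate_growth_phantom(12.8, 1.0, grid = gm_grid(c(16L, 16L, 16L)),
                                seed = 42)
  expect_error(affine_register(flat, ph$t1), "degenerate")
  expect_error(diffeo_register(flat, ph$t1), "degenerate")
})

test_that("registering an image to itself leaves a near-zero field", {
  ph <- simulate_growth_phantom(12.8, 1.0, grid = reg_grid, seed = 43)
  u <- diffeo_register(list(ph$t1, ph$t2), list(ph$t1, ph$t2), reg_params)
  expect_lt(max(field_norm_arr(u)) / min(reg_grid$spacing), 0.1)
})

test_that("a known smooth deformation is recovered within half a voxel and the field stays diffeomorphic", {
  ph <- simulate_growth_phantom(12.8, 1.05, grid = gm_grid(c(48L, 48L, 48L)),
                                noise_sd = 0.5, seed = 44)
  g <- grid_of(ph$t1)
  w <- gm_world(g)
  bump <- 2.2 * exp(-((w[, 1] - 18)^2 + (w[, 2] - 23.5)^2 +
                        (w[, 3] - 23.5)^2) / 60)
  utrue <- displacement_field(array(c(bump, 0.5 * bump, -0.8 * bump),
                                    c(48L, 48L, 48L, 3L)), g)
  fx1 <- warp(ph$t1, utrue); fx1$modality <- "T1"
  fx2 <- warp(ph$t2, utrue); fx2$modality <- "T2"
  p <- syn_params(shrink_factors = c(4L, 2L, 1L),
                  smoothing_sigmas_mm = c(3, 1.5, 0),
                  iterations_per_level = c(30L, 20L, 10L))
  u <- diffeo_register(list(ph$t1, ph$t2), list(fx1, fx2), p)
  fg <- as.vector(fx1$data > 20)
  err <- sqrt(rowSums((matrix(u$vectors, ncol = 3) -
                         matrix(utrue$vectors, ncol = 3))^2))
  expect_lt(mean(err[fg]), 0.5)
  expect_gt(attr(u, "min_jacobian"), 0)

  # energy is non-increasing within each level by construction
  for (tr in attr(u, "energy")) {
    expect_true(all(diff(tr) <= 1e-12))
  }
})

test_that("forward and backward registrations compose to under a voxel on smooth phantoms", {
  a <- simulate_growth_phantom(12.8, 1.0, grid = reg_grid, noise_sd = 0.5,
                               seed = 45)
  b <- simulate_growth_phantom(12.8, 1.06, grid = reg_grid, noise_sd = 0.5,
                               seed = 46)
  p <- syn_params(shrink_factors = c(2L, 1L), smoothing_sigmas_mm = c(3, 0),
                  iterations_per_level = c(20L, 10L))
  uab <- diffeo_register(list(a$t1, a$t2), list(b$t1, b$t2), p)
  uba <- diffeo_register(list(b$t1, b$t2), list(a$t1, a$t2), p)
  round_trip <- compose_fields(uab, uba)
  expect_lt(mean(field_norm_arr(round_trip)) / min(reg_grid$spacing), 1)
})
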