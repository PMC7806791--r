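test_that("volume NIfTI round-trip is bit-exact for data, spacing and affine", {
  v <- noise_volume(c(8L, 8L, 8L), seed = 3, spacing = c(1, 1, 2))
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(v, f)
  back <- read_volume(f)
  expect_identical(back$data, v$data)
  expect_identical(back$spacing, v$spacing)
  expect_equal(back$affine, v$affine, tolerance = 0)
})

test_that("anisotropic spacing survives the header round-trip (independent header dump)", {
  v <- noise_volume(c(6L, 6L, 6L), seed = 4, spacing = c(1, 1, 2))
  f <- withr::local_tempfile(fileext = ".nii")
  write_volume(v, f)
  out <- system2("python", c("-c", shQuote(sprintf(
    "import nibabel; img = nibabel.load('%s'); print(*img.header.get_zooms())", f))),
    stdout = TRUE)
  expect_equal(as.numeric(strsplit(trimws(out[length(out)]), " ")[[1]]),
               c(1, 1, 2))
})

test_that("read_volume rejects non-3-D images and NaN voxels", {
  f4 <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(0, c(4, 4, 4, 2))), f4)
  expect_error(read_volume(f4), "expected 3-D")
  expect_error(read_volume(tempfile(fileext = ".nii")), "not found")
  expect_error(as_volume(array(c(NaN, rep(0, 7)), c(2, 2, 2))),
               "non-finite voxel")
  bad <- array(1, c(3, 3, 3)); bad[1, 1, 1] <- NA
  expect_error(as_volume(bad), "1 non-finite")
})

test_that("volume invariants are enforced at construction", {
  expect_error(as_volume(array(0, c(4, 4, 4)), spacing = c(1, -1, 1)),
               "strictly positive")
  expect_error(as_volume(array(0.5, c(4, 4, 4)), modality = "label"),
               "non-negative integers")
  expect_error(as_volume(array(-1, c(4, 4, 4)), modality = "label"),
               "non-negative integers")
  expect_silent(as_volume(array(2L, c(4, 4, 4)), modality = "label"))
})

test_that("displacement fields round-trip through 5-D NIfTI with vector intent", {
  u <- compact_bump_field(12L)
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_field(u, f)
  back <- read_field(f)
  expect_identical(back$vectors, u$vectors)
  expect_equal(back$reference$affine, u$reference$affine)
  hdr <- RNifti::niftiHeader(RNifti::readNifti(f))
  expect_identical(hdr$intent_code, 1007L)
})

test_that("resample is the identity on its own grid and exact on constants and ramps", {
  v <- noise_volume(c(7L, 7L, 7L), seed = 5)
  expect_equal(resample(v, grid_of(v))$data, v$data, tolerance = 1e-12)
  const <- as_volume(array(3.5, c(6L, 6L, 6L)))
  tgt <- gm_grid(c(4L, 4L, 4L), c(1.3, 1.3, 1.3))
  expect_equal(unique(as.vector(resample(const, tgt)$data)), 3.5)
  # trilinear reproduces linear intensity functions exactly
  ramp <- ramp_volume(c(9L, 9L, 9L))
  half <- gm_grid(c(5L, 5L, 5L), c(2, 2, 2))
  expect_equal(resample(ramp, half)$data,
               ramp_volume(c(5L, 5L, 5L), spacing = c(2, 2, 2), slope = 2)$data,
               tolerance = 1e-12)
})

test_that("warp with the zero field is the identity; constant shifts move ramps by one sample", {
  v <- noise_volume(c(8L, 8L, 8L), seed = 6)
  expect_equal(warp(v, zero_field(grid_of(v)), order = "nearest")$data, v$data)
  expect_lt(max(abs(warp(v, zero_field(grid_of(v)))$data - v$data)) /
              diff(range(v$data)), 1e-6)
  ramp <- ramp_volume(c(9L, 9L, 9L))
  shift <- zero_field(grid_of(ramp))
  shift$vectors[, , , 1] <- 1
  w <- warp(ramp, shift)
  expect_equal(w$data[1:8, , ], ramp$data[2:9, , ], tolerance = 1e-12)
})

test_that("label volumes warp with nearest neighbour only and stay in the label set", {
  lab <- as_volume(array(sample(c(0L, 2L, 5L), 125, TRUE), c(5L, 5L, 5L)),
                   modality = "label")
  u <- zero_field(grid_of(lab))
  u$vectors[, , , 2] <- 0.4
  expect_error(warp(lab, u, order = "trilinear"), "nearest")
  w <- warp(lab, u)
  expect_true(all(w$data %in% c(0L, 2L, 5L)))
  expect_error(resample(lab, grid_of(lab), order = "trilinear"), "nearest")
})

test_that("cohort CSV loading validates labels, ages and uniqueness", {
  co <- small_cohort(seed = 2)
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, f)
  back <- read_cohort(f)
  expect_identical(back$subject_id, co$subject_id)
  expect_identical(back$age_days, co$age_days)

  dup <- rbind(as.data.frame(co), as.data.frame(co)[1, ])
  expect_error(as_cohort(dup), "duplicate")
  bad <- as.data.frame(co); bad$group[1] <- "XX"
  expect_error(as_cohort(bad), "unknown group")
  neg <- as.data.frame(co); neg$age_days[2] <- -1
  expect_error(as_cohort(neg), "positive")
  # group/sex/site must not vary within subject
  flip <- as.data.frame(co)
  s <- flip$subject_id[which(duplicated(flip$subject_id))[1]]
  flip$sex[flip$subject_id == s][1] <- setdiff(c("M", "F"),
                                               flip$sex[flip$subject_id == s][1])
  expect_error(as_cohort(flip), "constant within subject")
})

test_that("an empty cohort CSV yields an empty table with zero counts", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines("subject_id,group,sex,site,visit,age_days", f)
  co <- read_cohort(f)
  s <- cohort_summary(co)
  expect_identical(s$n_scans, 0L)
  expect_identical(s$n_participants, 0L)
})
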