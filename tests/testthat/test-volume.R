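test_that("volume construction validates geometry and clamps SPECT", {
  expect_error(sln_volume(array(0, c(4, 4)), c(1, 1, 1), modality = "CT"),
               "3-D")
  expect_error(sln_volume(array(0, c(2, 4, 4)), c(1, 1, 1), modality = "CT"),
               ">= 3")
  expect_error(sln_volume(array(0, c(4, 4, 4)), c(1, 0, 1), modality = "CT"),
               "positive")
  a <- array(c(-5, runif(63)), c(4, 4, 4))
  v <- sln_volume(a, c(4, 4, 4), modality = "SPECT")
  expect_true(all(v$values >= 0))
  ct <- sln_volume(a, c(1, 1, 5), modality = "CT")
  expect_equal(min(ct$values), -5)  # CT keeps negative HU
})

test_that("NIfTI round trip preserves values, spacing and origin", {
  a <- array(runif(4 * 5 * 6), c(4, 5, 6))
  v <- sln_volume(a, spacing_mm = c(1, 1, 5), origin_mm = c(10, -4, 2),
                  modality = "CT")
  f <- tempfile(fileext = ".nii.gz")
  write_volume(v, f)
  v2 <- load_volume(f, "CT")
  expect_equal(v2$spacing_mm, c(1, 1, 5))
  expect_equal(v2$origin_mm, c(10, -4, 2))
  expect_equal(v2$values, v$values, tolerance = 1e-6)

  s <- sln_volume(array(runif(27), c(3, 3, 3)), c(4, 4, 4),
                  modality = "SPECT")
  f2 <- tempfile(fileext = ".nii")
  write_volume(s, f2)
  s2 <- load_volume(f2, "SPECT")
  expect_equal(s2$spacing_mm, c(4, 4, 4))
  expect_equal(s2$values, s$values, tolerance = 1e-6)

  expect_error(load_volume(tempfile(), "CT"), "does not exist")
})

test_that("loading rejects non-3-D images", {
  f <- tempfile(fileext = ".nii")
  img <- RNifti::asNifti(array(0, c(4, 4, 4, 2)))
  RNifti::writeNifti(img, f)
  expect_error(load_volume(f, "SPECT"), "3-D")
})

test_that("resampling preserves constants, geometry and counts", {
  const <- sln_volume(array(7, c(5, 5, 5)), c(4, 4, 4), modality = "SPECT")
  r <- resample(const, resample_spec(c(1, 1, 1)))
  expect_equal(dim(r$values), c(20L, 20L, 20L))
  expect_true(all(abs(r$values - 7) < 1e-9))
  back <- resample(r, resample_spec(c(4, 4, 4)))
  expect_equal(back$values, const$values, tolerance = 1e-12)

  # counts integral preserved within 5 % for a single hot voxel
  a <- array(0, c(9, 9, 9)); a[5, 5, 5] <- 100
  v <- sln_volume(a, c(4, 4, 4), modality = "SPECT")
  r <- resample(v, resample_spec(c(1, 1, 1)))
  before <- sum(v$values) * prod(v$spacing_mm)
  after <- sum(r$values) * prod(r$spacing_mm)
  expect_lt(abs(after - before) / before, 0.05)

  # CT (1,1,5): axial dimension grows 5-fold (within one voxel)
  ct <- sln_volume(array(rnorm(6 * 6 * 8), c(6, 6, 8)), c(1, 1, 5),
                   modality = "CT")
  rct <- resample(ct, resample_spec(c(1, 1, 1)))
  expect_lte(abs(dim(rct$values)[3] - 5 * 8), 1)
  expect_equal(dim(rct$values)[1:2], c(6L, 6L))

  tiny <- sln_volume(array(0, c(3, 3, 3)), c(0.5, 0.5, 0.5),
                     modality = "CT")
  expect_error(resample(tiny, resample_spec(c(1, 1, 1))), "degenerate")
})

test_that("resampling onto a reference grid aligns world coordinates", {
  a <- array(0, c(12, 12, 12)); a[6, 6, 6] <- 50
  v <- sln_volume(a, c(1, 1, 1), origin_mm = c(0, 0, 0), modality = "CT")
  ref <- sln_volume(array(0, c(10, 10, 10)), c(1, 1, 1),
                    origin_mm = c(1, 1, 1), modality = "SPECT")
  r <- resample_to_reference(v, ref)
  expect_equal(dim(r$values), c(10L, 10L, 10L))
  # world position (5,5,5) is reference voxel (4,4,4)
  expect_equal(which.max(r$values), ijk <- 1 + 4 + 10 * (4 + 10 * 4))
})

test_that("background suppression follows the fractional threshold rule", {
  a <- array(runif(1000, 0, 999), c(10, 10, 10)); a[1] <- 1000
  v <- sln_volume(a, c(1, 1, 1), modality = "SPECT")
  s <- suppress_background(v, background_threshold(0.01))
  expect_true(all(s$values[s$values > 0] >= 10))
  expect_equal(s$values[a >= 10], a[a >= 10])  # survivors unchanged
  expect_equal(max(s$values), 1000)            # global max never zeroed

  toy <- array(0, c(3, 3, 3)); toy[1] <- 1000; toy[2] <- 5
  tv <- sln_volume(toy, c(1, 1, 1), modality = "SPECT")
  ts <- suppress_background(tv, background_threshold(0.01))
  expect_equal(as.numeric(ts$values[1:2]), c(1000, 0))

  # idempotence
  s2 <- suppress_background(s, background_threshold(0.01))
  expect_identical(s2$values, s$values)

  # all-zero volume: unchanged, not an error
  z <- sln_volume(array(0, c(3, 3, 3)), c(1, 1, 1), modality = "SPECT")
  expect_identical(suppress_background(z)$values, z$values)

  # total-counts reference
  tc <- suppress_background(tv, background_threshold(0.001, "total_counts"))
  expect_equal(as.numeric(tc$values[1:2]), c(1000, 5))  # cut = 1.005

  expect_error(suppress_background(sln_volume(array(0, c(3, 3, 3)),
                                              c(1, 1, 1), modality = "CT")),
               "SPECT")
  expect_error(background_threshold(1.5), "in \\(0, 1\\)")
})
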