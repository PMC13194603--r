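test_that("phantom generation is seed-deterministic and seed-sensitive", {
  sp <- phantom_spec(shape = c(10L, 24L, 24L), seed = 42L)
  p1 <- generate_phantom(sp)
  p2 <- generate_phantom(sp)
  expect_identical(p1$intensities, p2$intensities)
  p3 <- generate_phantom(phantom_spec(shape = c(10L, 24L, 24L), seed = 43L))
  expect_gt(sum(p1$intensities != p3$intensities), 0)
  expect_equal(dim(p1), c(10L, 24L, 24L))
  expect_equal(p1$spacing, c(2.5, 1, 1))
})

test_that("n_structures = 0 leaves only the body envelope", {
  p <- generate_phantom(phantom_spec(shape = c(32L, 48L, 48L),
                                     n_structures = 0L, seed = 1L))
  v <- p$intensities
  # two plateaus (air, body) plus smooth transitions: the plateau values
  # dominate and no voxel exceeds the body value
  frac_plateau <- mean(abs(v - min(v)) < 1 | abs(v - 30) < 1)
  expect_gt(frac_plateau, 0.7)
  expect_lte(max(v), 30 + 1e-9)
  # no third plateau: every voxel lies between air and body values
  expect_gte(min(v), -1000 - 1e-9)
})

test_that("phantom spec validation", {
  expect_error(phantom_spec(shape = c(4L, 24L, 24L)), "dims >= 8")
  expect_error(phantom_spec(intensity_range = c(10, -10)), "ordered")
})

test_that("projection pipeline approaches its noiseless limit as photons grow", {
  p <- small_phantom(seed = 2L, shape = c(8L, 32L, 32L))
  ref <- fbp_reference(p, dose_spec())
  ld <- simulate_low_dose(p, dose_spec(dose_factor = 1,
                                       incident_photons = 1e12, seed = 4L))
  expect_equal(dim(ld), dim(p))
  expect_lt(mean(abs(ld$intensities - ref$intensities)), 1)
  # ...and the noiseless reconstruction itself is close to the phantom
  expect_lt(sqrt(mean((ref$intensities - p$intensities)^2)), 40)
})

test_that("projection-Poisson noise grows as dose falls (Monte-Carlo)", {
  p <- small_phantom(seed = 3L, shape = c(20L, 24L, 24L))  # >= 20 slices
  ref <- fbp_reference(p, dose_spec())
  sd_q <- sd(simulate_low_dose(p, dose_spec(dose_factor = 0.25,
                                            seed = 7L))$intensities -
               ref$intensities)
  sd_f <- sd(simulate_low_dose(p, dose_spec(dose_factor = 1,
                                            seed = 7L))$intensities -
               ref$intensities)
  expect_gt(sd_q, sd_f)
  expect_equal(sd_q / sd_f, 2, tolerance = 0.25)
})

test_that("gaussian mode: variance ratio 4 between quarter and full dose", {
  p <- ct_volume(array(0, c(12L, 32L, 32L)))  # >= 1e4 voxels
  g <- function(df, seed) {
    simulate_low_dose(p, dose_spec(dose_factor = df, seed = seed,
                                   noise_mode = "image_gaussian"))
  }
  vq <- stats::var(as.numeric(g(0.25, 5L)$intensities))
  vf <- stats::var(as.numeric(g(1, 6L)$intensities))
  expect_equal(vq / vf, 4, tolerance = 0.2 * 4)
  # pure function: the clean input is untouched
  expect_identical(p$intensities, array(0, c(12L, 32L, 32L)))
})

test_that("dose spec validation", {
  expect_error(dose_spec(dose_factor = 0), "dose_factor")
  expect_error(dose_spec(dose_factor = 1.5), "dose_factor")
  expect_error(dose_spec(incident_photons = -1), "incident_photons")
})

test_that("unpaired dataset pooling, counts and shuffling", {
  w <- tiny_world(n = 2L, shape = c(8L, 16L, 16L))
  ds <- build_unpaired_dataset(w$ld, w$hd, "axial", shuffle_seed = 3L)
  expect_length(ds$low, 16L)   # 2 volumes x 8 axial slices
  expect_false(ds$paired)
  ds_s <- build_unpaired_dataset(w$ld, w$hd, "sagittal", shuffle_seed = 3L)
  expect_length(ds_s$low, 32L) # 2 volumes x 16 sagittal slices
  # reproducible per seed
  ds2 <- build_unpaired_dataset(w$ld, w$hd, "axial", shuffle_seed = 3L)
  expect_identical(ds$low, ds2$low)
  # single-volume axial example
  one <- ct_volume(array(rnorm(10 * 16 * 16), c(10, 16, 16)))
  expect_length(build_unpaired_dataset(list(one), list(one), "axial")$low,
                10L)
})

test_that("shuffling destroys the low/high index correspondence", {
  w <- tiny_world(n = 4L, shape = c(10L, 16L, 16L))
  paired <- build_unpaired_dataset(w$ld, w$hd, "axial", shuffle = FALSE)
  mlow <- vapply(paired$low, mean, numeric(1))
  mhigh <- vapply(paired$high, mean, numeric(1))
  expect_gt(cor(mlow, mhigh), 0.9)  # paired slices track each other
  shuf <- build_unpaired_dataset(w$ld, w$hd, "axial", shuffle_seed = 11L)
  expect_true(paired$paired)
  expect_lt(abs(cor(vapply(shuf$low, mean, numeric(1)),
                    vapply(shuf$high, mean, numeric(1)))), 0.5)
})

test_that("mixed in-plane shapes are rejected", {
  a <- ct_volume(array(0, c(4, 16, 16)))
  b <- ct_volume(array(0, c(4, 12, 16)))
  expect_error(build_unpaired_dataset(list(a, b), list(a, b), "axial"),
               "mixed in-plane shapes")
  expect_error(build_unpaired_dataset(list(), list(a), "axial"),
               "nonempty")
})
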