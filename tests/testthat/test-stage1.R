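# constant-offset translation model built from zeroed RED-CNNs; the
# low->high generator adds `c` (normalised units), everything else identity
offset_model <- function(view, c_l2h = 0, c_h2l = 0) {
  new_translation_model(offset_generator(c_l2h), offset_generator(c_h2l),
                        build_discriminator(tiny_disc_spec(), seed = 1),
                        build_discriminator(tiny_disc_spec(), seed = 2),
                        view, stage1_config(patch_size = 16L),
                        tiny_gen_spec("redcnn"), tiny_disc_spec(),
                        data.frame())
}

test_that("tiny smoke training run: finite losses, deterministic per seed", {
  w <- tiny_world(n = 2L, shape = c(8L, 24L, 24L))
  ds <- build_unpaired_dataset(w$ld, w$hd, "axial", shuffle_seed = 4L)
  cfg <- stage1_config(patch_size = 16L, batch_size = 2L,
                       patches_per_iteration = 1L, epochs = 2L,
                       learning_rate = 1e-3, seed = 5L,
                       iters_per_epoch = 3L)
  m1 <- train_view_model(ds, cfg, tiny_gen_spec("rescnn"),
                         tiny_disc_spec())
  expect_s3_class(m1, "mv_translation_model")
  expect_equal(nrow(m1$history), 6L)
  expect_true(all(is.finite(as.matrix(m1$history))))
  expect_true(all(m1$history$cycle >= 0 & m1$history$gan_g >= 0))
  m2 <- train_view_model(ds, cfg, tiny_gen_spec("rescnn"),
                         tiny_disc_spec())
  expect_identical(m1$history, m2$history)          # bit-identical losses
  x <- matrix(rnorm(24 * 24), 24)
  expect_identical(net_apply(m1$G_xy, x), net_apply(m2$G_xy, x))
})

test_that("training rejects invalid configurations", {
  w <- tiny_world(n = 1L, shape = c(8L, 16L, 16L))
  ds <- build_unpaired_dataset(w$ld, w$hd, "axial")
  cfg_big <- stage1_config(patch_size = 64L)
  expect_error(train_view_model(ds, cfg_big, tiny_gen_spec("rescnn")),
               "patch size")
  ds_paired <- build_unpaired_dataset(w$ld, w$hd, "axial",
                                      shuffle = FALSE)
  expect_error(train_view_model(ds_paired, stage1_config(patch_size = 16L),
                                tiny_gen_spec("rescnn")), "unpaired")
  expect_error(stage1_config(patch_size = 4L), "positive")
})

test_that("denoise_volume applies the generator slice-wise per view", {
  v <- small_phantom(seed = 4L, shape = c(8L, 20L, 20L))
  for (view in c("axial", "sagittal", "coronal")) {
    m <- offset_model(view)
    out <- denoise_volume(m, v, "l2h")
    expect_equal(dim(out), dim(v))
    expect_equal(out$intensities, v$intensities, tolerance = 1e-10)
  }
  # constant offset in normalised units scales to HU through the window
  mc <- offset_model("axial", c_l2h = 0.1)
  out <- denoise_volume(mc, v, "l2h")
  expect_equal(out$intensities, v$intensities + 0.1 * 1400 / 2,
               tolerance = 1e-8)
  # h2l direction routes through G_yx
  mh <- offset_model("axial", c_l2h = 0.5, c_h2l = -0.2)
  out2 <- denoise_volume(mh, v, "h2l")
  expect_equal(out2$intensities, v$intensities - 0.2 * 1400 / 2,
               tolerance = 1e-8)
})

test_that("view-complementary prediction triples align axial slices", {
  v <- small_phantom(seed = 6L, shape = c(8L, 20L, 20L))
  cs <- c(axial = 0.02, sagittal = 0.04, coronal = 0.08)
  models <- lapply(names(cs), function(vw) offset_model(vw, cs[[vw]]))
  triples <- generate_view_complementary_predictions(models, v, "l2h")
  expect_length(triples, 8L)  # one per axial slice
  ax <- resplit_axial(v)$slices
  for (i in c(1L, 3L, 5L)) {
    tr <- triples[[i]]
    expect_equal(tr$from_axial, ax[[i]] + 0.02 * 700, tolerance = 1e-8)
    expect_equal(tr$from_sagittal, ax[[i]] + 0.04 * 700, tolerance = 1e-8)
    expect_equal(tr$from_coronal, ax[[i]] + 0.08 * 700, tolerance = 1e-8)
    expect_equal(tr$axial_index$index, i - 1L)
  }
  # identity models: every triple equals the input axial slice
  id_models <- lapply(c("axial", "sagittal", "coronal"), offset_model)
  tid <- generate_view_complementary_predictions(id_models, v, "l2h")
  expect_equal(tid[[2]]$from_sagittal, ax[[2]], tolerance = 1e-10)
  # the axial component equals direct application of the axial model
  expect_equal(tid[[4]]$from_axial,
               resplit_axial(denoise_volume(id_models[[1]], v,
                                            "l2h"))$slices[[4]],
               tolerance = 1e-12)
  expect_error(generate_view_complementary_predictions(id_models[1:2], v),
               "one model per view")
})
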