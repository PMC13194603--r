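test_that("stage-2 objective arithmetic and limits", {
  expect_equal(stage2_generator_objective(0.5, 0.2, 0.1), 3)
  expect_equal(stage2_generator_objective(0, 0, 0), 0)
  # lambda3 = 0 reduces exactly to the stage-1 form on the same components
  gan <- 0.37; cyc <- 0.11
  expect_equal(stage2_generator_objective(gan, cyc, 99, lambda3 = 0),
               stage1_generator_objective(gan, 0, cyc) - 0)
  expect_error(stage2_generator_objective(1, 1, 1, lambda1 = -2),
               "nonnegative")
})

test_that("pseudo-supervised loss closed forms", {
  idf <- function(m) m
  x <- matrix(runif(36, -1, 1), 6); y <- matrix(runif(36, -1, 1), 6)
  # outputs equal to the pseudo-targets -> 0
  expect_equal(pseudo_supervised_loss(x, y, x, y, idf, idf), 0)
  # constant offsets c1, c2 between outputs and targets -> |c1| + |c2|
  expect_equal(pseudo_supervised_loss(x, y, x + 0.3, y - 0.2,
                                      idf, idf), 0.5)
  # symmetric under joint negation
  g <- function(m) 0.5 * m
  v1 <- pseudo_supervised_loss(x, y, x * 0.9, y * 1.1, g, g)
  v2 <- pseudo_supervised_loss(-x, -y, -x * 0.9, -y * 1.1,
                               function(m) 0.5 * m, function(m) 0.5 * m)
  expect_equal(v1, v2)
  expect_error(pseudo_supervised_loss(x, y, x[1:3, ], y, idf, idf),
               "shape|align")
})

test_that("prediction stores pair slices with aligned triples", {
  w <- tiny_world(n = 2L, shape = c(8L, 20L, 20L))
  id_models <- lapply(c("axial", "sagittal", "coronal"), function(v) {
    new_translation_model(offset_generator(0), offset_generator(0),
                          build_discriminator(tiny_disc_spec(), seed = 1),
                          build_discriminator(tiny_disc_spec(), seed = 2),
                          v, stage1_config(patch_size = 16L),
                          tiny_gen_spec("redcnn"), tiny_disc_spec(),
                          data.frame())
  })
  store <- build_prediction_store(id_models, w$ld, "l2h")
  expect_s3_class(store, "mv_prediction_store")
  expect_length(store, 16L)  # 2 volumes x 8 axial slices
  e <- store[[3]]
  expect_equal(dim(e$real), dim(e$triple$from_axial))
  # identity teachers: predictions equal the real slice, so any fused
  # pseudo-target equals the teacher prediction regardless of weights
  expect_equal(e$triple$from_sagittal, e$real, tolerance = 1e-10)
  diffs <- cycle_difference_maps(e$triple, e$real, function(m) m * 0.7)
  fused <- weighted_fuse(e$triple, weight_maps_from_diffs(diffs))
  expect_equal(fused, e$triple$from_axial, tolerance = 1e-12)
})

test_that("student smoke training: finite, deterministic, dynamic weights", {
  w <- tiny_world(n = 2L, shape = c(8L, 24L, 24L))
  # slightly disagreeing teachers so fusion weights are informative
  teachers <- lapply(seq_along(VIEW_TAGS), function(i) {
    new_translation_model(offset_generator(0.01 * i),
                          offset_generator(-0.01 * i),
                          build_discriminator(tiny_disc_spec(), seed = 1),
                          build_discriminator(tiny_disc_spec(), seed = 2),
                          VIEW_TAGS[i], stage1_config(patch_size = 16L),
                          tiny_gen_spec("redcnn"), tiny_disc_spec(),
                          data.frame())
  })
  l2h <- build_prediction_store(teachers, w$ld, "l2h")
  h2l <- build_prediction_store(teachers, w$hd, "h2l")
  ds <- build_unpaired_dataset(w$ld, w$hd, "axial", shuffle_seed = 2L)
  cfg <- stage2_config(patch_size = 16L, batch_size = 2L,
                       patches_per_iteration = 2L, epochs = 1L,
                       learning_rate = 1e-3, seed = 3L,
                       iters_per_epoch = 4L)
  st1 <- train_single_view(ds, l2h, h2l, cfg,
                           tiny_gen_spec("redcnn"), tiny_disc_spec())
  expect_equal(nrow(st1$history), 4L)
  expect_true(all(is.finite(as.matrix(st1$history))))
  expect_true(all(c("rec", "w_a", "w_s", "w_c") %in%
                    colnames(st1$history)))
  # reproducibility
  st2 <- train_single_view(ds, l2h, h2l, cfg,
                           tiny_gen_spec("redcnn"), tiny_disc_spec())
  expect_identical(st1$history, st2$history)
  # fusion weights are per-pixel maps recomputed each iteration with the
  # evolving student inverse generator: they must not stay constant
  wh <- st1$weight_history
  expect_length(wh, 4L)
  expect_equal(wh[[1]]$w_a + wh[[1]]$w_s + wh[[1]]$w_c,
               matrix(1, 16, 16))
  changes <- vapply(2:4, function(i) {
    max(abs(wh[[i]]$w_a - wh[[1]]$w_a))
  }, numeric(1))
  expect_gt(max(changes), 0)
})

test_that("stage-2 validates its inputs", {
  w <- tiny_world(n = 1L, shape = c(8L, 16L, 16L))
  ds_sag <- build_unpaired_dataset(w$ld, w$hd, "sagittal")
  dummy <- structure(list(), class = "mv_prediction_store")
  expect_error(train_single_view(ds_sag, dummy, dummy,
                                 stage2_config(patch_size = 8L)),
               "axial")
  ds <- build_unpaired_dataset(w$ld, w$hd, "axial")
  expect_error(train_single_view(ds, dummy, dummy,
                                 stage2_config(patch_size = 8L)),
               "nonempty")
})

test_that("denoise_axial is the single-model inference path", {
  v <- small_phantom(seed = 8L, shape = c(8L, 20L, 20L))
  student <- new_translation_model(
    offset_generator(0), offset_generator(0),
    build_discriminator(tiny_disc_spec(), seed = 1),
    build_discriminator(tiny_disc_spec(), seed = 2),
    "axial", stage2_config(patch_size = 16L), tiny_gen_spec("redcnn"),
    tiny_disc_spec(), data.frame())
  out <- denoise_axial(student, v)
  expect_equal(dim(out), dim(v))
  expect_equal(out$intensities, v$intensities, tolerance = 1e-10)
  # identical to the generic stage-1 inference path on the same weights
  expect_equal(out$intensities,
               denoise_volume(student, v, "l2h")$intensities)
  sag <- student; sag$view <- "sagittal"
  expect_error(denoise_axial(sag, v), "axial")
})
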