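# shared fixtures: everything is generated in code at test time

rand_volume <- function(shape = c(4L, 5L, 6L), seed = 1L, id = "v") {
  withr::with_seed(seed, {
    ct_volume(array(rnorm(prod(shape)), dim = shape), id = id)
  })
}

tiny_gen_spec <- function(family = "rescnn") {
  if (family == "rescnn") {
    generator_spec("rescnn", base_channels = c(4L, 8L, 16L),
                   n_residual_blocks = 1L)
  } else {
    generator_spec("redcnn", redcnn_channels = 8L, redcnn_depth = 3L,
                   redcnn_kernel = 3L)
  }
}

tiny_disc_spec <- function() discriminator_spec(2L, 8L)

# a RED-CNN generator that computes exactly  x + c  (the final deconv is
# zeroed so only the input shortcut survives)
offset_generator <- function(c = 0, spec = tiny_gen_spec("redcnn")) {
  g <- build_generator(spec, seed = 1L)
  last <- paste0("dec", spec$redcnn_depth)
  g$layers[[last]]$w[] <- 0
  g$layers[[last]]$b[] <- c
  g
}

# deterministic texture pair used for frozen-oracle metric tests
oracle_images <- function() {
  i <- 1:40
  ref <- 100 * outer(sin(i / 5), cos(i / 7)) +
    50 * outer(cos(i / 3), sin(i / 11))
  pred <- ref + 20 * outer(sin(i / 2), sin(i / 4))
  list(pred = pred, ref = ref)
}

small_phantom <- function(seed = 1L, shape = c(8L, 32L, 32L)) {
  generate_phantom(phantom_spec(shape = shape, seed = seed))
}

# paired tiny train/test world with fast image-domain noise
tiny_world <- function(n = 3L, shape = c(8L, 32L, 32L), seed = 1L) {
  hd <- lapply(seq_len(n), function(i) {
    generate_phantom(phantom_spec(shape = shape, seed = seed * 100L + i))
  })
  ld <- lapply(seq_len(n), function(i) {
    simulate_low_dose(hd[[i]], dose_spec(noise_mode = "image_gaussian",
                                         seed = seed * 100L + 50L + i))
  })
  list(hd = hd, ld = ld)
}
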