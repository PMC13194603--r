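#' Scaled-down end-to-end experiment on synthetic phantoms
#'
#' Runs the whole two-stage pipeline at desk scale: generates `n_train +
#' n_test` anisotropic phantoms with quarter-dose projection-Poisson
#' low-dose counterparts, trains the three tiny view models on the
#' unpaired training pools, measures their held-out denoising PSNR,
#' precomputes teacher prediction stores, trains the pseudo-supervised
#' student with the same budget, and evaluates everything on the held-out
#' paired volumes. The stage-1 axial model doubles as the axial-only
#' baseline (same budget, same data).
#'
#' Defaults are a deliberately tiny stated world (small channels, 16 px
#' patches, 1000 iterations at Adam 1e-3/0.5 with gradient clipping)
#' chosen to fit a single CPU; see the methods vignette for the
#' reasoning. Reference-scale defaults of
#' [stage1_config()]/[stage2_config()] are not used here.
#'
#' @param seed master seed; all phantom, dose, shuffling and training
#'   seeds derive from it.
#' @param n_train,n_test number of training / held-out phantoms.
#' @param shape phantom dimensions (z, y, x).
#' @param dose_factor,incident_photons low-dose simulation severity.
#' @param n_iters stage-1 training iterations per view model.
#' @param grad_clip global gradient-norm clip for all desk-scale training
#'   (see [stage1_config()]).
#' @param n_iters_student stage-2 iterations (default: same budget).
#' @param learning_rate Adam step size for the desk-scale runs.
#' @param batch_size,patches_per_iteration,patch_size sampling geometry.
#' @param gen_spec,student_spec,disc_spec tiny architecture specs.
#' @param verbose print per-epoch progress.
#' @return A list with elements `psnr` (named vector: `input`, `axial`,
#'   `sagittal`, `coronal`, `baseline`, `student`), `summaries` (per-model
#'   [evaluate_testset()] summaries), `student` (the trained student,
#'   including `$weight_history`), and `models` (the stage-1 models).
#' @export
desk_experiment <- function(seed = 1L, n_train = 10L, n_test = 2L,
                            shape = c(64L, 64L, 64L), dose_factor = 0.25,
                            incident_photons = 2e4, n_iters = 1000L,
                            n_iters_student = n_iters, grad_clip = 0.5,
                            learning_rate = 1e-3, batch_size = 5L,
                            patches_per_iteration = 1L, patch_size = 16L,
                            gen_spec = generator_spec(
                              "rescnn", base_channels = c(4L, 8L, 16L),
                              n_residual_blocks = 1L, global_skip = TRUE,
                              out_init_gain = 0.1),
                            student_spec = generator_spec(
                              "redcnn", redcnn_channels = 12L,
                              redcnn_depth = 3L, redcnn_kernel = 3L,
                              out_init_gain = 0.1),
                            disc_spec = discriminator_spec(
                              2L, 12L, norm = "none"),
                            verbose = FALSE) {
  seed <- as.integer(seed)
  n_all <- n_train + n_test
  say <- function(...) if (verbose) message(sprintf(...))

  say("generating %d phantoms (%s) ...", n_all,
      paste(shape, collapse = "x"))
  hd <- lapply(seq_len(n_all), function(i) {
    generate_phantom(phantom_spec(shape = shape, seed = seed * 1000L + i))
  })
  ld <- lapply(seq_len(n_all), function(i) {
    simulate_low_dose(hd[[i]], dose_spec(
      dose_factor = dose_factor, incident_photons = incident_photons,
      seed = seed * 1000L + 500L + i))
  })
  tr <- seq_len(n_train)
  te <- n_train + seq_len(n_test)
  test_pairs <- lapply(te, function(i) list(low = ld[[i]],
                                            high = hd[[i]]))

  s1cfg <- function(view_idx) {
    stage1_config(patch_size = patch_size, batch_size = batch_size,
                  patches_per_iteration = patches_per_iteration,
                  epochs = 1L, learning_rate = learning_rate,
                  seed = seed * 100L + view_idx, grad_clip = grad_clip,
                  iters_per_epoch = as.integer(n_iters))
  }
  models <- list()
  for (vi in seq_along(VIEW_TAGS)) {
    view <- VIEW_TAGS[vi]
    say("stage 1: training %s view model (%d iterations) ...", view,
        n_iters)
    dsv <- build_unpaired_dataset(ld[tr], hd[tr], view,
                                  shuffle_seed = seed * 10L + vi)
    models[[view]] <- train_view_model(dsv, s1cfg(vi), gen_spec,
                                       disc_spec, verbose = verbose)
  }

  say("evaluating stage-1 models on %d held-out volumes ...", n_test)
  summaries <- list(
    input = evaluate_testset("identity", test_pairs)$summary)
  for (view in VIEW_TAGS) {
    summaries[[view]] <- evaluate_testset(models[[view]],
                                          test_pairs)$summary
  }

  say("stage 1: generating teacher prediction stores ...")
  l2h_store <- build_prediction_store(models, ld[tr], "l2h")
  h2l_store <- build_prediction_store(models, hd[tr], "h2l")

  say("stage 2: training the student (%d iterations) ...",
      n_iters_student)
  axial_ds <- build_unpaired_dataset(ld[tr], hd[tr], "axial",
                                     shuffle_seed = seed * 10L + 7L)
  s2cfg <- stage2_config(patch_size = patch_size,
                         batch_size = batch_size,
                         patches_per_iteration = patches_per_iteration,
                         epochs = 1L, learning_rate = learning_rate,
                         seed = seed * 100L + 9L, grad_clip = grad_clip,
                         iters_per_epoch = as.integer(n_iters_student))
  student <- train_single_view(axial_ds, l2h_store, h2l_store, s2cfg,
                               student_spec, disc_spec,
                               verbose = verbose)
  summaries$student <- evaluate_testset(student, test_pairs)$summary

  get_psnr <- function(s) s$mean[s$metric == "psnr"]
  psnr_out <- c(input = get_psnr(summaries$input),
                axial = get_psnr(summaries$axial),
                sagittal = get_psnr(summaries$sagittal),
                coronal = get_psnr(summaries$coronal),
                baseline = get_psnr(summaries$axial),
                student = get_psnr(summaries$student))
  say("PSNR: %s", paste(sprintf("%s %.2f", names(psnr_out), psnr_out),
                        collapse = ", "))
  list(psnr = psnr_out, summaries = summaries, student = student,
       models = models)
}
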