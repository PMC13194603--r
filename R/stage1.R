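#' Stage-1 training configuration
#'
#' Defaults follow the reference training recipe: 256x256 patches, batches
#' of 5 slices with 2 random patches cropped per slice (10 patches per
#' step), Adam at learning rate 1e-5, cycle weight 10, 100 epochs. Those
#' values assume GPU-scale training; desk-scale runs pass smaller values
#' explicitly.
#'
#' @param patch_size square crop side in pixels.
#' @param batch_size slices sampled per iteration from each pool.
#' @param patches_per_iteration random crops per sampled slice.
#' @param epochs passes over the (smaller) pool.
#' @param learning_rate Adam step size.
#' @param lambda cycle-consistency weight.
#' @param seed reproducibility seed for init, sampling and cropping.
#' @param beta1 Adam first-moment decay (0.5, the usual GAN setting).
#' @param iters_per_epoch optional override of iterations per epoch
#'   (default: pool size / batch size).
#' @param grad_clip global gradient-norm clip applied before every Adam
#'   step (default `Inf`, i.e. off); desk-scale adversarial runs use a
#'   finite value to prevent occasional training collapse.
#' @return An object of class `mv_stage1_config`.
#' @export
stage1_config <- function(patch_size = 256L, batch_size = 5L,
                          patches_per_iteration = 2L, epochs = 100L,
                          learning_rate = 1e-5, lambda = 10, seed = 1L,
                          beta1 = 0.5, iters_per_epoch = NULL,
                          grad_clip = Inf) {
  stop_if_not(patch_size >= 8 && batch_size >= 1 &&
                patches_per_iteration >= 1 && epochs >= 1 &&
                learning_rate > 0 && lambda >= 0,
              "config values must be positive (lambda nonnegative)")
  structure(list(patch_size = as.integer(patch_size),
                 batch_size = as.integer(batch_size),
                 patches_per_iteration = as.integer(patches_per_iteration),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate, lambda = lambda,
                 seed = as.integer(seed), beta1 = beta1,
                 iters_per_epoch = iters_per_epoch,
                 grad_clip = grad_clip),
            class = "mv_stage1_config")
}

new_translation_model <- function(G_xy, G_yx, D_x, D_y, view, config,
                                  gen_spec, disc_spec, history,
                                  hu_window = HU_WINDOW, extra = list()) {
  structure(c(list(G_xy = G_xy, G_yx = G_yx, D_x = D_x, D_y = D_y,
                   view = view, config = config, gen_spec = gen_spec,
                   disc_spec = disc_spec, history = history,
                   hu_window = hu_window), extra),
            class = "mv_translation_model")
}

#' @export
print.mv_translation_model <- function(x, ...) {
  cat(sprintf("<translation model: view %s, %s generators, %d iterations trained>\n",
              x$view, x$gen_spec$family, nrow(x$history)))
  invisible(x)
}

# one generator pass on normalised patch batches xs, ys (lists of
# matrices, batched into single 4D forwards); returns loss nodes, scalar
# components and the detached fakes for the discriminator step
cyclegan_g_steps <- function(tp, G_xy, G_yx, D_x, D_y, xs, ys) {
  xb <- op_input(tp, xs)
  yb <- op_input(tp, ys)
  fx <- G_xy$forward(tp, xb)
  cyc_x <- op_l1(tp, G_yx$forward(tp, fx), xb)
  gan_x <- op_mse_const(tp, D_y$forward(tp, fx), 1)
  fy <- G_yx$forward(tp, yb)
  cyc_y <- op_l1(tp, G_xy$forward(tp, fy), yb)
  gan_y <- op_mse_const(tp, D_x$forward(tp, fy), 1)
  list(nodes = list(cyc_x, gan_x, cyc_y, gan_y),
       cyc = cyc_x$value + cyc_y$value,
       gan = 0.5 * (gan_x$value + gan_y$value),
       fakes_y = fx$value, fakes_x = fy$value,
       xb = xb$value, yb = yb$value)
}

# alternating update, part 2: discriminators on reals vs detached fakes
# (xb/yb/fakes are 4D batches); returns the summed LSGAN D losses
discriminator_step <- function(D_x, D_y, xb, yb, fakes_x, fakes_y, opt_d) {
  tp <- tape_new()
  nodes <- list(
    op_mse_const(tp, D_y$forward(tp, op_input(tp, yb)), 1),
    op_mse_const(tp, D_y$forward(tp, op_input(tp, fakes_y)), 0),
    op_mse_const(tp, D_x$forward(tp, op_input(tp, xb)), 1),
    op_mse_const(tp, D_x$forward(tp, op_input(tp, fakes_x)), 0))
  total <- op_wsum(tp, nodes, rep(0.5, 4))
  net_reset_grads(D_x); net_reset_grads(D_y)
  tape_backward(tp, total)
  adam_step(opt_d)
  total$value
}

sample_patch_batch <- function(pool, n_slices, n_patches, patch) {
  idx <- sample.int(length(pool), n_slices, replace = length(pool) < n_slices)
  out <- list()
  for (i in idx) {
    for (p in seq_len(n_patches)) {
      cc <- crop_coords(dim(pool[[i]]), patch)
      out[[length(out) + 1L]] <- pool[[i]][cc$rows, cc$cols, drop = FALSE]
    }
  }
  out
}

#' Train one view-independent unpaired translation model
#'
#' CycleGAN-style training on one view's unpaired slice pools: two
#' generators (low-to-high, high-to-low) and two PatchGAN discriminators,
#' optimised alternately (generators with discriminators frozen, then
#' discriminators on the detached fakes) with the least-squares adversarial
#' loss plus `lambda` times the cycle-consistency loss. Slices are
#' intensity-normalised from `hu_window` to \[-1, 1\] at the data boundary;
#' training crops random patches, inference (see [denoise_volume()]) runs
#' on full slices.
#'
#' @param dataset an unpaired [build_unpaired_dataset()] result whose view
#'   matches the intended model view.
#' @param config a [stage1_config()].
#' @param gen_spec a [generator_spec()] (the reference setup uses
#'   `rescnn`).
#' @param disc_spec a [discriminator_spec()].
#' @param hu_window intensity window mapped to \[-1, 1\].
#' @param verbose print a loss line per epoch.
#' @return An object of class `mv_translation_model` with the four
#'   networks and a per-iteration `history` data frame (columns `iter`,
#'   `cycle`, `gan_g`, `gan_d`, `total`).
#' @export
train_view_model <- function(dataset, config, gen_spec,
                             disc_spec = discriminator_spec(),
                             hu_window = HU_WINDOW, verbose = FALSE) {
  stop_if_not(inherits(dataset, "mv_unpaired_dataset"),
              "dataset must come from build_unpaired_dataset()")
  stop_if_not(!dataset$paired, "training dataset must be unpaired")
  stop_if_not(inherits(config, "mv_stage1_config"),
              "config must be a stage1_config()")
  hw <- dim(dataset$low[[1]])
  stop_if_not(config$patch_size <= min(hw),
              sprintf("patch size %d exceeds slice dims %d x %d",
                      config$patch_size, hw[1], hw[2]))
  with_seed(config$seed, {
    G_xy <- build_generator(gen_spec)
    G_yx <- build_generator(gen_spec)
    D_x <- build_discriminator(disc_spec)
    D_y <- build_discriminator(disc_spec)
    opt_g <- adam_new(list(G_xy, G_yx), lr = config$learning_rate,
                      beta1 = config$beta1, clip = config$grad_clip)
    opt_d <- adam_new(list(D_x, D_y), lr = config$learning_rate,
                      beta1 = config$beta1, clip = config$grad_clip)
    low <- lapply(dataset$low, normalize_hu, window = hu_window)
    high <- lapply(dataset$high, normalize_hu, window = hu_window)
    iters <- config$iters_per_epoch %||%
      max(1L, min(length(low), length(high)) %/% config$batch_size)
    hist <- vector("list", config$epochs * iters)
    step <- 0L
    for (ep in seq_len(config$epochs)) {
      for (it in seq_len(iters)) {
        step <- step + 1L
        xs <- sample_patch_batch(low, config$batch_size,
                                 config$patches_per_iteration,
                                 config$patch_size)
        ys <- sample_patch_batch(high, config$batch_size,
                                 config$patches_per_iteration,
                                 config$patch_size)
        tp <- tape_new()
        gs <- cyclegan_g_steps(tp, G_xy, G_yx, D_x, D_y, xs, ys)
        total <- op_wsum(tp, gs$nodes,
                         c(config$lambda, 0.5, config$lambda, 0.5))
        net_reset_grads(G_xy); net_reset_grads(G_yx)
        net_reset_grads(D_x); net_reset_grads(D_y)
        tape_backward(tp, total)
        adam_step(opt_g)
        d_loss <- discriminator_step(D_x, D_y, gs$xb, gs$yb, gs$fakes_x,
                                     gs$fakes_y, opt_d)
        rep_ <- loss_report(gs$cyc, gs$gan, d_loss, config$lambda)
        if (!all(is.finite(c(rep_$total, d_loss)))) {
          stop(sprintf("non-finite loss at iteration %d (cycle %.3g, gan %.3g, d %.3g)",
                       step, gs$cyc, gs$gan, d_loss), call. = FALSE)
        }
        hist[[step]] <- data.frame(iter = step, cycle = rep_$cycle,
                                   gan_g = rep_$gan_g, gan_d = rep_$gan_d,
                                   total = rep_$total)
      }
      if (verbose) {
        h <- hist[[step]]
        message(sprintf("[%s] epoch %d/%d: cycle %.4f gan_g %.4f gan_d %.4f",
                        dataset$view, ep, config$epochs, h$cycle, h$gan_g,
                        h$gan_d))
      }
    }
    new_translation_model(G_xy, G_yx, D_x, D_y, dataset$view, config,
                          gen_spec, disc_spec, do.call(rbind, hist),
                          hu_window)
  })
}

#' Denoise a volume with one view model
#'
#' Splits the volume along the model's view, applies the chosen generator
#' slice by slice (full-slice inference, no patching) and stacks the
#' results back; shape is preserved.
#'
#' @param model an `mv_translation_model`.
#' @param volume a [ct_volume()].
#' @param direction `"l2h"` (apply `G_xy`, the denoiser) or `"h2l"`.
#' @return A [ct_volume()] of identical shape.
#' @export
denoise_volume <- function(model, volume, direction = c("l2h", "h2l")) {
  stop_if_not(inherits(model, "mv_translation_model"),
              "model must be a translation model")
  direction <- match.arg(direction)
  gen <- if (direction == "l2h") model$G_xy else model$G_yx
  ss <- split_volume(volume, model$view)
  norm <- lapply(ss$slices, normalize_hu, window = model$hu_window)
  out_slices <- vector("list", length(norm))
  chunk <- 16L  # batched inference in chunks to bound memory
  for (i0 in seq(1L, length(norm), by = chunk)) {
    idx <- i0:min(i0 + chunk - 1L, length(norm))
    out_slices[idx] <- net_apply_batch(gen, norm[idx])
  }
  ss$slices <- lapply(out_slices, denormalize_hu,
                      window = model$hu_window)
  out <- stack_slices(ss)
  out$id <- paste0(volume$id, "-", model$view, "-", direction)
  out
}

#' Generate view-complementary predictions for every axial slice
#'
#' Runs [denoise_volume()] with each of the three view models, re-splits
#' each denoised volume axially and aligns the three axial slices per index
#' into [view_prediction_triple()]s. With `direction = "h2l"` this builds
#' the low-dose predictions for a high-dose volume.
#'
#' @param models list of three trained `mv_translation_model`s covering
#'   axial, sagittal and coronal.
#' @param volume a [ct_volume()].
#' @param direction `"l2h"` or `"h2l"`.
#' @return List of `mv_prediction_triple`, one per axial slice.
#' @export
generate_view_complementary_predictions <- function(models, volume,
                                                    direction = c("l2h", "h2l")) {
  direction <- match.arg(direction)
  views <- vapply(models, function(m) m$view, character(1))
  stop_if_not(setequal(views, VIEW_TAGS) && length(models) == 3L,
              "need exactly one model per view (axial, sagittal, coronal)")
  names(models) <- views
  den <- lapply(models, denoise_volume, volume = volume,
                direction = direction)
  ax <- lapply(den, function(v) resplit_axial(v)$slices)
  n <- dim(volume)[1]
  lapply(seq_len(n), function(i) {
    view_prediction_triple(ax$axial[[i]], ax$sagittal[[i]], ax$coronal[[i]],
                           axial_index = list(id = volume$id,
                                              index = i - 1L),
                           direction = direction)
  })
}

#' Save / load a translation model checkpoint
#'
#' Checkpoints store the architecture specs together with all weights and
#' round-trip losslessly.
#'
#' @param model an `mv_translation_model`.
#' @param path file path (RDS).
#' @return `save_model` the path invisibly; `load_model` the rebuilt model.
#' @export
save_model <- function(model, path) {
  stop_if_not(inherits(model, "mv_translation_model"),
              "model must be a translation model")
  obj <- list(view = model$view, config = model$config,
              gen_spec = model$gen_spec, disc_spec = model$disc_spec,
              history = model$history, hu_window = model$hu_window,
              weights = lapply(model[c("G_xy", "G_yx", "D_x", "D_y")],
                               net_get_weights))
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  G_xy <- build_generator(obj$gen_spec)
  G_yx <- build_generator(obj$gen_spec)
  D_x <- build_discriminator(obj$disc_spec)
  D_y <- build_discriminator(obj$disc_spec)
  net_set_weights(G_xy, obj$weights$G_xy)
  net_set_weights(G_yx, obj$weights$G_yx)
  net_set_weights(D_x, obj$weights$D_x)
  net_set_weights(D_y, obj$weights$D_y)
  new_translation_model(G_xy, G_yx, D_x, D_y, obj$view, obj$config,
                        obj$gen_spec, obj$disc_spec, obj$history,
                        obj$hu_window)
}
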