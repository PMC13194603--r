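#' Stage-2 training configuration
#'
#' Defaults follow the reference recipe for the single-view student:
#' 64x64 patches, batches of 3 slices with 10 patches per slice, Adam at
#' 1e-5, balance factors `lambda1 = 1` (adversarial), `lambda2 = 10`
#' (cycle), `lambda3 = 5` (pseudo-supervision), 100 epochs.
#'
#' @inheritParams stage1_config
#' @param lambda1,lambda2,lambda3 nonnegative balance factors of the
#'   adversarial, cycle and pseudo-supervised terms.
#' @return An object of class `mv_stage2_config`.
#' @export
stage2_config <- function(patch_size = 64L, batch_size = 3L,
                          patches_per_iteration = 10L, epochs = 100L,
                          learning_rate = 1e-5, lambda1 = 1, lambda2 = 10,
                          lambda3 = 5, seed = 1L, beta1 = 0.5,
                          iters_per_epoch = NULL, grad_clip = Inf) {
  stop_if_not(patch_size >= 8 && batch_size >= 1 &&
                patches_per_iteration >= 1 && epochs >= 1 &&
                learning_rate > 0 &&
                all(c(lambda1, lambda2, lambda3) >= 0),
              "config values must be positive (lambdas nonnegative)")
  structure(list(patch_size = as.integer(patch_size),
                 batch_size = as.integer(batch_size),
                 patches_per_iteration = as.integer(patches_per_iteration),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate, lambda1 = lambda1,
                 lambda2 = lambda2, lambda3 = lambda3,
                 seed = as.integer(seed), beta1 = beta1,
                 iters_per_epoch = iters_per_epoch,
                 grad_clip = grad_clip),
            class = "mv_stage2_config")
}

#' Precompute teacher predictions paired with their real axial slices
#'
#' Teachers are frozen after stage 1; their view-complementary predictions
#' are generated once, offline. Each store entry pairs one real axial
#' slice with its three aligned predictions (only the fusion weights are
#' recomputed dynamically during stage-2 training).
#'
#' @param models list of the three trained view models.
#' @param volumes list of [ct_volume()]: the low-dose training volumes for
#'   `direction = "l2h"` (yielding \{x; y-hat triples\}), the high-dose
#'   ones for `"h2l"`.
#' @param direction `"l2h"` or `"h2l"`.
#' @return An object of class `mv_prediction_store`: a flat list of
#'   entries `list(real = matrix, triple = mv_prediction_triple)`.
#' @export
build_prediction_store <- function(models, volumes,
                                   direction = c("l2h", "h2l")) {
  direction <- match.arg(direction)
  stop_if_not(length(volumes) > 0, "volumes must be nonempty")
  entries <- list()
  for (vol in volumes) {
    triples <- generate_view_complementary_predictions(models, vol,
                                                       direction)
    reals <- resplit_axial(vol)$slices
    for (i in seq_along(triples)) {
      entries[[length(entries) + 1L]] <- list(real = reals[[i]],
                                              triple = triples[[i]])
    }
  }
  structure(entries, class = "mv_prediction_store")
}

# crop one store entry to aligned patches (identical coordinates for the
# real slice and the three predictions -- mandatory for the fusion maps)
crop_store_entry <- function(entry, patch) {
  cc <- crop_coords(dim(entry$real), patch)
  sub <- function(m) m[cc$rows, cc$cols, drop = FALSE]
  list(real = sub(entry$real),
       preds = lapply(triple_list(entry$triple), sub))
}

# fuse pseudo-target for one cropped entry with the student's current
# inverse generator; everything here is detached (no gradients)
fuse_pseudo_patch <- function(cropped, inverse_gen, direction) {
  triple <- view_prediction_triple(cropped$preds$a, cropped$preds$s,
                                   cropped$preds$c, direction = direction)
  diffs <- cycle_difference_maps(triple, cropped$real, inverse_gen)
  weights <- weight_maps_from_diffs(diffs)
  list(target = weighted_fuse(triple, weights), weights = weights)
}

#' Train the single-view student under pseudo-supervision
#'
#' The student is itself a CycleGAN (RED-CNN generators by default) on the
#' unpaired axial pools; in addition to the adversarial and cycle terms it
#' minimises the pseudo-supervised loss against fused pseudo-targets.
#' Every iteration, for each sampled slice, aligned patches are cropped
#' from the real image and its three frozen teacher predictions, the
#' cycle-reconstruction difference maps are recomputed with the student's
#' *current* inverse generator, turned into per-pixel weights, and the
#' predictions fused into a pseudo-target (so the weights are dynamic even
#' though the teachers are frozen). Objective:
#' `lambda1 * GAN + lambda2 * cycle + lambda3 * pseudo`.
#'
#' @param unpaired the unpaired axial [build_unpaired_dataset()].
#' @param l2h_store,h2l_store [build_prediction_store()] results pairing
#'   real low-dose slices with high-dose prediction triples and vice
#'   versa.
#' @param config a [stage2_config()].
#' @param gen_spec student generator spec (default RED-CNN).
#' @param disc_spec a [discriminator_spec()].
#' @param hu_window intensity window mapped to \[-1, 1\].
#' @param record_weight_maps keep the first patch's fusion weight maps of
#'   every iteration in the result (`$weight_history`), for inspecting the
#'   dynamic-weight behaviour.
#' @param verbose print a loss line per epoch.
#' @return An `mv_translation_model` (view `"axial"`) whose `history`
#'   gains columns `rec` and mean fusion weights, plus `$weight_history`.
#' @export
train_single_view <- function(unpaired, l2h_store, h2l_store, config,
                              gen_spec = generator_spec("redcnn"),
                              disc_spec = discriminator_spec(),
                              hu_window = HU_WINDOW,
                              record_weight_maps = TRUE, verbose = FALSE) {
  stop_if_not(inherits(unpaired, "mv_unpaired_dataset") &&
                unpaired$view == "axial",
              "unpaired must be an axial dataset")
  stop_if_not(!unpaired$paired, "training dataset must be unpaired")
  stop_if_not(inherits(config, "mv_stage2_config"),
              "config must be a stage2_config()")
  stop_if_not(inherits(l2h_store, "mv_prediction_store") &&
                inherits(h2l_store, "mv_prediction_store") &&
                length(l2h_store) > 0 && length(h2l_store) > 0,
              "prediction stores must be nonempty mv_prediction_store")
  norm_store <- function(store) {
    lapply(store, function(e) {
      list(real = normalize_hu(e$real, hu_window),
           triple = view_prediction_triple(
             normalize_hu(e$triple$from_axial, hu_window),
             normalize_hu(e$triple$from_sagittal, hu_window),
             normalize_hu(e$triple$from_coronal, hu_window),
             axial_index = e$triple$axial_index,
             direction = e$triple$direction))
    })
  }
  with_seed(config$seed, {
    G_xy <- build_generator(gen_spec)
    G_yx <- build_generator(gen_spec)
    D_x <- build_discriminator(disc_spec)
    D_y <- build_discriminator(disc_spec)
    opt_g <- adam_new(list(G_xy, G_yx), lr = config$learning_rate,
                      beta1 = config$beta1, clip = config$grad_clip)
    opt_d <- adam_new(list(D_x, D_y), lr = config$learning_rate,
                      beta1 = config$beta1, clip = config$grad_clip)
    sl2h <- norm_store(l2h_store)
    sh2l <- norm_store(h2l_store)
    iters <- config$iters_per_epoch %||%
      max(1L, min(length(sl2h), length(sh2l)) %/% config$batch_size)
    hist <- vector("list", config$epochs * iters)
    wmaps <- if (record_weight_maps) vector("list", config$epochs * iters)
    step <- 0L
    for (ep in seq_len(config$epochs)) {
      for (it in seq_len(iters)) {
        step <- step + 1L
        ex <- sl2h[sample.int(length(sl2h), config$batch_size,
                              replace = length(sl2h) < config$batch_size)]
        ey <- sh2l[sample.int(length(sh2l), config$batch_size,
                              replace = length(sh2l) < config$batch_size)]
        crop_all <- function(entries) {
          unlist(lapply(entries, function(e) {
            lapply(seq_len(config$patches_per_iteration), function(p) {
              crop_store_entry(e, config$patch_size)
            })
          }), recursive = FALSE)
        }
        cx <- crop_all(ex)
        cy <- crop_all(ey)
        # pseudo-targets: one detached batched pass of the student's
        # current inverse generator over all 3 view predictions per crop
        fuse_targets <- function(crops, inverse_gen, direction) {
          preds <- unlist(lapply(crops, function(cr) cr$preds),
                          recursive = FALSE)
          recon <- net_apply_batch(inverse_gen, preds)
          lapply(seq_along(crops), function(i) {
            cr <- crops[[i]]
            rc <- recon[(3 * i - 2):(3 * i)]
            diffs <- list(diff_a = abs(rc[[1]] - cr$real),
                          diff_s = abs(rc[[2]] - cr$real),
                          diff_c = abs(rc[[3]] - cr$real))
            weights <- weight_maps_from_diffs(diffs)
            triple <- view_prediction_triple(cr$preds$a, cr$preds$s,
                                             cr$preds$c,
                                             direction = direction)
            list(target = weighted_fuse(triple, weights),
                 weights = weights)
          })
        }
        fx_t <- fuse_targets(cx, G_yx, "l2h")
        fy_t <- fuse_targets(cy, G_xy, "h2l")
        wrec <- fx_t[[1]]$weights
        xs <- lapply(cx, `[[`, "real")
        ys <- lapply(cy, `[[`, "real")
        pys <- lapply(fx_t, `[[`, "target")
        pxs <- lapply(fy_t, `[[`, "target")
        tp <- tape_new()
        xb <- op_input(tp, xs)
        yb <- op_input(tp, ys)
        fx <- G_xy$forward(tp, xb)
        cyc_x <- op_l1(tp, G_yx$forward(tp, fx), xb)
        gan_x <- op_mse_const(tp, D_y$forward(tp, fx), 1)
        psu_x <- op_l1(tp, fx, op_input(tp, pys))
        fy <- G_yx$forward(tp, yb)
        cyc_y <- op_l1(tp, G_xy$forward(tp, fy), yb)
        gan_y <- op_mse_const(tp, D_x$forward(tp, fy), 1)
        psu_y <- op_l1(tp, fy, op_input(tp, pxs))
        total <- op_wsum(tp, list(cyc_x, gan_x, psu_x, cyc_y, gan_y,
                                  psu_y),
                         c(config$lambda2, 0.5 * config$lambda1,
                           config$lambda3, config$lambda2,
                           0.5 * config$lambda1, config$lambda3))
        cyc_val <- cyc_x$value + cyc_y$value
        gan_val <- 0.5 * (gan_x$value + gan_y$value)
        rec_val <- psu_x$value + psu_y$value
        net_reset_grads(G_xy); net_reset_grads(G_yx)
        net_reset_grads(D_x); net_reset_grads(D_y)
        tape_backward(tp, total)
        adam_step(opt_g)
        d_loss <- discriminator_step(D_x, D_y, xb$value, yb$value,
                                     fy$value, fx$value, opt_d)
        tot <- config$lambda1 * gan_val + config$lambda2 * cyc_val +
          config$lambda3 * rec_val
        if (!all(is.finite(c(tot, d_loss)))) {
          stop(sprintf("non-finite loss at iteration %d", step),
               call. = FALSE)
        }
        hist[[step]] <- data.frame(iter = step, cycle = cyc_val,
                                   gan_g = gan_val, gan_d = d_loss,
                                   rec = rec_val, total = tot,
                                   w_a = mean(wrec$w_a),
                                   w_s = mean(wrec$w_s),
                                   w_c = mean(wrec$w_c))
        if (record_weight_maps) wmaps[[step]] <- wrec
      }
      if (verbose) {
        h <- hist[[step]]
        message(sprintf("[student] epoch %d/%d: cycle %.4f gan %.4f rec %.4f",
                        ep, config$epochs, h$cycle, h$gan_g, h$rec))
      }
    }
    new_translation_model(G_xy, G_yx, D_x, D_y, "axial", config, gen_spec,
                          disc_spec, do.call(rbind, hist), hu_window,
                          extra = list(weight_history =
                                         if (record_weight_maps) wmaps))
  })
}

#' Denoise a volume with the trained student (inference path)
#'
#' Slice-wise axial application of the student's low-to-high generator on
#' full slices; the single-model path used at deployment, with no
#' multi-view dependency.
#'
#' @param student the trained axial `mv_translation_model`.
#' @param volume a [ct_volume()].
#' @return A denoised [ct_volume()] of identical shape.
#' @export
denoise_axial <- function(student, volume) {
  stop_if_not(inherits(student, "mv_translation_model") &&
                student$view == "axial",
              "student must be an axial translation model")
  denoise_volume(student, volume, "l2h")
}
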