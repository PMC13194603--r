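# Closed-form loss functions shared by both training stages. These operate
# on plain matrices (or lists of matrices) and on generators given either
# as built networks or as plain R functions; the tape-based training loops
# compute the same quantities differentiably, and tests assert the two
# routes agree.

as_image_fun <- function(g) {
  if (is.function(g)) return(g)
  if (inherits(g, "mv_net")) return(function(m) net_apply(g, m))
  stop("generator must be a function or a built network", call. = FALSE)
}

as_batch <- function(x) {
  if (is.matrix(x)) list(x) else {
    stop_if_not(is.list(x) && length(x) > 0 && all(vapply(x, is.matrix,
                                                          logical(1))),
                "batch must be a matrix or nonempty list of matrices")
    x
  }
}

batch_mean <- function(batch, f) mean(vapply(batch, f, numeric(1)))

#' Cycle-consistency loss
#'
#' Mean absolute error of the forward cycle `G_yx(G_xy(x))` against `x`
#' plus that of the backward cycle `G_xy(G_yx(y))` against `y`,
#' expectations taken as batch means. Zero for any exact inverse pair.
#'
#' @param x_batch,y_batch matrix or list of matrices (one per domain).
#' @param G_xy,G_yx generators (networks or plain functions), low-to-high
#'   and high-to-low.
#' @return nonnegative scalar.
#' @export
cycle_loss <- function(x_batch, y_batch, G_xy, G_yx) {
  fxy <- as_image_fun(G_xy); fyx <- as_image_fun(G_yx)
  xs <- as_batch(x_batch); ys <- as_batch(y_batch)
  batch_mean(xs, function(x) mean(abs(fyx(fxy(x)) - x))) +
    batch_mean(ys, function(y) mean(abs(fxy(fyx(y)) - y)))
}

#' Least-squares GAN discriminator loss
#'
#' `0.5 * [mean((d(real) - 1)^2) + mean(d(fake)^2)]`, means over the batch
#' and all score-map positions. Zero iff the discriminator outputs exactly
#' 1 on real and 0 on fake everywhere.
#'
#' @param d discriminator (network or function returning a score map).
#' @param real_batch,fake_batch matrix or list of matrices.
#' @return nonnegative scalar.
#' @export
lsgan_d_loss <- function(d, real_batch, fake_batch) {
  fd <- as_image_fun(d)
  reals <- as_batch(real_batch); fakes <- as_batch(fake_batch)
  0.5 * (batch_mean(reals, function(r) mean((fd(r) - 1)^2)) +
           batch_mean(fakes, function(f) mean(fd(f)^2)))
}

#' Least-squares GAN generator loss
#'
#' `0.5 * mean((d(fake) - 1)^2)` over batch and score-map positions.
#'
#' @inheritParams lsgan_d_loss
#' @param fake_batch generated images.
#' @return nonnegative scalar.
#' @export
lsgan_g_loss <- function(d, fake_batch) {
  fd <- as_image_fun(d)
  0.5 * batch_mean(as_batch(fake_batch), function(f) mean((fd(f) - 1)^2))
}

#' Stage-1 combined generator objective
#'
#' `gan_g_xy + gan_g_yx + lambda * cycle`, the unpaired translation
#' objective with the cycle term weighted by `lambda` (default 10).
#'
#' @param gan_g_xy,gan_g_yx adversarial generator losses of the two
#'   directions.
#' @param cycle cycle-consistency loss.
#' @param lambda nonnegative cycle weight, default 10.
#' @return scalar objective.
#' @export
stage1_generator_objective <- function(gan_g_xy, gan_g_yx, cycle,
                                       lambda = 10) {
  stop_if_not(is_scalar_number(lambda) && lambda >= 0,
              "lambda must be nonnegative")
  stop_if_not(all(is.finite(c(gan_g_xy, gan_g_yx, cycle))),
              "loss components must be finite")
  gan_g_xy + gan_g_yx + lambda * cycle
}

#' Stage-2 pseudo-supervised loss
#'
#' `mean |G_xy(x) - pseudo_y| + mean |G_yx(y) - pseudo_x|`: the student's
#' outputs are pulled towards the fused pseudo-targets.
#'
#' @param x_batch,y_batch real image batches.
#' @param pseudo_y,pseudo_x fused pseudo-target batches aligned with
#'   `x_batch`/`y_batch`.
#' @param G_xy,G_yx student generators.
#' @return nonnegative scalar.
#' @export
pseudo_supervised_loss <- function(x_batch, y_batch, pseudo_y, pseudo_x,
                                   G_xy, G_yx) {
  fxy <- as_image_fun(G_xy); fyx <- as_image_fun(G_yx)
  xs <- as_batch(x_batch); ys <- as_batch(y_batch)
  pys <- as_batch(pseudo_y); pxs <- as_batch(pseudo_x)
  stop_if_not(length(xs) == length(pys) && length(ys) == length(pxs),
              "pseudo-target batches must align with the real batches")
  mean(mapply(function(x, py) {
    stop_if_not(all(dim(x) == dim(py)), "shape mismatch")
    mean(abs(fxy(x) - py))
  }, xs, pys)) +
    mean(mapply(function(y, px) {
      stop_if_not(all(dim(y) == dim(px)), "shape mismatch")
      mean(abs(fyx(y) - px))
    }, ys, pxs))
}

#' Stage-2 combined generator objective
#'
#' `lambda1 * gan + lambda2 * cycle + lambda3 * rec` with defaults
#' (1, 10, 5); `lambda3 = 0` reduces to the stage-1 objective form.
#'
#' @param gan,cycle,rec finite loss components.
#' @param lambda1,lambda2,lambda3 nonnegative balance factors.
#' @return scalar objective.
#' @export
stage2_generator_objective <- function(gan, cycle, rec, lambda1 = 1,
                                       lambda2 = 10, lambda3 = 5) {
  stop_if_not(all(c(lambda1, lambda2, lambda3) >= 0),
              "balance factors must be nonnegative")
  stop_if_not(all(is.finite(c(gan, cycle, rec))),
              "loss components must be finite")
  lambda1 * gan + lambda2 * cycle + lambda3 * rec
}

# per-iteration loss bookkeeping written to training history
loss_report <- function(cycle, gan_g, gan_d, lambda) {
  stop_if_not(all(is.finite(c(cycle, gan_g, gan_d))),
              "non-finite loss encountered")
  list(cycle = cycle, gan_g = gan_g, gan_d = gan_d,
       total = gan_g + lambda * cycle, lambda = lambda)
}
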