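#' Generator architecture specification
#'
#' Describes one of the two generator families used by the framework:
#' \describe{
#'   \item{`rescnn`}{encoder (three Conv-IN-ReLU blocks, strides 1,2,2) ->
#'     residual transfer module -> decoder (two transposed-conv IN-ReLU
#'     blocks) -> output convolution. First and last convolutions use a
#'     7x7 kernel, all interior ones 3x3. Total downsampling factor 4;
#'     inputs whose sides are not divisible by 4 are reflection-padded and
#'     cropped back.}
#'   \item{`redcnn`}{residual encoder-decoder: `depth` plain convolutions
#'     followed by `depth` transposed convolutions, all stride 1 (no
#'     resolution loss), with symmetric additive shortcuts (including the
#'     input image before the final, linear output).}
#' }
#' Generator outputs are linear (no final activation) so that normalised
#' Hounsfield-like intensity ranges are representable. All sizes are spec
#' fields so that tiny desk-scale variants use the same machinery.
#'
#' @param family `"rescnn"` or `"redcnn"`.
#' @param base_channels integer(3), encoder channels of the ResCNN
#'   (default 32, 64, 128).
#' @param n_residual_blocks residual blocks in the ResCNN transfer module
#'   (default 6).
#' @param kernel_first,kernel_inner kernel sizes of the first/last vs the
#'   interior convolutions of the ResCNN (defaults 7 and 3).
#' @param redcnn_channels,redcnn_depth,redcnn_kernel RED-CNN width (default
#'   96), number of conv/deconv pairs (default 5) and kernel size (default
#'   5).
#' @param global_skip add the input image to the ResCNN output (residual
#'   parameterisation). Off by default (the reference ResCNN has no such
#'   shortcut); desk-scale training budgets enable it so optimisation
#'   starts at the identity map. RED-CNN carries its input shortcut
#'   inherently.
#' @param out_init_gain relative initialisation scale of the output layer;
#'   small values (with a skip) start training near the identity.
#' @return An object of class `mv_generator_spec`.
#' @export
generator_spec <- function(family = c("rescnn", "redcnn"),
                           base_channels = c(32L, 64L, 128L),
                           n_residual_blocks = 6L,
                           kernel_first = 7L, kernel_inner = 3L,
                           redcnn_channels = 96L, redcnn_depth = 5L,
                           redcnn_kernel = 5L, global_skip = FALSE,
                           out_init_gain = 1) {
  family <- match.arg(family)
  if (family == "rescnn") {
    stop_if_not(length(base_channels) == 3L && all(base_channels >= 1),
                "rescnn needs three positive base_channels")
    stop_if_not(n_residual_blocks >= 1, "need at least one residual block")
  } else {
    stop_if_not(redcnn_channels >= 1 && redcnn_depth >= 2,
                "redcnn needs positive channels and depth >= 2")
  }
  structure(list(family = family,
                 base_channels = as.integer(base_channels),
                 n_residual_blocks = as.integer(n_residual_blocks),
                 kernel_first = as.integer(kernel_first),
                 kernel_inner = as.integer(kernel_inner),
                 redcnn_channels = as.integer(redcnn_channels),
                 redcnn_depth = as.integer(redcnn_depth),
                 redcnn_kernel = as.integer(redcnn_kernel),
                 global_skip = isTRUE(global_skip),
                 out_init_gain = out_init_gain),
            class = "mv_generator_spec")
}

#' Discriminator architecture specification
#'
#' PatchGAN: a stack of stride-2 4x4 convolutions with instance
#' normalisation and leaky-ReLU activations, ending in a 1-channel spatial
#' map of realness scores (one decision per local patch, not a single
#' scalar).
#'
#' @param n_layers number of stride-2 downsampling layers (default 3).
#' @param base_channels channels of the first layer (default 64); deeper
#'   layers double up to a cap of 8x.
#' @param norm `"instance"` (the reference choice) or `"none"`. Instance
#'   normalisation makes the discriminator blind to intensity offsets,
#'   which at desk-scale training budgets leaves a CycleGAN free to drift
#'   in mean intensity; `"none"` keeps the score map sensitive to the
#'   absolute level (see the methods vignette).
#' @return An object of class `mv_discriminator_spec`.
#' @export
discriminator_spec <- function(n_layers = 3L, base_channels = 64L,
                               norm = c("instance", "none")) {
  stop_if_not(n_layers >= 1 && base_channels >= 1,
              "n_layers and base_channels must be positive")
  structure(list(family = "patchgan", n_layers = as.integer(n_layers),
                 base_channels = as.integer(base_channels),
                 norm = match.arg(norm)),
            class = "mv_discriminator_spec")
}

#' Build a generator network
#'
#' @param spec a [generator_spec()].
#' @param seed optional integer; when given, weight initialisation is run
#'   under this seed (and the caller's RNG state is restored), so two builds
#'   with the same spec and seed are bit-identical.
#' @return An object of class `mv_generator`: a same-shape image-to-image
#'   function usable with [net_apply()] and the training routines.
#' @export
build_generator <- function(spec, seed = NULL) {
  stop_if_not(inherits(spec, "mv_generator_spec"), "spec must be a generator_spec")
  mk <- function() {
    if (spec$family == "rescnn") build_rescnn(spec) else build_redcnn(spec)
  }
  net <- if (is.null(seed)) mk() else with_seed(seed, mk())
  net$spec <- spec
  class(net) <- c("mv_generator", "mv_net")
  net
}

build_rescnn <- function(spec) {
  ch <- spec$base_channels
  kf <- spec$kernel_first; ki <- spec$kernel_inner
  L <- list(
    enc1 = layer_conv(1, ch[1], kf),
    enc1n = layer_inorm(ch[1]),
    enc2 = layer_conv(ch[1], ch[2], ki, stride = 2),
    enc2n = layer_inorm(ch[2]),
    enc3 = layer_conv(ch[2], ch[3], ki, stride = 2),
    enc3n = layer_inorm(ch[3])
  )
  for (i in seq_len(spec$n_residual_blocks)) {
    L[[paste0("rb", i, "a")]] <- layer_conv(ch[3], ch[3], ki)
    L[[paste0("rb", i, "an")]] <- layer_inorm(ch[3])
    L[[paste0("rb", i, "b")]] <- layer_conv(ch[3], ch[3], ki)
    L[[paste0("rb", i, "bn")]] <- layer_inorm(ch[3])
  }
  L$dec1 <- layer_convt(ch[3], ch[2], ki, stride = 2)
  L$dec1n <- layer_inorm(ch[2])
  L$dec2 <- layer_convt(ch[2], ch[1], ki, stride = 2)
  L$dec2n <- layer_inorm(ch[1])
  L$out <- layer_conv(ch[1], 1, kf, init_gain = spec$out_init_gain)
  fwd <- function(tp, xn) {
    d <- dim(xn$value)
    ph <- (4 - d[1] %% 4) %% 4
    pw <- (4 - d[2] %% 4) %% 4
    h <- xn
    if (ph > 0 || pw > 0) h <- op_pad_reflect(tp, h, c(0L, ph, 0L, pw))
    hp <- d[1] + ph; wp <- d[2] + pw
    h <- op_relu(tp, op_inorm(tp, L$enc1n, op_conv(tp, L$enc1, h)))
    h <- op_relu(tp, op_inorm(tp, L$enc2n, op_conv(tp, L$enc2, h)))
    h <- op_relu(tp, op_inorm(tp, L$enc3n, op_conv(tp, L$enc3, h)))
    for (i in seq_len(spec$n_residual_blocks)) {
      t <- op_relu(tp, op_inorm(tp, L[[paste0("rb", i, "an")]],
                                op_conv(tp, L[[paste0("rb", i, "a")]], h)))
      t <- op_inorm(tp, L[[paste0("rb", i, "bn")]],
                    op_conv(tp, L[[paste0("rb", i, "b")]], t))
      h <- op_relu(tp, op_add(tp, h, t))
    }
    h <- op_relu(tp, op_inorm(tp, L$dec1n,
                              op_convt(tp, L$dec1, h, c(hp / 2, wp / 2))))
    h <- op_relu(tp, op_inorm(tp, L$dec2n,
                              op_convt(tp, L$dec2, h, c(hp, wp))))
    h <- op_conv(tp, L$out, h)
    if (spec$global_skip) {
      h <- if (ph > 0 || pw > 0) {
        op_add(tp, op_crop(tp, h, seq_len(d[1]), seq_len(d[2])), xn)
      } else op_add(tp, h, xn)
    } else if (ph > 0 || pw > 0) {
      h <- op_crop(tp, h, seq_len(d[1]), seq_len(d[2]))
    }
    h
  }
  list(layers = L, forward = fwd)
}

build_redcnn <- function(spec) {
  ch <- spec$redcnn_channels; d <- spec$redcnn_depth; k <- spec$redcnn_kernel
  L <- list()
  for (i in seq_len(d)) {
    L[[paste0("enc", i)]] <- layer_conv(if (i == 1) 1 else ch, ch, k)
  }
  for (j in seq_len(d)) {
    L[[paste0("dec", j)]] <- layer_convt(ch, if (j == d) 1 else ch, k,
                                         stride = 1)
  }
  # start near the identity (the input shortcut dominates at init)
  L[[paste0("dec", d)]]$w <- L[[paste0("dec", d)]]$w * spec$out_init_gain
  fwd <- function(tp, xn) {
    hw <- dim(xn$value)[1:2]
    skips <- vector("list", d + 1L)
    skips[[1]] <- xn                      # e_0 = input image
    h <- xn
    for (i in seq_len(d)) {
      h <- op_relu(tp, op_conv(tp, L[[paste0("enc", i)]], h))
      skips[[i + 1L]] <- h
    }
    for (j in seq_len(d)) {
      h <- op_convt(tp, L[[paste0("dec", j)]], h, hw)
      if ((d - j) %% 2 == 0) h <- op_add(tp, h, skips[[d - j + 1L]])
      if (j < d) h <- op_relu(tp, h)      # final output stays linear
    }
    h
  }
  list(layers = L, forward = fwd)
}

#' Build a PatchGAN discriminator
#'
#' @param spec a [discriminator_spec()].
#' @param seed optional integer, as in [build_generator()].
#' @return An object of class `mv_discriminator` mapping an image to a
#'   smaller 2D score map.
#' @export
build_discriminator <- function(spec, seed = NULL) {
  stop_if_not(inherits(spec, "mv_discriminator_spec"),
              "spec must be a discriminator_spec")
  mk <- function() build_patchgan(spec)
  net <- if (is.null(seed)) mk() else with_seed(seed, mk())
  net$spec <- spec
  class(net) <- c("mv_discriminator", "mv_net")
  net
}

patchgan_channels <- function(spec) {
  c0 <- spec$base_channels
  vapply(seq_len(spec$n_layers + 1L),
         function(i) min(c0 * 2^(i - 1L), 8L * c0), numeric(1))
}

build_patchgan <- function(spec) {
  chs <- patchgan_channels(spec)
  use_norm <- !identical(spec$norm, "none")
  L <- list(l1 = layer_conv(1, chs[1], 4, stride = 2, pad = 1))
  for (i in seq_len(spec$n_layers - 1L) + 1L) {
    L[[paste0("l", i)]] <- layer_conv(chs[i - 1], chs[i], 4, stride = 2,
                                      pad = 1)
    if (use_norm) L[[paste0("l", i, "n")]] <- layer_inorm(chs[i])
  }
  np <- spec$n_layers + 1L
  L[[paste0("l", np)]] <- layer_conv(chs[np - 1], chs[np], 4, stride = 1,
                                     pad = 1)
  if (use_norm) L[[paste0("l", np, "n")]] <- layer_inorm(chs[np])
  L$out <- layer_conv(chs[np], 1, 4, stride = 1, pad = 1)
  use_in <- !identical(spec$norm, "none")
  fwd <- function(tp, xn) {
    hw <- dim(xn$value)[1:2]
    sz <- patchgan_scoremap_dim(hw, spec$n_layers)
    stop_if_not(all(sz >= 1),
                "input is smaller than the discriminator receptive field")
    h <- op_lrelu(tp, op_conv(tp, L$l1, xn))
    for (i in seq_len(spec$n_layers - 1L) + 1L) {
      h <- op_conv(tp, L[[paste0("l", i)]], h)
      if (use_in) h <- op_inorm(tp, L[[paste0("l", i, "n")]], h)
      h <- op_lrelu(tp, h)
    }
    np <- spec$n_layers + 1L
    h <- op_conv(tp, L[[paste0("l", np)]], h)
    if (use_in) h <- op_inorm(tp, L[[paste0("l", np, "n")]], h)
    h <- op_lrelu(tp, h)
    op_conv(tp, L$out, h)
  }
  list(layers = L, forward = fwd)
}

# output spatial size of the PatchGAN score map (kernel 4, pad 1)
patchgan_scoremap_dim <- function(hw, n_layers) {
  sz <- hw
  for (i in seq_len(n_layers)) sz <- (sz + 2 - 4) %/% 2 + 1  # stride 2
  sz <- sz + 2 - 4 + 1                                       # stride-1 conv
  sz + 2 - 4 + 1                                             # output conv
}

#' Apply a network to a single 2D image
#'
#' Runs a plain forward pass (no gradients kept).
#'
#' @param net an `mv_generator` or `mv_discriminator`.
#' @param img numeric matrix.
#' @return numeric matrix (same size for generators; a smaller score map for
#'   discriminators).
#' @export
net_apply <- function(net, img) {
  stop_if_not(inherits(net, "mv_net"), "net must be a built network")
  stop_if_not(is.matrix(img), "img must be a matrix")
  tp <- tape_new()
  as_mat(net$forward(tp, op_input(tp, img))$value)
}

#' Apply a network to a batch of equally-sized 2D images
#'
#' Single batched forward pass (no gradients kept); faster than repeated
#' [net_apply()] calls.
#'
#' @inheritParams net_apply
#' @param imgs list of matrices sharing one shape.
#' @return List of output matrices.
#' @export
net_apply_batch <- function(net, imgs) {
  stop_if_not(inherits(net, "mv_net"), "net must be a built network")
  tp <- tape_new()
  batch_to_mats(net$forward(tp, op_input(tp, imgs))$value)
}

#' Number of trainable parameters of a network
#' @param net a built network.
#' @return integer count.
#' @export
net_param_count <- function(net) {
  sum(vapply(net$layers, layer_n_params, numeric(1)))
}

net_get_weights <- function(net) {
  lapply(net$layers, function(ly) {
    stats::setNames(lapply(layer_param_names(ly), function(p) ly[[p]]),
                    layer_param_names(ly))
  })
}

net_set_weights <- function(net, weights) {
  stop_if_not(identical(names(weights), names(net$layers)),
              "weight list does not match network layers")
  for (nm in names(weights)) {
    for (p in names(weights[[nm]])) net$layers[[nm]][[p]] <- weights[[nm]][[p]]
  }
  invisible(net)
}

net_reset_grads <- function(net) {
  for (ly in net$layers) layer_reset_grads(ly)
  invisible(net)
}

#' @export
print.mv_net <- function(x, ...) {
  kind <- if (inherits(x, "mv_generator")) x$spec$family else "patchgan"
  cat(sprintf("<%s network: %s, %d parameters>\n",
              if (inherits(x, "mv_generator")) "generator" else "discriminator",
              kind, net_param_count(x)))
  invisible(x)
}
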