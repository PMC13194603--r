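# Adam over the layers of one or more networks. State (first/second moment)
# lives next to the parameters in the layer environments.

adam_new <- function(nets, lr = 1e-5, beta1 = 0.5, beta2 = 0.999,
                     eps = 1e-8, clip = Inf) {
  layers <- unlist(lapply(nets, function(n) n$layers), use.names = FALSE)
  for (ly in layers) {
    for (p in layer_param_names(ly)) {
      ly[[paste0("m_", p)]] <- ly[[p]] * 0
      ly[[paste0("v_", p)]] <- ly[[p]] * 0
    }
  }
  list(layers = layers, lr = lr, beta1 = beta1, beta2 = beta2, eps = eps,
       clip = clip, t = 0L)
}

# global gradient-norm clipping across every parameter the optimiser owns
clip_grads <- function(opt) {
  if (!is.finite(opt$clip)) return(invisible(NULL))
  total <- 0
  for (ly in opt$layers) {
    for (p in layer_param_names(ly)) {
      total <- total + sum(ly[[paste0("g", p)]]^2)
    }
  }
  total <- sqrt(total)
  if (total > opt$clip) {
    sc <- opt$clip / total
    for (ly in opt$layers) {
      for (p in layer_param_names(ly)) {
        ly[[paste0("g", p)]] <- ly[[paste0("g", p)]] * sc
      }
    }
  }
  invisible(NULL)
}

adam_step <- function(opt) {
  clip_grads(opt)
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  bc1 <- 1 - b1^opt$t
  bc2 <- 1 - b2^opt$t
  for (ly in opt$layers) {
    for (p in layer_param_names(ly)) {
      g <- ly[[paste0("g", p)]]
      m <- b1 * ly[[paste0("m_", p)]] + (1 - b1) * g
      v <- b2 * ly[[paste0("v_", p)]] + (1 - b2) * g * g
      ly[[paste0("m_", p)]] <- m
      ly[[paste0("v_", p)]] <- v
      ly[[p]] <- ly[[p]] - opt$lr * (m / bc1) / (sqrt(v / bc2) + opt$eps)
    }
  }
  opt
}
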