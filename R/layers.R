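# Parameterised layers are environments so that tape backward closures can
# accumulate gradients in place. Weight layout matches src/nn_ops.cpp:
# conv w is (Cout, Cin*k*k); transposed conv w is (Cin, Cout*k*k).

layer_conv <- function(cin, cout, k, stride = 1L, pad = k %/% 2L,
                       init_gain = 1) {
  ly <- new.env(parent = emptyenv())
  ly$type <- "conv"
  ly$cin <- cin; ly$cout <- cout
  ly$k <- as.integer(k); ly$stride <- as.integer(stride)
  ly$pad <- as.integer(pad)
  fan_in <- cin * k * k
  ly$w <- matrix(rnorm(cout * fan_in, sd = init_gain * sqrt(2 / fan_in)),
                 nrow = cout)
  ly$b <- numeric(cout)
  layer_reset_grads(ly)
  class(ly) <- "mv_layer"
  ly
}

layer_convt <- function(cin, cout, k, stride = 2L, pad = k %/% 2L) {
  ly <- new.env(parent = emptyenv())
  ly$type <- "convt"
  ly$cin <- cin; ly$cout <- cout
  ly$k <- as.integer(k); ly$stride <- as.integer(stride)
  ly$pad <- as.integer(pad)
  fan_in <- cin * k * k / (stride^2)
  ly$w <- matrix(rnorm(cin * cout * k * k, sd = sqrt(2 / max(fan_in, 1))),
                 nrow = cin)
  ly$b <- numeric(cout)
  layer_reset_grads(ly)
  class(ly) <- "mv_layer"
  ly
}

layer_inorm <- function(c) {
  ly <- new.env(parent = emptyenv())
  ly$type <- "inorm"
  ly$gamma <- rep(1, c)
  ly$beta <- numeric(c)
  layer_reset_grads(ly)
  class(ly) <- "mv_layer"
  ly
}

layer_param_names <- function(ly) {
  if (ly$type == "inorm") c("gamma", "beta") else c("w", "b")
}

layer_reset_grads <- function(ly) {
  for (p in layer_param_names(ly)) {
    ly[[paste0("g", p)]] <- ly[[p]] * 0
  }
  invisible(ly)
}

layer_n_params <- function(ly) {
  sum(vapply(layer_param_names(ly), function(p) length(ly[[p]]), numeric(1)))
}
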