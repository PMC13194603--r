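# Minimal reverse-mode tape for the fixed network topologies used here.
#
# Values are batched 4D arrays (H, W, C, N), or length-1 scalars for
# losses. Each tape node records its parent node ids and a backward
# closure mapping the incoming gradient to a list of parent gradients;
# parameter gradients are accumulated directly into the owning layer
# environment as a side effect. Networks are small fixed DAGs, so a full
# graph engine is unnecessary, but the tape lets gradients flow through
# composed generators (the cycle G_yx(G_xy(x)) trains both networks in one
# backward pass).

tape_new <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp
}

tp_emit <- function(tp, value, parents = integer(), backward = NULL) {
  tp$n <- tp$n + 1L
  if (tp$n > length(tp$nodes)) {
    tp$nodes <- c(tp$nodes, vector("list", length(tp$nodes)))
  }
  node <- list(id = tp$n, value = value, parents = parents,
               backward = backward)
  tp$nodes[[tp$n]] <- node
  node
}

# Leaf input (no gradient propagated past it); accepts a matrix, a list of
# matrices (batched) or a ready-made 4D array.
op_input <- function(tp, x) {
  if (is.list(x)) x <- batch_input(x)
  tp_emit(tp, as_chw(x))
}

# Backward pass from a scalar loss node; seeds d(loss)/d(loss) = 1 and
# accumulates parameter gradients into layers along the way.
tape_backward <- function(tp, loss_node) {
  grads <- vector("list", tp$n)
  grads[[loss_node$id]] <- 1
  for (id in seq(loss_node$id, 1L)) {
    g <- grads[[id]]
    if (is.null(g)) next
    node <- tp$nodes[[id]]
    if (is.null(node$backward)) next
    pg <- node$backward(g)
    ps <- node$parents
    for (k in seq_along(ps)) {
      if (is.null(pg[[k]])) next
      pid <- ps[k]
      grads[[pid]] <- if (is.null(grads[[pid]])) pg[[k]] else
        grads[[pid]] + pg[[k]]
    }
    grads[[id]] <- NULL  # free
  }
  invisible(NULL)
}

## ---- differentiable ops -------------------------------------------------

op_conv <- function(tp, layer, xn) {
  x <- xn$value
  y <- cpp_conv2d_forward(x, layer$w, layer$b, layer$k, layer$k,
                          layer$stride, layer$pad)
  tp_emit(tp, y, parents = xn$id, backward = function(g) {
    bw <- cpp_conv2d_backward(x, layer$w, g, layer$k, layer$k,
                              layer$stride, layer$pad)
    layer$gw <- layer$gw + bw$gw
    layer$gb <- layer$gb + as.numeric(bw$gb)
    list(bw$gx)
  })
}

op_convt <- function(tp, layer, xn, out_hw) {
  x <- xn$value
  y <- cpp_convt2d_forward(x, layer$w, layer$b, layer$k, layer$k,
                           layer$stride, layer$pad, out_hw[1], out_hw[2])
  tp_emit(tp, y, parents = xn$id, backward = function(g) {
    bw <- cpp_convt2d_backward(x, layer$w, g, layer$k, layer$k,
                               layer$stride, layer$pad)
    layer$gw <- layer$gw + bw$gw
    layer$gb <- layer$gb + as.numeric(bw$gb)
    list(bw$gx)
  })
}

op_inorm <- function(tp, layer, xn, eps = 1e-5) {
  fw <- cpp_inorm_forward(xn$value, layer$gamma, layer$beta, eps)
  tp_emit(tp, fw$y, parents = xn$id, backward = function(g) {
    bw <- cpp_inorm_backward(g, fw$xhat, fw$sd, layer$gamma)
    layer$ggamma <- layer$ggamma + as.numeric(bw$ggamma)
    layer$gbeta <- layer$gbeta + as.numeric(bw$gbeta)
    list(bw$gx)
  })
}

op_relu <- function(tp, xn) {
  mask <- xn$value > 0
  tp_emit(tp, xn$value * mask, parents = xn$id,
          backward = function(g) list(g * mask))
}

op_lrelu <- function(tp, xn, slope = 0.2) {
  scale <- (xn$value > 0) * (1 - slope) + slope
  tp_emit(tp, xn$value * scale, parents = xn$id,
          backward = function(g) list(g * scale))
}

op_add <- function(tp, an, bn) {
  tp_emit(tp, an$value + bn$value, parents = c(an$id, bn$id),
          backward = function(g) list(g, g))
}

# Reflection padding on the two spatial dims; pads = c(top, bottom, left,
# right). Needed so ResCNN accepts sizes not divisible by 4.
op_pad_reflect <- function(tp, xn, pads) {
  x <- xn$value
  d <- dim(x)
  ri <- reflect_index(d[1], pads[1], pads[2])
  ci <- reflect_index(d[2], pads[3], pads[4])
  y <- x[ri, ci, , , drop = FALSE]
  tp_emit(tp, y, parents = xn$id, backward = function(g) {
    gx <- array(0, dim = d)
    for (nn in seq_len(d[4])) for (cc in seq_len(d[3])) {
      m <- rowsum(g[, , cc, nn], group = ri)        # duplicated rows
      gx[, , cc, nn] <- t(rowsum(t(m), group = ci)) # duplicated cols
    }
    list(gx)
  })
}

reflect_index <- function(n, before, after) {
  stopifnot(before < n, after < n)
  c(rev(seq_len(before) + 1L), seq_len(n), n - seq_len(after))
}

op_crop <- function(tp, xn, rows, cols) {
  d <- dim(xn$value)
  y <- xn$value[rows, cols, , , drop = FALSE]
  tp_emit(tp, y, parents = xn$id, backward = function(g) {
    gx <- array(0, dim = d)
    gx[rows, cols, , ] <- g
    list(gx)
  })
}

## ---- scalar loss ops ----------------------------------------------------

# mean |a - b| over batch and pixels; subgradient 0 at ties
op_l1 <- function(tp, an, bn) {
  dif <- an$value - bn$value
  n <- length(dif)
  tp_emit(tp, mean(abs(dif)), parents = c(an$id, bn$id),
          backward = function(g) {
            s <- g * sign(dif) / n
            list(s, -s)
          })
}

# mean (a - t)^2 against a constant target t
op_mse_const <- function(tp, an, target) {
  dif <- an$value - target
  n <- length(dif)
  tp_emit(tp, mean(dif^2), parents = an$id,
          backward = function(g) list(g * 2 * dif / n))
}

# weighted sum of scalar nodes
op_wsum <- function(tp, nodes, weights) {
  vals <- vapply(nodes, function(nd) nd$value, numeric(1))
  tp_emit(tp, sum(vals * weights),
          parents = vapply(nodes, function(nd) nd$id, integer(1)),
          backward = function(g) as.list(g * weights))
}
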