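# internal helpers shared across modules

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

stop_if_not <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

# Values flowing through the tape are 4D arrays (H, W, C, N); N is the
# batch. Helpers convert between matrices / matrix lists and that layout.
as_chw <- function(m) {
  if (is.matrix(m)) array(m, dim = c(dim(m), 1L, 1L)) else m
}

as_mat <- function(a) {
  d <- dim(a)
  if (length(d) == 4L) {
    stopifnot(d[3] == 1L, d[4] == 1L)
    matrix(a, nrow = d[1], ncol = d[2])
  } else a
}

batch_input <- function(mats) {
  if (is.matrix(mats)) mats <- list(mats)
  d <- dim(mats[[1]])
  array(unlist(mats, use.names = FALSE), dim = c(d[1], d[2], 1L,
                                                 length(mats)))
}

batch_to_mats <- function(a) {
  d <- dim(a)
  stopifnot(d[3] == 1L)
  lapply(seq_len(d[4]), function(n) matrix(a[, , 1L, n], d[1], d[2]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
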