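#' Phantom generation specification
#'
#' Describes a piecewise-smooth anisotropic 3D phantom: an elliptical body
#' envelope of soft-tissue intensity on an air background, containing
#' `n_structures` random ellipsoidal or tubular inclusions with distinct
#' intensities. Intensities are Hounsfield-like (air near -1000, water 0)
#' and span `intensity_range`, so standard CT display windows are
#' meaningful.
#'
#' @param shape integer(3) array dimensions (z, y, x), each >= 8.
#' @param spacing numeric(3) voxel spacing in mm; anisotropic by default
#'   (thicker axial slices, as in abdominal protocols).
#' @param n_structures number of inclusions (default 6).
#' @param intensity_range ordered numeric(2), default c(-1000, 400).
#' @param seed integer; the same spec generates a bit-identical phantom.
#' @return An object of class `mv_phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64L, 64L, 64L), spacing = c(2.5, 1, 1),
                         n_structures = 6L,
                         intensity_range = c(-1000, 400), seed = 1L) {
  stop_if_not(length(shape) == 3L && all(shape >= 8L),
              "shape must be three dims >= 8")
  stop_if_not(length(intensity_range) == 2L &&
                intensity_range[1] < intensity_range[2],
              "intensity_range must be ordered")
  stop_if_not(n_structures >= 0L, "n_structures must be >= 0")
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 n_structures = as.integer(n_structures),
                 intensity_range = as.numeric(intensity_range),
                 seed = as.integer(seed)),
            class = "mv_phantom_spec")
}

# one 3-tap smoothing pass (0.25, 0.5, 0.25) along every axis, replicated
# edges; turns hard inclusion boundaries into smooth transitions
smooth3 <- function(v) {
  d <- dim(v)
  if (d[1] > 1) {
    v <- 0.25 * v[c(1, seq_len(d[1] - 1)), , , drop = FALSE] + 0.5 * v +
      0.25 * v[c(seq_len(d[1] - 1) + 1L, d[1]), , , drop = FALSE]
  }
  if (d[2] > 1) {
    v <- 0.25 * v[, c(1, seq_len(d[2] - 1)), , drop = FALSE] + 0.5 * v +
      0.25 * v[, c(seq_len(d[2] - 1) + 1L, d[2]), , drop = FALSE]
  }
  if (d[3] > 1) {
    v <- 0.25 * v[, , c(1, seq_len(d[3] - 1)), drop = FALSE] + 0.5 * v +
      0.25 * v[, , c(seq_len(d[3] - 1) + 1L, d[3]), drop = FALSE]
  }
  v
}

#' Generate a synthetic high-dose CT phantom
#'
#' Deterministic per seed: the body envelope is an ellipsoid of
#' soft-tissue-like intensity; inclusions are ellipsoids or z-oriented
#' tubes placed inside the body with intensities drawn from the upper half
#' of `intensity_range`, then one light smoothing pass is applied.
#'
#' @param spec a [phantom_spec()].
#' @return A [ct_volume()] (the clean, high-dose ground truth).
#' @export
generate_phantom <- function(spec) {
  stop_if_not(inherits(spec, "mv_phantom_spec"), "spec must be a phantom_spec")
  d <- spec$shape
  lo <- spec$intensity_range[1]; hi <- spec$intensity_range[2]
  body_hu <- min(max(30, lo), hi)   # soft tissue
  with_seed(spec$seed, {
    z <- if (d[1] > 1) seq(-1, 1, length.out = d[1]) else 0
    y <- if (d[2] > 1) seq(-1, 1, length.out = d[2]) else 0
    x <- if (d[3] > 1) seq(-1, 1, length.out = d[3]) else 0
    v <- array(lo, dim = d)
    qb <- outer(outer((z / 0.95)^2, (y / 0.80)^2, "+"), (x / 0.80)^2, "+")
    v[qb <= 1] <- body_hu
    if (spec$n_structures > 0L) {
      for (s in seq_len(spec$n_structures)) {
        ctr <- runif(3, -0.45, 0.45)
        tube <- runif(1) < 0.3
        val <- runif(1, lo + 0.55 * (hi - lo), hi)
        if (tube) {
          ax <- runif(2, 0.06, 0.2)
          q2 <- outer(((y - ctr[2]) / ax[1])^2, ((x - ctr[3]) / ax[2])^2, "+")
          half <- runif(1, 0.3, 0.9)
          inside <- outer(abs(z - ctr[1]) <= half, q2 <= 1, "&")
          v[inside] <- val
        } else {
          ax <- runif(3, 0.08, 0.3)
          q <- outer(outer(((z - ctr[1]) / ax[1])^2,
                           ((y - ctr[2]) / ax[2])^2, "+"),
                     ((x - ctr[3]) / ax[3])^2, "+")
          v[q <= 1] <- val
        }
      }
    }
    v <- smooth3(v)
    v[v < lo] <- lo; v[v > hi] <- hi
    ct_volume(v, spacing = spec$spacing,
              id = sprintf("phantom-seed%d", spec$seed))
  })
}
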