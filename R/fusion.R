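#' View-complementary prediction triple
#'
#' The three predictions aligned to one axial slice: the outputs of the
#' axial-, sagittal- and coronal-view translation models after restacking
#' their per-view results into volumes and re-splitting axially.
#'
#' @param from_axial,from_sagittal,from_coronal numeric matrices of one
#'   axial slice shape.
#' @param axial_index list(volume id, 0-based slice index) provenance.
#' @param direction `"l2h"` (predictions of high-dose from low) or `"h2l"`.
#' @return An object of class `mv_prediction_triple`.
#' @export
view_prediction_triple <- function(from_axial, from_sagittal, from_coronal,
                                   axial_index = list(id = "", index = 0L),
                                   direction = c("l2h", "h2l")) {
  direction <- match.arg(direction)
  stop_if_not(is.matrix(from_axial) &&
                all(dim(from_axial) == dim(from_sagittal)) &&
                all(dim(from_axial) == dim(from_coronal)),
              "the three predictions must share one shape")
  structure(list(from_axial = from_axial, from_sagittal = from_sagittal,
                 from_coronal = from_coronal, axial_index = axial_index,
                 direction = direction),
            class = "mv_prediction_triple")
}

triple_list <- function(triple) {
  list(a = triple$from_axial, s = triple$from_sagittal,
       c = triple$from_coronal)
}

#' Cycle-reconstruction difference maps
#'
#' For each view prediction, maps it back to the reference domain with
#' `inverse_generator` and takes the elementwise absolute difference to
#' the reference image: `diff_V = |G_inv(pred_V) - reference|`. The total
#' map is the elementwise sum over views.
#'
#' @param triple a [view_prediction_triple()].
#' @param reference the real axial image in the opposite domain (e.g. the
#'   low-dose slice when the triple predicts high-dose).
#' @param inverse_generator generator (network or function) mapping the
#'   triple's domain back to the reference's domain.
#' @return An object of class `mv_difference_maps` with fields `diff_a`,
#'   `diff_s`, `diff_c`, `total`.
#' @export
cycle_difference_maps <- function(triple, reference, inverse_generator) {
  stop_if_not(inherits(triple, "mv_prediction_triple"),
              "triple must be a view_prediction_triple")
  stop_if_not(is.matrix(reference) &&
                all(dim(reference) == dim(triple$from_axial)),
              "reference shape mismatch")
  g <- as_image_fun(inverse_generator)
  dmaps <- lapply(triple_list(triple), function(p) abs(g(p) - reference))
  structure(list(diff_a = dmaps$a, diff_s = dmaps$s, diff_c = dmaps$c,
                 total = dmaps$a + dmaps$s + dmaps$c),
            class = "mv_difference_maps")
}

#' Per-pixel fusion weights from difference maps
#'
#' The core weighting rule: with `Diff = diff_a + diff_s + diff_c`,
#' \deqn{w_s = (diff_a + diff_c) / (2 Diff), \quad
#'       w_c = (diff_a + diff_s) / (2 Diff), \quad
#'       w_a = 1 - w_s - w_c,}
#' elementwise, so the view with the smallest cycle-reconstruction error
#' receives the largest weight. Weights sum to 1 at every pixel and each
#' lies in \[0, 1/2\] wherever `Diff > 0`. Pixels where all three
#' differences vanish get uniform weights 1/3 (configurable via `eps`:
#' with `eps > 0` the denominator becomes `Diff + eps` instead).
#'
#' @param diffs an [cycle_difference_maps()] result, or any list with
#'   nonnegative `diff_a`, `diff_s`, `diff_c` matrices.
#' @param mode `"map"` (per-pixel, default) or `"scalar"` (one weight per
#'   image from the mean differences; ablation aid).
#' @param eps optional nonnegative stabiliser added to the denominator;
#'   `0` (default) uses exact uniform weights at zero-total pixels.
#' @return An object of class `mv_weight_maps` with matrices `w_a`, `w_s`,
#'   `w_c`.
#' @export
weight_maps_from_diffs <- function(diffs, mode = c("map", "scalar"),
                                   eps = 0) {
  mode <- match.arg(mode)
  da <- diffs$diff_a; ds <- diffs$diff_s; dc <- diffs$diff_c
  stop_if_not(all(da >= 0) && all(ds >= 0) && all(dc >= 0),
              "difference maps must be nonnegative")
  if (mode == "scalar") {
    da <- matrix(mean(da), nrow(da), ncol(da))
    ds <- matrix(mean(ds), nrow(ds), ncol(ds))
    dc <- matrix(mean(dc), nrow(dc), ncol(dc))
  }
  total <- da + ds + dc
  if (eps > 0) {
    den <- total + eps
    ws <- 0.5 * (da + dc) / den
    wc <- 0.5 * (da + ds) / den
    wa <- 1 - ws - wc
  } else {
    # exact three-way ties (including all-zero) resolve to exact thirds,
    # so equal difference maps reproduce average fusion bit-exactly
    tie <- (da == ds) & (ds == dc)
    den <- ifelse(total == 0, 1, total)
    ws <- ifelse(tie, 1 / 3, 0.5 * (da + dc) / den)
    wc <- ifelse(tie, 1 / 3, 0.5 * (da + ds) / den)
    wa <- ifelse(tie, 1 / 3, 1 - ws - wc)
  }
  structure(list(w_a = wa, w_s = ws, w_c = wc),
            class = "mv_weight_maps")
}

#' Cycle-consistency-weighted fusion
#'
#' Elementwise convex combination `w_a * p_a + w_s * p_s + w_c * p_c` of
#' the three view predictions; the fused pseudo-image used as a
#' supervision target in stage 2.
#'
#' @param triple a [view_prediction_triple()].
#' @param weights an [weight_maps_from_diffs()] result (maps must sum to 1
#'   elementwise within `tol`).
#' @param tol tolerance for the sum-to-one check (default 1e-6).
#' @return Fused matrix.
#' @export
weighted_fuse <- function(triple, weights, tol = 1e-6) {
  stop_if_not(inherits(triple, "mv_prediction_triple"),
              "triple must be a view_prediction_triple")
  stop_if_not(all(dim(weights$w_a) == dim(triple$from_axial)),
              "weight map shape mismatch")
  s <- weights$w_a + weights$w_s + weights$w_c
  stop_if_not(max(abs(s - 1)) <= tol, "weights must sum to one elementwise")
  weights$w_a * triple$from_axial + weights$w_s * triple$from_sagittal +
    weights$w_c * triple$from_coronal
}

#' Average fusion (ablation baseline)
#'
#' Unweighted elementwise mean of the three predictions; identical to
#' [weighted_fuse()] with uniform weights, and reproduced bit-exactly by
#' the weighted rule whenever the three difference maps are equal.
#'
#' @param triple a [view_prediction_triple()].
#' @return Fused matrix.
#' @export
average_fuse <- function(triple) {
  stop_if_not(inherits(triple, "mv_prediction_triple"),
              "triple must be a view_prediction_triple")
  u <- matrix(1 / 3, nrow(triple$from_axial), ncol(triple$from_axial))
  weighted_fuse(triple, list(w_a = u, w_s = u, w_c = u), tol = 1e-9)
}
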