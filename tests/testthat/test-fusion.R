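triple_const <- function(a, s, c, n = 6L) {
  view_prediction_triple(matrix(a, n, n), matrix(s, n, n), matrix(c, n, n))
}

test_that("cycle difference maps implement |G_inv(pred) - reference|", {
  ref <- matrix(runif(36, -1, 1), 6)
  tr <- view_prediction_triple(ref, ref, ref)
  dm <- cycle_difference_maps(tr, ref, function(m) m)
  expect_true(all(dm$diff_a == 0) && all(dm$diff_s == 0) &&
                all(dm$diff_c == 0))
  # predictions at reference + (0, 1, 2), identity inverse
  tr2 <- view_prediction_triple(ref, ref + 1, ref + 2)
  dm2 <- cycle_difference_maps(tr2, ref, function(m) m)
  expect_equal(dm2$diff_a, matrix(0, 6, 6))
  expect_equal(dm2$diff_s, matrix(1, 6, 6))
  expect_equal(dm2$diff_c, matrix(2, 6, 6))
  expect_equal(dm2$total, matrix(3, 6, 6))
  # pure function: same values on a copied array
  tr3 <- view_prediction_triple(ref + 0, ref + 1, ref + 2)
  expect_identical(cycle_difference_maps(tr3, ref, function(m) m), dm2)
})

test_that("weight maps match the hand-computed triples", {
  mk <- function(a, s, c) {
    list(diff_a = matrix(a, 2, 2), diff_s = matrix(s, 2, 2),
         diff_c = matrix(c, 2, 2))
  }
  w1 <- weight_maps_from_diffs(mk(1, 1, 1))
  expect_equal(w1$w_a, matrix(1 / 3, 2, 2))
  expect_equal(w1$w_s, matrix(1 / 3, 2, 2))
  expect_equal(w1$w_c, matrix(1 / 3, 2, 2))
  w2 <- weight_maps_from_diffs(mk(0, 1, 1))  # best view gets most weight
  expect_equal(w2$w_a, matrix(0.5, 2, 2))
  expect_equal(w2$w_s, matrix(0.25, 2, 2))
  expect_equal(w2$w_c, matrix(0.25, 2, 2))
  w3 <- weight_maps_from_diffs(mk(2, 1, 1))
  expect_equal(w3$w_a, matrix(0.25, 2, 2))
  expect_equal(w3$w_s, matrix(3 / 8, 2, 2))
  expect_equal(w3$w_c, matrix(3 / 8, 2, 2))
})

test_that("weights sum to one and lie in [0, 1/2] wherever Diff > 0", {
  withr::with_seed(11, {
    for (rep in 1:20) {
      diffs <- list(diff_a = matrix(rexp(25), 5),
                    diff_s = matrix(rexp(25), 5),
                    diff_c = matrix(rexp(25), 5))
      w <- weight_maps_from_diffs(diffs)
      expect_equal(w$w_a + w$w_s + w$w_c, matrix(1, 5, 5))
      for (m in w[c("w_a", "w_s", "w_c")]) {
        expect_true(all(m >= 0 - 1e-12) && all(m <= 0.5 + 1e-12))
      }
    }
  })
})

test_that("decreasing one view's difference never decreases its weight", {
  withr::with_seed(3, {
    base <- list(diff_a = matrix(rexp(16), 4), diff_s = matrix(rexp(16), 4),
                 diff_c = matrix(rexp(16), 4))
    w0 <- weight_maps_from_diffs(base)
    better <- base
    better$diff_s <- base$diff_s * 0.5
    w1 <- weight_maps_from_diffs(better)
    expect_true(all(w1$w_s >= w0$w_s - 1e-12))
  })
})

test_that("zero-total pixels get uniform thirds; eps mode is available", {
  diffs <- list(diff_a = matrix(c(0, 1), 1, 2),
                diff_s = matrix(c(0, 1), 1, 2),
                diff_c = matrix(c(0, 2), 1, 2))
  w <- weight_maps_from_diffs(diffs)
  expect_equal(c(w$w_a[1, 1], w$w_s[1, 1], w$w_c[1, 1]), rep(1 / 3, 3))
  expect_equal(w$w_c[1, 2], 0.5 * (1 + 1) / 4)
  # eps mode smooths the denominator instead; at a zero-total pixel the
  # sagittal/coronal weights vanish and the axial complement takes all
  we <- weight_maps_from_diffs(diffs, eps = 1e-8)
  expect_equal(we$w_s[1, 1], 0)
  expect_equal(we$w_a[1, 1] + we$w_s[1, 1] + we$w_c[1, 1], 1)
  expect_equal(we$w_c[1, 2], w$w_c[1, 2], tolerance = 1e-6)
})

test_that("scalar mode gives constant per-image weights", {
  withr::with_seed(8, {
    diffs <- list(diff_a = matrix(rexp(16), 4), diff_s = matrix(rexp(16), 4),
                  diff_c = matrix(rexp(16), 4))
    w <- weight_maps_from_diffs(diffs, mode = "scalar")
    for (m in w[c("w_a", "w_s", "w_c")]) expect_equal(max(m) - min(m), 0)
    expect_equal(w$w_a + w$w_s + w$w_c, matrix(1, 4, 4))
  })
})

test_that("weighted fusion closed forms and convexity", {
  tr <- triple_const(0, 4, 8)
  w <- list(w_a = matrix(0.5, 6, 6), w_s = matrix(0.25, 6, 6),
            w_c = matrix(0.25, 6, 6))
  expect_equal(weighted_fuse(tr, w), matrix(3, 6, 6))
  w100 <- list(w_a = matrix(1, 6, 6), w_s = matrix(0, 6, 6),
               w_c = matrix(0, 6, 6))
  expect_identical(weighted_fuse(tr, w100), tr$from_axial)
  # identical predictions are a fixed point for any valid weights
  same <- view_prediction_triple(matrix(1:36, 6), matrix(1:36, 6),
                                 matrix(1:36, 6))
  withr::with_seed(2, {
    wa <- matrix(runif(36, 0, 0.5), 6); ws <- matrix(runif(36, 0, 0.5), 6)
    wr <- list(w_a = wa, w_s = ws, w_c = 1 - wa - ws)
    expect_equal(weighted_fuse(same, wr), same$from_axial)
    # fused image within [min, max] of the predictions
    tr2 <- view_prediction_triple(matrix(runif(36), 6),
                                  matrix(runif(36), 6),
                                  matrix(runif(36), 6))
    f <- weighted_fuse(tr2, wr)
    lo <- pmin(tr2$from_axial, tr2$from_sagittal, tr2$from_coronal)
    hi <- pmax(tr2$from_axial, tr2$from_sagittal, tr2$from_coronal)
    expect_true(all(f >= lo - 1e-12) && all(f <= hi + 1e-12))
  })
  bad <- list(w_a = matrix(0.6, 6, 6), w_s = matrix(0.6, 6, 6),
              w_c = matrix(0.2, 6, 6))
  expect_error(weighted_fuse(tr, bad), "sum to one")
})

test_that("average fusion equals uniform and equal-diff weighted fusion", {
  expect_equal(average_fuse(triple_const(0, 3, 6)), matrix(3, 6, 6))
  withr::with_seed(7, {
    tr <- view_prediction_triple(matrix(rnorm(36), 6), matrix(rnorm(36), 6),
                                 matrix(rnorm(36), 6))
    unif <- list(w_a = matrix(1 / 3, 6, 6), w_s = matrix(1 / 3, 6, 6),
                 w_c = matrix(1 / 3, 6, 6))
    expect_identical(average_fuse(tr),
                     weighted_fuse(tr, unif, tol = 1e-9))
    # equal diffs reproduce average fusion through the weighting rule
    d <- matrix(rexp(36), 6)
    w <- weight_maps_from_diffs(list(diff_a = d, diff_s = d, diff_c = d))
    expect_identical(weighted_fuse(tr, w), average_fuse(tr))
  })
})

test_that("fusion inputs are validated", {
  expect_error(view_prediction_triple(matrix(0, 2, 2), matrix(0, 2, 2),
                                      matrix(0, 3, 3)), "share one shape")
  expect_error(weight_maps_from_diffs(list(diff_a = matrix(-1, 2, 2),
                                           diff_s = matrix(1, 2, 2),
                                           diff_c = matrix(1, 2, 2))),
               "nonnegative")
  tr <- triple_const(0, 1, 2, n = 4L)
  expect_error(cycle_difference_maps(tr, matrix(0, 3, 3), function(m) m),
               "shape")
})
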