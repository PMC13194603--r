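#' Peak signal-to-noise ratio
#'
#' `10 * log10(data_range^2 / MSE)` in dB. Identical inputs (MSE 0) return
#' `Inf` as a sentinel.
#'
#' @param pred,ref numeric arrays of equal shape.
#' @param data_range positive intensity span of the data (default: the
#'   package HU window span, 1400).
#' @return scalar dB.
#' @export
psnr <- function(pred, ref, data_range = diff(HU_WINDOW)) {
  stop_if_not(all(dim(pred) == dim(ref)) || (is.null(dim(pred)) &&
                                               length(pred) == length(ref)),
              "shape mismatch")
  stop_if_not(is_scalar_number(data_range) && data_range > 0,
              "data_range must be positive")
  mse <- mean((pred - ref)^2)
  if (mse == 0) return(Inf)
  10 * log10(data_range^2 / mse)
}

gaussian_kernel <- function(size, sigma) {
  half <- (size - 1) / 2
  g <- exp(-(seq(-half, half)^2) / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

# valid-mode windowed filtering of a matrix with a kernel matrix
win_filter <- function(m, kern) {
  k <- nrow(kern)
  out <- cpp_conv2d_forward(array(m, dim = c(dim(m), 1L, 1L)),
                            matrix(as.numeric(t(kern)), nrow = 1),
                            0, k, k, 1L, 0L)
  matrix(out, nrow = dim(out)[1])
}

#' Structural similarity index (SSIM)
#'
#' Standard windowed SSIM with a Gaussian window (default 11x11,
#' sigma 1.5) and stabilisers `C1 = (k1 * data_range)^2`,
#' `C2 = (k2 * data_range)^2` with `k1 = 0.01`, `k2 = 0.03`; the mean of
#' the local SSIM map over the valid (fully-windowed) region.
#'
#' @param pred,ref numeric matrices of equal shape.
#' @param data_range positive intensity span.
#' @param window_size odd window side, must not exceed the image.
#' @param sigma Gaussian window standard deviation.
#' @param k1,k2 stabiliser constants.
#' @return scalar in \[-1, 1\]; exactly 1 for identical images.
#' @export
ssim <- function(pred, ref, data_range = diff(HU_WINDOW),
                 window_size = 11L, sigma = 1.5, k1 = 0.01, k2 = 0.03) {
  stop_if_not(is.matrix(pred) && all(dim(pred) == dim(ref)),
              "shape mismatch")
  stop_if_not(window_size <= min(dim(pred)),
              "window larger than image")
  kern <- gaussian_kernel(window_size, sigma)
  c1 <- (k1 * data_range)^2
  c2 <- (k2 * data_range)^2
  mu1 <- win_filter(pred, kern)
  mu2 <- win_filter(ref, kern)
  s11 <- win_filter(pred * pred, kern) - mu1^2
  s22 <- win_filter(ref * ref, kern) - mu2^2
  s12 <- win_filter(pred * ref, kern) - mu1 * mu2
  num <- (2 * mu1 * mu2 + c1) * (2 * s12 + c2)
  den <- (mu1^2 + mu2^2 + c1) * (s11 + s22 + c2)
  mean(num / den)
}

#' Relative mean absolute error
#'
#' `scale * sum(|pred - ref|) / sum(|ref - offset|)`. The exact scale and
#' offset convention behind published RMAE values is not recoverable; the
#' default reports a percentage (`scale = 100`) against intensities
#' rebased to an air floor of -1024 HU so the denominator is positive on
#' CT-like data. Both are configurable and every report states them.
#'
#' @param pred,ref numeric arrays of equal shape; `ref` must not be
#'   identically equal to `offset`.
#' @param scale multiplier of the ratio (default 100).
#' @param offset intensity rebasing constant (default -1024).
#' @return nonnegative scalar.
#' @export
rmae <- function(pred, ref, scale = 100, offset = -1024) {
  stop_if_not(all(dim(pred) == dim(ref)) || (is.null(dim(pred)) &&
                                               length(pred) == length(ref)),
              "shape mismatch")
  den <- sum(abs(ref - offset))
  stop_if_not(den > 0, "reference is identically equal to the offset")
  scale * sum(abs(pred - ref)) / den
}

#' Evaluate a model on paired test volumes
#'
#' Applies the model to each low-dose test volume and computes PSNR, SSIM
#' and RMAE per axial slice against the paired high-dose volume,
#' aggregated as mean and standard deviation. Passing `model =
#' "identity"` scores the noisy input itself (the LDCT row of a results
#' table).
#'
#' @param model an `mv_translation_model`, the string `"identity"`, or a
#'   function mapping a [ct_volume()] to a [ct_volume()].
#' @param test_pairs list of `list(low = ct_volume, high = ct_volume)`
#'   paired test volumes.
#' @param data_range PSNR/SSIM intensity span.
#' @param rmae_offset RMAE rebasing constant (see [rmae()]).
#' @param csv optional path; when given the per-slice table is written as
#'   CSV.
#' @return list with `table` (per-slice data frame) and `summary`
#'   (mean/sd per metric).
#' @export
evaluate_testset <- function(model, test_pairs,
                             data_range = diff(HU_WINDOW),
                             rmae_offset = -1024, csv = NULL) {
  stop_if_not(length(test_pairs) > 0, "test_pairs must be nonempty")
  ok <- vapply(test_pairs, function(p) {
    is.list(p) && inherits(p$low, "ct_volume") &&
      inherits(p$high, "ct_volume") &&
      all(dim(p$low) == dim(p$high))
  }, logical(1))
  stop_if_not(all(ok), "test volumes must be paired low/high ct_volumes of equal shape")
  apply_model <- if (identical(model, "identity")) {
    function(v) v
  } else if (is.function(model)) {
    model
  } else if (inherits(model, "mv_translation_model")) {
    function(v) denoise_volume(model, v, "l2h")
  } else stop("unsupported model argument", call. = FALSE)
  rows <- list()
  for (p in test_pairs) {
    pred <- apply_model(p$low)
    ps <- resplit_axial(pred)$slices
    hs <- resplit_axial(p$high)$slices
    for (i in seq_along(ps)) {
      rows[[length(rows) + 1L]] <- data.frame(
        volume = p$low$id, slice = i - 1L,
        psnr = psnr(ps[[i]], hs[[i]], data_range),
        ssim = ssim(ps[[i]], hs[[i]], data_range),
        rmae = rmae(ps[[i]], hs[[i]], offset = rmae_offset))
    }
  }
  tab <- do.call(rbind, rows)
  summ <- data.frame(
    metric = c("psnr", "ssim", "rmae"),
    mean = c(mean(tab$psnr), mean(tab$ssim), mean(tab$rmae)),
    sd = c(sd(tab$psnr), sd(tab$ssim), sd(tab$rmae)))
  if (!is.null(csv)) write.csv(tab, csv, row.names = FALSE)
  list(table = tab, summary = summ)
}
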