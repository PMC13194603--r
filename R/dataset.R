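#' Build an unpaired view-wise slice dataset
#'
#' Splits every volume along `view`, concatenates the slices into a
#' low-dose pool and a high-dose pool, and destroys the index
#' correspondence between the pools by shuffling each independently
#' (training sets only; keep test volumes paired and evaluate with
#' [evaluate_testset()]). Pools may have unequal sizes.
#'
#' @param ldct_volumes,hdct_volumes nonempty lists of [ct_volume()].
#' @param view `"axial"`, `"sagittal"` or `"coronal"`.
#' @param shuffle_seed integer; shuffling is reproducible per seed.
#' @param shuffle destroy pairing (default TRUE). With `shuffle = FALSE`
#'   the dataset keeps `paired = TRUE` and index correspondence.
#' @return An object of class `mv_unpaired_dataset` with fields `low`,
#'   `high` (lists of matrices), `view`, `paired`.
#' @export
build_unpaired_dataset <- function(ldct_volumes, hdct_volumes, view,
                                   shuffle_seed = 1L, shuffle = TRUE) {
  stop_if_not(length(ldct_volumes) > 0 && length(hdct_volumes) > 0,
              "volume lists must be nonempty")
  pool <- function(vols) {
    sets <- lapply(vols, split_volume, view = view)
    shapes <- unique(lapply(sets, function(s) dim(s$slices[[1]])))
    stop_if_not(length(shapes) == 1L,
                sprintf("mixed in-plane shapes within view '%s' would break batching",
                        view))
    unlist(lapply(sets, function(s) s$slices), recursive = FALSE)
  }
  low <- pool(ldct_volumes)
  high <- pool(hdct_volumes)
  if (shuffle) {
    with_seed(shuffle_seed, {
      low <- low[sample.int(length(low))]
      high <- high[sample.int(length(high))]
    })
  }
  structure(list(low = low, high = high, view = view, paired = !shuffle),
            class = "mv_unpaired_dataset")
}

#' @export
print.mv_unpaired_dataset <- function(x, ...) {
  cat(sprintf("<unpaired %s dataset: %d low-dose / %d high-dose slices%s>\n",
              x$view, length(x$low), length(x$high),
              if (x$paired) " (paired)" else ""))
  invisible(x)
}

# intensity normalisation: affine map of the HU window to [-1, 1] at the
# data boundary, inverted on network output
HU_WINDOW <- c(-1000, 400)

normalize_hu <- function(m, window = HU_WINDOW) {
  2 * (m - window[1]) / (window[2] - window[1]) - 1
}

denormalize_hu <- function(m, window = HU_WINDOW) {
  (m + 1) / 2 * (window[2] - window[1]) + window[1]
}

# random aligned patch coordinates for an H x W slice
crop_coords <- function(hw, patch) {
  stop_if_not(patch <= hw[1] && patch <= hw[2],
              sprintf("patch size %d exceeds slice dims %d x %d", patch,
                      hw[1], hw[2]))
  r <- sample.int(hw[1] - patch + 1L, 1L)
  c <- sample.int(hw[2] - patch + 1L, 1L)
  list(rows = r:(r + patch - 1L), cols = c:(c + patch - 1L))
}
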