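#' CT volume container
#'
#' A 3D intensity array in Hounsfield-like units with voxel spacing
#' metadata. The canonical axis order is fixed package-wide as (z, y, x):
#' the first array dimension is the axial slice axis, the second the
#' coronal (y) axis and the third the sagittal (x) axis. Anisotropic
#' spacing is carried as metadata only; no resampling is ever performed.
#'
#' @param intensities numeric 3D array.
#' @param spacing numeric(3), strictly positive voxel spacing in mm along
#'   (z, y, x).
#' @param id opaque identifier string.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(intensities, spacing = c(1, 1, 1), id = "vol") {
  stop_if_not(is.array(intensities) && length(dim(intensities)) == 3L,
              "intensities must be a 3D array")
  stop_if_not(all(dim(intensities) >= 1L), "all dimensions must be >= 1")
  stop_if_not(is.numeric(spacing) && length(spacing) == 3L &&
                all(spacing > 0), "spacing must be three positive lengths")
  structure(list(intensities = intensities, spacing = as.numeric(spacing),
                 axis_order = "zyx", id = as.character(id)),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<ct_volume '%s': %d x %d x %d (z,y,x), spacing %.3g/%.3g/%.3g mm>\n",
              x$id, d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$intensities)

VIEW_TAGS <- c("axial", "sagittal", "coronal")

view_axis <- function(view) {
  switch(view, axial = 1L, coronal = 2L, sagittal = 3L,
         stop(sprintf("unknown view tag '%s'; expected one of %s", view,
                      paste(VIEW_TAGS, collapse = ", ")), call. = FALSE))
}

#' Split a volume into 2D slices along one anatomical view
#'
#' Lossless extraction (no interpolation or resampling): axial gives z
#' slices of shape (y, x); coronal gives y slices of (z, x); sagittal gives
#' x slices of (z, y). Slices are ordered ascending along the view axis
#' (0-based source indices `seq_along(slices) - 1`).
#'
#' @param volume a [ct_volume()].
#' @param view `"axial"`, `"sagittal"` or `"coronal"`.
#' @return An object of class `slice_set` with fields `view`, `slices`
#'   (list of matrices), `source_shape`, `source_id`.
#' @export
split_volume <- function(volume, view) {
  stop_if_not(inherits(volume, "ct_volume"), "volume must be a ct_volume")
  ax <- view_axis(view)
  v <- volume$intensities
  d <- dim(v)
  slices <- switch(as.character(ax),
    "1" = lapply(seq_len(d[1]), function(i) matrix(v[i, , ], d[2], d[3])),
    "2" = lapply(seq_len(d[2]), function(j) matrix(v[, j, ], d[1], d[3])),
    "3" = lapply(seq_len(d[3]), function(k) matrix(v[, , k], d[1], d[2])))
  structure(list(view = view, slices = slices, source_shape = d,
                 source_id = volume$id, spacing = volume$spacing),
            class = "slice_set")
}

#' Reassemble a slice set into a volume
#'
#' Exact inverse of [split_volume()]: every intensity returns to its
#' original voxel coordinate, bit-exactly.
#'
#' @param slices a `slice_set`.
#' @return A [ct_volume()] with the original shape.
#' @export
stack_slices <- function(slices) {
  stop_if_not(inherits(slices, "slice_set"), "slices must be a slice_set")
  d <- slices$source_shape
  ax <- view_axis(slices$view)
  n_expect <- d[ax]
  stop_if_not(length(slices$slices) == n_expect,
              sprintf("slice count %d inconsistent with source shape (expected %d)",
                      length(slices$slices), n_expect))
  expect_hw <- dim(slices$slices[[1]])
  want_hw <- switch(as.character(ax), "1" = d[2:3], "2" = d[c(1, 3)],
                    "3" = d[1:2])
  stop_if_not(all(vapply(slices$slices,
                         function(s) identical(dim(s), as.integer(want_hw)) ||
                           all(dim(s) == want_hw), logical(1))),
              "slice shapes inconsistent with source shape")
  stop_if_not(all(expect_hw == want_hw),
              "slice shapes inconsistent with source shape")
  v <- array(0, dim = d)
  for (i in seq_along(slices$slices)) {
    switch(as.character(ax),
           "1" = {v[i, , ] <- slices$slices[[i]]},
           "2" = {v[, i, ] <- slices$slices[[i]]},
           "3" = {v[, , i] <- slices$slices[[i]]})
  }
  ct_volume(v, spacing = slices$spacing %||% c(1, 1, 1),
            id = slices$source_id)
}

#' Convenience: split along the axial view
#'
#' Identical to `split_volume(volume, "axial")`; used when re-splitting
#' stacked per-view denoising results into axial images.
#'
#' @inheritParams split_volume
#' @return A `slice_set` with `view = "axial"`.
#' @export
resplit_axial <- function(volume) split_volume(volume, "axial")

#' @export
print.slice_set <- function(x, ...) {
  cat(sprintf("<slice_set: %d %s slices of %d x %d from '%s'>\n",
              length(x$slices), x$view, nrow(x$slices[[1]]),
              ncol(x$slices[[1]]), x$source_id))
  invisible(x)
}
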