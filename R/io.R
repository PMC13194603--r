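#' Write a CT volume to a raw array container
#'
#' The container is a little-endian float32 `.bin` file (Fortran/column
#' order over the canonical (z, y, x) array) with a JSON sidecar
#' (`<path>.json`) recording shape, spacing, dtype and id.
#'
#' @param volume a [ct_volume()].
#' @param path output path; `.bin` is appended when absent.
#' @return The `.bin` path, invisibly.
#' @export
write_volume <- function(volume, path) {
  stop_if_not(inherits(volume, "ct_volume"), "volume must be a ct_volume")
  if (!grepl("\\.bin$", path)) path <- paste0(path, ".bin")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(volume$intensities), con, size = 4L,
           endian = "little")
  meta <- list(shape = dim(volume$intensities), spacing = volume$spacing,
               dtype = "float32", axis_order = volume$axis_order,
               id = volume$id)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a CT volume from a raw array container
#'
#' @param path path to the `.bin` file written by [write_volume()].
#' @return A [ct_volume()].
#' @export
read_volume <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  stop_if_not(identical(meta$dtype, "float32"),
              sprintf("unsupported dtype '%s'", meta$dtype))
  n <- prod(meta$shape)
  con <- file(path, "rb")
  on.exit(close(con))
  vals <- readBin(con, numeric(), n = n, size = 4L, endian = "little")
  stop_if_not(length(vals) == n, "truncated volume file")
  ct_volume(array(vals, dim = meta$shape), spacing = meta$spacing,
            id = meta$id %||% basename(path))
}
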