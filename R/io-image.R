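#' Read a greyscale projection image as a slice grid
#'
#' Loads an 8-bit greyscale PNG (e.g. a screen capture of a 3-D projection
#' view, pre-cropped to the brain area) into a [slice_grid()] with bit
#' depth 8 and no slice index. Multi-channel images are accepted only when
#' all colour channels are identical (true greyscale stored as RGB); an
#' alpha channel, if present, is ignored.
#'
#' @param path path to the PNG file.
#' @return A [slice_grid()] with `bit_depth = 8` and `slice_index = NA`.
#' @export
read_projection_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) {
    nc <- dim(img)[3]
    ch <- min(nc, 3L)  # drop alpha
    if (ch > 1L) {
      for (k in 2:ch) {
        if (any(abs(img[, , k] - img[, , 1]) > 1e-9)) {
          stop("multi-channel image with unequal channels; ",
               "projection captures must be greyscale", call. = FALSE)
        }
      }
    }
    img <- img[, , 1]
  }
  # PNG rows run top-to-bottom in y; transpose into [x, y] pixel indexing
  vals <- round(t(img) * 255)
  slice_grid(vals, bit_depth = 8L, slice_index = NA_integer_)
}

#' Write a slice grid as an 8-bit greyscale PNG
#'
#' Intensities are scaled by the slice's bit-depth maximum, so the full
#' dynamic range maps to 0..255. Useful for exporting a phantom's slice as
#' a stand-in projection image.
#'
#' @param slice a [slice_grid()].
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_slice_png <- function(slice, path) {
  stopifnot(inherits(slice, "slice_grid"))
  g <- t(slice$values) / intensity_max(slice$bit_depth)
  png::writePNG(g, path)
  invisible(path)
}
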