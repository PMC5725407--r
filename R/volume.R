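#' Construct a voxel volume
#'
#' A `voxel_volume` is a dense 3-D grid of non-negative integer intensities
#' with isotropic-or-not physical spacing and a stated bit depth. Voxel
#' coordinates are 0-based throughout the package; the z axis counts
#' downward from the top of the head, so the 30th slice from the top is
#' z index 29.
#'
#' @param values 3-D numeric array of non-negative integers, indexed
#'   `[x + 1, y + 1, z + 1]` for 0-based voxel coordinates (x, y, z).
#' @param spacing_mm positive length-3 numeric, physical voxel size in mm.
#'   Default `c(2, 2, 2)`, the standard-model geometry.
#' @param bit_depth positive integer; every value must lie in
#'   `[0, 2^bit_depth - 1]`. Default 15.
#' @return An object of class `voxel_volume` with fields `values`, `dims`,
#'   `spacing_mm`, `bit_depth`.
#' @examples
#' v <- voxel_volume(array(0L, c(4, 5, 6)), bit_depth = 8)
#' v$dims
#' @export
voxel_volume <- function(values, spacing_mm = c(2, 2, 2), bit_depth = 15L) {
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("`values` must be a 3-D array", call. = FALSE)
  }
  if (!is.numeric(spacing_mm) || length(spacing_mm) != 3L ||
      any(spacing_mm <= 0)) {
    stop("`spacing_mm` must be 3 positive numbers", call. = FALSE)
  }
  bit_depth <- as.integer(bit_depth)
  if (length(bit_depth) != 1L || is.na(bit_depth) || bit_depth < 1L) {
    stop("`bit_depth` must be a positive integer", call. = FALSE)
  }
  vmax <- intensity_max(bit_depth)
  rng <- range(values)
  if (is.na(rng[1])) stop("`values` contains NA", call. = FALSE)
  if (rng[1] < 0) stop("voxel values must be non-negative", call. = FALSE)
  if (rng[2] > vmax) {
    stop(sprintf("voxel value %s exceeds bit-depth maximum %s",
                 format(rng[2]), format(vmax)), call. = FALSE)
  }
  structure(
    list(values = values, dims = dim(values),
         spacing_mm = as.numeric(spacing_mm), bit_depth = bit_depth),
    class = "voxel_volume"
  )
}

# maximum allowable intensity for a bit depth; double to stay exact past 2^31
intensity_max <- function(bit_depth) 2^as.numeric(bit_depth) - 1

#' @export
print.voxel_volume <- function(x, ...) {
  cat(sprintf("<voxel_volume> %d x %d x %d voxels, %g x %g x %g mm, %d-bit\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$spacing_mm[1], x$spacing_mm[2], x$spacing_mm[3],
              x$bit_depth))
  cat(sprintf("  nonzero voxels: %d; intensity range [%s, %s]\n",
              sum(x$values != 0), format(min(x$values)),
              format(max(x$values))))
  invisible(x)
}

#' Construct a 2-D slice grid
#'
#' A `slice_grid` holds one lateral plane of intensities plus a logical
#' mask marking the pixels that remain eligible for sonification. Fresh
#' slices start fully unmasked; [apply_mask()] clears pixels below the
#' white-matter threshold.
#'
#' @param values numeric matrix indexed `[x + 1, y + 1]` (0-based pixel
#'   coordinates).
#' @param bit_depth positive integer bit depth of the intensities.
#' @param slice_index 0-based depth index of the plane within its parent
#'   volume, or `NA` for standalone images (e.g. projection screen grabs).
#' @param mask logical matrix of the same shape; default all `TRUE`.
#' @return An object of class `slice_grid`.
#' @export
slice_grid <- function(values, bit_depth, slice_index = NA_integer_,
                       mask = NULL) {
  if (!is.matrix(values)) stop("`values` must be a matrix", call. = FALSE)
  bit_depth <- as.integer(bit_depth)
  vmax <- intensity_max(bit_depth)
  if (any(values < 0) || any(values > vmax)) {
    stop("slice values outside [0, 2^bit_depth - 1]", call. = FALSE)
  }
  if (is.null(mask)) {
    mask <- matrix(TRUE, nrow(values), ncol(values))
  }
  stopifnot(is.logical(mask), all(dim(mask) == dim(values)))
  structure(
    list(values = values, mask = mask, dims = dim(values),
         slice_index = as.integer(slice_index), bit_depth = bit_depth),
    class = "slice_grid"
  )
}

#' @export
print.slice_grid <- function(x, ...) {
  cat(sprintf("<slice_grid> %d x %d pixels, %d-bit, slice index %s\n",
              x$dims[1], x$dims[2], x$bit_depth,
              ifelse(is.na(x$slice_index), "n/a",
                     as.character(x$slice_index))))
  cat(sprintf("  unmasked pixels: %d / %d\n", sum(x$mask), length(x$mask)))
  invisible(x)
}
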