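#' Extract a lateral slice from a volume
#'
#' Slices are counted ordinally from the top of the head: ordinal 1 is the
#' top plane and ordinal k is depth index k - 1. With the standard-model
#' geometry (86 x 100 x 86 voxels at 2 mm) the 30th slice spans physical
#' depths 58--60 mm from the top edge, passing through representative
#' frontal, parietal, and sensorimotor regions.
#'
#' @param volume a [voxel_volume()].
#' @param ordinal_from_top 1-based slice ordinal counted from the top
#'   (default 30, the diagnostic slice).
#' @return A [slice_grid()] with an all-true mask and `slice_index`
#'   `ordinal_from_top - 1`.
#' @export
extract_slice <- function(volume, ordinal_from_top = 30L) {
  stopifnot(inherits(volume, "voxel_volume"))
  k <- as.integer(ordinal_from_top)
  if (length(k) != 1L || is.na(k) || k < 1L || k > volume$dims[3]) {
    stop(sprintf("slice ordinal %s out of range [1, %d]",
                 format(ordinal_from_top), volume$dims[3]), call. = FALSE)
  }
  slice_grid(volume$values[, , k], bit_depth = volume$bit_depth,
             slice_index = k - 1L)
}

#' White-matter masking threshold
#'
#' The masking threshold is a fraction of the maximum allowable intensity
#' for the dataset's bit depth: `fraction * (2^bit_depth - 1)`, not
#' rounded. At the default 45% and 15 bits this is 14745.15 out of 32767.
#' Voxels below it (white matter and background, whose metabolic signal is
#' not diagnostic for AD) are excluded from sonification.
#'
#' @param fraction masking fraction in (0, 1); default 0.45.
#' @param bit_depth positive integer bit depth.
#' @return The threshold intensity (numeric scalar).
#' @examples
#' mask_threshold(0.45, 15) # 14745.15
#' @export
mask_threshold <- function(fraction = 0.45, bit_depth = 15L) {
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction >= 1) {
    stop("`fraction` must lie strictly between 0 and 1", call. = FALSE)
  }
  fraction * intensity_max(bit_depth)
}

#' Mask sub-threshold pixels of a slice
#'
#' Marks as masked every pixel whose intensity fell below the threshold;
#' the rule is strict (`value < threshold` is masked), so a value exactly
#' at the threshold survives. Values are left untouched -- only the mask
#' changes -- and masking composes with any mask already present.
#'
#' @param slice a [slice_grid()].
#' @param threshold intensity threshold, typically from [mask_threshold()].
#' @return The slice with its mask updated.
#' @export
apply_mask <- function(slice, threshold) {
  stopifnot(inherits(slice, "slice_grid"))
  vmax <- intensity_max(slice$bit_depth)
  if (threshold < 0 || threshold > vmax) {
    stop(sprintf("threshold %s outside [0, %s]", format(threshold),
                 format(vmax)), call. = FALSE)
  }
  slice$mask <- slice$mask & (slice$values >= threshold)
  slice
}

# Half-open even-odd point-in-polygon rasterization over pixel centers.
# A pixel center on an upward-crossed left edge is inside and on the
# matching right edge is outside, so regions sharing an edge tile the
# plane with no gap or double coverage. Returns a logical [nx, ny] matrix.
rasterize_polygon <- function(poly, nx, ny) {
  px <- matrix(rep(0:(nx - 1L), ny), nx, ny)
  py <- matrix(rep(0:(ny - 1L), each = nx), nx, ny)
  inside <- matrix(FALSE, nx, ny)
  n <- nrow(poly)
  j <- n
  for (i in seq_len(n)) {
    x1 <- poly[j, 1]; y1 <- poly[j, 2]
    x2 <- poly[i, 1]; y2 <- poly[i, 2]
    if (y1 != y2) {
      crosses <- ((y1 <= py) != (y2 <= py))
      xint <- x1 + (py - y1) * (x2 - x1) / (y2 - y1)
      inside <- xor(inside, crosses & (px < xint))
    }
    j <- i
  }
  inside
}

#' Rasterize lobe boundaries into a region label map
#'
#' Every pixel inside a region's straight-line polygon receives that
#' region's label; pixels in no region are labelled outside and never
#' sonified. The inside test is a deterministic half-open even-odd rule on
#' pixel centers (0-based integer coordinates), so adjoining regions that
#' share an edge stay disjoint. Overlapping polygons are an error.
#'
#' @param slice a [slice_grid()] (only its dims are used).
#' @param boundaries a [boundary_config()].
#' @return An integer matrix of slice dims with class `region_label_map`;
#'   codes 0 = outside, 1 = frontal, 2 = parietal, 3 = sensorimotor (the
#'   `regions` attribute names them).
#' @export
segment_lobes <- function(slice, boundaries) {
  stopifnot(inherits(slice, "slice_grid"),
            inherits(boundaries, "boundary_config"))
  nx <- slice$dims[1]; ny <- slice$dims[2]
  for (nm in names(boundaries)) {
    m <- boundaries[[nm]]
    if (any(m[, 1] < -0.5 | m[, 1] > nx - 0.5 |
            m[, 2] < -0.5 | m[, 2] > ny - 0.5)) {
      stop(sprintf("region '%s': boundary point outside slice dims", nm),
           call. = FALSE)
    }
  }
  labels <- matrix(OUTSIDE, nx, ny)
  coverage <- matrix(0L, nx, ny)
  for (nm in names(REGIONS)) {
    inside <- rasterize_polygon(boundaries[[nm]], nx, ny)
    if (!any(inside)) {
      stop(sprintf("region '%s' rasterizes to zero pixels", nm),
           call. = FALSE)
    }
    labels[inside] <- REGIONS[[nm]]
    coverage <- coverage + inside
  }
  n_overlap <- sum(coverage > 1L)
  if (n_overlap > 0L) {
    stop(sprintf("region polygons overlap on %d pixel(s)", n_overlap),
         call. = FALSE)
  }
  structure(labels, class = "region_label_map", regions = REGIONS)
}

#' @export
print.region_label_map <- function(x, ...) {
  counts <- vapply(REGIONS, function(code) sum(unclass(x) == code),
                   integer(1))
  cat(sprintf("<region_label_map> %d x %d pixels\n", nrow(x), ncol(x)))
  for (nm in names(counts)) {
    cat(sprintf("  %-13s %d pixels\n", nm, counts[[nm]]))
  }
  cat(sprintf("  outside       %d pixels\n", sum(unclass(x) == OUTSIDE)))
  invisible(x)
}
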