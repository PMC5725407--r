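#' Read a voxel volume from the line-oriented text format
#'
#' The input dialect has one voxel per line with four fields: x-location,
#' y-location, z-location, value. Fields may be separated by whitespace or
#' commas. Coordinates are 0-based; voxels absent from the file default to
#' intensity 0 (background, which the masking step removes anyway). Lines
#' that are empty or start with `#` are ignored.
#'
#' @param path path to the voxel text file.
#' @param dims optional integer triple overriding the grid dimensions;
#'   by default the tight bounding box (max coordinate + 1 per axis).
#' @param bit_depth bit depth of the dataset (default 15). Any value above
#'   `2^bit_depth - 1` is an error, never clamped.
#' @param spacing_mm physical voxel spacing, default `c(2, 2, 2)` mm.
#' @return A [voxel_volume()].
#' @seealso [write_voxel_text()]
#' @export
read_voxel_text <- function(path, dims = NULL, bit_depth = 15L,
                            spacing_mm = c(2, 2, 2)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !grepl("^\\s*#", lines))
  n <- length(keep)
  xs <- ys <- zs <- vs <- numeric(n)
  for (i in seq_len(n)) {
    ln <- keep[i]
    fields <- strsplit(trimws(lines[ln]), "[,[:space:]]+")[[1]]
    if (length(fields) != 4L) {
      stop(sprintf("line %d: expected 4 fields, found %d",
                   ln, length(fields)), call. = FALSE)
    }
    num <- suppressWarnings(as.numeric(fields))
    if (anyNA(num)) {
      stop(sprintf("line %d: non-numeric field '%s'",
                   ln, fields[which(is.na(num))[1]]), call. = FALSE)
    }
    xs[i] <- num[1]; ys[i] <- num[2]; zs[i] <- num[3]; vs[i] <- num[4]
  }
  if (n > 0) {
    if (any(xs < 0 | ys < 0 | zs < 0) ||
        any(xs != floor(xs) | ys != floor(ys) | zs != floor(zs))) {
      bad <- which(xs < 0 | ys < 0 | zs < 0 |
                   xs != floor(xs) | ys != floor(ys) | zs != floor(zs))[1]
      stop(sprintf("line %d: coordinates must be non-negative integers",
                   keep[bad]), call. = FALSE)
    }
    vmax <- intensity_max(bit_depth)
    if (any(vs < 0 | vs > vmax)) {
      bad <- which(vs < 0 | vs > vmax)[1]
      stop(sprintf("line %d: value %s outside [0, %s] for bit depth %d",
                   keep[bad], format(vs[bad]), format(vmax),
                   as.integer(bit_depth)), call. = FALSE)
    }
  }
  if (is.null(dims)) {
    if (n == 0) stop("empty voxel file and no `dims` given", call. = FALSE)
    dims <- c(max(xs), max(ys), max(zs)) + 1
  }
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(dims < 1L)) {
    stop("`dims` must be 3 positive integers", call. = FALSE)
  }
  if (n > 0 && any(xs >= dims[1] | ys >= dims[2] | zs >= dims[3])) {
    bad <- which(xs >= dims[1] | ys >= dims[2] | zs >= dims[3])[1]
    stop(sprintf("line %d: coordinate outside volume dims", keep[bad]),
         call. = FALSE)
  }
  # duplicate coordinates: tolerated when consistent, an error on conflict
  key <- paste(xs, ys, zs)
  if (anyDuplicated(key)) {
    split_v <- split(vs, key)
    conflict <- names(split_v)[vapply(split_v, function(v)
      length(unique(v)) > 1L, logical(1))]
    if (length(conflict)) {
      stop("duplicate voxel coordinate with conflicting values at (",
           conflict[1], ")", call. = FALSE)
    }
  }
  arr <- array(0, dim = dims)
  if (n > 0) arr[cbind(xs + 1, ys + 1, zs + 1)] <- vs
  voxel_volume(arr, spacing_mm = spacing_mm, bit_depth = bit_depth)
}

#' Write a voxel volume to the line-oriented text format
#'
#' Writes one line per nonzero voxel, four whitespace-separated fields
#' `x y z value`, in deterministic x-major order (x varies slowest, then y,
#' then z). Zero voxels are omitted; [read_voxel_text()] restores them.
#'
#' @param volume a [voxel_volume()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_voxel_text <- function(volume, path) {
  stopifnot(inherits(volume, "voxel_volume"))
  idx <- which(volume$values != 0, arr.ind = TRUE)
  if (nrow(idx)) {
    xs <- idx[, 1] - 1L; ys <- idx[, 2] - 1L; zs <- idx[, 3] - 1L
    vals <- volume$values[idx]
    ord <- order(xs, ys, zs)
    out <- sprintf("%d %d %d %s", xs[ord], ys[ord], zs[ord],
                   format(vals[ord], scientific = FALSE, trim = TRUE))
  } else {
    out <- character(0)
  }
  ok <- tryCatch({ writeLines(out, path); TRUE },
                 error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) stop("cannot write: ", path, call. = FALSE)
  invisible(path)
}
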