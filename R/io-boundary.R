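#' Construct a lobe boundary configuration
#'
#' Straight-line region boundaries for the three sonified areas on a
#' lateral slice: frontal lobe, parietal lobe, and sensorimotor cortex.
#' Each region is an ordered list of 2-D points in 0-based slice pixel
#' coordinates, interpreted as a closed polygon.
#'
#' @param frontal,parietal,sensorimotor two-column numeric matrices
#'   (x, y) with at least 2 rows each.
#' @return An object of class `boundary_config`: a named list of the three
#'   coordinate matrices.
#' @export
boundary_config <- function(frontal, parietal, sensorimotor) {
  regions <- list(frontal = frontal, parietal = parietal,
                  sensorimotor = sensorimotor)
  for (nm in names(regions)) {
    m <- regions[[nm]]
    if (!is.matrix(m) || ncol(m) != 2L || !is.numeric(m)) {
      stop(sprintf("region '%s': need a 2-column numeric matrix", nm),
           call. = FALSE)
    }
    if (nrow(m) < 2L) {
      stop(sprintf("region '%s': fewer than 2 boundary points", nm),
           call. = FALSE)
    }
    dimnames(regions[[nm]]) <- list(NULL, c("x", "y"))
  }
  structure(regions, class = "boundary_config")
}

#' @export
print.boundary_config <- function(x, ...) {
  cat("<boundary_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-13s %d points\n", nm, nrow(x[[nm]])))
  }
  invisible(x)
}

#' Read lobe boundaries from a text file
#'
#' The file format is plain text: a region header line (`frontal`,
#' `parietal`, or `sensorimotor`, case-insensitive), followed by one `x y`
#' coordinate pair per line (whitespace- or comma-separated, 0-based slice
#' pixel coordinates). All three regions must be present with at least two
#' points each. Blank lines and `#` comments are ignored. This file layout
#' is the package's own plumbing: boundary coordinates are assumed to have
#' been exported from whatever contouring tool drew the straight-line
#' segmentation.
#'
#' @param path path to the boundary file.
#' @return A [boundary_config()].
#' @seealso [write_boundary_file()]
#' @export
read_boundary_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  region_names <- names(REGIONS)
  pts <- stats::setNames(vector("list", 3L), region_names)
  current <- NULL
  for (i in seq_along(lines)) {
    txt <- trimws(lines[i])
    if (!nzchar(txt) || startsWith(txt, "#")) next
    low <- tolower(txt)
    if (low %in% region_names) {
      current <- low
      if (is.null(pts[[current]])) pts[[current]] <- list()
      next
    }
    if (is.null(current)) {
      stop(sprintf("line %d: coordinates before any region header", i),
           call. = FALSE)
    }
    fields <- strsplit(txt, "[,[:space:]]+")[[1]]
    num <- suppressWarnings(as.numeric(fields))
    if (length(num) != 2L || anyNA(num)) {
      stop(sprintf("line %d: expected 'x y' pair, got '%s'", i, txt),
           call. = FALSE)
    }
    pts[[current]] <- c(pts[[current]], list(num))
  }
  missing <- region_names[vapply(pts, is.null, logical(1))]
  if (length(missing)) {
    stop("boundary file is missing region(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  too_few <- region_names[vapply(pts, length, integer(1)) < 2L]
  if (length(too_few)) {
    stop("fewer than 2 points for region(s): ",
         paste(too_few, collapse = ", "), call. = FALSE)
  }
  mats <- lapply(pts, function(p) do.call(rbind, p))
  boundary_config(mats$frontal, mats$parietal, mats$sensorimotor)
}

#' Write lobe boundaries to a text file
#'
#' Inverse of [read_boundary_file()]: region header lines followed by one
#' `x y` pair per line.
#'
#' @param boundaries a [boundary_config()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_boundary_file <- function(boundaries, path) {
  stopifnot(inherits(boundaries, "boundary_config"))
  out <- character(0)
  for (nm in names(boundaries)) {
    m <- boundaries[[nm]]
    out <- c(out, nm,
             sprintf("%s %s",
                     format(m[, 1], scientific = FALSE, trim = TRUE),
                     format(m[, 2], scientific = FALSE, trim = TRUE)))
  }
  ok <- tryCatch({ writeLines(out, path); TRUE }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write: ", path, call. = FALSE)
  invisible(path)
}
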