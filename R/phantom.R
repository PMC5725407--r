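# run code with a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specify a synthetic brain phantom
#'
#' Parameters for [generate_phantom()]: an already-normalized synthetic
#' volume with a gray-matter shell over a white-matter core, and three
#' straight-line-bounded lobe patches (frontal, parietal, sensorimotor)
#' painted into a band of slices around the diagnostic slice. Gray matter
#' sits above the masking threshold, white matter and background below
#' it, and the frontal/parietal patches are dimmed by known
#' hypometabolism fractions -- so the pipeline's recovered deviations
#' have exact ground truth.
#'
#' Well-posedness requires `wm_level < mask_fraction * (2^bit_depth - 1)
#' <= gm_level * (1 - max(hypo_fl, hypo_pl))`: white matter is always
#' masked and even the most hypometabolic gray matter always survives.
#'
#' @param dims integer triple, default `c(86, 100, 86)`.
#' @param bit_depth intensity bit depth, default 15.
#' @param gm_level gray-matter baseline intensity; default 80% of the
#'   maximum allowable intensity.
#' @param wm_level white-matter intensity; default 30% of maximum,
#'   safely below the 45% masking threshold.
#' @param hypo_fl,hypo_pl fractional intensity reductions in `[0, 1)`
#'   applied to frontal / parietal gray matter (0 = healthy).
#' @param noise_sd additive Gaussian noise standard deviation in
#'   intensity units (0 = noiseless).
#' @param seed integer RNG seed recorded in the spec; drawn at random if
#'   omitted.
#' @param slice_ordinal 1-based diagnostic slice (default 30).
#' @param mask_fraction masking fraction the phantom must be well-posed
#'   for (default 0.45).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(dims = c(86L, 100L, 86L), bit_depth = 15L,
                         gm_level = NULL, wm_level = NULL,
                         hypo_fl = 0, hypo_pl = 0, noise_sd = 0,
                         seed = NULL, slice_ordinal = 30L,
                         mask_fraction = 0.45) {
  dims <- as.integer(dims)
  vmax <- intensity_max(bit_depth)
  if (is.null(gm_level)) gm_level <- 0.8 * vmax
  if (is.null(wm_level)) wm_level <- 0.3 * vmax
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  spec <- structure(
    list(dims = dims, bit_depth = as.integer(bit_depth),
         gm_level = gm_level, wm_level = wm_level,
         hypo_fl = hypo_fl, hypo_pl = hypo_pl, noise_sd = noise_sd,
         seed = as.integer(seed), slice_ordinal = as.integer(slice_ordinal),
         mask_fraction = mask_fraction),
    class = "phantom_spec"
  )
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  vmax <- intensity_max(spec$bit_depth)
  thr <- spec$mask_fraction * vmax
  if (length(spec$dims) != 3L || any(spec$dims < 8L)) {
    stop("phantom dims must be 3 integers >= 8", call. = FALSE)
  }
  if (spec$hypo_fl < 0 || spec$hypo_fl >= 1 ||
      spec$hypo_pl < 0 || spec$hypo_pl >= 1) {
    stop("hypometabolism fractions must lie in [0, 1)", call. = FALSE)
  }
  if (spec$noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (spec$gm_level > vmax || spec$wm_level < 0) {
    stop("tissue levels outside the intensity range", call. = FALSE)
  }
  if (!(spec$wm_level < thr)) {
    stop(sprintf(
      "ill-posed phantom: wm_level %.1f is not below the masking threshold %.2f",
      spec$wm_level, thr), call. = FALSE)
  }
  lowest_gm <- spec$gm_level * (1 - max(spec$hypo_fl, spec$hypo_pl))
  if (!(thr <= lowest_gm)) {
    stop(sprintf(
      "ill-posed phantom: hypometabolic gray matter %.1f falls below the masking threshold %.2f",
      lowest_gm, thr), call. = FALSE)
  }
  if (spec$slice_ordinal < 1L || spec$slice_ordinal > spec$dims[3]) {
    stop("slice_ordinal outside the volume", call. = FALSE)
  }
  invisible(spec)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "<phantom_spec> %d x %d x %d, %d-bit, gm %.1f, wm %.1f\n",
    x$dims[1], x$dims[2], x$dims[3], x$bit_depth, x$gm_level, x$wm_level))
  cat(sprintf("  hypo FL %.3f, hypo PL %.3f, noise sd %.1f, seed %d\n",
              x$hypo_fl, x$hypo_pl, x$noise_sd, x$seed))
  invisible(x)
}

#' Phantom presets for the four severity categories
#'
#' Monotone hypometabolism presets spanning the four categories, with
#' the parietal lobe always more affected than the frontal (the typical
#' AD pattern): normal (0, 0.02), mild (0.05, 0.10), moderate
#' (0.12, 0.20), severe (0.25, 0.35) as (frontal, parietal) fractions,
#' plus noise at 1% of the maximum intensity. These are calibration
#' points of the generator, not clinical measurements; they are chosen
#' so that the four categories produce clearly distinct beat rates at
#' the standard detune factors.
#'
#' @param severity `"normal"`, `"mild"`, `"moderate"`, or `"severe"`.
#' @param seed optional RNG seed, passed to [phantom_spec()].
#' @param noise_sd noise standard deviation; default 1% of the 15-bit
#'   maximum intensity.
#' @param ... further overrides passed to [phantom_spec()].
#' @return A [phantom_spec()].
#' @export
severity_preset <- function(severity, seed = NULL,
                            noise_sd = 0.01 * intensity_max(15L), ...) {
  presets <- list(normal   = c(0.00, 0.02),
                  mild     = c(0.05, 0.10),
                  moderate = c(0.12, 0.20),
                  severe   = c(0.25, 0.35))
  if (!is.character(severity) || length(severity) != 1L ||
      !(severity %in% names(presets))) {
    stop("unknown severity '", paste(severity, collapse = ","),
         "'; expected one of ", paste(names(presets), collapse = ", "),
         call. = FALSE)
  }
  h <- presets[[severity]]
  phantom_spec(hypo_fl = h[1], hypo_pl = h[2], noise_sd = noise_sd,
               seed = seed, ...)
}

# inclusive 0-based pixel ranges of the three lobe patches for given dims
lobe_rectangles <- function(dims) {
  nx <- dims[1]; ny <- dims[2]
  xr <- round(c(0.38, 0.62) * (nx - 1))
  list(
    frontal      = list(x = xr, y = round(c(0.14, 0.33) * (ny - 1))),
    parietal     = list(x = xr, y = round(c(0.66, 0.86) * (ny - 1))),
    sensorimotor = list(x = xr, y = round(c(0.45, 0.55) * (ny - 1)))
  )
}

#' Generate a synthetic brain phantom
#'
#' Builds a deterministic (for a fixed seed) voxel volume: background 0,
#' a white-matter ellipsoidal core at `wm_level`, a gray-matter
#' ellipsoidal shell at `gm_level`, and — in a five-slice band around the
#' diagnostic slice — three rectangular lobe patches painted at
#' gray-matter intensity, dimmed by the spec's hypometabolism fractions
#' for the frontal and parietal patches. Gaussian noise (if any) is added
#' to tissue voxels only, then all intensities are rounded to integers
#' and truncated to the valid range. The returned boundary configuration
#' outlines the painted patches exactly (half-pixel-offset rectangle
#' corners, so rasterization recovers precisely the painted pixels).
#'
#' @param spec a [phantom_spec()].
#' @return A list of class `phantom` with `volume` (a [voxel_volume()]),
#'   `boundaries` (a [boundary_config()]), and `spec`.
#' @examples
#' ph <- generate_phantom(phantom_spec(hypo_pl = 0.25, seed = 42))
#' ph$volume
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  validate_phantom_spec(spec)
  nx <- spec$dims[1]; ny <- spec$dims[2]; nz <- spec$dims[3]
  vmax <- intensity_max(spec$bit_depth)

  cx <- (nx - 1) / 2; cy <- (ny - 1) / 2; cz <- (nz - 1) / 2
  fx <- ((0:(nx - 1) - cx) / (0.44 * nx))^2
  fy <- ((0:(ny - 1) - cy) / (0.46 * ny))^2
  fz <- ((0:(nz - 1) - cz) / (0.48 * nz))^2
  r2 <- outer(outer(fx, fy, "+"), fz, "+")

  vals <- array(0, dim = spec$dims)
  vals[r2 <= 1] <- spec$gm_level            # gray-matter shell
  vals[r2 <= 0.62^2] <- spec$wm_level       # white-matter core

  rects <- lobe_rectangles(spec$dims)
  level <- c(frontal = spec$gm_level * (1 - spec$hypo_fl),
             parietal = spec$gm_level * (1 - spec$hypo_pl),
             sensorimotor = spec$gm_level)
  slice_idx <- spec$slice_ordinal - 1L
  zband <- max(0L, slice_idx - 2L):min(nz - 1L, slice_idx + 2L)
  for (nm in names(rects)) {
    r <- rects[[nm]]
    vals[(r$x[1]:r$x[2]) + 1L, (r$y[1]:r$y[2]) + 1L, zband + 1L] <-
      level[[nm]]
  }

  if (spec$noise_sd > 0) {
    tissue <- which(vals > 0)
    noise <- with_seed(spec$seed,
                       stats::rnorm(length(tissue), 0, spec$noise_sd))
    vals[tissue] <- vals[tissue] + noise
  }
  vals <- pmin(pmax(round(vals), 0), vmax)

  polys <- lapply(rects, function(r) {
    x0 <- r$x[1] - 0.5; x1 <- r$x[2] + 0.5
    y0 <- r$y[1] - 0.5; y1 <- r$y[2] + 0.5
    cbind(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))
  })
  structure(
    list(volume = voxel_volume(vals, bit_depth = spec$bit_depth),
         boundaries = boundary_config(polys$frontal, polys$parietal,
                                      polys$sensorimotor),
         spec = spec),
    class = "phantom"
  )
}

#' @export
print.phantom <- function(x, ...) {
  cat("<phantom>\n")
  print(x$spec)
  print(x$volume)
  invisible(x)
}
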