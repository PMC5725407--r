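#' Triple-tone sonification of a brain slice
#'
#' The package's central computation. Given a lateral slice and the
#' straight-line lobe boundaries, it (1) masks white matter and background
#' at `mask_fraction` of the bit-depth maximum intensity, (2) rasterizes
#' the frontal, parietal, and sensorimotor polygons into a label map,
#' (3) averages surviving intensities per lobe, and (4) maps the relative
#' deviations from the sensorimotor mean to three oscillator frequencies
#' through the detune factor. The result holds everything downstream
#' steps need: region statistics, deviations, the tone set, and the
#' masked slice with its label map.
#'
#' Exactly one of `severity` or `detune` must be given: a severity
#' category looks the detune factor up in the standard table
#' ([severity_to_detune()]), while an explicit numeric `detune` supports
#' data-driven experimentation.
#'
#' @param slice a [slice_grid()], e.g. from [extract_slice()] or
#'   [read_projection_image()].
#' @param boundaries a [boundary_config()].
#' @param severity severity category (`"normal"`, `"mild"`, `"moderate"`,
#'   `"severe"`), or `NULL` when `detune` is given.
#' @param detune explicit positive detune factor, or `NULL` when
#'   `severity` is given.
#' @param f_default base frequency in Hz for the sensorimotor tone
#'   (default 440).
#' @param mask_fraction masking fraction of the maximum allowable
#'   intensity (default 0.45).
#' @param parietal_sign see [tts_frequencies()].
#' @return An object of class `tts`: a list with components
#'   \describe{
#'     \item{stats}{region means/counts (`av_fl`, `av_pl`, `av_smc`,
#'       `n_fl`, `n_pl`, `n_smc`).}
#'     \item{tones}{the [tts_frequencies()] `tone_set`.}
#'     \item{slice}{the masked [slice_grid()].}
#'     \item{labels}{the [segment_lobes()] label map.}
#'     \item{threshold}{the masking threshold used.}
#'     \item{params}{call parameters (severity, detune, `f_default`,
#'       `mask_fraction`, `parietal_sign`, slice index).}
#'   }
#' @examples
#' ph <- generate_phantom(severity_preset("severe", seed = 1))
#' sl <- extract_slice(ph$volume, 30)
#' fit <- sonify_slice(sl, ph$boundaries, severity = "severe")
#' fit
#' coef(fit)
#' @export
sonify_slice <- function(slice, boundaries, severity = NULL, detune = NULL,
                         f_default = 440, mask_fraction = 0.45,
                         parietal_sign = c("negative", "positive")) {
  stopifnot(inherits(slice, "slice_grid"),
            inherits(boundaries, "boundary_config"))
  if (is.null(severity) == is.null(detune)) {
    stop("give exactly one of `severity` or `detune`", call. = FALSE)
  }
  if (!is.null(severity)) detune <- severity_to_detune(severity)
  parietal_sign <- match.arg(parietal_sign)

  thr <- mask_threshold(mask_fraction, slice$bit_depth)
  masked <- apply_mask(slice, thr)
  labels <- segment_lobes(masked, boundaries)

  fl <- region_average(masked, labels, "frontal")
  pl <- region_average(masked, labels, "parietal")
  smc <- region_average(masked, labels, "sensorimotor")
  if (smc$mean <= 0) {
    stop("sensorimotor mean intensity is not positive; cannot anchor the base tone",
         call. = FALSE)
  }
  stats <- list(av_fl = fl$mean, av_pl = pl$mean, av_smc = smc$mean,
                n_fl = fl$n, n_pl = pl$n, n_smc = smc$n)
  tones <- tts_frequencies(stats, detune = detune, f_default = f_default,
                           parietal_sign = parietal_sign)
  structure(
    list(stats = stats, tones = tones, slice = masked, labels = labels,
         threshold = thr,
         params = list(severity = severity, detune = detune,
                       f_default = f_default,
                       mask_fraction = mask_fraction,
                       parietal_sign = parietal_sign,
                       slice_index = slice$slice_index)),
    class = "tts"
  )
}

#' @export
print.tts <- function(x, ...) {
  cat("Triple-tone sonification\n")
  sev <- x$params$severity
  cat(sprintf("  detune factor: %.3f%s\n", x$tones$detune,
              if (is.null(sev)) " (explicit)" else paste0(" (", sev, ")")))
  cat(sprintf("  f_SMC = %.3f Hz, f_FL = %.3f Hz, f_PL = %.3f Hz\n",
              x$tones$f_smc, x$tones$f_fl, x$tones$f_pl))
  cat(sprintf("  delta_FL = %.4f, delta_PL = %.4f\n",
              x$tones$delta_fl, x$tones$delta_pl))
  invisible(x)
}

#' @export
summary.tts <- function(object, ...) {
  x <- object
  br <- beat_rates(x$tones)
  out <- list(
    regions = data.frame(
      region = c("frontal", "parietal", "sensorimotor"),
      mean_intensity = c(x$stats$av_fl, x$stats$av_pl, x$stats$av_smc),
      n_pixels = c(x$stats$n_fl, x$stats$n_pl, x$stats$n_smc),
      frequency_hz = c(x$tones$f_fl, x$tones$f_pl, x$tones$f_smc)
    ),
    deltas = c(frontal = x$tones$delta_fl, parietal = x$tones$delta_pl),
    detune = x$tones$detune,
    threshold = x$threshold,
    masked_fraction = 1 - mean(x$slice$mask),
    beat_rates = br
  )
  class(out) <- "summary.tts"
  out
}

#' @export
print.summary.tts <- function(x, ...) {
  cat("Triple-tone sonification summary\n\n")
  print(x$regions, row.names = FALSE)
  cat(sprintf("\nmasking threshold: %.2f (%.1f%% of slice masked)\n",
              x$threshold, 100 * x$masked_fraction))
  cat(sprintf("detune factor: %.3f\n", x$detune))
  cat(sprintf("beat rates: FL-SMC %.2f Hz, SMC-PL %.2f Hz, FL-PL %.2f Hz\n",
              x$beat_rates[["fl_smc"]], x$beat_rates[["smc_pl"]],
              x$beat_rates[["fl_pl"]]))
  invisible(x)
}

#' @export
coef.tts <- function(object, ...) {
  c(f_smc = object$tones$f_smc, f_fl = object$tones$f_fl,
    f_pl = object$tones$f_pl)
}

#' Plot a sonified slice
#'
#' Shows the masked slice as a greyscale image with the three lobe
#' boundary polygons overlaid (frontal, parietal, sensorimotor), each
#' annotated with its oscillator frequency.
#'
#' @param x a `tts` object from [sonify_slice()].
#' @param boundaries optional [boundary_config()] to overlay; polygons are
#'   reconstructed from the label map extents when omitted.
#' @param ... passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.tts <- function(x, boundaries = NULL, ...) {
  vals <- x$slice$values
  vals[!x$slice$mask] <- 0
  nx <- nrow(vals); ny <- ncol(vals)
  graphics::image(x = 0:(nx - 1), y = 0:(ny - 1), z = vals,
                  col = grDevices::gray(seq(0, 1, length.out = 256)),
                  xlab = "x (pixels)", ylab = "y (pixels)",
                  main = "Triple-tone sonification regions", ...)
  cols <- c(frontal = "red", parietal = "blue", sensorimotor = "green3")
  labm <- unclass(x$labels)
  for (nm in names(REGIONS)) {
    sel <- which(labm == REGIONS[[nm]], arr.ind = TRUE)
    if (nrow(sel)) {
      graphics::rect(min(sel[, 1]) - 1.5, min(sel[, 2]) - 1.5,
                     max(sel[, 1]) - 0.5, max(sel[, 2]) - 0.5,
                     border = cols[[nm]], lwd = 2)
    }
  }
  graphics::legend("topright", bty = "n", lty = 1, lwd = 2, col = cols,
                   legend = sprintf("%s: %.1f Hz", names(cols),
                                    c(x$tones$f_fl, x$tones$f_pl,
                                      x$tones$f_smc)))
  invisible(x)
}

#' Machine-readable sonification report
#'
#' Collects the audit trail of a sonification -- regional means and
#' counts, deviations, detune factor, frequencies, masking threshold and
#' masked fraction -- as a flat named list, optionally written to a JSON
#' file for downstream testing.
#'
#' @param x a `tts` object.
#' @param path optional output JSON path.
#' @return The report list, invisibly when `path` is given.
#' @export
sonification_report <- function(x, path = NULL) {
  stopifnot(inherits(x, "tts"))
  rep <- list(
    av_FL = x$stats$av_fl, av_PL = x$stats$av_pl, av_SMC = x$stats$av_smc,
    n_FL = x$stats$n_fl, n_PL = x$stats$n_pl, n_SMC = x$stats$n_smc,
    delta_FL = x$tones$delta_fl, delta_PL = x$tones$delta_pl,
    detune_factor = x$tones$detune,
    severity = if (is.null(x$params$severity)) NA else x$params$severity,
    f_default = x$tones$f_default,
    f_SMC = x$tones$f_smc, f_FL = x$tones$f_fl, f_PL = x$tones$f_pl,
    mask_fraction = x$params$mask_fraction,
    mask_threshold = x$threshold,
    masked_fraction = 1 - mean(x$slice$mask),
    slice_index = if (is.na(x$params$slice_index)) NA
                  else x$params$slice_index,
    parietal_sign = x$params$parietal_sign
  )
  if (!is.null(path)) {
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
    return(invisible(rep))
  }
  rep
}
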