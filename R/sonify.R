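#' Masked mean intensity of one labelled region
#'
#' Averages the slice intensities over pixels that carry the requested
#' region label AND survived masking. White matter inside a lobe polygon
#' therefore never contributes. A region with no surviving pixels has no
#' defined mean and is an error.
#'
#' @param slice a [slice_grid()] (mask already applied).
#' @param labels a region label map from [segment_lobes()].
#' @param region one of `"frontal"`, `"parietal"`, `"sensorimotor"`.
#' @return A list with `mean` (numeric) and `n` (surviving pixel count).
#' @export
region_average <- function(slice, labels, region) {
  stopifnot(inherits(slice, "slice_grid"))
  region <- match.arg(region, names(REGIONS))
  if (!all(dim(labels) == slice$dims)) {
    stop("label map dims do not match slice dims", call. = FALSE)
  }
  sel <- (unclass(labels) == REGIONS[[region]]) & slice$mask
  n <- sum(sel)
  if (n == 0L) {
    stop(sprintf("region '%s' has no surviving (unmasked) pixels", region),
         call. = FALSE)
  }
  list(mean = mean(slice$values[sel]), n = n)
}

#' Relative deviation of a regional mean from the reference
#'
#' The dimensionless deviation `|av_region - av_SMC| / av_SMC` of a lobe's
#' average intensity from the sensorimotor reference. The absolute value
#' makes hypo- and hypermetabolism of equal size indistinguishable here;
#' the direction of the frequency shift is fixed later by the lobe's sign
#' convention, not by the data.
#'
#' @param av_region non-negative regional mean intensity.
#' @param av_smc positive sensorimotor mean intensity.
#' @return Non-negative numeric scalar.
#' @export
relative_deviation <- function(av_region, av_smc) {
  if (!is.numeric(av_smc) || length(av_smc) != 1L || av_smc <= 0) {
    stop("reference mean `av_smc` must be positive", call. = FALSE)
  }
  abs(av_region - av_smc) / av_smc
}

#' Detune factor for a severity category
#'
#' The severity-to-detune-factor table: normal 0.05, mild 0.10,
#' moderate 0.15, severe 0.20. The detune factor scales how strongly a
#' given metabolic deviation detunes its oscillator, so more severe
#' disease produces faster, more complex beating. Severity is supplied by
#' the analyst (ground truth); deriving it from the data is out of scope.
#'
#' @param severity `"normal"`, `"mild"`, `"moderate"`, or `"severe"`.
#' @return The detune factor (numeric scalar).
#' @export
severity_to_detune <- function(severity) {
  table <- c(normal = 0.05, mild = 0.10, moderate = 0.15, severe = 0.20)
  if (!is.character(severity) || length(severity) != 1L ||
      !(severity %in% names(table))) {
    stop("unknown severity '", paste(severity, collapse = ","),
         "'; expected one of ", paste(names(table), collapse = ", "),
         call. = FALSE)
  }
  table[[severity]]
}

#' Map regional statistics to the three oscillator frequencies
#'
#' The sensorimotor cortex anchors the base frequency `f_default`
#' (440 Hz, A above middle C). The frontal and parietal tones are detuned
#' in proportion to their relative deviations:
#' \deqn{f_{FL} = f_{default} (1 + DF\,|\Delta_{FL}|), \qquad
#'       f_{PL} = f_{default} (1 - DF\,|\Delta_{PL}|)}
#' The frontal deviation is forced positive and the parietal negative so
#' that equal-magnitude deviations in both lobes still yield three
#' distinct tones rather than collapsing to two beating pairs. Setting
#' `parietal_sign = "positive"` applies the deviation upward for both
#' lobes instead (a documented compatibility variant; it defeats the
#' anti-collapse property and is not the default).
#'
#' @param stats list with positive `av_smc` and non-negative `av_fl`,
#'   `av_pl` regional means (as produced inside [sonify_slice()], or built
#'   by hand).
#' @param detune positive detune factor, typically from
#'   [severity_to_detune()].
#' @param f_default base frequency in Hz (default 440).
#' @param parietal_sign `"negative"` (default) or `"positive"`.
#' @return An object of class `tone_set` with fields `f_smc`, `f_fl`,
#'   `f_pl` (Hz), `delta_fl`, `delta_pl` (dimensionless), `detune`,
#'   `f_default`, `parietal_sign`.
#' @examples
#' s <- list(av_fl = 75, av_pl = 80, av_smc = 100)
#' tts_frequencies(s, detune = 0.20)
#' @export
tts_frequencies <- function(stats, detune, f_default = 440,
                            parietal_sign = c("negative", "positive")) {
  parietal_sign <- match.arg(parietal_sign)
  if (!is.numeric(detune) || length(detune) != 1L || detune <= 0) {
    stop("`detune` must be a positive number", call. = FALSE)
  }
  if (!is.numeric(f_default) || length(f_default) != 1L || f_default <= 0) {
    stop("`f_default` must be a positive frequency", call. = FALSE)
  }
  d_fl <- relative_deviation(stats$av_fl, stats$av_smc)
  d_pl <- relative_deviation(stats$av_pl, stats$av_smc)
  sgn <- if (parietal_sign == "negative") -1 else 1
  if (sgn < 0 && detune * d_pl >= 1) {
    stop(sprintf(
      "frequency collapse: DF * |delta_PL| = %.3f >= 1 gives a non-positive parietal frequency",
      detune * d_pl), call. = FALSE)
  }
  structure(
    list(f_smc = f_default,
         f_fl = f_default * (1 + detune * d_fl),
         f_pl = f_default * (1 + sgn * detune * d_pl),
         delta_fl = d_fl, delta_pl = d_pl,
         detune = detune, f_default = f_default,
         parietal_sign = parietal_sign),
    class = "tone_set"
  )
}

#' @export
print.tone_set <- function(x, ...) {
  cat("<tone_set>\n")
  cat(sprintf("  f_SMC %8.3f Hz  (base)\n", x$f_smc))
  cat(sprintf("  f_FL  %8.3f Hz  (delta %.4f, +)\n", x$f_fl, x$delta_fl))
  cat(sprintf("  f_PL  %8.3f Hz  (delta %.4f, %s)\n", x$f_pl, x$delta_pl,
              ifelse(x$parietal_sign == "negative", "-", "+")))
  cat(sprintf("  detune factor %.2f, beat rates %.2f / %.2f Hz\n",
              x$detune, abs(x$f_fl - x$f_smc), abs(x$f_smc - x$f_pl)))
  invisible(x)
}

#' Expected beat rates of a tone set
#'
#' Beating between two mixed tones has rate equal to their frequency
#' difference, so the frontal and parietal tones beat against the base at
#' `f_default * DF * |delta|` exactly (and against each other at the sum
#' of the two rates under the default sign convention).
#'
#' @param tones a `tone_set` (or a `tts` result).
#' @return Named numeric vector `c(fl_smc =, smc_pl =, fl_pl =)` in Hz.
#' @export
beat_rates <- function(tones) {
  if (inherits(tones, "tts")) tones <- tones$tones
  stopifnot(inherits(tones, "tone_set"))
  c(fl_smc = abs(tones$f_fl - tones$f_smc),
    smc_pl = abs(tones$f_smc - tones$f_pl),
    fl_pl = abs(tones$f_fl - tones$f_pl))
}
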