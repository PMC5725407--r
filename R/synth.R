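#' Construct an audio buffer
#'
#' @param samples numeric vector of samples in `[-1, 1]`.
#' @param sample_rate samples per second (default 44100).
#' @return An object of class `audio_buffer` with `samples`,
#'   `sample_rate`, and `duration_s = length / rate`.
#' @export
audio_buffer <- function(samples, sample_rate = 44100) {
  stopifnot(is.numeric(samples), sample_rate > 0)
  if (length(samples) && max(abs(samples)) > 1 + 1e-12) {
    stop("samples exceed [-1, 1]", call. = FALSE)
  }
  structure(list(samples = as.numeric(samples),
                 sample_rate = sample_rate,
                 duration_s = length(samples) / sample_rate),
            class = "audio_buffer")
}

#' @export
print.audio_buffer <- function(x, ...) {
  cat(sprintf("<audio_buffer> %d samples @ %g Hz (%.3f s), peak %.4f\n",
              length(x$samples), x$sample_rate, x$duration_s,
              if (length(x$samples)) max(abs(x$samples)) else 0))
  invisible(x)
}

#' Ideal triangular-wave oscillator
#'
#' Generates the naive (non-band-limited) triangle waveform
#' `(2/pi) * asin(sin(2*pi*f*t + phase))`, which starts at 0 on its rising
#' edge for zero phase and has period `sample_rate / freq` samples. At the
#' few-hundred-Hz fundamentals used here and a 44.1 kHz rate, the aliasing
#' of the ideal waveform's high harmonics (which decay as 1/k^2) is
#' inaudible, and the closed form keeps the waveform exactly testable.
#'
#' @param freq oscillator frequency in Hz; must be below Nyquist
#'   (`sample_rate / 2`).
#' @param duration_s duration in seconds (default 30, the standard
#'   playback length).
#' @param sample_rate samples per second (default 44100).
#' @param amplitude peak amplitude in (0, 1] (default 1).
#' @param phase initial phase in radians (default 0).
#' @return An [audio_buffer()] of `round(sample_rate * duration_s)`
#'   samples.
#' @export
triangle_wave <- function(freq, duration_s = 30, sample_rate = 44100,
                          amplitude = 1, phase = 0) {
  if (!is.numeric(freq) || length(freq) != 1L || freq <= 0) {
    stop("`freq` must be a positive frequency", call. = FALSE)
  }
  if (freq >= sample_rate / 2) {
    stop(sprintf("freq %g Hz is at or above Nyquist (%g Hz): aliasing",
                 freq, sample_rate / 2), call. = FALSE)
  }
  if (amplitude <= 0 || amplitude > 1) {
    stop("`amplitude` must lie in (0, 1]", call. = FALSE)
  }
  n <- round(sample_rate * duration_s)
  t <- (seq_len(n) - 1) / sample_rate
  s <- amplitude * (2 / pi) * asin(sin(2 * pi * freq * t + phase))
  audio_buffer(s, sample_rate)
}

#' Render a tone set as three mixed triangular oscillators
#'
#' Sums equal-amplitude (1/3 each) zero-phase triangle oscillators at the
#' sensorimotor, frontal, and parietal frequencies. The mix is
#' peak-normalized so no sample exceeds 1. Frequency differences between
#' the three tones produce the audible beating pattern; identical
#' frequencies (a metabolically uniform brain) give a steady tone.
#' Rendering is fully deterministic.
#'
#' @param tones a `tone_set` from [tts_frequencies()], or a `tts` result
#'   from [sonify_slice()].
#' @param duration_s duration in seconds (default 30).
#' @param sample_rate samples per second (default 44100).
#' @return An [audio_buffer()].
#' @export
render_tts <- function(tones, duration_s = 30, sample_rate = 44100) {
  if (inherits(tones, "tts")) tones <- tones$tones
  stopifnot(inherits(tones, "tone_set"))
  freqs <- c(tones$f_smc, tones$f_fl, tones$f_pl)
  s <- 0
  for (f in freqs) {
    s <- s + triangle_wave(f, duration_s, sample_rate,
                           amplitude = 1)$samples / 3
  }
  peak <- max(abs(s))
  if (peak > 1) s <- s / peak
  audio_buffer(s, sample_rate)
}

#' Dominant spectral peaks of an audio buffer
#'
#' Hann-windowed magnitude FFT over the whole buffer; returns the
#' frequencies of the `n_peaks` largest local maxima, in descending
#' magnitude order. Frequencies are quantized to the FFT bin width
#' `sample_rate / length`. Negligible maxima (below 1e-6 of the global
#' peak, or everything for silence) are dropped, so the list may be
#' shorter than requested.
#'
#' @param buffer an [audio_buffer()].
#' @param n_peaks maximum number of peaks to return.
#' @return Numeric vector of frequencies in Hz (possibly empty).
#' @export
spectral_peaks <- function(buffer, n_peaks = 3L) {
  stopifnot(inherits(buffer, "audio_buffer"))
  x <- buffer$samples
  n <- length(x)
  if (n < 4L) stop("buffer too short for spectral analysis", call. = FALSE)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  mag <- Mod(stats::fft(x * w))[seq_len(n %/% 2)]
  freqs <- (seq_len(n %/% 2) - 1) * buffer$sample_rate / n
  pick_peaks(freqs, mag, n_peaks)
}

# local maxima of a magnitude spectrum, descending by magnitude
pick_peaks <- function(freqs, mag, n_peaks) {
  m <- length(mag)
  if (m < 3L) return(numeric(0))
  top <- max(mag)
  if (top <= 0) return(numeric(0))
  i <- 2:(m - 1)
  is_peak <- mag[i] > mag[i - 1] & mag[i] >= mag[i + 1] &
    mag[i] > 1e-6 * top
  cand <- i[is_peak]
  if (!length(cand)) return(numeric(0))
  cand <- cand[order(mag[cand], decreasing = TRUE)]
  freqs[utils::head(cand, n_peaks)]
}

#' Amplitude envelope of an audio buffer
#'
#' Full-wave rectifies the signal and smooths it with a moving average
#' one carrier period wide, which removes the carrier oscillation while
#' preserving beat-rate modulation (beat periods are far longer than a
#' carrier period). Edge samples without a full window are dropped.
#'
#' @param buffer an [audio_buffer()].
#' @param carrier_hz the carrier frequency whose period sets the
#'   smoothing window (default 440).
#' @return Numeric vector, the smoothed envelope.
#' @export
amplitude_envelope <- function(buffer, carrier_hz = 440) {
  stopifnot(inherits(buffer, "audio_buffer"))
  w <- max(3L, round(buffer$sample_rate / carrier_hz))
  env <- stats::filter(abs(buffer$samples), rep(1 / w, w), sides = 2)
  as.numeric(env[!is.na(env)])
}

#' Modulation depth of an amplitude envelope
#'
#' `(max - min) / (max + min)` of the envelope: 0 for a steady tone,
#' approaching 1 for full beating. Used to verify that a healthy
#' (zero-deviation) render does not beat while diseased renders do.
#'
#' @param buffer an [audio_buffer()].
#' @param carrier_hz see [amplitude_envelope()].
#' @return Numeric scalar in `[0, 1]`.
#' @export
modulation_depth <- function(buffer, carrier_hz = 440) {
  env <- amplitude_envelope(buffer, carrier_hz)
  (max(env) - min(env)) / (max(env) + min(env))
}

#' Beat-rate peaks from the envelope spectrum
#'
#' Detects the periodicities of the amplitude envelope with a square-law
#' detector: the squared, mean-removed signal is Hann-windowed and
#' Fourier transformed, and the dominant low-frequency local maxima are
#' returned. Squaring is used rather than full-wave rectification because
#' the squared envelope of a multi-tone mix contains exactly the pairwise
#' frequency differences (the beat rates), whereas the modulus envelope
#' adds harmonics and combination tones of them.
#'
#' @param buffer an [audio_buffer()].
#' @param n_peaks maximum number of peaks to return (default 3).
#' @param max_hz upper band edge for the search (default 100 Hz, well
#'   below any carrier).
#' @return Numeric vector of envelope periodicities in Hz, descending by
#'   magnitude.
#' @export
envelope_beat_peaks <- function(buffer, n_peaks = 3L, max_hz = 100) {
  stopifnot(inherits(buffer, "audio_buffer"))
  x <- buffer$samples^2
  x <- x - mean(x)
  n <- length(x)
  if (n < 4L) stop("buffer too short for envelope analysis", call. = FALSE)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  mag <- Mod(stats::fft(x * w))[seq_len(n %/% 2)]
  freqs <- (seq_len(n %/% 2) - 1) * buffer$sample_rate / n
  band <- freqs > 0 & freqs <= max_hz
  pick_peaks(freqs[band], mag[band], n_peaks)
}
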