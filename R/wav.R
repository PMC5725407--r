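#' Write an audio buffer as a 16-bit PCM mono WAV file
#'
#' Samples are scaled by 32767 and rounded half-away-from-zero into
#' 16-bit signed PCM, wrapped in a minimal canonical RIFF/WAVE container
#' (fmt chunk + data chunk, little-endian).
#'
#' @param buffer an [audio_buffer()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_wav()]
#' @export
write_wav <- function(buffer, path) {
  stopifnot(inherits(buffer, "audio_buffer"))
  x <- buffer$samples
  pcm <- as.integer(sign(x) * floor(abs(x) * 32767 + 0.5))
  pcm <- pmax(pmin(pcm, 32767L), -32768L)
  n_bytes <- length(pcm) * 2L
  sr <- as.integer(round(buffer$sample_rate))
  con <- withCallingHandlers(
    tryCatch(file(path, "wb"), error = function(e) {
      stop("cannot write: ", path, call. = FALSE)
    }),
    warning = function(w) invokeRestart("muffleWarning"))
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")      # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")       # PCM
  writeBin(1L, con, size = 2, endian = "little")       # mono
  writeBin(sr, con, size = 4, endian = "little")
  writeBin(sr * 2L, con, size = 4, endian = "little")  # byte rate
  writeBin(2L, con, size = 2, endian = "little")       # block align
  writeBin(16L, con, size = 2, endian = "little")      # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  if (length(pcm)) writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM mono WAV file
#'
#' Minimal chunk-walking reader for the files [write_wav()] produces
#' (16-bit PCM, one channel). Samples are rescaled to `[-1, 1]` by
#' 1/32767.
#'
#' @param path path to the WAV file.
#' @return An [audio_buffer()].
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file", call. = FALSE)
  readBin(con, integer(), size = 4, endian = "little")
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file", call. = FALSE)
  sr <- NULL; bits <- NULL; channels <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0L || !nzchar(id)) break
    size <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      if (fmt[1] != 1L) stop("only PCM WAV supported", call. = FALSE)
      channels <- fmt[2]
      sr <- readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 2, endian = "little")
      bits <- readBin(con, integer(), size = 2, endian = "little")
      if (size > 16L) readBin(con, raw(), n = size - 16L)
    } else if (id == "data") {
      samples <- readBin(con, integer(), n = size %/% 2, size = 2,
                         signed = TRUE, endian = "little")
    } else {
      readBin(con, raw(), n = size)
    }
  }
  if (is.null(sr) || is.null(samples)) {
    stop("missing fmt or data chunk", call. = FALSE)
  }
  if (bits != 16L || channels != 1L) {
    stop("only 16-bit mono WAV supported", call. = FALSE)
  }
  audio_buffer(pmax(samples / 32767, -1), sample_rate = sr)
}
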