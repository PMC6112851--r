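## Minimal mono RIFF/WAVE reader and writer (PCM-16 and IEEE float-32).
## Only the subset of the format used by the song pipeline is supported;
## anything else is rejected with an explicit message.

#' Audio recording container
#'
#' Lightweight container for a mono waveform plus its sampling rate and
#' optional provenance (recording day in days post hatch, rendition index).
#'
#' @param samples Numeric vector of samples, nominally in `[-1, 1]`.
#' @param sample_rate Sampling rate in Hz.
#' @param day_dph Optional recording day (days post hatch).
#' @param rendition Optional rendition index within the day.
#' @return An object of class `audio_recording`.
#' @export
audio_recording <- function(samples, sample_rate, day_dph = NA_integer_,
                            rendition = NA_integer_) {
  abort_if(!is.numeric(samples), "`samples` must be numeric")
  abort_if(!is_number(sample_rate) || sample_rate <= 0,
           "`sample_rate` must be a positive number")
  structure(
    list(samples = as.numeric(samples), sample_rate = sample_rate,
         day_dph = day_dph, rendition = rendition),
    class = "audio_recording"
  )
}

#' @export
print.audio_recording <- function(x, ...) {
  cat(sprintf("<audio_recording> %d samples @ %g Hz (%.3f s)\n",
              length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate))
  invisible(x)
}

#' Read a mono WAV file
#'
#' Supports uncompressed PCM-16 and IEEE float-32 mono files. Multichannel
#' or otherwise encoded files are rejected with an informative error, as
#' are truncated files.
#'
#' @param path Path to a `.wav` file.
#' @return An [audio_recording()].
#' @export
read_wav <- function(path) {
  abort_if(!file.exists(path), "file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  read_tag <- function() rawToChar(readBin(con, "raw", 4L))
  u32 <- function() readBin(con, "integer", 1L, size = 4L, endian = "little")
  u16 <- function() readBin(con, "integer", 1L, size = 2L, signed = FALSE,
                            endian = "little")
  abort_if(!identical(read_tag(), "RIFF"), "not a RIFF file: ", path)
  u32() # total size, unused
  abort_if(!identical(read_tag(), "WAVE"), "not a WAVE file: ", path)

  fmt <- NULL
  repeat {
    tag <- readBin(con, "raw", 4L)
    if (length(tag) < 4L) stop("truncated WAV file: ", path, call. = FALSE)
    id <- rawToChar(tag)
    size <- u32()
    if (length(size) == 0L) stop("truncated WAV file: ", path, call. = FALSE)
    if (id == "fmt ") {
      fmt <- list(audio_format = u16(), channels = u16(),
                  sample_rate = u32(), byte_rate = u32(),
                  block_align = u16(), bits = u16())
      if (size > 16L) readBin(con, "raw", size - 16L)
    } else if (id == "data") {
      abort_if(is.null(fmt), "malformed WAV: data chunk before fmt chunk")
      abort_if(fmt$channels != 1L,
               "only mono WAV is supported (file has ", fmt$channels,
               " channels)")
      if (fmt$audio_format == 1L && fmt$bits == 16L) {
        n <- size %/% 2L
        x <- readBin(con, "integer", n, size = 2L, signed = TRUE,
                     endian = "little")
        abort_if(length(x) < n, "truncated WAV data chunk: ", path)
        samples <- x / 32767
      } else if (fmt$audio_format == 3L && fmt$bits == 32L) {
        n <- size %/% 4L
        samples <- readBin(con, "double", n, size = 4L, endian = "little")
        abort_if(length(samples) < n, "truncated WAV data chunk: ", path)
      } else {
        stop("unsupported WAV encoding (format ", fmt$audio_format, ", ",
             fmt$bits, " bits); use PCM-16 or float-32", call. = FALSE)
      }
      return(audio_recording(samples, fmt$sample_rate))
    } else {
      skip <- readBin(con, "raw", size + size %% 2L)
      if (length(skip) < size) stop("truncated WAV file: ", path,
                                    call. = FALSE)
    }
  }
}

#' Write a mono WAV file
#'
#' @param audio An [audio_recording()] (or numeric vector with
#'   `sample_rate` given).
#' @param path Output path.
#' @param encoding `"float32"` (lossless for analysis data, default) or
#'   `"pcm16"`.
#' @param sample_rate Required when `audio` is a bare numeric vector.
#' @return `path`, invisibly.
#' @export
write_wav <- function(audio, path, encoding = c("float32", "pcm16"),
                      sample_rate = NULL) {
  encoding <- match.arg(encoding)
  if (is.numeric(audio)) {
    abort_if(is.null(sample_rate), "`sample_rate` required for bare vectors")
    audio <- audio_recording(audio, sample_rate)
  }
  x <- audio$samples
  sr <- as.integer(round(audio$sample_rate))
  if (encoding == "pcm16") {
    bytes_per <- 2L; fmt_code <- 1L; bits <- 16L
  } else {
    bytes_per <- 4L; fmt_code <- 3L; bits <- 32L
  }
  data_size <- length(x) * bytes_per
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  w32 <- function(v) writeBin(as.integer(v), con, size = 4L,
                              endian = "little")
  w16 <- function(v) writeBin(as.integer(v), con, size = 2L,
                              endian = "little")
  writeChar("RIFF", con, 4L, eos = NULL)
  w32(36L + data_size)
  writeChar("WAVE", con, 4L, eos = NULL)
  writeChar("fmt ", con, 4L, eos = NULL)
  w32(16L); w16(fmt_code); w16(1L); w32(sr)
  w32(sr * bytes_per); w16(bytes_per); w16(bits)
  writeChar("data", con, 4L, eos = NULL)
  w32(data_size)
  if (encoding == "pcm16") {
    q <- as.integer(round(pmax(pmin(x, 1), -1) * 32767))
    writeBin(q, con, size = 2L, endian = "little")
  } else {
    writeBin(as.numeric(x), con, size = 4L, endian = "little")
  }
  invisible(path)
}
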