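#' Scale raw integer PCM samples to arbitrary amplitude units (AAU)
#'
#' Full-scale signed `b`-bit integers are divided by `0.5 * 2^b`, placing
#' every recording on a common `[-1, 1]` scale regardless of bit depth, so
#' that amplitudes are directly comparable across sensors.
#'
#' @param raw Integer (or integer-valued numeric) vector of signed PCM samples.
#' @param bit_depth Bit depth `b` of the container, e.g. 16.
#' @return Numeric vector of amplitudes in AAU.
#' @examples
#' scale_to_aau(16384L, 16) # 0.5
#' @export
scale_to_aau <- function(raw, bit_depth) {
  if (!is.numeric(bit_depth) || length(bit_depth) != 1 || bit_depth <= 0) {
    stop("`bit_depth` must be a single positive number", call. = FALSE)
  }
  half_scale <- 0.5 * 2^bit_depth
  if (any(raw < -half_scale | raw > half_scale - 1, na.rm = TRUE)) {
    stop("raw samples are not representable as signed ", bit_depth, "-bit integers",
      call. = FALSE
    )
  }
  as.numeric(raw) / half_scale
}

#' Construct a wingbeat recording
#'
#' The basic container for one opto-acoustic recording: amplitude samples in
#' AAU together with the sample rate, bit depth and optional metadata
#' (species label, temperature, humidity).
#'
#' @param samples Numeric vector of amplitudes in AAU (within `[-1, 1]`).
#' @param sample_rate Sampling rate in Hz.
#' @param bit_depth Bit depth of the source container.
#' @param id Opaque identifier string.
#' @param species Species label, or `NA` for unknown.
#' @param temperature,humidity Optional covariates (deg C, %RH).
#' @return An object of class `wb_recording`.
#' @export
wb_recording <- function(samples, sample_rate, bit_depth = 16, id = NA_character_,
                         species = NA_character_, temperature = NA_real_,
                         humidity = NA_real_) {
  stopifnot(is.numeric(samples), length(samples) >= 1)
  if (!is.numeric(sample_rate) || sample_rate <= 0) {
    stop("`sample_rate` must be positive", call. = FALSE)
  }
  if (any(abs(samples) > 1 + 1e-9, na.rm = TRUE)) {
    stop("AAU samples must lie in [-1, 1]; did you forget scale_to_aau()?",
      call. = FALSE
    )
  }
  structure(
    list(
      samples = as.numeric(samples), sample_rate = sample_rate,
      bit_depth = bit_depth, n = length(samples),
      id = as.character(id), species = as.character(species),
      temperature = as.numeric(temperature), humidity = as.numeric(humidity)
    ),
    class = "wb_recording"
  )
}

#' @export
print.wb_recording <- function(x, ...) {
  cat(sprintf(
    "<wb_recording %s> %d samples @ %g Hz (%.3f s), %d-bit, species: %s\n",
    x$id, x$n, x$sample_rate, x$n / x$sample_rate, x$bit_depth,
    ifelse(is.na(x$species), "unknown", x$species)
  ))
  invisible(x)
}

# ---- minimal RIFF/WAVE PCM reader and writer (mono, 8/16-bit) ----

read_wav_mono <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) {
    stop("not a RIFF/WAVE file: ", path, call. = FALSE)
  }
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) {
    stop("not a RIFF/WAVE file: ", path, call. = FALSE)
  }
  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = readBin(body[1:2], "integer", 1, 2, endian = "little"),
        channels = readBin(body[3:4], "integer", 1, 2, endian = "little"),
        sample_rate = readBin(body[5:8], "integer", 1, 4, endian = "little"),
        bits = readBin(body[15:16], "integer", 1, 2, endian = "little")
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      invisible(readBin(con, "raw", size))
    }
    if (size %% 2 == 1) invisible(readBin(con, "raw", 1)) # chunk padding
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    stop("malformed WAV (missing fmt or data chunk): ", path, call. = FALSE)
  }
  if (fmt$audio_format != 1L) {
    stop("unsupported WAV encoding (need integer PCM, got format tag ",
      fmt$audio_format, "): ", path,
      call. = FALSE
    )
  }
  if (fmt$channels != 1L) {
    stop("multichannel WAV not supported (", fmt$channels, " channels): ", path,
      call. = FALSE
    )
  }
  if (fmt$bits == 8L) {
    # 8-bit WAV is unsigned by convention; re-centre before scaling
    raw_int <- as.integer(data_raw) - 128L
  } else if (fmt$bits == 16L) {
    raw_int <- readBin(data_raw, "integer",
      n = length(data_raw) / 2, size = 2,
      signed = TRUE, endian = "little"
    )
  } else {
    stop("unsupported PCM bit depth ", fmt$bits, ": ", path, call. = FALSE)
  }
  list(raw = raw_int, sample_rate = fmt$sample_rate, bit_depth = fmt$bits)
}

write_wav_mono <- function(raw, sample_rate, bit_depth, path) {
  stopifnot(bit_depth %in% c(8L, 16L))
  bytes_per_sample <- bit_depth / 8
  data_size <- length(raw) * bytes_per_sample
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little") # PCM
  writeBin(1L, con, size = 2, endian = "little") # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * bytes_per_sample), con, size = 4, endian = "little")
  writeBin(as.integer(bytes_per_sample), con, size = 2, endian = "little")
  writeBin(as.integer(bit_depth), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (bit_depth == 8L) {
    writeBin(as.raw(as.integer(raw) + 128L), con)
  } else {
    writeBin(as.integer(raw), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Load a mono PCM WAV recording
#'
#' Reads a mono integer-PCM WAV file, scales samples to AAU by the container's
#' bit depth (see [scale_to_aau()]), and attaches any sidecar metadata.
#' Sample rate and bit depth are always taken from the WAV header.
#'
#' @param path Path to a mono PCM WAV file.
#' @param metadata Optional one-row data frame (or named list) with columns
#'   among `id`, `species`, `temperature`, `humidity`.
#' @return A [wb_recording()].
#' @export
load_recording <- function(path, metadata = NULL) {
  wav <- read_wav_mono(path)
  get_meta <- function(field, default) {
    if (!is.null(metadata) && field %in% names(metadata)) metadata[[field]][1] else default
  }
  wb_recording(
    samples = scale_to_aau(wav$raw, wav$bit_depth),
    sample_rate = wav$sample_rate,
    bit_depth = wav$bit_depth,
    id = get_meta("id", tools::file_path_sans_ext(basename(path))),
    species = get_meta("species", NA_character_),
    temperature = get_meta("temperature", NA_real_),
    humidity = get_meta("humidity", NA_real_)
  )
}

#' Write a recording to a mono PCM WAV file
#'
#' Quantizes AAU samples back to signed integers at the recording's bit depth
#' and writes a RIFF PCM container.
#'
#' @param rec A [wb_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "wb_recording"))
  half_scale <- 0.5 * 2^rec$bit_depth
  raw <- as.integer(pmin(pmax(round(rec$samples * half_scale), -half_scale), half_scale - 1))
  write_wav_mono(raw, rec$sample_rate, rec$bit_depth, path)
}

#' Load a directory of recordings with a sidecar metadata table
#'
#' @param dir Directory containing `.wav` files.
#' @param sidecar Path to a CSV with columns `id`, `species` and optionally
#'   `temperature`, `humidity`; defaults to `sidecar.csv` inside `dir`.
#'   Rows are matched to files by `id` = file name without extension.
#' @return A list of [wb_recording()] objects, named by id.
#' @export
load_corpus <- function(dir, sidecar = file.path(dir, "sidecar.csv")) {
  files <- sort(list.files(dir, pattern = "\\.wav$", full.names = TRUE))
  if (length(files) == 0) stop("no .wav files found in ", dir, call. = FALSE)
  meta <- if (file.exists(sidecar)) {
    utils::read.csv(sidecar, stringsAsFactors = FALSE)
  } else {
    NULL
  }
  recs <- lapply(files, function(f) {
    id <- tools::file_path_sans_ext(basename(f))
    row <- if (!is.null(meta)) meta[meta$id == id, , drop = FALSE] else NULL
    if (!is.null(row) && nrow(row) == 0) row <- NULL
    load_recording(f, metadata = row)
  })
  names(recs) <- vapply(recs, function(r) r$id, character(1))
  recs
}
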