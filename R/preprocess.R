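#' Trim silence from a recording
#'
#' Background noise sits below a fixed amplitude threshold (0.0061 AAU by
#' default). Because noise is stochastic, isolated supra-threshold samples far
#' from the flight are not evidence of sound: among the indices whose absolute
#' amplitude exceeds the threshold, any index lying more than
#' `iqr_multiplier` interquartile ranges beyond the upper or lower quartile of
#' the index distribution is treated as stochastic variation and discarded.
#' The recording is trimmed to the span of the surviving indices (the
#' boxplot-whisker rule).
#'
#' @param rec A [wb_recording()].
#' @param threshold Amplitude threshold in AAU below which sound is background.
#' @param iqr_multiplier Fence width in IQR units for the temporal outlier rule.
#' @param min_length Trimmed spans shorter than this many samples are flagged
#'   `too_short` (they carry no usable flight).
#' @return An object of class `wb_trimmed`: trimmed samples, `start_index` /
#'   `end_index` (0-based, inclusive, into the parent recording), `duration`
#'   in seconds, `too_short` flag and provenance fields.
#' @export
trim_silence <- function(rec, threshold = 0.0061, iqr_multiplier = 3,
                         min_length = 128L) {
  stopifnot(inherits(rec, "wb_recording"))
  supra <- which(abs(rec$samples) > threshold)
  if (length(supra) == 0) {
    stop(
      "NoSignal: no samples exceed ", threshold,
      " AAU in recording ", rec$id,
      call. = FALSE
    )
  }
  qs <- stats::quantile(supra, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- qs[2] - qs[1]
  lower_fence <- qs[1] - iqr_multiplier * iqr
  upper_fence <- qs[2] + iqr_multiplier * iqr
  keep <- supra[supra >= lower_fence & supra <= upper_fence]
  start <- min(keep)
  end <- max(keep)
  span <- end - start + 1L
  structure(
    list(
      samples = rec$samples[start:end],
      start_index = start - 1L, # 0-based, inclusive
      end_index = end - 1L,
      duration = span / rec$sample_rate,
      sample_rate = rec$sample_rate,
      bit_depth = rec$bit_depth,
      too_short = span < min_length,
      parent_id = rec$id,
      species = rec$species,
      temperature = rec$temperature,
      humidity = rec$humidity
    ),
    class = "wb_trimmed"
  )
}

#' @export
print.wb_trimmed <- function(x, ...) {
  cat(sprintf(
    "<wb_trimmed %s> span [%d, %d] (%d samples, %.4f s)%s\n",
    x$parent_id, x$start_index, x$end_index, length(x$samples), x$duration,
    if (x$too_short) " [too short]" else ""
  ))
  invisible(x)
}

#' Minimum-length filter
#'
#' Trimmed recordings shorter than the minimum length carry too little flight
#' to support feature extraction and are excluded. Rejection is a normal
#' outcome, not an error.
#'
#' @param t A `wb_trimmed` object from [trim_silence()].
#' @param min_length Minimum trimmed length in samples.
#' @return `t` if retained, otherwise `NULL` (with attribute-free rejection;
#'   batch callers count rejections).
#' @export
min_length_filter <- function(t, min_length = 128L) {
  stopifnot(inherits(t, "wb_trimmed"))
  if (length(t$samples) < min_length) NULL else t
}

#' Trim a corpus and report retention
#'
#' Applies [trim_silence()] and [min_length_filter()] to every recording and
#' returns a per-recording report.
#'
#' @param recordings List of [wb_recording()] objects.
#' @inheritParams trim_silence
#' @return A tibble with one row per recording: `id`, `start`, `end`
#'   (0-based, inclusive; `NA` when no signal), `duration`, `retained` and
#'   `reason` (`"ok"`, `"no_signal"` or `"too_short"`). The list of retained
#'   `wb_trimmed` objects is attached as attribute `"trimmed"`.
#' @export
trim_corpus <- function(recordings, threshold = 0.0061, iqr_multiplier = 3,
                        min_length = 128L) {
  rows <- vector("list", length(recordings))
  trimmed <- list()
  for (i in seq_along(recordings)) {
    rec <- recordings[[i]]
    tr <- tryCatch(
      trim_silence(rec, threshold, iqr_multiplier, min_length),
      error = function(e) NULL
    )
    if (is.null(tr)) {
      rows[[i]] <- tibble::tibble(
        id = rec$id, start = NA_integer_, end = NA_integer_,
        duration = NA_real_, retained = FALSE, reason = "no_signal"
      )
    } else if (tr$too_short) {
      rows[[i]] <- tibble::tibble(
        id = rec$id, start = tr$start_index, end = tr$end_index,
        duration = tr$duration, retained = FALSE, reason = "too_short"
      )
    } else {
      rows[[i]] <- tibble::tibble(
        id = rec$id, start = tr$start_index, end = tr$end_index,
        duration = tr$duration, retained = TRUE, reason = "ok"
      )
      trimmed[[rec$id]] <- tr
    }
  }
  report <- dplyr::bind_rows(rows)
  attr(report, "trimmed") <- trimmed
  report
}

# Hann-windowed frame matrix of x (zero-padded at both ends by wl), hop wl/2.
# Periodic Hann: w(k) + w(k + wl/2) = 1 exactly, so plain overlap-add of
# unmodified frames reconstructs the interior signal exactly.
stft_frames <- function(x, wl) {
  hop <- wl %/% 2
  pad <- wl
  xp <- c(rep(0, pad), x, rep(0, pad + wl))
  starts <- seq(1, length(xp) - wl + 1, by = hop)
  win <- 0.5 * (1 - cos(2 * pi * (0:(wl - 1)) / wl))
  mat <- vapply(starts, function(s) xp[s:(s + wl - 1)] * win, numeric(wl))
  list(fft = stats::mvfft(mat), starts = starts, wl = wl, pad = pad, n = length(x))
}

#' Background-variation filter (spectral subtraction)
#'
#' Decomposes the trimmed signal into Hann-windowed frames (short-time Fourier
#' transform, 50% overlap), estimates a noise floor, subtracts the floor from
#' each frame's magnitude (clipped at zero, phase preserved), and
#' resynthesizes by overlap-add. Output length equals input length. Signals
#' shorter than the window are passed through with a warning.
#'
#' The floor is a pluggable strategy. The default, `"frame_median"`, takes
#' each frame's median magnitude across frequency bins: the wingbeat tone and
#' its harmonics occupy only a few of the 65 bins, so the across-bin median
#' measures the broadband background level and subtracting it preserves the
#' harmonic peaks while flattening the noise. The alternative `"bin_median"`
#' (per-bin median across frames) removes everything temporally stationary —
#' including a persistent wingbeat tone — and is provided only for signals
#' whose foreground is intermittent.
#'
#' @param t A `wb_trimmed` object.
#' @param wl STFT window length in samples.
#' @param floor Noise-floor strategy, `"frame_median"` or `"bin_median"`.
#' @return `t` with filtered samples (field `filtered` set to `TRUE`).
#' @export
background_filter <- function(t, wl = 128L, floor = c("frame_median", "bin_median")) {
  stopifnot(inherits(t, "wb_trimmed"))
  floor <- match.arg(floor)
  x <- t$samples
  n <- length(x)
  if (n < wl) {
    warning("signal shorter than filter window (", n, " < ", wl,
      "); background filter skipped",
      call. = FALSE
    )
    t$filtered <- FALSE
    return(t)
  }
  fr <- stft_frames(x, wl)
  mag <- Mod(fr$fft)
  phase <- fr$fft / (mag + (mag == 0)) # unit phasors; 0 where mag 0
  nbin <- wl %/% 2 + 1
  if (floor == "frame_median") {
    # median over the one-sided bins of each frame, applied to that frame
    fl <- matrix(
      rep(apply(mag[1:nbin, , drop = FALSE], 2, stats::median), each = wl),
      nrow = wl
    )
  } else {
    fl <- apply(mag, 1, stats::median)
  }
  mag_clean <- pmax(mag - fl, 0)
  clean_frames <- Re(stats::mvfft(mag_clean * phase, inverse = TRUE)) / wl
  # overlap-add; Hann at 50% hop satisfies constant overlap-add, so an
  # unfiltered signal reconstructs exactly in the interior
  out <- numeric(length(fr$starts) * (wl %/% 2) + wl)
  for (j in seq_along(fr$starts)) {
    s <- fr$starts[j]
    out[s:(s + wl - 1)] <- out[s:(s + wl - 1)] + clean_frames[, j]
  }
  t$samples <- out[(fr$pad + 1):(fr$pad + n)]
  t$filtered <- TRUE
  t
}
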