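#' The 52-feature schema
#'
#' One row per extracted feature: its key, extraction stage (1-7), whether it
#' is computed on the detrended signal, the storage transformation (natural
#' log, square root, or none) and its family. Feature-set definitions are
#' derived from this table so the schema is the single source of truth.
#'
#' @return A 52-row tibble with columns `feature`, `stage`, `detrended`,
#'   `transform`, `family`.
#' @export
feature_schema <- function() {
  energy <- c(
    "max_amplitude", "amplitude_range", "amplitude_iqr",
    "power", "rms", "crest_factor"
  )
  raw <- dplyr::bind_rows(
    tibble::tibble(feature = energy, stage = 1L, transform = "log", family = "audio"),
    tibble::tibble(
      feature = c("amplitude_index", "temporal_entropy"), stage = 2L,
      transform = c("log", "none"), family = "audio"
    ),
    tibble::tibble(
      feature = paste0("bioacoustic_index_", 1:4), stage = 3L,
      transform = "none", family = "frequency"
    ),
    tibble::tibble(
      feature = c("spectral_entropy", "acoustic_entropy"), stage = 3L,
      transform = "none", family = c("frequency", "audio-frequency")
    ),
    tibble::tibble(
      feature = "dominant_frequency", stage = 3L,
      transform = "sqrt", family = "frequency"
    ),
    tibble::tibble(
      feature = paste0("harmonic_", 1:10), stage = 3L,
      transform = "none", family = "harmonics"
    )
  )
  raw$detrended <- FALSE
  det <- dplyr::bind_rows(
    tibble::tibble(
      feature = "gam_amplitude_range", stage = 4L,
      transform = "log", family = "audio"
    ),
    tibble::tibble(feature = paste0(energy, "_g"), stage = 4L, transform = "log", family = "audio"),
    tibble::tibble(
      feature = c("amplitude_index_g", "temporal_entropy_g"), stage = 5L,
      transform = c("log", "none"), family = "audio"
    ),
    tibble::tibble(
      feature = paste0("bioacoustic_index_", 1:4, "_g"), stage = 6L,
      transform = "none", family = "frequency"
    ),
    tibble::tibble(
      feature = c("spectral_entropy_g", "acoustic_entropy_g"), stage = 6L,
      transform = "none", family = c("frequency", "audio-frequency")
    ),
    tibble::tibble(
      feature = "dominant_frequency_g", stage = 6L,
      transform = "sqrt", family = "frequency"
    ),
    tibble::tibble(
      feature = paste0("harmonic_", 1:10, "_g"), stage = 6L,
      transform = "none", family = "harmonics"
    ),
    tibble::tibble(
      feature = "fundamental_frequency_g", stage = 7L,
      transform = "log", family = "harmonics"
    )
  )
  det$detrended <- TRUE
  out <- dplyr::bind_rows(raw, det)
  out[, c("feature", "stage", "detrended", "transform", "family")]
}

# storage transformation per the schema; non-positive values under log (and
# negative under sqrt) are undefined and stored as missing
apply_transform <- function(value, transform) {
  switch(transform,
    log = ifelse(is.na(value) | value <= 0, NA_real_, log(value)),
    sqrt = ifelse(is.na(value) | value < 0, NA_real_, sqrt(value)),
    none = value
  )
}

back_transform <- function(value, transform) {
  switch(transform,
    log = exp(value),
    sqrt = value^2,
    none = value
  )
}

#' Amplitude and energy summary statistics (stage 1 / 4)
#'
#' Six flight-energy summaries of an amplitude series: maximum absolute
#' amplitude, amplitude range, amplitude interquartile range, power (mean
#' squared amplitude), RMS, and the crest factor (peak over RMS). Values are
#' returned untransformed; the pipeline log-transforms them at storage.
#'
#' @param x Amplitude vector (AAU).
#' @return Named list of six reals.
#' @export
amplitude_energy_stats <- function(x) {
  stopifnot(length(x) >= 1)
  qs <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
  power <- mean(x^2)
  rms <- sqrt(power)
  list(
    max_amplitude = max(abs(x)),
    amplitude_range = max(x) - min(x),
    amplitude_iqr = qs[2] - qs[1],
    power = power,
    rms = rms,
    crest_factor = if (rms > 0) max(abs(x)) / rms else NA_real_
  )
}

# analytic signal via FFT: one-sided spectrum doubling
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Hilbert amplitude envelope
#'
#' Magnitude of the analytic signal: a smooth loudness contour over time.
#'
#' @param x Amplitude vector.
#' @return Nonnegative numeric vector, same length as `x`.
#' @export
hilbert_envelope <- function(x) {
  Mod(analytic_signal(x))
}

#' Temporal entropy of an amplitude envelope
#'
#' Shannon evenness of the unit-sum normalized envelope:
#' `-(1 / log n) * sum(p * log p)` with `0 * log 0 := 0`. Equals 0 for an
#' envelope concentrated in one sample and 1 for a perfectly uniform one.
#'
#' @param envelope Nonnegative numeric vector (e.g. from
#'   [hilbert_envelope()]).
#' @return A value in `[0, 1]`, or `NA` for a zero envelope.
#' @export
temporal_entropy <- function(envelope) {
  if (any(envelope < 0, na.rm = TRUE)) {
    stop("envelope must be nonnegative", call. = FALSE)
  }
  shannon_evenness(envelope)
}

#' Spectral entropy of a mean magnitude spectrum
#'
#' Shannon evenness of the unit-sum normalized mean spectrum over its
#' frequency bins: 0 when all spectral mass sits in one bin (a pure tone),
#' 1 for a perfectly flat spectrum.
#'
#' @param s A `wb_spectrum`, or a nonnegative numeric vector of mean
#'   magnitudes.
#' @return A value in `[0, 1]`, or `NA` for a zero spectrum.
#' @export
spectral_entropy <- function(s) {
  m <- if (inherits(s, "wb_spectrum")) s$mean_mag else s
  shannon_evenness(m)
}

# Shannon evenness of a nonnegative weight vector: -(1/log n) sum p log p,
# with 0 log 0 := 0, on the unit-sum normalization of w
shannon_evenness <- function(w) {
  n <- length(w)
  total <- sum(w)
  if (!is.finite(total) || total <= 0 || n < 2) {
    return(NA_real_)
  }
  p <- w / total
  p <- p[p > 0]
  -sum(p * log(p)) / log(n)
}

#' Envelope summaries: amplitude index and temporal entropy (stage 2 / 5)
#'
#' The amplitude index is the median of the Hilbert amplitude envelope; the
#' temporal entropy is the Shannon evenness of the unit-sum normalized
#' envelope, lying in `[0, 1]` (0 = a single click, 1 = constant loudness).
#'
#' @param x Amplitude vector (the pipeline passes zero-padded trimmed audio).
#' @return List with `amplitude_index` (untransformed median envelope) and
#'   `temporal_entropy`.
#' @export
envelope_stats <- function(x) {
  env <- hilbert_envelope(x)
  if (all(env == 0)) {
    return(list(amplitude_index = NA_real_, temporal_entropy = NA_real_))
  }
  list(
    amplitude_index = stats::median(env),
    temporal_entropy = temporal_entropy(env)
  )
}

#' Mean magnitude spectrum by short-time Fourier transform (stage 3 / 6)
#'
#' The signal is zero-padded to `pad_to` samples (recordings already longer
#' than `pad_to` are left unpadded), cut into non-overlapping Hann windows of
#' `wl` samples, and the magnitude spectra of the windows are averaged. The
#' frequency axis runs from 0 to Nyquist in steps of `sample_rate / wl`.
#'
#' @param x Amplitude vector (trimmed, or trimmed-and-detrended, audio).
#' @param sample_rate Sampling rate in Hz.
#' @param wl Window length in samples.
#' @param pad_to Zero-padding target length in samples.
#' @return An object of class `wb_spectrum`: `freqs`, `mean_mag`, and the
#'   unit-sum `normalized` version.
#' @export
mean_spectrum <- function(x, sample_rate, wl = 128L, pad_to = 8192L) {
  n <- length(x)
  if (n < pad_to) x <- c(x, rep(0, pad_to - n))
  nf <- floor(length(x) / wl)
  win <- signal::hanning(wl)
  frames <- matrix(x[seq_len(nf * wl)], nrow = wl, ncol = nf)
  mag <- Mod(stats::mvfft(frames * win))[1:(wl / 2 + 1), , drop = FALSE]
  mean_mag <- rowMeans(mag)
  total <- sum(mean_mag)
  structure(
    list(
      freqs = (0:(wl / 2)) * sample_rate / wl,
      mean_mag = mean_mag,
      normalized = if (total > 0) mean_mag / total else rep(NA_real_, length(mean_mag)),
      sample_rate = sample_rate, wl = wl
    ),
    class = "wb_spectrum"
  )
}

#' Bioacoustic indices (stage 3 / 6)
#'
#' Area under the mean magnitude spectrum within four frequency bands:
#' 0-1000 Hz (including slow body oscillations below 50 Hz), 50-1000 Hz,
#' 50-300 Hz (low-order harmonics including the fundamental) and 200-3000 Hz
#' (higher-order harmonics). A band lying entirely above Nyquist yields `NA`.
#'
#' @param s A `wb_spectrum`.
#' @return Named list `bioacoustic_index_1` ... `bioacoustic_index_4`.
#' @export
bioacoustic_indices <- function(s) {
  stopifnot(inherits(s, "wb_spectrum"))
  bands <- list(c(0, 1000), c(50, 1000), c(50, 300), c(200, 3000))
  out <- lapply(bands, function(b) {
    if (b[1] > max(s$freqs)) {
      return(NA_real_)
    }
    sum(s$mean_mag[s$freqs >= b[1] & s$freqs <= b[2]])
  })
  names(out) <- paste0("bioacoustic_index_", 1:4)
  out
}

#' Spectral and acoustic entropy (stage 3 / 6)
#'
#' Spectral entropy is the Shannon evenness of the unit-sum normalized mean
#' spectrum (0 = pure tone, 1 = flat). Acoustic entropy is the product of the
#' temporal and spectral entropies, an overall index of sound clarity.
#'
#' @param s A `wb_spectrum`.
#' @param temporal_entropy The matching temporal entropy from [envelope_stats()].
#' @return List with `spectral_entropy` and `acoustic_entropy`.
#' @export
spectral_acoustic_entropy <- function(s, temporal_entropy) {
  stopifnot(inherits(s, "wb_spectrum"))
  if (sum(s$mean_mag) <= 0) {
    return(list(spectral_entropy = NA_real_, acoustic_entropy = NA_real_))
  }
  hf <- spectral_entropy(s)
  list(
    spectral_entropy = hf,
    acoustic_entropy = temporal_entropy * hf
  )
}

#' Harmonic peaks and dominant frequency (stage 3 / 6)
#'
#' Peaks are strict local maxima of the mean magnitude spectrum. The ten
#' tallest (ties broken toward lower frequency) are recorded in descending
#' height order as harmonics 1-10, with no lower frequency limit. The
#' dominant frequency is the tallest peak strictly above 50 Hz, excluding
#' slow body oscillations; it can differ from the first harmonic when the
#' tallest peak sits below 50 Hz.
#'
#' @param s A `wb_spectrum`.
#' @return List with `harmonics` (length-10 numeric, Hz, `NA` beyond the
#'   available peaks) and `dominant` (Hz, untransformed).
#' @export
harmonic_peaks <- function(s) {
  stopifnot(inherits(s, "wb_spectrum"))
  m <- s$mean_mag
  k <- length(m)
  if (k < 3 || all(m == 0)) {
    return(list(harmonics = rep(NA_real_, 10), dominant = NA_real_))
  }
  idx <- which(m[2:(k - 1)] > m[1:(k - 2)] & m[2:(k - 1)] > m[3:k]) + 1L
  if (length(idx) == 0) {
    return(list(harmonics = rep(NA_real_, 10), dominant = NA_real_))
  }
  ord <- idx[order(-m[idx], s$freqs[idx])]
  harmonics <- rep(NA_real_, 10)
  top <- utils::head(ord, 10)
  harmonics[seq_along(top)] <- s$freqs[top]
  above <- ord[s$freqs[ord] > 50]
  dominant <- if (length(above)) s$freqs[above[1]] else NA_real_
  list(harmonics = harmonics, dominant = dominant)
}

#' Fundamental (wingbeat) frequency by autocorrelation (stage 7)
#'
#' The wingbeat repeats with period `T`; the normalized autocorrelation of
#' the detrended signal therefore peaks at lag `T`. Peaks are located on the
#' signed autocorrelation (see the methods vignette for why the signed
#' function, rather than its modulus, is searched), constrained to be at
#' least `min_separation` samples apart and at least `min_height` tall; the
#' fundamental is the inverse of the first (smallest-lag) qualifying peak.
#' Estimates outside `[f_min, f_max]` — or signals with no qualifying peak,
#' such as pure noise — yield a missing value.
#'
#' @param x Detrended amplitude vector.
#' @param sample_rate Sampling rate in Hz.
#' @param min_separation Minimum distance between peaks, in samples; also the
#'   minimum admissible lag.
#' @param min_height Minimum autocorrelation at a peak.
#' @param f_min,f_max Admissible frequency range in Hz.
#' @return List with `f0` (Hz), `period` (s) and `acf_peak_lag` (samples),
#'   all `NA` when no qualifying peak exists.
#' @export
fundamental_frequency <- function(x, sample_rate, min_separation = 10L,
                                  min_height = 0.2, f_min = 20, f_max = 2000) {
  n <- length(x)
  empty <- list(f0 = NA_real_, period = NA_real_, acf_peak_lag = NA_integer_)
  if (n < 2 * min_separation || stats::sd(x) == 0) {
    return(empty)
  }
  lag_max <- min(n - 1, ceiling(sample_rate / f_min))
  a <- as.numeric(stats::acf(x, lag.max = lag_max, plot = FALSE, demean = TRUE)$acf)[-1]
  pk <- tryCatch(
    pracma::findpeaks(a,
      minpeakdistance = min_separation,
      minpeakheight = min_height
    ),
    error = function(e) NULL
  )
  if (is.null(pk) || nrow(pk) == 0) {
    return(empty)
  }
  lags <- pk[, 2]
  lags <- lags[lags >= min_separation]
  if (length(lags) == 0) {
    return(empty)
  }
  lag <- min(lags)
  f0 <- sample_rate / lag
  if (f0 < f_min || f0 > f_max) {
    return(empty)
  }
  list(f0 = f0, period = lag / sample_rate, acf_peak_lag = as.integer(lag))
}

# assemble the 17 spectrum-derived features (stages 3 / 6) for one signal
spectrum_features <- function(x, sample_rate, temporal_entropy, wl, pad_to, suffix = "") {
  s <- mean_spectrum(x, sample_rate, wl = wl, pad_to = pad_to)
  bio <- bioacoustic_indices(s)
  ent <- spectral_acoustic_entropy(s, temporal_entropy)
  hp <- harmonic_peaks(s)
  out <- c(
    bio,
    ent,
    list(dominant_frequency = hp$dominant),
    stats::setNames(as.list(hp$harmonics), paste0("harmonic_", 1:10))
  )
  names(out) <- paste0(names(out), suffix)
  out
}

#' Extract the full 52-feature vector from one recording
#'
#' Runs the whole per-recording pipeline: silence trimming, minimum-length
#' check, background filtering, stage 1-3 features on the trimmed audio
#' (energy statistics; envelope summaries and spectrum features on the
#' zero-padded signal), GAM detrending, stage 4-6 features on the detrended
#' signal, and the stage-7 autocorrelation fundamental frequency. Storage
#' transformations (natural log, square root) from the schema are applied;
#' undefined computations yield missing values, never sentinels.
#'
#' @param rec A [wb_recording()].
#' @param config A [pipeline_config()] (defaults used when `NULL`).
#' @return A one-row tibble: `id`, `species`, `temperature`, `humidity`,
#'   `duration`, then the 52 feature columns in schema order.
#' @export
extract_features <- function(rec, config = NULL) {
  cfg <- config %||% pipeline_config()
  tr <- trim_silence(rec,
    threshold = cfg$threshold, iqr_multiplier = cfg$iqr_multiplier,
    min_length = cfg$min_length
  )
  if (is.null(min_length_filter(tr, cfg$min_length))) {
    stop("recording ", rec$id, " is too short after trimming (",
      length(tr$samples), " < ", cfg$min_length, " samples)",
      call. = FALSE
    )
  }
  extract_features_trimmed(tr, cfg)
}

# feature extraction on an already retained wb_trimmed
extract_features_trimmed <- function(tr, cfg) {
  ft <- background_filter(tr, wl = cfg$window_length)
  x <- ft$samples
  sr <- ft$sample_rate
  sch <- feature_schema()
  vals <- stats::setNames(
    as.list(rep(NA_real_, nrow(sch))),
    sch$feature
  )

  # stages 1-3: raw (filtered, trimmed) audio
  st1 <- amplitude_energy_stats(x)
  vals[names(st1)] <- st1
  xp <- if (length(x) < cfg$pad_length) c(x, rep(0, cfg$pad_length - length(x))) else x
  env <- envelope_stats(xp)
  vals$amplitude_index <- env$amplitude_index
  vals$temporal_entropy <- env$temporal_entropy
  vals[] <- utils::modifyList(
    vals,
    spectrum_features(x, sr, env$temporal_entropy,
      wl = cfg$window_length, pad_to = cfg$pad_length
    )
  )[names(vals)]

  # stages 4-7: detrended audio
  trend <- fit_trend(ft,
    k_divisor = cfg$gam_k_divisor, k_min = cfg$gam_k_min,
    max_trend_frequency = cfg$gam_max_trend_frequency
  )
  if (trend$ok) {
    xd <- trend$residuals
    vals$gam_amplitude_range <- trend$gam_amplitude_range
    st4 <- amplitude_energy_stats(xd)
    vals[paste0(names(st4), "_g")] <- st4
    xdp <- if (length(xd) < cfg$pad_length) c(xd, rep(0, cfg$pad_length - length(xd))) else xd
    envd <- envelope_stats(xdp)
    vals$amplitude_index_g <- envd$amplitude_index
    vals$temporal_entropy_g <- envd$temporal_entropy
    vals[] <- utils::modifyList(
      vals,
      spectrum_features(xd, sr, envd$temporal_entropy,
        wl = cfg$window_length, pad_to = cfg$pad_length, suffix = "_g"
      )
    )[names(vals)]
    f0 <- fundamental_frequency(xd, sr,
      min_separation = cfg$acf_min_separation,
      min_height = cfg$acf_min_height
    )
    vals$fundamental_frequency_g <- f0$f0
  }

  stored <- mapply(
    function(v, tf) apply_transform(v, tf),
    unlist(vals[sch$feature]), sch$transform
  )
  dplyr::bind_cols(
    tibble::tibble(
      id = tr$parent_id, species = tr$species,
      temperature = tr$temperature, humidity = tr$humidity,
      duration = tr$duration
    ),
    tibble::as_tibble(as.list(stored))
  )
}

#' Extract features for a whole corpus
#'
#' Trims every recording, drops those with no signal or a sub-minimum trimmed
#' length, and extracts the 52 features for the rest.
#'
#' @param recordings List of [wb_recording()] objects (e.g. from
#'   [load_corpus()] or [simulate_corpus()]).
#' @param config A [pipeline_config()].
#' @return A tibble with one row per retained recording. The trim report
#'   (see [trim_corpus()]) is attached as attribute `"trim_report"`.
#' @export
extract_corpus <- function(recordings, config = NULL) {
  cfg <- config %||% pipeline_config()
  report <- trim_corpus(recordings,
    threshold = cfg$threshold,
    iqr_multiplier = cfg$iqr_multiplier, min_length = cfg$min_length
  )
  trimmed <- attr(report, "trimmed")
  rows <- lapply(trimmed, function(tr) {
    tryCatch(extract_features_trimmed(tr, cfg), error = function(e) {
      warning("feature extraction failed for ", tr$parent_id, ": ",
        conditionMessage(e),
        call. = FALSE
      )
      NULL
    })
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "trim_report") <- report
  out
}
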