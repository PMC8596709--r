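#' Define a synthetic species template
#'
#' Parameters of the generative model for one species' wingbeat recordings:
#' a harmonic tone at a species-specific fundamental with geometrically
#' decaying overtones, shaped by a raised-cosine flight envelope, riding on a
#' slow single peak-and-trough movement trend, in Gaussian background noise,
#' quantized at a stated bit depth.
#'
#' @param name Species label.
#' @param f0_mean,f0_sd Fundamental (wingbeat) frequency distribution, Hz.
#' @param n_harmonics Number of harmonic components.
#' @param harmonic_decay Amplitude ratio between successive harmonics (0, 1].
#' @param base_amplitude Amplitude of the fundamental, AAU.
#' @param trend_amplitude Peak-to-trough range of the movement trend, AAU.
#' @param flight_duration_mean,flight_duration_sd Flight length distribution, s.
#' @param noise_rms Background noise RMS, AAU.
#' @param temperature_coefficient Shift in f0 per degree C away from 20 C.
#' @param order Insect order label (used by order-level classification tasks).
#' @return A `wb_template` list.
#' @export
species_template <- function(name, f0_mean, f0_sd = 3, n_harmonics = 3,
                             harmonic_decay = 0.5, base_amplitude = 0.2,
                             trend_amplitude = 0.1,
                             flight_duration_mean = 0.17,
                             flight_duration_sd = 0.06,
                             noise_rms = 0.0015,
                             temperature_coefficient = 0,
                             order = "Hemiptera") {
  stopifnot(f0_mean > 0, f0_sd >= 0, harmonic_decay > 0, harmonic_decay <= 1)
  structure(
    list(
      name = name, f0_mean = f0_mean, f0_sd = f0_sd,
      n_harmonics = n_harmonics, harmonic_decay = harmonic_decay,
      base_amplitude = base_amplitude, trend_amplitude = trend_amplitude,
      flight_duration_mean = flight_duration_mean,
      flight_duration_sd = flight_duration_sd,
      noise_rms = noise_rms,
      temperature_coefficient = temperature_coefficient,
      order = order
    ),
    class = "wb_template"
  )
}

#' Study-species template presets
#'
#' Templates for the six classified study species, with mean wingbeat
#' frequencies set to the covariate-adjusted species means reported for the
#' real corpus (A. fabae 134, D. platanoidis 104, P. testudinaceus 113,
#' S. avenae 106 Hz for the aphids; P. chrysocephala 121, B. aeneus 139 Hz
#' for the beetles).
#'
#' @param f0_sd Within-species fundamental-frequency SD, Hz.
#' @param ... Further arguments passed to every [species_template()].
#' @return Named list of `wb_template` objects.
#' @export
species_presets <- function(f0_sd = 3, ...) {
  spec <- list(
    A_fabae = list(f0 = 134, order = "Hemiptera", dur = 0.17),
    D_platanoidis = list(f0 = 104, order = "Hemiptera", dur = 0.17),
    P_testudinaceus = list(f0 = 113, order = "Hemiptera", dur = 0.17),
    S_avenae = list(f0 = 106, order = "Hemiptera", dur = 0.17),
    # the cabbage stem flea beetle's flights are distinctively short
    P_chrysocephala = list(f0 = 121, order = "Coleoptera", dur = 0.076),
    B_aeneus = list(f0 = 139, order = "Coleoptera", dur = 0.17)
  )
  purrr::imap(spec, function(s, nm) {
    species_template(nm,
      f0_mean = s$f0, f0_sd = f0_sd, order = s$order,
      flight_duration_mean = s$dur,
      flight_duration_sd = min(0.06, s$dur / 2.5), ...
    )
  })
}

#' Class-imbalance preset
#'
#' Per-species recording counts in the ratio observed in the real corpus
#' (3323 : 848 : 274 : 186 : 161 : 113 for D. platanoidis, B. aeneus,
#' S. avenae, P. chrysocephala, A. fabae, P. testudinaceus), scaled by
#' `scale` and rounded.
#'
#' @param scale Scaling factor applied to the full-corpus counts.
#' @return Named integer vector of counts.
#' @export
imbalance_preset <- function(scale = 1) {
  counts <- c(
    D_platanoidis = 3323, B_aeneus = 848, S_avenae = 274,
    P_chrysocephala = 186, A_fabae = 161, P_testudinaceus = 113
  )
  scaled <- pmax(1L, as.integer(round(counts * scale)))
  stats::setNames(scaled, names(counts))
}

# raised-cosine on/off flight envelope: ramps of `ramp` samples, flat middle
flight_envelope <- function(n, ramp) {
  ramp <- min(ramp, floor(n / 2))
  env <- rep(1, n)
  if (ramp > 0) {
    up <- 0.5 * (1 - cos(pi * (seq_len(ramp) - 0.5) / ramp))
    env[seq_len(ramp)] <- up
    env[n - seq_len(ramp) + 1] <- up
  }
  env
}

#' Simulate one wingbeat recording
#'
#' Draws a flight duration and fundamental frequency from the template,
#' synthesizes `trend + envelope * harmonic tone + noise` inside a silent
#' buffer, and quantizes to the requested bit depth. The movement trend is a
#' single smooth peak then trough confined to the flight. Uses the current
#' RNG stream (seed the caller for reproducibility).
#'
#' @param template A [species_template()].
#' @param sample_rate Hz.
#' @param bit_depth Bits.
#' @param total_length Buffer length in seconds.
#' @param temperature,humidity Covariates; drawn uniformly from lab ranges
#'   (18-25 C, 40-70 %RH) when `NULL`. Temperature shifts the drawn f0 by
#'   `temperature_coefficient * (temperature - 20)`.
#' @param id Recording identifier.
#' @return List with `recording` (a [wb_recording()]) and `truth` (one-row
#'   tibble: true f0, onset/offset sample (0-based), duration, realized trend
#'   range, covariates).
#' @export
simulate_recording <- function(template, sample_rate = 10000, bit_depth = 16,
                               total_length = 0.6, temperature = NULL,
                               humidity = NULL, id = template$name) {
  stopifnot(inherits(template, "wb_template"))
  n_total <- round(total_length * sample_rate)
  temperature <- temperature %||% stats::runif(1, 18, 25)
  humidity <- humidity %||% stats::runif(1, 40, 70)

  dur_s <- stats::rnorm(1, template$flight_duration_mean, template$flight_duration_sd)
  dur_s <- min(max(dur_s, 0.02), total_length - 0.02)
  n_flight <- round(dur_s * sample_rate)
  if (n_flight >= n_total) stop("flight longer than buffer", call. = FALSE)
  onset <- sample.int(n_total - n_flight - round(0.005 * sample_rate), 1) +
    round(0.0025 * sample_rate)

  f0 <- stats::rnorm(
    1,
    template$f0_mean + template$temperature_coefficient * (temperature - 20),
    template$f0_sd
  )
  f0 <- max(f0, 40)

  tau <- (seq_len(n_flight) - 1) / sample_rate
  env <- flight_envelope(n_flight, ramp = round(0.01 * sample_rate))
  tone <- numeric(n_flight)
  for (k in seq_len(template$n_harmonics)) {
    tone <- tone + template$base_amplitude * template$harmonic_decay^(k - 1) *
      sin(2 * pi * k * f0 * tau + stats::runif(1, 0, 2 * pi))
  }
  trend <- template$trend_amplitude / 2 * sin(2 * pi * tau / dur_s) * env
  flight <- trend + env * tone

  x <- stats::rnorm(n_total, 0, template$noise_rms)
  x[onset:(onset + n_flight - 1)] <- x[onset:(onset + n_flight - 1)] + flight
  x <- pmin(pmax(x, -1), 1)
  half_scale <- 0.5 * 2^bit_depth
  x <- pmin(pmax(round(x * half_scale), -half_scale), half_scale - 1) / half_scale

  rec <- wb_recording(x, sample_rate, bit_depth,
    id = id, species = template$name,
    temperature = temperature, humidity = humidity
  )
  truth <- tibble::tibble(
    id = id, species = template$name, f0 = f0,
    onset = onset - 1L, offset = onset + n_flight - 2L,
    duration = n_flight / sample_rate,
    trend_range = if (template$trend_amplitude > 0) max(trend) - min(trend) else 0,
    temperature = temperature, humidity = humidity
  )
  list(recording = rec, truth = truth)
}

#' Simulate a labelled corpus
#'
#' Generates `counts[s]` recordings from each template, optionally writing
#' them as WAV files with a sidecar CSV (id, species, temperature, humidity)
#' and a ground-truth CSV, in the same shape as a real-corpus input
#' directory.
#'
#' @param templates Named list of [species_template()]s (e.g.
#'   [species_presets()]).
#' @param counts Named integer vector of per-species recording counts; names
#'   must match `templates`.
#' @param dir Output directory for WAV + CSV files, or `NULL` to keep the
#'   corpus in memory only.
#' @param seed Integer seed; the corpus is bitwise reproducible given it.
#' @inheritParams simulate_recording
#' @return List with `recordings` (named list of [wb_recording()]s),
#'   `sidecar` (tibble) and `truth` (tibble).
#' @export
simulate_corpus <- function(templates, counts, dir = NULL, seed = 1,
                            sample_rate = 10000, bit_depth = 16,
                            total_length = 0.6) {
  if (length(counts) == 0 || is.null(names(counts)) ||
    !all(names(counts) %in% names(templates))) {
    stop("`counts` must be a named vector matching `templates`", call. = FALSE)
  }
  set.seed(seed)
  recordings <- list()
  truths <- list()
  for (sp in names(counts)) {
    for (i in seq_len(counts[[sp]])) {
      sim <- simulate_recording(templates[[sp]],
        sample_rate = sample_rate,
        bit_depth = bit_depth, total_length = total_length,
        id = sprintf("%s_%04d", sp, i)
      )
      recordings[[sim$recording$id]] <- sim$recording
      truths[[sim$recording$id]] <- sim$truth
    }
  }
  truth <- dplyr::bind_rows(truths)
  sidecar <- truth[, c("id", "species", "temperature", "humidity")]
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (rec in recordings) {
      write_recording(rec, file.path(dir, paste0(rec$id, ".wav")))
    }
    utils::write.csv(sidecar, file.path(dir, "sidecar.csv"), row.names = FALSE)
    utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  }
  list(recordings = recordings, sidecar = sidecar, truth = truth)
}
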