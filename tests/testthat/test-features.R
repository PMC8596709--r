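test_that("amplitude and energy statistics match closed forms", {
  s <- amplitude_energy_stats(c(-1, 1, -1, 1))
  expect_equal(s$max_amplitude, 1)
  expect_equal(s$amplitude_range, 2)
  expect_equal(s$power, 1)
  expect_equal(s$rms, 1)
  expect_equal(s$crest_factor, 1)

  a <- 0.4
  x <- a * sin(2 * pi * (0:9999) / 100) # integer number of cycles
  s2 <- amplitude_energy_stats(x)
  expect_equal(s2$rms, a / sqrt(2), tolerance = 1e-6)
  expect_equal(s2$crest_factor, sqrt(2), tolerance = 1e-6)

  s3 <- amplitude_energy_stats(rep(0.3, 50))
  expect_equal(s3$amplitude_range, 0)
  expect_equal(s3$crest_factor, 1)
})

test_that("entropies obey their closed forms exactly", {
  n <- 1024
  expect_equal(temporal_entropy(rep(1, n)), 1, tolerance = 1e-9)
  expect_equal(temporal_entropy(c(1, rep(0, n - 1))), 0, tolerance = 1e-9)
  expect_equal(
    temporal_entropy(c(rep(1, n / 2), rep(0, n / 2))),
    log(n / 2) / log(n),
    tolerance = 1e-9
  )
  expect_equal(spectral_entropy(c(0, 5, 0, 0)), 0, tolerance = 1e-9)
  expect_equal(spectral_entropy(rep(2.5, 65)), 1, tolerance = 1e-9)
})

test_that("entropies and indices respect their bounds", {
  set.seed(8)
  for (case in 1:20) {
    env <- abs(rnorm(256))
    ht <- temporal_entropy(env)
    expect_gte(ht, 0)
    expect_lte(ht, 1)
  }
  x <- 0.2 * sin(2 * pi * 110 * (0:1999) / 10000) + rnorm(2000, 0, 0.01)
  s <- mean_spectrum(x, 10000)
  hf <- spectral_entropy(s)
  est <- envelope_stats(x)
  both <- spectral_acoustic_entropy(s, est$temporal_entropy)
  expect_lte(both$acoustic_entropy, min(est$temporal_entropy, hf))
  expect_true(all(unlist(bioacoustic_indices(s)) >= 0))
})

test_that("the mean spectrum concentrates a pure tone at its bin", {
  sr <- 10000
  f_bin <- 10 * sr / 128 # exactly bin 10
  x <- sin(2 * pi * f_bin * (0:2047) / sr)
  s <- mean_spectrum(x, sr)
  expect_equal(s$freqs, (0:64) * sr / 128)
  in_bin <- sum(s$mean_mag[10:12]) # bin 10 +/- 1 (1-based offset)
  expect_gt(in_bin / sum(s$mean_mag), 0.8)
})

test_that("zero signals yield zero spectra and missing dependants", {
  s <- mean_spectrum(rep(0, 1000), 10000)
  expect_true(all(s$mean_mag == 0))
  expect_true(all(is.na(s$normalized)))
  ent <- spectral_acoustic_entropy(s, 0.5)
  expect_true(is.na(ent$spectral_entropy))
  hp <- harmonic_peaks(s)
  expect_true(all(is.na(hp$harmonics)))
  expect_true(is.na(hp$dominant))
  expect_equal(envelope_stats(rep(0, 256))$temporal_entropy, NA_real_)
})

test_that("white-noise mean spectra are roughly flat", {
  set.seed(9)
  s <- mean_spectrum(rnorm(10000), 10000)
  expect_lt(stats::sd(s$mean_mag) / mean(s$mean_mag), 0.5)
})

test_that("bioacoustic indices integrate the stated bands", {
  sr <- 10000
  x <- sin(2 * pi * 500 * (0:4095) / sr)
  idx <- bioacoustic_indices(mean_spectrum(x, sr))
  expect_lt(idx$bioacoustic_index_3 / idx$bioacoustic_index_2, 0.05)
  set.seed(10)
  s_any <- mean_spectrum(rnorm(3000), sr)
  i_any <- bioacoustic_indices(s_any)
  expect_gte(i_any$bioacoustic_index_1, i_any$bioacoustic_index_2)
  # flat unit spectrum: index = number of bins in band
  flat <- structure(
    list(freqs = (0:64) * sr / 128, mean_mag = rep(1, 65)),
    class = "wb_spectrum"
  )
  i_flat <- bioacoustic_indices(flat)
  expect_equal(i_flat$bioacoustic_index_1, sum(flat$freqs <= 1000))
  expect_equal(i_flat$bioacoustic_index_3, sum(flat$freqs >= 50 & flat$freqs <= 300))
})

test_that("harmonic peaks rank by height and the dominant excludes < 50 Hz", {
  sr <- 2000 # 15.6 Hz bins: tones resolvable
  tt <- (0:3999) / sr
  x <- sin(2 * pi * 100 * tt) + 0.5 * sin(2 * pi * 200 * tt + 1) +
    0.25 * sin(2 * pi * 300 * tt + 2)
  hp <- harmonic_peaks(mean_spectrum(x, sr))
  bin <- sr / 128
  expect_lt(abs(hp$harmonics[1] - 100), bin)
  expect_lt(abs(hp$harmonics[2] - 200), bin)
  expect_lt(abs(hp$harmonics[3] - 300), bin)
  expect_true(all(is.na(hp$harmonics[4:10])))
  expect_equal(hp$dominant, hp$harmonics[1])

  pure <- harmonic_peaks(mean_spectrum(sin(2 * pi * 120 * (0:1999) / 10000), 10000))
  expect_lt(abs(pure$harmonics[1] - 120), 10000 / 128)
  expect_equal(pure$dominant, pure$harmonics[1])

  # tallest peak below 50 Hz: first harmonic and dominant differ
  low <- 0.8 * sin(2 * pi * 30 * tt) + 0.3 * sin(2 * pi * 110 * tt)
  hp2 <- harmonic_peaks(mean_spectrum(low, sr))
  expect_lt(abs(hp2$harmonics[1] - 30), bin)
  expect_lt(abs(hp2$dominant - 110), bin)
  expect_false(isTRUE(all.equal(hp2$harmonics[1], hp2$dominant)))
})

test_that("the autocorrelation fundamental hits integer-lag closed forms", {
  sr <- 10000
  x100 <- sin(2 * pi * 100 * (0:1999) / sr)
  f <- fundamental_frequency(x100, sr)
  expect_equal(f$acf_peak_lag, 100L)
  expect_equal(f$f0, 100)
  expect_equal(f$period, 0.01)

  x120 <- sin(2 * pi * 120 * (0:1999) / sr)
  f2 <- fundamental_frequency(x120, sr)
  expect_true(f2$acf_peak_lag %in% c(83L, 84L))
  expect_true(abs(f2$f0 - 120) < 1.5)

  set.seed(13)
  fn <- fundamental_frequency(rnorm(8192), sr)
  expect_true(is.na(fn$f0))
  expect_true(is.na(fundamental_frequency(rep(0.2, 500), sr)$f0))
})

test_that("the full feature vector has 52 slots and recovers ground truth", {
  sch <- feature_schema()
  expect_equal(nrow(sch), 52)
  expect_equal(sum(!sch$detrended), 25)
  expect_equal(sum(sch$detrended), 27)
  expect_equal(anyDuplicated(sch$feature), 0)

  tpl <- species_template("truthy", f0_mean = 110, f0_sd = 0, trend_amplitude = 0.3)
  set.seed(14)
  sim <- simulate_recording(tpl, id = "t1")
  fv <- extract_features(sim$recording)
  expect_true(all(sch$feature %in% names(fv)))
  expect_equal(ncol(fv), 52 + 5) # metadata: id, species, temperature, humidity, duration
  expect_lt(abs(exp(fv$fundamental_frequency_g) - 110), 2)

  # determinism: identical input, identical stored values
  fv2 <- extract_features(sim$recording)
  expect_identical(fv, fv2)
})

test_that("stage-4 statistics differ from stage-1 when a trend is present", {
  tpl <- species_template("trendy", f0_mean = 120, trend_amplitude = 0.4)
  set.seed(15)
  sim <- simulate_recording(tpl, id = "t2")
  fv <- extract_features(sim$recording)
  expect_false(isTRUE(all.equal(fv$amplitude_range, fv$amplitude_range_g)))
  expect_false(isTRUE(all.equal(fv$power, fv$power_g)))
  expect_gt(fv$crest_factor, 0) # log crest >= 0 <=> crest >= 1
  expect_gt(fv$crest_factor_g, 0)
})

test_that("too-short recordings are refused by name", {
  rec <- recording_from_indices(101:180, 1000)
  expect_error(extract_features(rec), "too short")
})
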