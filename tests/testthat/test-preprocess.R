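test_that("trimming requires some supra-threshold signal", {
  rec <- wb_recording(runif(1000, -0.006, 0.006), 10000, id = "bg")
  expect_error(trim_silence(rec), "NoSignal")
})

test_that("contiguous supra-threshold spans trim to their ends", {
  # supra-threshold samples exactly at 0-based indices 100..400
  rec <- recording_from_indices(101:401, 1000)
  tr <- trim_silence(rec)
  expect_equal(tr$start_index, 100L)
  expect_equal(tr$end_index, 400L)
  expect_equal(tr$duration, 301 / 10000)
  expect_false(tr$too_short)
})

test_that("temporal outliers beyond the IQR fence are discarded", {
  # indices {100..400} + {999} (0-based): q1 = 175.25, q3 = 325.75,
  # upper fence 777.25 < 999, so the stray sample is stochastic noise
  rec <- recording_from_indices(c(101:401, 1000), 1000)
  tr <- trim_silence(rec)
  expect_equal(tr$start_index, 100L)
  expect_equal(tr$end_index, 400L)
})

test_that("trim agrees exactly with the brute-force fence oracle", {
  set.seed(11)
  for (case in 1:1000) {
    n <- sample(500:4000, 1)
    # random supra-threshold index set: a contiguous block plus strays
    block_start <- sample(1:(n - 200), 1)
    block <- block_start:(block_start + sample(50:199, 1))
    strays <- sample(setdiff(1:n, block), sample(0:5, 1))
    idx <- sort(unique(c(block, strays)))
    bounds <- oracle_trim_bounds(idx)
    tr <- trim_silence(recording_from_indices(idx, n))
    expect_identical(tr$start_index + 1L, as.integer(bounds[1]))
    expect_identical(tr$end_index + 1L, as.integer(bounds[2]))
  }
})

test_that("trimming is idempotent and bounds lie on retained samples", {
  set.seed(12)
  for (case in 1:25) {
    n <- sample(1000:5000, 1)
    idx <- sort(sample(1:n, sample(100:500, 1)))
    rec <- recording_from_indices(idx, n)
    tr1 <- trim_silence(rec)
    # bounds are supra-threshold
    expect_gt(abs(tr1$samples[1]), 0.0061)
    expect_gt(abs(tr1$samples[length(tr1$samples)]), 0.0061)
    rec2 <- wb_recording(tr1$samples, rec$sample_rate, id = "re")
    tr2 <- trim_silence(rec2)
    expect_equal(tr2$start_index, 0L)
    expect_equal(tr2$end_index, length(tr1$samples) - 1L)
  }
})

test_that("the minimum-length filter cuts exactly at 128 samples", {
  short <- trim_silence(recording_from_indices(101:227, 1000)) # 127 samples
  long <- trim_silence(recording_from_indices(101:228, 1000)) # 128 samples
  expect_true(short$too_short)
  expect_false(long$too_short)
  expect_null(min_length_filter(short))
  expect_identical(min_length_filter(long), long)
})

test_that("corpus trimming reports removals and retentions", {
  recs <- c(
    lapply(1:7, function(i) recording_from_indices(101:500, 1000, sr = 10000)),
    lapply(1:3, function(i) recording_from_indices(101:180, 1000, sr = 10000))
  )
  for (i in seq_along(recs)) recs[[i]]$id <- paste0("r", i)
  report <- trim_corpus(recs)
  expect_equal(nrow(report), 10)
  expect_equal(sum(report$retained), 7)
  expect_equal(sum(report$reason == "too_short"), 3)
  expect_length(attr(report, "trimmed"), 7)
})

test_that("background filter preserves a clean tone and removes noise", {
  sr <- 10000
  tt <- (0:2047) / sr
  # noise-free tone: overlap-add reconstruction is near-exact
  tone <- 0.3 * sin(2 * pi * 100 * tt)
  tr <- trim_silence(wb_recording(c(rep(0, 150), tone, rep(0, 150)), sr, id = "t"))
  out <- background_filter(tr)
  expect_equal(length(out$samples), length(tr$samples))
  rel_err <- sqrt(mean((out$samples - tr$samples)^2)) / sqrt(mean(tr$samples^2))
  expect_lt(rel_err, 0.05)

  # tone + white noise 30 dB down: out-of-band energy drops, tone survives
  set.seed(3)
  noisy <- tone + rnorm(length(tone), 0, 0.3 * 10^(-30 / 20))
  tr2 <- trim_silence(wb_recording(c(rep(0, 150), noisy, rep(0, 150)), sr, id = "n"))
  out2 <- background_filter(tr2)
  band_power <- function(x, lo, hi) {
    f <- abs(stats::fft(x))^2
    freqs <- (seq_along(f) - 1) * sr / length(x)
    sum(f[freqs >= lo & freqs <= hi])
  }
  tone_before <- band_power(tr2$samples, 60, 140)
  tone_after <- band_power(out2$samples, 60, 140)
  noise_before <- band_power(tr2$samples, 500, 4000)
  noise_after <- band_power(out2$samples, 500, 4000)
  expect_gt(tone_after / tone_before, 0.9)
  expect_lt(noise_after, noise_before)
})

test_that("background filter handles degenerate inputs", {
  tr <- trim_silence(recording_from_indices(101:400, 1000))
  tr$samples <- rep(0, length(tr$samples))
  out <- background_filter(tr)
  expect_true(all(out$samples == 0))

  short <- trim_silence(recording_from_indices(101:150, 1000))
  expect_warning(out2 <- background_filter(short), "skipped")
  expect_identical(out2$samples, short$samples)
})

test_that("filtering never increases total signal power", {
  set.seed(21)
  for (case in 1:10) {
    x <- 0.2 * sin(2 * pi * runif(1, 80, 200) * (0:1999) / 10000) +
      rnorm(2000, 0, 0.02)
    tr <- trim_silence(wb_recording(pmin(pmax(c(rep(0, 150), x, rep(0, 150)), -1), 1), 10000, id = "p"))
    out <- background_filter(tr)
    expect_lte(sum(out$samples^2), sum(tr$samples^2) * (1 + 1e-9))
  }
})
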