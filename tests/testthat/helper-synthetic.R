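# Helpers building small synthetic inputs in code. Audio helpers construct
# wb_recording objects directly; feature-table helpers emit Gaussian feature
# tibbles keyed by schema names so classifier machinery can be exercised
# without the (slower) audio pipeline.

# a tone burst with silent margins: margins + optional noise stay sub-threshold
tone_recording <- function(f0, sr = 10000, amp = 0.3, dur = 0.2, margin = 0.05,
                           noise = 0, harmonics = 1, decay = 0.5,
                           id = "tone", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_m <- round(margin * sr)
  tt <- (0:(round(dur * sr) - 1)) / sr
  tone <- 0
  for (k in seq_len(harmonics)) tone <- tone + amp * decay^(k - 1) * sin(2 * pi * k * f0 * tt)
  x <- c(rep(0, n_m), tone, rep(0, n_m))
  if (noise > 0) x <- x + rnorm(length(x), 0, noise)
  wb_recording(pmin(pmax(x, -1), 1), sr, id = id)
}

# Gaussian feature table: k classes shifted by `shift` SDs on `n_informative`
# schema features, plus uninformative ones
gaussian_features <- function(n_per_class, classes = c("A", "B"), shift = 3,
                              n_informative = 3, n_noise = 5, seed = 1) {
  set.seed(seed)
  keys <- feature_schema()$feature
  inf_keys <- keys[seq_len(n_informative)]
  noise_keys <- keys[n_informative + seq_len(n_noise)]
  rows <- lapply(seq_along(classes), function(ci) {
    n <- if (length(n_per_class) > 1) n_per_class[ci] else n_per_class
    d <- tibble::tibble(
      id = sprintf("%s_%03d", classes[ci], seq_len(n)),
      species = classes[ci],
      temperature = runif(n, 18, 25),
      humidity = runif(n, 40, 70),
      duration = runif(n, 0.05, 0.3)
    )
    for (k in inf_keys) d[[k]] <- rnorm(n, mean = shift * (ci - 1), sd = 1)
    for (k in noise_keys) d[[k]] <- rnorm(n)
    d
  })
  dplyr::bind_rows(rows)
}

# independently coded type-7 quantile (linear interpolation between order
# statistics), used as the brute-force oracle for the trim fence rule
oracle_quantile7 <- function(v, p) {
  v <- sort(v)
  h <- (length(v) - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  v[lo] + (h - lo) * (v[hi] - v[lo])
}

oracle_trim_bounds <- function(supra_idx, mult = 3) {
  q1 <- oracle_quantile7(supra_idx, 0.25)
  q3 <- oracle_quantile7(supra_idx, 0.75)
  iqr <- q3 - q1
  keep <- supra_idx[supra_idx >= q1 - mult * iqr & supra_idx <= q3 + mult * iqr]
  c(min(keep), max(keep))
}

# recording whose supra-threshold samples sit exactly at `idx` (1-based)
recording_from_indices <- function(idx, n, sr = 10000) {
  x <- rep(0, n)
  x[idx] <- 0.5
  wb_recording(x, sr, id = "idx")
}
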