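#' Fit and remove the long-term flight-movement trend
#'
#' Most recordings carry a slow trend — typically a single peak and trough —
#' attributed to whole-body flight movement (e.g. banking) rather than to the
#' wingbeat itself. The trend is estimated by a generalized additive model:
#' a penalized thin-plate regression spline of amplitude on time, with basis
#' dimension `k = max(k_min, floor(n / k_divisor))` and smoothness chosen by
#' generalized cross-validation. The wingbeat oscillation (>= 90 Hz) is far
#' above the spline's resolvable frequency at this basis dimension, so the
#' trend cannot absorb it.
#'
#' The basis dimension is additionally capped so the smooth cannot oscillate
#' faster than `max_trend_frequency` (a thin-plate basis of dimension `k`
#' over a signal of duration `d` seconds can track roughly `k / 2` cycles,
#' i.e. `k / (2 d)` Hz): flight-movement trends occupy a few hertz, while
#' anything above the 50 Hz body-oscillation band belongs to the wingbeat
#' and must survive detrending. Without the cap, a generalized
#' cross-validated smooth will happily absorb a strong wingbeat tone
#' whenever the basis can represent it.
#'
#' @param t A `wb_trimmed` object (length >= 128 recommended).
#' @param k_divisor Basis dimension is 1/`k_divisor` of the trimmed length.
#' @param k_min Minimum basis dimension.
#' @param max_trend_frequency Fastest oscillation (Hz) the trend is allowed
#'   to represent.
#' @return An object of class `wb_trend`: `g` (fitted trend per sample, AAU),
#'   `residuals` (detrended amplitude, so `g + residuals` reconstructs the
#'   input exactly), `basis_dim`, `gam_amplitude_range` (`max g - min g`) and
#'   `ok` (`FALSE` when the smoother failed; downstream detrended features
#'   then become missing).
#' @export
fit_trend <- function(t, k_divisor = 50, k_min = 10, max_trend_frequency = 50) {
  stopifnot(inherits(t, "wb_trimmed"))
  x <- t$samples
  n <- length(x)
  k_cap <- floor(2 * max_trend_frequency * n / t$sample_rate)
  k <- max(k_min, min(floor(n / k_divisor), k_cap))
  k <- min(k, n - 1) # degenerate tiny inputs
  # sample index rescaled to [0, 1]: pure conditioning, g(t) is unchanged
  tt <- seq(0, 1, length.out = n)
  fit <- tryCatch(
    mgcv::gam(x ~ s(tt, bs = "tp", k = k), method = "GCV.Cp"),
    error = function(e) NULL,
    warning = function(w) {
      suppressWarnings(mgcv::gam(x ~ s(tt, bs = "tp", k = k), method = "GCV.Cp"))
    }
  )
  if (is.null(fit)) {
    return(structure(
      list(
        g = rep(NA_real_, n), residuals = rep(NA_real_, n),
        basis_dim = k, gam_amplitude_range = NA_real_, ok = FALSE,
        sample_rate = t$sample_rate, parent_id = t$parent_id
      ),
      class = "wb_trend"
    ))
  }
  g <- as.numeric(stats::fitted(fit))
  structure(
    list(
      g = g, residuals = x - g, basis_dim = k,
      gam_amplitude_range = max(g) - min(g), ok = TRUE,
      sample_rate = t$sample_rate, parent_id = t$parent_id
    ),
    class = "wb_trend"
  )
}

#' @export
print.wb_trend <- function(x, ...) {
  cat(sprintf(
    "<wb_trend %s> k = %d, trend range = %.4g AAU%s\n",
    x$parent_id, x$basis_dim, x$gam_amplitude_range,
    if (!x$ok) " [smoother failed]" else ""
  ))
  invisible(x)
}

#' Plot a fitted flight trend over the signal
#'
#' @param object A `wb_trend` object.
#' @param ... Unused.
#' @return A ggplot: amplitude and fitted trend against time.
#' @export
autoplot.wb_trend <- function(object, ...) {
  n <- length(object$g)
  df <- tibble::tibble(
    time = (seq_len(n) - 1) / object$sample_rate,
    amplitude = object$g + object$residuals,
    trend = object$g
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$amplitude), colour = "grey60", linewidth = 0.2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$trend), colour = "#d1495b", linewidth = 0.7) +
    ggplot2::labs(x = "Time (s)", y = "Amplitude (AAU)", title = object$parent_id)
}
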