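#' Locally weighted regression smoothing with a point-count span
#'
#' Loess smoothing parameterised by the number of nearest points `q` in
#' each local neighbourhood rather than a span fraction: at every point,
#' a weighted least-squares polynomial of the `q` nearest neighbours is
#' fitted with tricube weights on distance scaled by the neighbourhood
#' radius, and evaluated at the point. No robustness iterations are
#' applied. Boundary windows shrink asymmetrically, as is standard for
#' local regression.
#'
#' @param y Numeric series.
#' @param q Number of points in each smoothing window (>= degree + 2).
#' @param degree Local polynomial degree, 1 or 2.
#' @param x Abscissa; defaults to the observation index.
#' @return The smoothed series.
#' @export
loess_smooth <- function(y, q, degree = 1L, x = seq_along(y)) {
  n <- length(y)
  stopifnot(length(x) == n, degree %in% c(1L, 2L))
  if (q < degree + 2) stop("q must be at least degree + 2")
  if (q > n) stop("q cannot exceed the series length")
  fit <- stats::loess(
    y ~ x, data = data.frame(x = as.numeric(x), y = as.numeric(y)),
    span = q / n, degree = degree, family = "gaussian",
    surface = "direct"
  )
  as.numeric(stats::fitted(fit))
}

#' Additive trend-seasonal-remainder decomposition
#'
#' Splits a monthly carcass-rate series as `Y_t = T_t + S_t + E_t`: the
#' long-term trend `T` is a first-order loess over `trend_q` monthly
#' points; the seasonal component `S` is a second-order loess of the
#' residuals `Y - T` over `seasonal_q` points; the remainder `E = Y - T -
#' S` is defined by subtraction, so additivity is exact by construction.
#' The defaults (24-point linear trend, 6-point quadratic seasonal) follow
#' the smoothing windows used for 13 years of monthly market data. As an
#' alternative, `seasonal_method = "cycle"` smooths each calendar-month
#' subseries separately (the STL-style convention) instead of the
#' consecutive residual series.
#'
#' @param series A [monthly_series()] (gap-free) or numeric vector.
#' @param trend_q,trend_degree Trend smoother window and degree.
#' @param seasonal_q,seasonal_degree Seasonal smoother window and degree.
#' @param seasonal_method `"consecutive"` (default) or `"cycle"`.
#' @param period Season length, used by the `"cycle"` method.
#' @return A `rate_decomposition` tibble: month, y, trend, seasonal,
#'   remainder.
#' @examples
#' y <- 0.05 * (1:60) + sin(2 * pi * (1:60) / 12)
#' d <- decompose_rates(monthly_series(month_seq("1997-10", 60), y))
#' max(abs(d$y - d$trend - d$seasonal - d$remainder))
#' @export
decompose_rates <- function(series, trend_q = 24L, trend_degree = 1L,
                            seasonal_q = 6L, seasonal_degree = 2L,
                            seasonal_method = c("consecutive", "cycle"),
                            period = 12L) {
  seasonal_method <- match.arg(seasonal_method)
  if (is.numeric(series)) {
    series <- monthly_series(month_seq(study_origin(), length(series)),
                             series)
  }
  y <- series$value
  if (anyNA(y)) stop("series has gaps; impute before decomposing")
  if (length(y) < trend_q) {
    stop("series shorter than the trend window (", trend_q, " months)")
  }
  trend <- loess_smooth(y, q = trend_q, degree = trend_degree)
  resid <- y - trend
  seasonal <- switch(
    seasonal_method,
    consecutive = loess_smooth(resid, q = min(seasonal_q, length(y)),
                               degree = seasonal_degree),
    cycle = {
      s <- numeric(length(y))
      cyc <- (seq_along(y) - 1L) %% period + 1L
      for (k in seq_len(period)) {
        i <- which(cyc == k)
        qk <- min(seasonal_q, length(i))
        s[i] <- if (qk >= seasonal_degree + 2) {
          loess_smooth(resid[i], q = qk, degree = seasonal_degree,
                       x = seq_along(i))
        } else mean(resid[i])
      }
      s
    }
  )
  out <- tibble::tibble(
    month = series$month, y = y, trend = trend, seasonal = seasonal,
    remainder = y - trend - seasonal
  )
  class(out) <- c("rate_decomposition", class(out))
  out
}

#' Deseasonalized and denoised series
#'
#' `deseasonalize()` returns the trend plus remainder (`T + E`), the input
#' for period trend regressions where seasonal swings would obscure
#' long-term change. `denoise()` returns the trend plus seasonal
#' (`T + S`), the input for income-proxy regressions where month-to-month
#' error variation is unwanted.
#'
#' @param decomposition A [decompose_rates()] result.
#' @return A [monthly_series()].
#' @export
deseasonalize <- function(decomposition) {
  stopifnot(inherits(decomposition, "rate_decomposition"))
  monthly_series(decomposition$month,
                 decomposition$trend + decomposition$remainder)
}

#' @rdname deseasonalize
#' @export
denoise <- function(decomposition) {
  stopifnot(inherits(decomposition, "rate_decomposition"))
  monthly_series(decomposition$month,
                 decomposition$trend + decomposition$seasonal)
}
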