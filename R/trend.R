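#' Per-period trend fit with midpoint slope
#'
#' Quadratic least-squares regression of deseasonalized carcass rates on
#' serially numbered months, reduced to a straight line whenever the
#' quadratic term does not significantly improve the fit (partial F-test
#' at `alpha`). The summary quantity is the average change in carcass rate
#' per month: for a linear fit, the slope `b1` with its standard
#' confidence interval; for a retained quadratic, the slope at the period
#' midpoint `t_m`, `b1 + 2 b2 t_m`, with variance `Var(b1) + 4 t_m^2
#' Var(b2) + 4 t_m Cov(b1, b2)` and a t-based 95% interval from linear
#' model theory.
#'
#' @param value Deseasonalized rates for one period.
#' @param t Month indices (serially numbered over the whole study, not
#'   restarted per period).
#' @param alpha Level for the quadratic-vs-linear partial F-test.
#' @param label Optional period label.
#' @return An object of class `trend_fit`: model type, coefficients and
#'   covariance, `midpoint_slope`, `slope_se`, `ci95_halfwidth`, `n`.
#' @export
fit_period_trend <- function(value, t, alpha = 0.05, label = NULL) {
  stopifnot(length(value) == length(t))
  n <- length(value)
  if (n < 6) stop("need at least 6 months in a period")
  df <- data.frame(y = as.numeric(value), t = as.numeric(t))
  lin <- stats::lm(y ~ t, data = df)
  quad <- stats::lm(y ~ t + I(t^2), data = df)
  # exact polynomial inputs trip R's "essentially perfect fit" notice;
  # such inputs are legitimate here (noise-free checks)
  ftest <- muffle_perfect_fit(stats::anova(lin, quad))
  p_quad <- ftest$`Pr(>F)`[2]
  use_quad <- is.finite(p_quad) && p_quad < alpha
  t_m <- (min(df$t) + max(df$t)) / 2
  if (use_quad) {
    b <- stats::coef(quad)
    V <- muffle_perfect_fit(stats::vcov(quad))
    slope <- unname(b[2] + 2 * b[3] * t_m)
    slope_var <- V[2, 2] + 4 * t_m^2 * V[3, 3] + 4 * t_m * V[2, 3]
    df_resid <- n - 3L
    model <- quad
  } else {
    b <- stats::coef(lin)
    V <- muffle_perfect_fit(stats::vcov(lin))
    slope <- unname(b[2])
    slope_var <- V[2, 2]
    df_resid <- n - 2L
    model <- lin
  }
  slope_se <- sqrt(slope_var)
  structure(
    list(label = label, model = if (use_quad) "quadratic" else "linear",
         coefficients = b, vcov = V,
         midpoint = t_m, midpoint_slope = slope, slope_se = slope_se,
         ci95_halfwidth = stats::qt(0.975, df_resid) * slope_se,
         df_resid = df_resid, n = n, p_quadratic = p_quad, fit = model),
    class = "trend_fit"
  )
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf(
    "%s trend (%s, n = %d): slope %.4f +/- %.4f (95%% CI half-width)\n",
    x$model, x$label %||% "period", x$n, x$midpoint_slope,
    x$ci95_halfwidth))
  invisible(x)
}

#' Fit trends for every period of a labelled series
#'
#' @param series A period-labelled series ([assign_periods()]) of
#'   deseasonalized rates.
#' @param alpha Partial F-test level.
#' @param origin Origin for serial month numbering.
#' @return A named list of [fit_period_trend()] results, one per period.
#' @export
fit_period_trends <- function(series, alpha = 0.05,
                              origin = study_origin()) {
  stopifnot("period" %in% names(series))
  t_all <- month_index(series$month, origin)
  out <- lapply(levels(series$period), function(lab) {
    i <- series$period == lab
    fit_period_trend(series$value[i], t_all[i], alpha = alpha, label = lab)
  })
  names(out) <- levels(series$period)
  out
}

#' Normalize a trend slope for cross-taxon comparison
#'
#' Raw slopes scale with a taxon's share of the market, so taxa of very
#' different abundance cannot be compared directly. Two normalizations are
#' supported: dividing the slope by the ratio of the standard deviations
#' of the taxon and total series (`"sd_ratio"`, slightly more conservative
#' for uncommon taxa), or by the taxon's fraction of the total market rate
#' (`"fraction"`, the ratio of series means).
#'
#' @param slope Raw slope (carcasses per market day per month).
#' @param taxon_series,total_series Full-length rate series (numeric or
#'   [monthly_series()]).
#' @param method `"sd_ratio"` or `"fraction"`.
#' @return The normalized slope.
#' @export
normalize_slope <- function(slope, taxon_series, total_series,
                            method = c("sd_ratio", "fraction")) {
  method <- match.arg(method)
  tx <- if (is.data.frame(taxon_series)) taxon_series$value
        else as.numeric(taxon_series)
  tot <- if (is.data.frame(total_series)) total_series$value
         else as.numeric(total_series)
  stopifnot(length(tx) == length(tot))
  if (method == "sd_ratio") {
    s_tx <- stats::sd(tx)
    s_tot <- stats::sd(tot)
    if (s_tx == 0 || s_tot == 0) stop("constant series: SD ratio undefined")
    slope / (s_tx / s_tot)
  } else {
    m_tx <- mean(tx)
    m_tot <- mean(tot)
    if (m_tx == 0 || m_tot == 0) stop("zero-mean series: fraction undefined")
    slope / (m_tx / m_tot)
  }
}

#' Pairwise comparison of period slopes
#'
#' Flags pairs of periods whose midpoint slopes differ: a Welch-type
#' z-test on the slope difference (the operational definition of
#' "significantly different") alongside the more conservative
#' non-overlap of the 95% confidence intervals.
#'
#' @param fits List of [fit_period_trend()] results (>= 2).
#' @param alpha Level for the z-test.
#' @return A tibble with one row per period pair.
#' @export
compare_slopes <- function(fits, alpha = 0.05) {
  stopifnot(length(fits) >= 2)
  labs <- vapply(seq_along(fits), function(i) {
    fits[[i]]$label %||% names(fits)[i] %||% paste0("period", i)
  }, character(1))
  pairs <- utils::combn(seq_along(fits), 2)
  rows <- apply(pairs, 2, function(ij) {
    a <- fits[[ij[1]]]
    b <- fits[[ij[2]]]
    d <- a$midpoint_slope - b$midpoint_slope
    se <- sqrt(a$slope_se^2 + b$slope_se^2)
    z <- if (se == 0) 0 else d / se
    tibble::tibble(
      period_a = labs[ij[1]], period_b = labs[ij[2]],
      slope_a = a$midpoint_slope, slope_b = b$midpoint_slope,
      difference = d, z = z,
      p_value = 2 * stats::pnorm(-abs(z)),
      ci_overlap = abs(d) <= a$ci95_halfwidth + b$ci95_halfwidth,
      significant = 2 * stats::pnorm(-abs(z)) < alpha
    )
  })
  dplyr::bind_rows(rows)
}
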