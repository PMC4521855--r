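#' Heteroscedastic two-factor GLS ANOVA
#'
#' Two-factor analysis of variance of log-transformed monthly carcass
#' rates on capture method and market period, allowing a different
#' residual variance for each factor-level combination. Estimation is
#' iterative feasible generalized least squares: residual variances are
#' estimated per variance stratum, observations reweighted by their
#' inverses, the model refitted, and the cycle repeated until the
#' coefficients change by less than `tol` (relative). Main effects and the
#' interaction are tested with Wald F statistics on sum-to-zero contrast
#' blocks, with denominator degrees of freedom `N - p`.
#'
#' Zero rates are handled before the log by an offset equal to half the
#' smallest positive observed rate (no offset when all rates are
#' positive); monthly market rates are rarely exactly zero, and the census
#' protocol gives no guidance, so the offset is the documented convention.
#'
#' @param data Data frame with columns `rate`, `method`, `period` (or pass
#'   the column names via `rate`, `method`, `period`).
#' @param rate,method,period Column names in `data`.
#' @param variance `"cell"` (default): one variance per method x period
#'   cell; `"factor"`: multiplicative variance factors per level of each
#'   factor (2 + 3 multipliers instead of 6).
#' @param log_transform Log-transform the response (default `TRUE`).
#' @param offset Log offset; `NULL` chooses the documented convention.
#' @param tol,max_iter FGLS convergence controls.
#' @return An object of class `gls_anova`: `anova_table` (term, df1, df2,
#'   statistic, p_value), `variances` per stratum, `mse` (weighted
#'   residual mean square), `coefficients`, `iterations`.
#' @export
gls_anova <- function(data, rate = "rate", method = "method",
                      period = "period", variance = c("cell", "factor"),
                      log_transform = TRUE, offset = NULL, tol = 1e-6,
                      max_iter = 100L) {
  variance <- match.arg(variance)
  y <- data[[rate]]
  f_m <- factor(data[[method]])
  f_p <- factor(data[[period]])
  if (nlevels(f_m) < 2 || nlevels(f_p) < 2) {
    stop("need at least two levels of each factor")
  }
  cell <- interaction(f_m, f_p, drop = FALSE)
  if (any(table(cell) < 3)) {
    stop("every method x period cell needs at least 3 observations")
  }
  if (log_transform) {
    if (is.null(offset)) {
      offset <- if (any(y == 0)) min(y[y > 0]) / 2 else 0
    }
    if (any(y + offset <= 0)) stop("rates must be positive after offset")
    y <- log(y + offset)
  }
  X <- stats::model.matrix(
    ~ f_m * f_p,
    contrasts.arg = list(f_m = "contr.sum", f_p = "contr.sum")
  )
  assign <- attr(X, "assign")
  n <- length(y)
  p <- ncol(X)
  w <- rep(1, n)
  beta_old <- rep(Inf, p)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    fit <- stats::lm.wfit(X, y, w)
    beta <- fit$coefficients
    e <- y - drop(X %*% beta)
    if (max(abs(beta - beta_old)) <=
        tol * max(1, max(abs(beta))) || iter >= max_iter) break
    beta_old <- beta
    if (variance == "cell") {
      s2 <- tapply(e^2, cell, mean)
      w <- 1 / s2[cell]
    } else {
      # multiplicative per-level factors sigma2_ij = a_i * b_j
      a <- tapply(e^2, f_m, mean)
      a <- a / exp(mean(log(a)))
      b <- tapply(e^2 / a[f_m], f_p, mean)
      w <- 1 / (a[f_m] * b[f_p])
    }
    w <- as.numeric(w)
  }
  if (iter >= max_iter) {
    stop("FGLS did not converge within ", max_iter, " iterations")
  }
  mse <- sum(w * e^2) / (n - p)
  XtWX_inv <- solve(crossprod(X * sqrt(w)))
  V <- mse * XtWX_inv
  terms <- c("method", "period", "method:period")
  tab <- lapply(seq_along(terms), function(k) {
    idx <- which(assign == k)
    bk <- beta[idx]
    Fk <- drop(t(bk) %*% solve(V[idx, idx, drop = FALSE]) %*% bk) /
      length(idx)
    tibble::tibble(
      term = terms[k], df1 = length(idx), df2 = n - p, statistic = Fk,
      p_value = stats::pf(Fk, length(idx), n - p, lower.tail = FALSE)
    )
  })
  variances <- if (variance == "cell") {
    tibble::tibble(stratum = names(tapply(e^2, cell, mean)),
                   variance = as.numeric(tapply(e^2, cell, mean)))
  } else {
    tibble::tibble(
      stratum = c(levels(f_m), levels(f_p)),
      variance = c(as.numeric(tapply(e^2, f_m, mean)),
                   as.numeric(tapply(e^2, f_p, mean)))
    )
  }
  structure(
    list(anova_table = dplyr::bind_rows(tab), variances = variances,
         mse = mse, coefficients = beta, vcov = V, weights = w,
         iterations = iter, offset = if (log_transform) offset else NULL),
    class = "gls_anova"
  )
}

#' @export
print.gls_anova <- function(x, ...) {
  cat("Heteroscedastic two-factor GLS ANOVA\n")
  print(as.data.frame(x$anova_table), row.names = FALSE)
  cat(sprintf("weighted MSE %.4f, %d FGLS iterations\n", x$mse,
              x$iterations))
  invisible(x)
}

#' Bootstrap confidence interval for a Pearson correlation
#'
#' Pearson correlation of two paired monthly series with a confidence
#' interval from paired nonparametric resampling: months are resampled
#' with replacement, the correlation recomputed for each resample, and the
#' interval taken from the percentiles (default) or with
#' bias-corrected-accelerated (BCa) adjustment.
#'
#' @param x,y Paired numeric series (equal length >= 10).
#' @param n_boot Number of bootstrap resamples.
#' @param seed Integer seed; output is deterministic given the seed.
#' @param level Confidence level.
#' @param method `"percentile"` (default) or `"bca"`.
#' @return A list with `r`, `lower`, `upper`, `level`, `n_boot`.
#' @export
bootstrap_correlation <- function(x, y, n_boot = 10000L, seed = 1L,
                                  level = 0.95,
                                  method = c("percentile", "bca")) {
  method <- match.arg(method)
  x <- if (is.data.frame(x)) x$value else as.numeric(x)
  y <- if (is.data.frame(y)) y$value else as.numeric(y)
  n <- length(x)
  stopifnot(length(y) == n, n >= 10)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: correlation undefined")
  }
  r <- stats::cor(x, y)
  set.seed(seed)
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
  xs <- matrix(x[idx], nrow = n)
  ys <- matrix(y[idx], nrow = n)
  sx <- colSums(xs); sy <- colSums(ys)
  sxx <- colSums(xs^2); syy <- colSums(ys^2); sxy <- colSums(xs * ys)
  denom <- sqrt(pmax(n * sxx - sx^2, 0) * pmax(n * syy - sy^2, 0))
  r_boot <- ifelse(denom > 0, (n * sxy - sx * sy) / denom, NA_real_)
  alpha <- (1 - level) / 2
  if (method == "percentile") {
    qs <- stats::quantile(r_boot, c(alpha, 1 - alpha), na.rm = TRUE,
                          names = FALSE)
  } else {
    z0 <- stats::qnorm(mean(r_boot < r, na.rm = TRUE))
    jack <- vapply(seq_len(n), function(i) stats::cor(x[-i], y[-i]),
                   numeric(1))
    jm <- mean(jack)
    acc <- sum((jm - jack)^3) / (6 * sum((jm - jack)^2)^1.5)
    adj <- function(a) {
      stats::pnorm(z0 + (z0 + stats::qnorm(a)) /
                     (1 - acc * (z0 + stats::qnorm(a))))
    }
    qs <- stats::quantile(r_boot, c(adj(alpha), adj(1 - alpha)),
                          na.rm = TRUE, names = FALSE)
  }
  list(r = r, lower = qs[1], upper = qs[2], level = level,
       n_boot = n_boot, method = method)
}

#' Income-proxy regressions by stratum and period
#'
#' Ordinary least-squares regression of denoised monthly carcass rates on
#' a monthly income proxy (an oil spot price where income statistics are
#' unavailable), fitted separately for each stratum within each market
#' period and for all periods pooled (`"All"`). Reports intercept, slope,
#' R-squared and the two-sided p-value for the slope, with a significance
#' star at p < 0.05.
#'
#' @param rates Long tibble with columns `month`, `stratum`, `value`
#'   (denoised rates).
#' @param covariate Tibble with columns `month` and `value` (the proxy),
#'   covering every month of `rates`.
#' @param partition A [period_partition()].
#' @return A tibble: stratum, period, intercept, slope, r_squared,
#'   p_value, significant.
#' @export
proxy_regression <- function(rates, covariate,
                             partition = period_partition()) {
  stopifnot(all(c("month", "stratum", "value") %in% names(rates)),
            all(c("month", "value") %in% names(covariate)))
  rates$month <- as_month(rates$month)
  covariate$month <- as_month(covariate$month)
  miss <- setdiff(unique(rates$month), covariate$month)
  if (length(miss)) {
    stop("covariate missing for month(s): ",
         paste(format(as.Date(miss, origin = "1970-01-01"), "%Y-%m"),
               collapse = ", "))
  }
  rates$proxy <- covariate$value[match(rates$month, covariate$month)]
  idx <- findInterval(as.numeric(rates$month),
                      as.numeric(partition$breakpoints)) + 1L
  rates$period <- factor(partition$labels[idx], levels = partition$labels)
  one <- function(df, stratum, label) {
    fit <- stats::lm(value ~ proxy, data = df)
    s <- muffle_perfect_fit(summary(fit))
    if (stats::var(df$value) == 0) {
      # constant response: no explainable variation, slope indistinguishable
      # from zero by convention
      r2 <- 0
      p <- 1
    } else {
      r2 <- s$r.squared
      p <- s$coefficients["proxy", "Pr(>|t|)"]
    }
    tibble::tibble(
      stratum = stratum, period = label,
      intercept = unname(stats::coef(fit)[1]),
      slope = unname(stats::coef(fit)[2]),
      r_squared = r2, p_value = p, significant = p < 0.05
    )
  }
  out <- list()
  for (st in unique(rates$stratum)) {
    sub <- rates[rates$stratum == st, ]
    for (lab in c(levels(sub$period), "All")) {
      df <- if (lab == "All") sub else sub[sub$period == lab, ]
      if (nrow(df) >= 3) {
        out[[length(out) + 1L]] <- one(df, st, lab)
      }
    }
  }
  dplyr::bind_rows(out)
}
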