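# Independent oracles used across the suite. Each is a deliberately naive,
# direct implementation of the defining formula, kept separate from the
# package's computational path.

# Per-point tricube weighted polynomial regression (textbook loess).
brute_loess <- function(x, y, q, degree) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    d <- abs(x - x[i])
    dq <- sort(d)[q]
    w <- ifelse(d < dq, (1 - (d / dq)^3)^3, 0)
    X <- outer(x - x[i], 0:degree, `^`)
    fit <- stats::lm.wfit(X, y, w)
    fit$coefficients[1]
  }, numeric(1))
}

# Theoretical autocorrelations of a stationary AR(p) by solving the
# Yule-Walker linear system for rho_1..rho_p, then extending by recursion.
yule_walker_acf <- function(ar, max_lag) {
  p <- length(ar)
  # system rho_k = sum_j ar_j * rho_{|k-j|} with rho_0 = 1, k = 1..p
  A <- matrix(0, p, p)
  b <- numeric(p)
  for (k in seq_len(p)) {
    for (j in seq_len(p)) {
      lag <- abs(k - j)
      if (lag == 0) {
        b[k] <- b[k] - ar[j]
      } else {
        A[k, lag] <- A[k, lag] + ar[j]
      }
    }
    A[k, k] <- A[k, k] - 1
  }
  rho <- solve(A, b)
  if (max_lag <= p) return(rho[seq_len(max_lag)])
  rho <- c(rho, numeric(max_lag - p))
  for (k in (p + 1):max_lag) {
    rho[k] <- sum(ar * rho[k - seq_len(p)])
  }
  rho[seq_len(max_lag)]
}

# Term-by-term Ljung-Box statistic from the defining sum.
ljung_box_direct <- function(x, lags) {
  n <- length(x)
  xc <- x - mean(x)
  denom <- sum(xc^2)
  q <- 0
  for (k in seq_len(lags)) {
    rho_k <- sum(xc[(k + 1):n] * xc[1:(n - k)]) / denom
    q <- q + rho_k^2 / (n - k)
  }
  n * (n + 2) * q
}

# Midpoint slope and variance of a quadratic OLS fit straight from the
# normal equations.
quad_midpoint_oracle <- function(t, y) {
  X <- cbind(1, t, t^2)
  XtX <- crossprod(X)
  beta <- solve(XtX, crossprod(X, y))
  res <- y - X %*% beta
  sigma2 <- sum(res^2) / (length(y) - 3)
  V <- sigma2 * solve(XtX)
  tm <- (min(t) + max(t)) / 2
  list(
    slope = beta[2] + 2 * beta[3] * tm,
    var = V[2, 2] + 4 * tm^2 * V[3, 3] + 4 * tm * V[2, 3]
  )
}

# Study-pattern intervention configuration used by recovery experiments.
study_events <- function() {
  list(
    intervention_spec("1998-02", pulse = -1.357),
    intervention_spec("2002-03", step = 0.457, pulse = -0.625),
    intervention_spec("2003-11", step = -1.001, pulse = 3.037),
    intervention_spec("2007-11", step = 3.037, pulse = -5.202, lag = 0.945)
  )
}

study_noise <- function(mean = 2) {
  sarima_spec(ar = c(0.343, 0.301), seasonal_ar = 0.208, sd = 0.323,
              mean = mean)
}

# Balanced two-factor fixture whose per-cell residual patterns are
# identical, so per-cell variances are exactly equal and FGLS weights are
# uniform (GLS must then reduce to OLS).
balanced_fixture <- function() {
  cells <- expand.grid(method = c("shotgun", "trap"),
                       period = c("Early", "Pre-ban", "Post-ban"))
  mu <- c(1, 2, 3, 1.5, 2.5, 4)
  res_pattern <- c(-0.3, -0.1, 0, 0.1, 0.3)
  do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    data.frame(method = cells$method[i], period = cells$period[i],
               rate = exp(mu[i] + res_pattern))
  }))
}

# Small deterministic census table builder for io tests.
toy_records <- function(species, n_each, month = "1998-01",
                        group = "rodent", method = "trap",
                        origin = "island") {
  dplyr::bind_rows(lapply(seq_along(species), function(i) {
    tibble::tibble(
      date = as_month(month), species = species[i], group = group,
      method = method, origin = origin, condition = "fresh",
      price_fcfa = 1000
    )[rep(1, n_each[i]), ]
  }))
}
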