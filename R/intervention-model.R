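#' Specify a seasonal ARIMA noise process
#'
#' Describes the Gaussian noise model used both to simulate square-root
#' scale carcass-rate series and as the noise component of the intervention
#' model. The default shape is the pure-AR seasonal model
#' ARIMA(2,0,0)x(1,0,0)_12 used for monthly market data: two regular
#' autoregressive terms plus one seasonal autoregressive term at lag 12.
#'
#' @param ar Regular AR coefficients (may be empty).
#' @param seasonal_ar Seasonal AR coefficients (may be empty).
#' @param period Season length in months.
#' @param mean Process mean on the sqrt scale.
#' @param sd Innovation standard deviation (>= 0; zero gives the
#'   deterministic limit, useful for noiseless checks).
#' @return An object of class `sarima_spec`.
#' @examples
#' sarima_spec(ar = c(0.343, 0.301), seasonal_ar = 0.208, sd = 0.323)
#' @export
sarima_spec <- function(ar = numeric(), seasonal_ar = numeric(), period = 12L,
                        mean = 0, sd = 1) {
  stopifnot(is.numeric(ar), is.numeric(seasonal_ar), length(period) == 1L,
            period >= 1, length(mean) == 1L, length(sd) == 1L)
  if (sd < 0) stop("innovation sd must be non-negative")
  check_stationary(ar, "regular AR")
  check_stationary(seasonal_ar, "seasonal AR")
  structure(
    list(ar = as.numeric(ar), seasonal_ar = as.numeric(seasonal_ar),
         period = as.integer(period), mean = mean, sd = sd),
    class = "sarima_spec"
  )
}

# Reject AR polynomials with roots on or inside the unit circle, reporting
# the offending roots.
check_stationary <- function(coef, what) {
  if (length(coef) == 0) return(invisible(TRUE))
  roots <- polyroot(c(1, -coef))
  bad <- Mod(roots) <= 1 + 1e-10
  if (any(bad)) {
    stop(sprintf(
      "%s polynomial is non-stationary; root moduli: %s",
      what, paste(sprintf("%.4f", Mod(roots)), collapse = ", ")
    ))
  }
  invisible(TRUE)
}

# Expand a (regular AR, seasonal AR) pair into the coefficients of the
# product polynomial, suitable for arima.sim().
expand_ar_polynomial <- function(ar, seasonal_ar, period) {
  p <- c(1, -ar)
  ps <- c(1, -seasonal_ar)
  full <- numeric(length(p) + (length(ps) - 1L) * period)
  full[seq_along(p)] <- p
  if (length(ps) > 1L) {
    for (j in seq_along(seasonal_ar)) {
      idx <- j * period + seq_along(p)
      full[idx] <- full[idx] + ps[j + 1L] * p
    }
  }
  -full[-1L]
}

#' Specify an intervention event
#'
#' An intervention is an external shock to the market (a coup attempt, a
#' hunting law, a trade ban) entering the sqrt-scale series as a transfer
#' function: a *pulse* (momentary deviation that returns to baseline), a
#' *step* (permanent shift in the mean), and optionally a geometric *lag*
#' term `1/(1 - w B)` that spreads the pulse (or step) over subsequent
#' months, `B` being the backshift operator.
#'
#' @param event Event month (`Date` or `"YYYY-MM"`), the first month in
#'   which the shock is visible in the series.
#' @param step Step weight, or `NULL` for no step component.
#' @param pulse Pulse weight, or `NULL` for no pulse component.
#' @param lag Lag weight in (-1, 1), or `NULL` for no lag dynamics.
#' @param lag_on Which component the lag operator acts on; the default
#'   `"pulse"` makes the pulse decay geometrically back to the (possibly
#'   stepped) mean.
#' @param targets Taxon groups whose counts the event perturbs when the
#'   specification is used by the synthetic census generator.
#' @param label Optional display label.
#' @return An object of class `intervention_spec`.
#' @examples
#' # The 11/2007 primate hunting ban: permanent upward step, large negative
#' # pulse, slow geometric recovery.
#' intervention_spec("2007-11", step = 3.037, pulse = -5.202, lag = 0.945)
#' @export
intervention_spec <- function(event, step = NULL, pulse = NULL, lag = NULL,
                              lag_on = c("pulse", "step"),
                              targets = "primate", label = NULL) {
  lag_on <- match.arg(lag_on)
  event <- as_month(event)
  if (is.null(step) && is.null(pulse)) {
    stop("an intervention needs at least a step or a pulse component")
  }
  if (!is.null(lag)) {
    if (abs(lag) >= 1) stop("lag weight must lie strictly inside (-1, 1)")
    if (lag_on == "pulse" && is.null(pulse)) {
      stop("lag_on = 'pulse' requires a pulse component")
    }
    if (lag_on == "step" && is.null(step)) {
      stop("lag_on = 'step' requires a step component")
    }
  }
  structure(
    list(event = event, step = step, pulse = pulse, lag = lag,
         lag_on = lag_on, targets = targets,
         label = label %||% format(event, "%m/%Y")),
    class = "intervention_spec"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Transfer-function response of an intervention
#'
#' Evaluates the deterministic sqrt-scale response
#' `m_t = w_S 1(t >= e) + w_P d^(t - e) 1(t >= e)` of one intervention over
#' a window of months, where `d` is the lag weight (0 when absent, making
#' the pulse a one-month spike). The lagged component is computed by the
#' exact recursion `m_t = d m_{t-1} + w P_t`, so the response satisfies the
#' defining difference equation to machine precision.
#'
#' @param spec An [intervention_spec()].
#' @param months Months over which to evaluate (a `Date` vector from
#'   [month_seq()], or an integer count of months starting at `origin`).
#' @param origin First month of the window when `months` is a count.
#' @return Numeric vector of responses, one per month.
#' @examples
#' ban <- intervention_spec("2007-11", step = 3.037, pulse = -5.202,
#'                          lag = 0.945)
#' m <- transfer_response(ban, month_seq("1997-10", 156))
#' m[month_index("2007-12")] # one month after the event
#' @export
transfer_response <- function(spec, months, origin = study_origin()) {
  stopifnot(inherits(spec, "intervention_spec"))
  if (length(months) == 1L && is.numeric(months)) {
    months <- month_seq(origin, months)
  }
  months <- as_month(months)
  e <- match(spec$event, months)
  if (is.na(e)) {
    if (spec$event > max(months)) {
      stop("event month ", format(spec$event, "%Y-%m"),
           " lies after the series window")
    }
    e <- -Inf # event before the window: step already on, pulse decayed
  }
  n <- length(months)
  t_rel <- seq_len(n) - e
  on <- as.numeric(t_rel >= 0)
  delta <- spec$lag %||% 0
  step_part <- pulse_part <- numeric(n)
  if (!is.null(spec$step)) {
    if (!is.null(spec$lag) && spec$lag_on == "step") {
      # m_t = delta * m_{t-1} + w_S * S_t  (saturating ramp)
      s <- spec$step * on
      prev <- 0
      for (t in seq_len(n)) {
        prev <- delta * prev + s[t]
        step_part[t] <- prev
      }
    } else {
      step_part <- spec$step * on
    }
  }
  if (!is.null(spec$pulse)) {
    if (!is.null(spec$lag) && spec$lag_on == "pulse") {
      p <- as.numeric(t_rel == 0)
      prev <- if (is.infinite(e)) 0 else 0
      for (t in seq_len(n)) {
        prev <- delta * prev + spec$pulse * p[t]
        pulse_part[t] <- prev
      }
    } else {
      pulse_part <- spec$pulse * as.numeric(t_rel == 0)
    }
  }
  step_part + pulse_part
}

# Deterministic regressor columns for one intervention at a given lag
# weight. Columns are linear in the step/pulse weights, which is what lets
# the joint fit profile out the lag parameter.
intervention_regressors <- function(spec, months, delta = spec$lag) {
  n <- length(months)
  e <- match(spec$event, months)
  if (is.na(e)) stop("event month outside the fitted window: ", spec$label)
  on <- as.numeric(seq_len(n) >= e)
  cols <- list()
  if (!is.null(spec$step)) {
    if (!is.null(spec$lag) && spec$lag_on == "step") {
      unit <- stats::filter(on, delta, method = "recursive")
      cols[[paste0("step_", format(spec$event, "%Y_%m"))]] <- as.numeric(unit)
    } else {
      cols[[paste0("step_", format(spec$event, "%Y_%m"))]] <- on
    }
  }
  if (!is.null(spec$pulse)) {
    p <- as.numeric(seq_len(n) == e)
    if (!is.null(spec$lag) && spec$lag_on == "pulse") {
      unit <- stats::filter(p, delta, method = "recursive")
      cols[[paste0("pulse_", format(spec$event, "%Y_%m"))]] <- as.numeric(unit)
    } else {
      cols[[paste0("pulse_", format(spec$event, "%Y_%m"))]] <- p
    }
  }
  do.call(cbind, cols)
}

# One exact Gaussian ML fit of the SARIMA(+regression) model at fixed
# transfer-function shape, via the state-space prediction-error likelihood
# (conditional sum of squares used only to initialise).
fit_sarima_core <- function(z, order, seasonal, period, xreg = NULL,
                            include_mean = TRUE, method = "CSS-ML",
                            fixed = NULL) {
  seasonal <- list(order = seasonal, period = period)
  attempt <- function(meth, control) {
    tryCatch(
      suppressWarnings(stats::arima(
        z, order = order, seasonal = seasonal, xreg = xreg,
        include.mean = include_mean, method = meth,
        fixed = fixed, transform.pars = is.null(fixed),
        optim.control = control
      )),
      error = function(e) e
    )
  }
  fit <- attempt(method, list())
  if (inherits(fit, "error") || (!is.null(fit$code) && fit$code != 0)) {
    # one retry with a larger iteration budget, then the pure-ML path
    fit <- attempt(method, list(maxit = 500))
  }
  if (inherits(fit, "error") || (!is.null(fit$code) && fit$code != 0)) {
    fit <- attempt("ML", list(maxit = 500))
  }
  if (inherits(fit, "error")) {
    stop("SARIMA fit failed: ", conditionMessage(fit), call. = FALSE)
  }
  if (!is.null(fit$code) && fit$code != 0) {
    stop("SARIMA optimizer did not converge (optim code ", fit$code, ")")
  }
  fit
}

#' Fit a seasonal ARIMA model by exact maximum likelihood
#'
#' Gaussian maximum likelihood through the state-space prediction-error
#' decomposition (Kalman filter), initialised from conditional sums of
#' squares. Returns estimates with standard errors from the inverse
#' observed information, the log-likelihood, AIC, and the root mean square
#' of the one-step residuals.
#'
#' @param z Numeric series (monthly, no missing values).
#' @param order Regular `(p, d, q)` orders.
#' @param seasonal Seasonal `(P, D, Q)` orders.
#' @param period Season length.
#' @param include_mean Estimate a mean term? On by default; monthly carcass
#'   rates have no natural zero level.
#' @param method Estimation route passed to the likelihood engine;
#'   `"CSS-ML"` (exact ML initialised by CSS) is the default.
#' @return An object of class `sarima_fit` with elements `coefficients`
#'   (tibble of term, estimate, se), `loglik`, `aic`, `rmse`, `sigma2`,
#'   `residuals`, `fitted` and the underlying `arima` object as `model`.
#' @examples
#' z <- generate_sqrt_series(sarima_spec(ar = c(0.343, 0.301),
#'                                       seasonal_ar = 0.208),
#'                           n_months = 121, seed = 1)
#' sarima_fit(z)
#' @export
sarima_fit <- function(z, order = c(2L, 0L, 0L), seasonal = c(1L, 0L, 0L),
                       period = 12L, include_mean = TRUE, method = "CSS-ML") {
  z <- as.numeric(z)
  npar <- sum(order[c(1, 3)]) + sum(seasonal[c(1, 3)]) + include_mean
  if (length(z) <= 5 * npar) {
    stop("series too short for the requested model (need > ", 5 * npar,
         " points)")
  }
  if (anyNA(z)) stop("series contains missing values; impute gaps first")
  fit <- fit_sarima_core(z, order, seasonal, period,
                         include_mean = include_mean, method = method)
  structure(
    list(
      coefficients = coef_table(fit),
      loglik = as.numeric(stats::logLik(fit)),
      aic = fit$aic,
      sigma2 = fit$sigma2,
      rmse = sqrt(mean(stats::residuals(fit)^2)),
      residuals = as.numeric(stats::residuals(fit)),
      fitted = z - as.numeric(stats::residuals(fit)),
      order = order, seasonal = seasonal, period = period,
      include_mean = include_mean, z = z, model = fit
    ),
    class = "sarima_fit"
  )
}

coef_table <- function(fit) {
  est <- stats::coef(fit)
  se <- rep(NA_real_, length(est))
  if (length(fit$var.coef)) {
    v <- diag(fit$var.coef)
    se[match(rownames(fit$var.coef), names(est))] <- sqrt(pmax(v, 0))
  }
  tibble::tibble(term = names(est), estimate = as.numeric(est), se = se)
}

#' @export
print.sarima_fit <- function(x, ...) {
  cat("Seasonal ARIMA fit (", paste(x$order, collapse = ","), ")x(",
      paste(x$seasonal, collapse = ","), ")_", x$period, "\n", sep = "")
  print(as.data.frame(x$coefficients), row.names = FALSE)
  cat(sprintf("loglik %.3f  AIC %.2f  RMSE %.4f\n", x$loglik, x$aic, x$rmse))
  invisible(x)
}

#' Joint intervention (transfer-function) model fit
#'
#' Fits `z_t = mu + sum_j m_t(j) + N_t` by joint Gaussian maximum
#' likelihood, where each `m_t(j)` is the transfer response of one
#' intervention and `N_t` is the seasonal ARIMA noise process. Step and
#' pulse weights enter linearly and are estimated together with the noise
#' parameters; a geometric lag weight is profiled out on a coarse grid and
#' refined by golden-section search, so the reported fit maximises the full
#' likelihood over every parameter.
#'
#' @inheritParams sarima_fit
#' @param interventions List of [intervention_spec()] objects. Stored lag
#'   values are used as search starting points only; the lag is always
#'   re-estimated.
#' @param months Months corresponding to `z` (`Date` vector or first month;
#'   defaults to the study origin).
#' @param delta_grid Grid of lag values bracketing the profile search.
#' @param se `"conditional"` (from the inverse observed information at the
#'   profiled lag, plus a profile-curvature standard error for the lag) or
#'   `"joint"` (numerical Hessian over all parameters including the lag).
#' @return An object of class `intervention_fit`; see
#'   [intervention_table()] for the estimate/(SE) layout and
#'   [percent_change()] for implied rate changes.
#' @examples
#' events <- list(intervention_spec("2007-11", step = 3.037, pulse = -5.202,
#'                                  lag = 0.945))
#' noise <- sarima_spec(ar = c(0.343, 0.301), seasonal_ar = 0.208, sd = 0.323)
#' z <- generate_sqrt_series(noise, events, n_months = 156, seed = 7)
#' fit <- arimax_fit(z, interventions = events)
#' intervention_table(fit)
#' @export
arimax_fit <- function(z, order = c(2L, 0L, 0L), seasonal = c(1L, 0L, 0L),
                       period = 12L, interventions = list(),
                       months = study_origin(), include_mean = TRUE,
                       method = "CSS-ML",
                       delta_grid = c(-0.8, -0.4, 0, 0.4, 0.7, 0.9, 0.96),
                       se = c("conditional", "joint")) {
  se <- match.arg(se)
  z <- as.numeric(z)
  if (anyNA(z)) stop("series contains missing values; impute gaps first")
  if (length(months) == 1L) months <- month_seq(months, length(z))
  months <- as_month(months)
  stopifnot(length(months) == length(z))
  if (length(interventions) == 0) {
    out <- sarima_fit(z, order, seasonal, period, include_mean, method)
    out$interventions <- list()
    out$months <- months
    out$structural <- rep(
      if (include_mean) out$coefficients$estimate[out$coefficients$term ==
                                                    "intercept"] else 0,
      length(z))
    out$delta <- NULL
    class(out) <- c("intervention_fit", "sarima_fit")
    return(out)
  }
  check_collinear(interventions)
  lagged <- which(vapply(interventions, function(s) !is.null(s$lag),
                         logical(1)))
  if (length(lagged) > 1L) {
    stop("at most one lagged intervention is supported per fit")
  }

  make_x <- function(delta) {
    cols <- lapply(interventions, function(s) {
      d <- if (!is.null(s$lag)) delta else NULL
      intervention_regressors(s, months, delta = d %||% 0)
    })
    do.call(cbind, cols)
  }

  if (length(lagged) == 0L) {
    fit <- fit_sarima_core(z, order, seasonal, period, xreg = make_x(0),
                           include_mean = include_mean, method = method)
    delta_hat <- NULL
    delta_se <- NULL
  } else {
    profile_fit <- function(delta) {
      fit_sarima_core(z, order, seasonal, period, xreg = make_x(delta),
                      include_mean = include_mean, method = method)
    }
    nll <- function(delta) {
      tryCatch(-as.numeric(stats::logLik(profile_fit(delta))),
               error = function(e) Inf)
    }
    # Stage 1: locate the lag with the cheap conditional-sum-of-squares
    # criterion (initialisation only); stage 2: refine by exact ML.
    nll_css <- function(delta) {
      f <- tryCatch(
        fit_sarima_core(z, order, seasonal, period, xreg = make_x(delta),
                        include_mean = include_mean, method = "CSS"),
        error = function(e) NULL
      )
      if (is.null(f)) Inf else f$sigma2
    }
    grid <- sort(unique(c(delta_grid, interventions[[lagged]]$lag)))
    grid <- grid[abs(grid) < 0.995]
    prof <- vapply(grid, nll_css, numeric(1))
    k <- which.min(prof)
    lo <- if (k > 1) grid[k - 1] else max(-0.995, grid[1] - 0.2)
    hi <- if (k < length(grid)) grid[k + 1] else min(0.995, grid[k] + 0.04)
    coarse <- stats::optimize(nll_css, interval = c(lo, hi), tol = 2e-3)
    bracket <- c(max(-0.995, coarse$minimum - 0.04),
                 min(0.995, coarse$minimum + 0.04))
    opt <- stats::optimize(nll, interval = bracket, tol = 1e-3)
    delta_hat <- opt$minimum
    fit <- profile_fit(delta_hat)
    # profile-curvature standard error for the lag weight
    h <- 5e-3
    curv <- (nll(delta_hat + h) - 2 * opt$objective + nll(delta_hat - h)) / h^2
    delta_se <- if (is.finite(curv) && curv > 0) 1 / sqrt(curv) else NA_real_
  }

  coefs <- coef_table(fit)
  n_delta <- length(lagged)
  out <- structure(
    list(
      coefficients = coefs,
      interventions = fill_intervention_estimates(interventions, coefs,
                                                  delta_hat, delta_se),
      delta = delta_hat, delta_se = delta_se,
      loglik = as.numeric(stats::logLik(fit)),
      # arima's AIC does not count the profiled lag weight
      aic = fit$aic + 2 * n_delta,
      sigma2 = fit$sigma2,
      rmse = sqrt(mean(stats::residuals(fit)^2)),
      residuals = as.numeric(stats::residuals(fit)),
      fitted = z - as.numeric(stats::residuals(fit)),
      structural = structural_series(fit, interventions, months, delta_hat,
                                     include_mean),
      order = order, seasonal = seasonal, period = period,
      include_mean = include_mean, method = method,
      z = z, months = months, model = fit
    ),
    class = c("intervention_fit", "sarima_fit")
  )
  if (se == "joint") out$vcov_joint <- joint_vcov(out)
  out
}

check_collinear <- function(interventions) {
  key <- unlist(lapply(interventions, function(s) {
    c(if (!is.null(s$step)) paste0("step@", format(s$event)),
      if (!is.null(s$pulse)) paste0("pulse@", format(s$event)))
  }))
  if (anyDuplicated(key)) {
    stop("collinear interventions: duplicated component(s) ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  }
}

# Noise-free part of the fit: mu + summed transfer responses with weights
# at their estimates.
structural_series <- function(fit, interventions, months, delta_hat,
                              include_mean) {
  est <- stats::coef(fit)
  mu <- if (include_mean) unname(est["intercept"]) else 0
  m <- rep(mu, length(months))
  for (s in interventions) {
    if (!is.null(s$lag)) s$lag <- delta_hat
    w_s <- if (!is.null(s$step)) {
      unname(est[paste0("step_", format(s$event, "%Y_%m"))])
    } else NULL
    w_p <- if (!is.null(s$pulse)) {
      unname(est[paste0("pulse_", format(s$event, "%Y_%m"))])
    } else NULL
    s$step <- w_s
    s$pulse <- w_p
    m <- m + transfer_response(s, months)
  }
  m
}

fill_intervention_estimates <- function(interventions, coefs, delta_hat,
                                        delta_se) {
  lapply(interventions, function(s) {
    nm <- format(s$event, "%Y_%m")
    pick <- function(prefix) {
      row <- coefs[coefs$term == paste0(prefix, "_", nm), ]
      if (nrow(row)) list(estimate = row$estimate, se = row$se) else NULL
    }
    s$estimates <- list(
      step = if (!is.null(s$step)) pick("step"),
      pulse = if (!is.null(s$pulse)) pick("pulse"),
      lag = if (!is.null(s$lag)) list(estimate = delta_hat, se = delta_se)
    )
    s
  })
}

#' @export
print.intervention_fit <- function(x, ...) {
  cat("Intervention model: ARIMA(", paste(x$order, collapse = ","), ")x(",
      paste(x$seasonal, collapse = ","), ")_", x$period, " noise, ",
      length(x$interventions), " intervention(s)\n", sep = "")
  if (length(x$interventions)) print(intervention_table(x))
  cat(sprintf("loglik %.3f  AIC %.2f  RMSE %.4f\n", x$loglik, x$aic, x$rmse))
  invisible(x)
}

#' Intervention parameter table
#'
#' Lays out the fitted step, pulse and lag weights as one row per component
#' type and one column per event, each cell formatted `estimate (SE)` —
#' the conventional presentation for transfer-function intervention models.
#'
#' @param fit An [arimax_fit()] result.
#' @return A tibble with a `component` column and one column per event.
#' @export
intervention_table <- function(fit) {
  stopifnot(inherits(fit, "intervention_fit"))
  fmt <- function(e) {
    if (is.null(e)) "---" else sprintf("%.3f (%.3f)", e$estimate, e$se)
  }
  cols <- lapply(fit$interventions, function(s) {
    c(step = fmt(s$estimates$step), pulse = fmt(s$estimates$pulse),
      lag = fmt(s$estimates$lag))
  })
  names(cols) <- vapply(fit$interventions, `[[`, character(1), "label")
  dplyr::bind_cols(
    tibble::tibble(component = c("step", "pulse", "lag")),
    tibble::as_tibble(cols)
  )
}

#' Drop interventions that do not significantly perturb the series
#'
#' Iteratively removes the least significant intervention component with
#' `|estimate| / SE < z_crit` and refits the joint model, stopping when
#' every remaining component survives. This is the conventional
#' backward-elimination rule for intervention models; with the default
#' `z_crit = 1.96` a truly null component is removed with probability about
#' 0.95 at each evaluation.
#'
#' @param fit An [arimax_fit()] result.
#' @param z_crit Critical ratio below which a component is dropped.
#' @return A refitted `intervention_fit` containing only surviving
#'   components.
#' @export
prune_nonsignificant <- function(fit, z_crit = 1.96) {
  stopifnot(inherits(fit, "intervention_fit"))
  repeat {
    if (length(fit$interventions) == 0) return(fit)
    comp <- component_z(fit)
    weak <- comp[abs(comp$z) < z_crit, ]
    if (nrow(weak) == 0) return(fit)
    drop <- weak[which.min(abs(weak$z)), ]
    specs <- fit$interventions
    i <- drop$index
    s <- specs[[i]]
    if (drop$component == "step") s$step <- NULL else s$pulse <- NULL
    if (!is.null(s$lag)) {
      keep_lag <- (s$lag_on == "pulse" && !is.null(s$pulse)) ||
        (s$lag_on == "step" && !is.null(s$step))
      if (!keep_lag) s$lag <- NULL
    }
    specs[[i]] <- s
    specs <- Filter(function(x) !is.null(x$step) || !is.null(x$pulse), specs)
    specs <- lapply(specs, function(x) { x$estimates <- NULL; x })
    fit <- arimax_fit(fit$z, fit$order, fit$seasonal, fit$period,
                      interventions = specs, months = fit$months,
                      include_mean = fit$include_mean, method = fit$method)
  }
}

component_z <- function(fit) {
  rows <- list()
  for (i in seq_along(fit$interventions)) {
    s <- fit$interventions[[i]]
    for (comp in c("step", "pulse")) {
      e <- s$estimates[[comp]]
      if (!is.null(e)) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          index = i, label = s$label, component = comp,
          estimate = e$estimate, se = e$se, z = e$estimate / e$se
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}

# Full negative log-likelihood as a function of every parameter (noise,
# mean, weights, lag), evaluated through fixed-parameter filter runs; used
# for the joint observed-information matrix.
joint_vcov <- function(fit) {
  est <- stats::coef(fit$model)
  has_delta <- !is.null(fit$delta)
  theta <- c(est, if (has_delta) c(lag = fit$delta))
  lagged <- Filter(function(s) !is.null(s$lag), fit$interventions)
  make_x <- function(delta) {
    do.call(cbind, lapply(fit$interventions, function(s) {
      d <- if (!is.null(s$lag)) delta else 0
      intervention_regressors(s, fit$months, delta = d)
    }))
  }
  nll <- function(th) {
    delta <- if (has_delta) th[length(th)] else 0
    if (has_delta && abs(delta) >= 0.999) return(1e10)
    fixed <- th[seq_along(est)]
    f <- tryCatch(
      fit_sarima_core(fit$z, fit$order, fit$seasonal, fit$period,
                      xreg = make_x(delta), include_mean = fit$include_mean,
                      method = "ML", fixed = fixed),
      error = function(e) NULL
    )
    if (is.null(f)) 1e10 else -as.numeric(stats::logLik(f))
  }
  H <- stats::optimHess(theta, nll)
  V <- tryCatch(solve(H), error = function(e) {
    warning("observed information is singular; using pseudo-inverse")
    MASS_ginv(H)
  })
  dimnames(V) <- list(names(theta), names(theta))
  V
}

# Moore-Penrose pseudo-inverse via SVD (fallback for a singular Hessian).
MASS_ginv <- function(X, tol = sqrt(.Machine$double.eps)) {
  s <- svd(X)
  pos <- s$d > max(tol * s$d[1L], 0)
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Ljung-Box portmanteau test
#'
#' Computes `Q = n (n + 2) sum_{k=1..L} acf_k^2 / (n - k)` on a residual
#' series and refers it to a chi-square upper tail with `L - fitdf` degrees
#' of freedom. By default `fitdf` should be the number of fitted AR plus
#' seasonal-AR parameters of the model that produced the residuals.
#'
#' @param residuals Residual series.
#' @param lags Number of autocorrelation lags `L` (must be < length/2).
#' @param fitdf Degrees of freedom consumed by the fitted model.
#' @return A list with `statistic`, `df`, `p_value` and the lag count.
#' @export
ljung_box <- function(residuals, lags = 12L, fitdf = 0L) {
  x <- as.numeric(residuals)
  n <- length(x)
  if (lags >= n / 2) stop("lags must be below half the series length")
  if (stats::sd(x) == 0) {
    stop("residuals are constant; autocorrelation undefined")
  }
  rho <- stats::acf(x, lag.max = lags, plot = FALSE,
                    demean = TRUE)$acf[-1]
  q <- n * (n + 2) * sum(rho^2 / (n - seq_len(lags)))
  df <- lags - fitdf
  if (df <= 0) stop("fitdf must be smaller than the number of lags")
  list(statistic = q, df = df, p_value = stats::pchisq(q, df,
                                                       lower.tail = FALSE),
       lags = lags)
}

#' Implied percentage change in the carcass rate between two months
#'
#' The intervention model is fitted on the square-root scale; the implied
#' original-scale rate in month `t` is the square of the structural
#' (noise-free) fitted value. This returns
#' `100 (yhat_from - yhat_to) / yhat_from`, the percentage decline from
#' `from_month` to `to_month`, with a 95% confidence interval by the delta
#' method on the mean, intervention-weight and lag estimates (default) or
#' by a parametric bootstrap from their joint sampling distribution.
#'
#' @param fit An [arimax_fit()] result.
#' @param from_month,to_month Months within the fitted window.
#' @param level Confidence level.
#' @param method `"delta"` or `"bootstrap"`.
#' @param n_boot Parametric-bootstrap draws.
#' @param seed Seed for the bootstrap draws.
#' @return A list with `estimate`, `lower`, `upper`, `level`.
#' @export
percent_change <- function(fit, from_month, to_month, level = 0.95,
                           method = c("delta", "bootstrap"), n_boot = 1000L,
                           seed = 1L) {
  method <- match.arg(method)
  stopifnot(inherits(fit, "intervention_fit"))
  i_from <- match(as_month(from_month), fit$months)
  i_to <- match(as_month(to_month), fit$months)
  if (is.na(i_from) || is.na(i_to)) stop("month outside the fitted window")

  est <- stats::coef(fit$model)
  has_delta <- !is.null(fit$delta)
  theta_hat <- c(est, if (has_delta) c(lag = fit$delta))

  pct_of <- function(theta) {
    delta <- if (has_delta) theta[length(theta)] else NULL
    mu <- if (fit$include_mean) unname(theta["intercept"]) else 0
    m <- rep(mu, length(fit$months))
    for (s in fit$interventions) {
      nm <- format(s$event, "%Y_%m")
      if (!is.null(s$step)) s$step <- unname(theta[paste0("step_", nm)])
      if (!is.null(s$pulse)) s$pulse <- unname(theta[paste0("pulse_", nm)])
      if (!is.null(s$lag)) s$lag <- delta
      m <- m + transfer_response(s, fit$months)
    }
    y_from <- m[i_from]^2
    y_to <- m[i_to]^2
    if (y_from == 0) stop("structural rate is zero in the reference month")
    100 * (y_from - y_to) / y_from
  }

  estimate <- pct_of(theta_hat)
  V <- fit$vcov_joint %||% joint_vcov(fit)
  alpha <- (1 - level) / 2
  if (method == "delta") {
    g <- numeric(length(theta_hat))
    h <- pmax(1e-5, abs(theta_hat) * 1e-5)
    for (j in seq_along(theta_hat)) {
      up <- dn <- theta_hat
      up[j] <- up[j] + h[j]
      dn[j] <- dn[j] - h[j]
      g[j] <- (pct_of(up) - pct_of(dn)) / (2 * h[j])
    }
    sd_pct <- sqrt(max(0, drop(t(g) %*% V %*% g)))
    zq <- stats::qnorm(1 - alpha)
    lower <- estimate - zq * sd_pct
    upper <- estimate + zq * sd_pct
  } else {
    set.seed(seed)
    L <- tryCatch(chol(V), error = function(e) {
      ev <- eigen(V, symmetric = TRUE)
      ev$vectors %*% diag(sqrt(pmax(ev$values, 0))) %*% t(ev$vectors)
    })
    draws <- matrix(stats::rnorm(n_boot * length(theta_hat)), n_boot)
    thetas <- sweep(draws %*% L, 2, theta_hat, `+`)
    pcts <- apply(thetas, 1, function(th) {
      names(th) <- names(theta_hat)
      tryCatch(pct_of(th), error = function(e) NA_real_)
    })
    qs <- stats::quantile(pcts, c(alpha, 1 - alpha), na.rm = TRUE,
                          names = FALSE)
    lower <- qs[1]
    upper <- qs[2]
  }
  list(estimate = estimate, lower = lower, upper = upper, level = level)
}
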