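test_that("GLS reduces to ordinary two-way ANOVA when variances are equal", {
  df <- balanced_fixture()
  g <- gls_anova(df)
  a <- stats::anova(stats::aov(log(rate) ~ method * period, data = df))
  expect_equal(g$anova_table$statistic,
               a$`F value`[1:3], tolerance = 1e-6)
  expect_equal(g$anova_table$df1, a$Df[1:3])
  expect_equal(g$anova_table$df2, rep(a$Df[4], 3))
  expect_equal(g$anova_table$p_value, a$`Pr(>F)`[1:3], tolerance = 1e-6)
})

test_that("the GLS F statistics are invariant to rate rescaling", {
  set.seed(25)
  df <- data.frame(
    method = rep(c("shotgun", "trap"), each = 90),
    period = rep(rep(c("Early", "Pre-ban", "Post-ban"), each = 30), 2),
    rate = exp(rnorm(180, rep(1:6, each = 30),
                     rep(c(0.2, 0.5, 0.3, 0.6, 0.4, 0.8), each = 30)))
  )
  f1 <- gls_anova(df)$anova_table$statistic
  df2 <- df
  df2$rate <- df2$rate * 7.3
  f2 <- gls_anova(df2)$anova_table$statistic
  expect_equal(f1, f2, tolerance = 1e-8)
})

test_that("degenerate ANOVA inputs are rejected", {
  df <- balanced_fixture()
  expect_error(gls_anova(df[df$method == "trap", ]), "two levels")
  expect_error(gls_anova(df[-(1:3), ]), "3 observations")
})

test_that("FGLS agrees with reference ML estimation of the same model", {
  skip_if_not_installed("nlme")
  set.seed(26)
  df <- data.frame(
    method = rep(c("shotgun", "trap"), each = 150),
    period = rep(rep(c("Early", "Pre-ban", "Post-ban"), each = 50), 2)
  )
  cell_sd <- c(0.2, 0.6, 0.3, 0.5, 0.4, 0.9)
  cell <- as.integer(interaction(df$method, df$period))
  df$rate <- exp(rnorm(300, mean = cell / 2, sd = cell_sd[cell]))
  g <- gls_anova(df)
  ref <- nlme::gls(
    log(rate) ~ method * period, data = df,
    weights = nlme::varIdent(form = ~ 1 | method * period),
    method = "ML"
  )
  # same mean structure under different parameterizations: compare the six
  # fitted cell means
  X <- stats::model.matrix(
    ~ f_m * f_p,
    data.frame(f_m = factor(df$method), f_p = factor(df$period)),
    contrasts.arg = list(f_m = "contr.sum", f_p = "contr.sum")
  )
  fitted_mine <- unname(drop(X %*% g$coefficients))
  expect_equal(fitted_mine, as.numeric(stats::fitted(ref)),
               tolerance = 0.02)
})

test_that("bootstrap correlation handles exact dependence and seeds", {
  x <- rnorm(50)
  r_pos <- bootstrap_correlation(x, 2 * x + 1, n_boot = 200, seed = 1)
  expect_equal(r_pos$r, 1)
  r_neg <- bootstrap_correlation(x, -x, n_boot = 200, seed = 1)
  expect_equal(r_neg$r, -1)
  y_noisy <- x + rnorm(50)
  a <- bootstrap_correlation(x, y_noisy, n_boot = 500, seed = 9)
  b <- bootstrap_correlation(x, y_noisy, n_boot = 500, seed = 9)
  expect_identical(a[c("lower", "upper")], b[c("lower", "upper")])
  expect_error(bootstrap_correlation(x, rep(1, 50)), "zero variance")
  expect_error(bootstrap_correlation(x[1:5], x[1:5]))
})

test_that("bootstrap CI width shrinks roughly as 1/sqrt(n)", {
  set.seed(27)
  width_at <- function(n) {
    x <- rnorm(n)
    y <- 0.5 * x + rnorm(n, 0, 0.9)
    ci <- bootstrap_correlation(x, y, n_boot = 2000, seed = 3)
    ci$upper - ci$lower
  }
  w100 <- width_at(100)
  w400 <- width_at(400)
  ratio <- w100 / w400
  expect_gt(ratio, 1.4) # ~2 expected; allow sampling slack
  expect_lt(ratio, 2.9)
})

test_that("BCa intervals stay close to percentile intervals here", {
  set.seed(28)
  x <- rnorm(120)
  y <- -0.8 * x + rnorm(120, 0, 0.5)
  p <- bootstrap_correlation(x, y, n_boot = 3000, seed = 4)
  b <- bootstrap_correlation(x, y, n_boot = 3000, seed = 4,
                             method = "bca")
  expect_lt(abs(p$lower - b$lower), 0.05)
  expect_lt(abs(p$upper - b$upper), 0.05)
})

proxy_fixture <- function(n = 156, seed = 29) {
  set.seed(seed)
  months <- month_seq("1997-10", n)
  price <- tibble::tibble(month = months,
                          value = 25 + cumsum(rnorm(n, 0.4, 2)))
  list(months = months, price = price)
}

test_that("proxy regression recovers exact linear dependence", {
  fx <- proxy_fixture()
  rates <- tibble::tibble(month = fx$months, stratum = "total",
                          value = 2 * fx$price$value)
  out <- proxy_regression(rates, fx$price)
  expect_equal(nrow(out), 4L) # three periods plus All
  expect_equal(out$slope, rep(2, 4), tolerance = 1e-10)
  expect_equal(out$r_squared, rep(1, 4), tolerance = 1e-10)
  expect_true(all(out$significant))
})

test_that("constant rates give a null regression row", {
  fx <- proxy_fixture()
  rates <- tibble::tibble(month = fx$months, stratum = "total", value = 5)
  out <- proxy_regression(rates, fx$price)
  expect_equal(out$slope, rep(0, 4), tolerance = 1e-12)
  expect_equal(out$r_squared, rep(0, 4))
  expect_false(any(out$significant))
})

test_that("the pooled All row equals a direct pooled regression", {
  fx <- proxy_fixture()
  set.seed(30)
  rates <- tibble::tibble(month = fx$months, stratum = "shotgun",
                          value = 0.3 * fx$price$value + rnorm(156))
  out <- proxy_regression(rates, fx$price)
  direct <- stats::lm(rates$value ~ fx$price$value)
  all_row <- out[out$period == "All", ]
  expect_equal(all_row$slope, unname(coef(direct)[2]), tolerance = 1e-12)
  expect_equal(all_row$r_squared, summary(direct)$r.squared,
               tolerance = 1e-12)
})

test_that("misaligned covariates are reported by month", {
  fx <- proxy_fixture(n = 24)
  rates <- tibble::tibble(month = fx$months, stratum = "total",
                          value = rnorm(24))
  expect_error(
    proxy_regression(rates, fx$price[-5, ],
                     period_partition(breakpoints = c("1998-02", "1999-01"))),
    "1998-02"
  )
})

test_that("independent covariates are flagged at about the test level", {
  set.seed(31)
  n_rep <- 300
  hits <- 0
  months <- month_seq("1997-10", 60)
  part <- period_partition(breakpoints = c("1999-10", "2001-10"))
  for (i in seq_len(n_rep)) {
    rates <- tibble::tibble(month = months, stratum = "total",
                            value = rnorm(60))
    price <- tibble::tibble(month = months, value = rnorm(60))
    out <- proxy_regression(rates, price, part)
    hits <- hits + out$significant[out$period == "All"]
  }
  expect_gt(hits / n_rep, 0.02)
  expect_lt(hits / n_rep, 0.09)
})
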