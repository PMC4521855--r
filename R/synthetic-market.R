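#' Describe one species for the synthetic census
#'
#' A species profile carries everything the generator needs to emulate a
#' market species: its taxon group and body mass, the proportion of
#' carcasses originating on the island (vs. imported), a baseline carcass
#' rate per market day, a per-period linear trend in that rate, a 12-month
#' seasonal modulation, and a per-period probability that a carcass was
#' taken by shotgun rather than trap (the study market shifted from
#' trapping to shotgun hunting over time).
#'
#' @param name Species identifier.
#' @param group One of `r paste(taxon_groups(), collapse = ", ")`.
#' @param mass_kg Body mass in kg (> 0).
#' @param island_proportion Probability a carcass originates on the island.
#' @param baseline_rate Carcasses per market day at the series start (>= 0).
#' @param trend_per_month Change in rate per month, one value per period.
#' @param shotgun_probability Per-period shotgun probability.
#' @param seasonal_amplitude Relative seasonal modulation in [0, 1).
#' @param seasonal_phase Month offset of the seasonal peak in [0, 12).
#' @return An object of class `species_profile`.
#' @export
species_profile <- function(name, group, mass_kg, island_proportion = 1,
                            baseline_rate = 1, trend_per_month = 0,
                            shotgun_probability = 0.5,
                            seasonal_amplitude = 0, seasonal_phase = 0) {
  if (!group %in% taxon_groups()) {
    stop("unknown taxon group '", group, "' for species ", name)
  }
  stopifnot(mass_kg > 0, island_proportion >= 0, island_proportion <= 1,
            baseline_rate >= 0, all(shotgun_probability >= 0),
            all(shotgun_probability <= 1), seasonal_phase >= 0,
            seasonal_phase < 12)
  if (seasonal_amplitude < 0 || seasonal_amplitude >= 1) {
    stop("seasonal_amplitude must lie in [0, 1) so rates stay non-negative")
  }
  structure(
    list(name = name, group = group, mass_kg = mass_kg,
         island_proportion = island_proportion,
         baseline_rate = baseline_rate,
         trend_per_month = trend_per_month,
         shotgun_probability = shotgun_probability,
         seasonal_amplitude = seasonal_amplitude,
         seasonal_phase = seasonal_phase),
    class = "species_profile"
  )
}

#' Assemble a synthetic-census scenario
#'
#' A scenario fixes every input of the generator: the monthly window,
#' species profiles, intervention events (which perturb the sqrt-scale rate
#' of targeted taxon groups), the noise model for sqrt-scale series, the
#' market-day law (26 potential days per month minus a binomial dropout,
#' reflecting a Monday-Saturday market with occasional Sunday activity),
#' categorical laws for condition and price, and the seed that fully
#' determines the output.
#'
#' @param species List of [species_profile()] objects.
#' @param start_month First survey month.
#' @param n_months Number of months (>= 24).
#' @param breakpoints Two months opening the second and third period.
#' @param interventions List of [intervention_spec()] objects.
#' @param noise A [sarima_spec()] for sqrt-scale series generation.
#' @param market_day_base Potential market days per month.
#' @param market_day_dropout_size,market_day_dropout_prob Binomial law for
#'   days lost per month.
#' @param condition_probs Named probabilities for carcass condition.
#' @param count_model `"poisson"` (default) or `"nbinom"`; the daily count
#'   law. The census protocol does not constrain this choice, so Poisson is
#'   the documented default with a negative-binomial option.
#' @param nbinom_size Dispersion parameter when `count_model = "nbinom"`.
#' @param price_base,price_exponent,price_sdlog Log-normal price law:
#'   `meanlog = log(price_base * mass_kg^price_exponent)`.
#' @param missing_months Months with total data loss (no records, zero
#'   surveyed days); imputed later from neighbours.
#' @param seed Integer seed; identical seeds give byte-identical censuses.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(species, start_month = study_origin(),
                            n_months = 156L,
                            breakpoints = c("2003-04", "2007-11"),
                            interventions = list(),
                            noise = sarima_spec(ar = c(0.343, 0.301),
                                                seasonal_ar = 0.208,
                                                sd = 0.323),
                            market_day_base = 26L,
                            market_day_dropout_size = 4L,
                            market_day_dropout_prob = 0.5,
                            condition_probs = c(fresh = 0.819,
                                                smoked = 0.126,
                                                alive = 0.055),
                            count_model = c("poisson", "nbinom"),
                            nbinom_size = 10,
                            price_base = 1500, price_exponent = 0.6,
                            price_sdlog = 0.3,
                            missing_months = NULL, seed = 1L) {
  count_model <- match.arg(count_model)
  if (n_months < 24) stop("n_months must be at least 24")
  stopifnot(length(seed) == 1L, is.finite(seed))
  if (inherits(species, "species_profile")) species <- list(species)
  lapply(species, function(s) {
    if (!inherits(s, "species_profile")) {
      stop("species must be species_profile objects")
    }
  })
  stopifnot(inherits(noise, "sarima_spec"))
  condition_probs <- condition_probs / sum(condition_probs)
  structure(
    list(species = species, start_month = as_month(start_month),
         n_months = as.integer(n_months),
         breakpoints = as_month(breakpoints),
         interventions = interventions, noise = noise,
         market_day_base = as.integer(market_day_base),
         market_day_dropout_size = as.integer(market_day_dropout_size),
         market_day_dropout_prob = market_day_dropout_prob,
         condition_probs = condition_probs,
         count_model = count_model, nbinom_size = nbinom_size,
         price_base = price_base, price_exponent = price_exponent,
         price_sdlog = price_sdlog,
         missing_months = if (is.null(missing_months)) NULL
                          else as_month(missing_months),
         seed = as.integer(seed)),
    class = "scenario_config"
  )
}

#' Expected carcass rate of a species in a given month
#'
#' The deterministic mean of the generator before count noise:
#' `lambda_t = max(0, baseline + cumulative trend) * (1 + a cos(2 pi (t -
#' phase) / 12))`, optionally perturbed on the square-root scale by the
#' summed transfer responses of interventions targeting the species' group.
#' Negative extrapolated rates are truncated at zero (rates are physical
#' counts).
#'
#' @param profile A [species_profile()].
#' @param config The [scenario_config()] supplying window, breakpoints and
#'   interventions.
#' @return Numeric vector of expected carcasses per market day, one per
#'   month.
#' @export
expected_rate <- function(profile, config) {
  n <- config$n_months
  months <- month_seq(config$start_month, n)
  t <- seq_len(n)
  per <- period_of_month(months, config$breakpoints)
  trend <- rep_len(profile$trend_per_month, 3L)[per]
  base <- profile$baseline_rate + cumsum(trend)
  seas <- 1 + profile$seasonal_amplitude *
    cos(2 * pi * (t - profile$seasonal_phase) / 12)
  lambda <- pmax(0, base) * seas
  m <- rep(0, n)
  for (s in config$interventions) {
    if (profile$group %in% s$targets && s$event <= max(months)) {
      m <- m + transfer_response(s, months)
    }
  }
  pmax(0, sqrt(lambda) + m)^2
}

period_of_month <- function(months, breakpoints) {
  findInterval(as.numeric(as_month(months)),
               as.numeric(as_month(breakpoints))) + 1L
}

#' Generate a synthetic daily carcass census
#'
#' Draws a full record-level census from a [scenario_config()]: for each
#' species and month, daily counts are Poisson (or negative-binomial) with
#' mean [expected_rate()] per market day; each carcass is then assigned a
#' capture method (Bernoulli with the period-specific shotgun probability),
#' an origin (island vs. import), a condition, and a log-normal price.
#' Output is fully determined by the scenario seed.
#'
#' @param config A [scenario_config()].
#' @return A list with `records` (tibble: date, species, group, method,
#'   origin, condition, price_fcfa) and `calendar` (tibble: month,
#'   market_days; zero days for months with total data loss).
#' @examples
#' cfg <- default_scenario(seed = 1)
#' census <- generate_census(cfg)
#' head(census$records)
#' @export
generate_census <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(substream_seed(config$seed, "census"))
  n <- config$n_months
  months <- month_seq(config$start_month, n)
  market_days <- config$market_day_base -
    stats::rbinom(n, config$market_day_dropout_size,
                  config$market_day_dropout_prob)
  market_days <- pmax(1L, market_days)
  missing <- months %in% (config$missing_months %||% as.Date(character()))
  per <- period_of_month(months, config$breakpoints)

  blocks <- vector("list", length(config$species))
  for (k in seq_along(config$species)) {
    sp <- config$species[[k]]
    lambda <- expected_rate(sp, config)
    shot_p <- rep_len(sp$shotgun_probability, 3L)
    rows <- vector("list", n)
    for (t in seq_len(n)) {
      if (missing[t]) next
      nd <- market_days[t]
      counts <- if (config$count_model == "poisson") {
        stats::rpois(nd, lambda[t])
      } else {
        stats::rnbinom(nd, mu = lambda[t], size = config$nbinom_size)
      }
      tot <- sum(counts)
      if (tot == 0) next
      dates <- rep(months[t] + seq_len(nd) - 1L, counts)
      rows[[t]] <- tibble::tibble(
        date = dates,
        method = ifelse(stats::runif(tot) < shot_p[per[t]],
                        "shotgun", "trap"),
        origin = ifelse(stats::runif(tot) < sp$island_proportion,
                        "island", "import")
      )
    }
    block <- dplyr::bind_rows(rows)
    if (nrow(block)) {
      block$species <- sp$name
      block$group <- sp$group
      block$condition <- sample(names(config$condition_probs), nrow(block),
                                replace = TRUE,
                                prob = config$condition_probs)
      block$price_fcfa <- round(stats::rlnorm(
        nrow(block),
        meanlog = log(config$price_base * sp$mass_kg^config$price_exponent),
        sdlog = config$price_sdlog
      ))
    }
    blocks[[k]] <- block
  }
  records <- dplyr::bind_rows(blocks)
  records <- records[order(records$date, records$species), ,
                     drop = FALSE]
  records <- records[, c("date", "species", "group", "method", "origin",
                         "condition", "price_fcfa")]
  calendar <- tibble::tibble(
    month = months,
    market_days = ifelse(missing, 0L, market_days)
  )
  list(records = tibble::as_tibble(records), calendar = calendar)
}

#' Simulate a sqrt-scale monthly series with interventions
#'
#' Returns `z_t = mu + m_t + N_t`, where `m_t` is the summed
#' transfer-function response of the interventions and `N_t` a mean-zero
#' Gaussian seasonal-AR realization with the spec's coefficients and
#' innovation SD. A burn-in of at least ten seasonal cycles is discarded so
#' the noise starts from its stationary distribution. This is the exact
#' generating process assumed by [arimax_fit()], which makes it the
#' reference simulator for parameter-recovery experiments.
#'
#' @param noise A [sarima_spec()].
#' @param interventions List of [intervention_spec()] objects (may be
#'   empty).
#' @param n_months Series length.
#' @param seed Integer seed.
#' @param origin First month of the window.
#' @param burn_in Discarded initial months (default 120 = 10 cycles).
#' @return Numeric vector of length `n_months`.
#' @export
generate_sqrt_series <- function(noise, interventions = list(), n_months,
                                 seed = 1L, origin = study_origin(),
                                 burn_in = 120L) {
  stopifnot(inherits(noise, "sarima_spec"), n_months >= 1)
  months <- month_seq(origin, n_months)
  m <- rep(0, n_months)
  for (s in interventions) m <- m + transfer_response(s, months)
  set.seed(seed)
  ar_full <- expand_ar_polynomial(noise$ar, noise$seasonal_ar, noise$period)
  n_start <- max(burn_in, length(ar_full) + 1L)
  N <- if (length(ar_full)) {
    as.numeric(stats::arima.sim(model = list(ar = ar_full), n = n_months,
                                sd = noise$sd, n.start = n_start))
  } else {
    stats::rnorm(n_months, sd = noise$sd)
  }
  noise$mean + m + N
}

#' Study-shaped demonstration scenario
#'
#' A ready-made [scenario_config()] emulating the structure of a 13-year
#' urban bushmeat market: 156 months from October 1997, three market
#' periods (breakpoints April 2003 and November 2007), eleven species
#' across the six taxon groups with rates scaled so the market grows from
#' roughly 30 to roughly 90 carcasses per market day, a shift from trap to
#' shotgun capture, one month of total data loss (February 2001), and four
#' intervention events on the primate group including the late-2007
#' hunting-ban pattern (sharp negative pulse, permanent upward step, slow
#' geometric recovery).
#'
#' @param seed Integer seed.
#' @param n_months Window length in months.
#' @return A [scenario_config()].
#' @export
default_scenario <- function(seed = 1L, n_months = 156L) {
  sp <- list(
    species_profile("blue_duiker", "ungulate", 4.90,
                    baseline_rate = 10, trend_per_month = c(0.05, 0.12, 0.10),
                    shotgun_probability = c(0.30, 0.50, 0.75),
                    seasonal_amplitude = 0.15, seasonal_phase = 2),
    species_profile("ogilby_duiker", "ungulate", 19.50,
                    baseline_rate = 1.6, trend_per_month = c(0.01, 0.03, 0.05),
                    shotgun_probability = c(0.55, 0.70, 0.80),
                    seasonal_amplitude = 0.10, seasonal_phase = 2),
    species_profile("pouched_rat", "rodent", 1.14,
                    baseline_rate = 8, trend_per_month = c(0.08, 0.20, -0.25),
                    shotgun_probability = c(0.10, 0.30, 0.45),
                    seasonal_amplitude = 0.12, seasonal_phase = 1),
    species_profile("brush_tailed_porcupine", "rodent", 2.83,
                    island_proportion = 0.91,
                    baseline_rate = 4.5, trend_per_month = c(0.04, 0.12, -0.15),
                    shotgun_probability = c(0.20, 0.35, 0.45),
                    seasonal_amplitude = 0.12, seasonal_phase = 1),
    species_profile("red_eared_monkey", "primate", 3.40,
                    baseline_rate = 2.2, trend_per_month = c(0.01, 0.08, 0.30),
                    shotgun_probability = c(0.90, 0.96, 0.99),
                    seasonal_amplitude = 0.15, seasonal_phase = 3),
    species_profile("drill", "primate", 14.25,
                    baseline_rate = 0.7, trend_per_month = c(0, 0.02, 0.06),
                    shotgun_probability = c(0.95, 0.98, 0.99),
                    seasonal_amplitude = 0.15, seasonal_phase = 3),
    species_profile("black_colobus", "primate", 9.25,
                    baseline_rate = 0.8, trend_per_month = c(0, 0.02, 0.05),
                    shotgun_probability = c(0.95, 0.98, 0.99),
                    seasonal_amplitude = 0.15, seasonal_phase = 3),
    species_profile("great_blue_turaco", "avian", 1.20,
                    baseline_rate = 0.5, trend_per_month = c(0, 0.01, -0.01),
                    shotgun_probability = c(0.50, 0.60, 0.60),
                    seasonal_amplitude = 0.10, seasonal_phase = 5),
    species_profile("nile_monitor", "reptile", 6.50,
                    island_proportion = 0.45,
                    baseline_rate = 0.35, trend_per_month = c(0, 0.005, -0.01),
                    shotgun_probability = c(0.30, 0.35, 0.40)),
    species_profile("tree_pangolin", "other", 1.50,
                    island_proportion = 0.50,
                    baseline_rate = 1.4, trend_per_month = c(0, 0.01, -0.02),
                    shotgun_probability = c(0.10, 0.10, 0.15)),
    # deliberately rare: exercises the <75-record rarity filter
    species_profile("pygmy_squirrel", "rodent", 0.02,
                    baseline_rate = 0.01, trend_per_month = 0,
                    shotgun_probability = 0.05)
  )
  events <- list(
    intervention_spec("1998-02", pulse = -1.357, targets = "primate"),
    intervention_spec("2002-03", step = 0.457, pulse = -0.625,
                      targets = "primate"),
    intervention_spec("2003-11", step = -1.001, pulse = 3.037,
                      targets = "primate"),
    intervention_spec("2007-11", step = 3.037, pulse = -5.202, lag = 0.945,
                      targets = "primate")
  )
  scenario_config(
    species = sp, n_months = n_months, interventions = events,
    missing_months = if (n_months >= 41) "2001-02",
    seed = seed
  )
}
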