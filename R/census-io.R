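#' Read and write census tables
#'
#' Plain-CSV interchange for the three market-census tables: record-level
#' census (date, species, group, method, origin, condition, price_fcfa),
#' market-day calendar (year, month, market_days), and monthly series in
#' long format (month, stratum, rate, market_days).
#'
#' @param path File path.
#' @return A tibble.
#' @name census_csv
NULL

#' @rdname census_csv
#' @export
read_census_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "species", "group", "method", "origin", "condition",
            "price_fcfa")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("census file lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  df$date <- as.Date(df$date)
  tibble::as_tibble(df)
}

#' @rdname census_csv
#' @param census The `records`/`calendar` list from [generate_census()], or
#'   a records tibble.
#' @param dir Output directory.
#' @export
write_census_csv <- function(census, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  records <- if (is.data.frame(census)) census else census$records
  utils::write.csv(records, file.path(dir, "census.csv"), row.names = FALSE)
  if (!is.data.frame(census) && !is.null(census$calendar)) {
    cal <- census$calendar
    out <- data.frame(
      year = as.integer(format(cal$month, "%Y")),
      month = as.integer(format(cal$month, "%m")),
      market_days = cal$market_days
    )
    utils::write.csv(out, file.path(dir, "calendar.csv"), row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname census_csv
#' @export
read_calendar_csv <- function(path) {
  df <- utils::read.csv(path)
  if (all(c("year", "month") %in% names(df))) {
    df$month <- as.Date(sprintf("%04d-%02d-01", df$year, df$month))
    df$year <- NULL
  } else if ("month" %in% names(df)) {
    df$month <- as_month(df$month)
  } else {
    stop("calendar file needs either year+month or month columns")
  }
  tibble::as_tibble(df[, c("month", "market_days")])
}

#' Packaged species reference table
#'
#' The species-level reference for the Malabo market: 28 species with taxon
#' group, body mass (kg), proportion of carcasses originating on Bioko,
#' total study-wide carcass count, and published biomass. Masses and
#' biomasses are the printed values; for two species (African rock python,
#' brush-tailed porcupine) the printed biomass implies an unrounded mass,
#' so `n * mass_kg` differs from `biomass_kg` by a few tens of kg — the
#' table keeps both and downstream summaries recompute biomass from
#' `n * mass_kg`.
#'
#' @param path Optional path to an alternative reference CSV with the same
#'   columns.
#' @return A tibble with columns species, common_name, group, status,
#'   mass_kg, island_proportion, n, biomass_kg.
#' @export
species_reference <- function(path = NULL) {
  path <- path %||% system.file("extdata", "species_reference.csv",
                                package = "bushmeatTS", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("species", "group", "mass_kg", "island_proportion",
                  "n") %in% names(df)))
  if (anyDuplicated(df$species)) stop("reference has duplicated species")
  if (any(df$mass_kg <= 0)) stop("reference masses must be positive")
  tibble::as_tibble(df)
}

normalize_species <- function(x) tolower(trimws(gsub("\\s+", " ", x)))

#' Drop species recorded fewer than a threshold number of times
#'
#' Rarely recorded species are removed from all analyses: sporadic imports
#' and identification errors concentrate in species the data collectors
#' rarely saw. A species is dropped when its study-wide total count is
#' strictly below `threshold`; a species with exactly `threshold` records
#' is retained.
#'
#' @param records Census records tibble.
#' @param threshold Minimum study-wide count to keep a species.
#' @return The filtered records tibble.
#' @export
filter_rare <- function(records, threshold = 75L) {
  if (nrow(records) == 0) return(records)
  counts <- table(records$species)
  keep <- names(counts)[counts >= threshold]
  records[records$species %in% keep, , drop = FALSE]
}

#' Monthly carcass-rate series
#'
#' Aggregates record-level census data to carcasses per market day: the
#' number of selected records in each calendar month divided by the number
#' of days the market was surveyed that month. Months the calendar lists
#' with zero surveyed days and no records get an `NA` rate (a documented
#' data gap, to be filled with [impute_gap()]); a month with records but
#' zero surveyed days is an inconsistency and errors.
#'
#' @param records Census records tibble.
#' @param calendar Tibble with `month` and `market_days` covering every
#'   month of the study window.
#' @param species,group,method,origin Optional record selectors (character
#'   vectors); `NULL` selects everything. Records with method `"unknown"`
#'   are excluded whenever `method` is specified, but counted in
#'   unstratified totals.
#' @return A `monthly_series` tibble: month, value, market_days.
#' @export
monthly_rates <- function(records, calendar, species = NULL, group = NULL,
                          method = NULL, origin = NULL) {
  stopifnot(all(c("month", "market_days") %in% names(calendar)))
  calendar$month <- as_month(calendar$month)
  sel <- rep(TRUE, nrow(records))
  if (!is.null(species)) {
    sel <- sel & normalize_species(records$species) %in%
      normalize_species(species)
  }
  if (!is.null(group)) sel <- sel & records$group %in% group
  if (!is.null(method)) sel <- sel & records$method %in% method
  if (!is.null(origin)) sel <- sel & records$origin %in% origin
  rec <- records[sel, , drop = FALSE]
  m <- as_month(rec$date)
  extra <- setdiff(unique(m), calendar$month)
  if (length(extra)) {
    stop("records outside the calendar window: ",
         paste(format(as.Date(extra, origin = "1970-01-01"), "%Y-%m"),
               collapse = ", "))
  }
  counts <- table(factor(format(m, "%Y-%m"),
                         levels = format(calendar$month, "%Y-%m")))
  counts <- as.integer(counts)
  bad <- counts > 0 & calendar$market_days == 0
  if (any(bad)) {
    stop("month(s) with records but zero surveyed days: ",
         paste(format(calendar$month[bad], "%Y-%m"), collapse = ", "))
  }
  value <- ifelse(calendar$market_days > 0, counts / calendar$market_days,
                  NA_real_)
  monthly_series(calendar$month, value, calendar$market_days)
}

#' Monthly series container
#'
#' A thin tibble subclass holding a gap-free monthly grid with one value
#' per month (carcasses per market day) and the surveyed-day count.
#'
#' @param month Consecutive months (`Date` or `"YYYY-MM"`).
#' @param value Numeric values (`NA` marks a documented gap).
#' @param market_days Surveyed days per month.
#' @return A tibble of class `monthly_series`.
#' @export
monthly_series <- function(month, value, market_days = NA_integer_) {
  month <- as_month(month)
  if (length(month) > 1) {
    idx <- month_index(month, origin = month[1])
    if (!identical(idx, seq_along(month))) {
      stop("months must be strictly increasing and consecutive")
    }
  }
  stopifnot(length(value) == length(month))
  out <- tibble::tibble(month = month, value = as.numeric(value),
                        market_days = market_days)
  class(out) <- c("monthly_series", class(out))
  out
}

#' Impute a single-month gap by averaging its neighbours
#'
#' Replaces the value of one missing month with the arithmetic mean of the
#' two adjacent months, the documented repair for an isolated one-month
#' data loss. Both neighbours must be observed: chains of missing months
#' are an error, not imputed.
#'
#' @param series A [monthly_series()].
#' @param month The month to impute (`NA` or flagged).
#' @return The series with the gap filled.
#' @export
impute_gap <- function(series, month) {
  month <- as_month(month)
  i <- match(month, series$month)
  if (is.na(i)) stop("month ", format(month, "%Y-%m"), " not in series")
  if (i == 1L || i == nrow(series)) {
    stop("cannot impute the first or last month of a series")
  }
  left <- series$value[i - 1L]
  right <- series$value[i + 1L]
  if (is.na(left) || is.na(right)) {
    stop("neighbouring month missing; refusing chained imputation")
  }
  series$value[i] <- (left + right) / 2
  series
}

#' Three-period partition of the study window
#'
#' Markets under changing legislation are analysed in contiguous periods.
#' The default partition follows the study design: an Early period through
#' March 2003, a Pre-ban period from April 2003, and a Post-ban period
#' opened by the November 2007 primate hunting ban.
#'
#' @param breakpoints Two months, each opening its period.
#' @param labels Period labels, one more than breakpoints.
#' @return An object of class `period_partition`.
#' @export
period_partition <- function(breakpoints = c("2003-04", "2007-11"),
                             labels = c("Early", "Pre-ban", "Post-ban")) {
  breakpoints <- as_month(breakpoints)
  if (is.unsorted(breakpoints, strictly = TRUE)) {
    stop("breakpoints must be strictly increasing")
  }
  if (length(labels) != length(breakpoints) + 1L) {
    stop("need one more label than breakpoints")
  }
  structure(list(breakpoints = breakpoints, labels = labels),
            class = "period_partition")
}

#' Label each month of a series with its period
#'
#' @param series A [monthly_series()] (or any tibble with a `month`
#'   column).
#' @param partition A [period_partition()]; breakpoints must fall inside
#'   the series range.
#' @return The input with a `period` factor column added.
#' @export
assign_periods <- function(series, partition = period_partition()) {
  stopifnot(inherits(partition, "period_partition"))
  rng <- range(series$month)
  if (any(partition$breakpoints <= rng[1]) ||
      any(partition$breakpoints > rng[2])) {
    stop("breakpoints must lie inside the series window")
  }
  idx <- findInterval(as.numeric(series$month),
                      as.numeric(partition$breakpoints)) + 1L
  series$period <- factor(partition$labels[idx], levels = partition$labels)
  series
}

#' Market summary: counts, biomass and shares
#'
#' Per-species and per-group totals of carcass counts and biomass
#' (`biomass = n * mass_kg`), plus overall totals and percentage shares of
#' counts and biomass (subtotal / total x 100, reported to 2 decimals).
#' When `records` is supplied, species counts are tallied from it;
#' otherwise the `n` column of the reference is used, which reproduces the
#' published study-wide summary from the packaged reference alone.
#'
#' @param reference A [species_reference()]-shaped tibble (species, group,
#'   mass_kg, n).
#' @param records Optional census records; every species present must
#'   appear in the reference.
#' @return A list of tibbles `species`, `groups`, `overall`.
#' @export
market_summary <- function(reference, records = NULL) {
  ref <- reference
  if (!is.null(records)) {
    seen <- unique(records$species)
    unknown <- seen[!normalize_species(seen) %in%
                      normalize_species(ref$species)]
    if (length(unknown)) {
      stop("species absent from the reference: ",
           paste(unknown, collapse = ", "))
    }
    tab <- table(normalize_species(records$species))
    ref$n <- as.integer(tab[normalize_species(ref$species)])
    ref$n[is.na(ref$n)] <- 0L
  }
  ref$biomass <- ref$n * ref$mass_kg
  total_n <- sum(ref$n)
  total_b <- sum(ref$biomass)
  species <- tibble::tibble(
    species = ref$species, group = ref$group, n = ref$n,
    biomass_kg = ref$biomass,
    share_n_pct = round(100 * ref$n / total_n, 2),
    share_biomass_pct = round(100 * ref$biomass / total_b, 2)
  )
  groups <- species |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n = sum(.data$n), biomass_kg = sum(.data$biomass_kg),
                     .groups = "drop") |>
    dplyr::mutate(
      share_n_pct = round(100 * .data$n / total_n, 2),
      share_biomass_pct = round(100 * .data$biomass_kg / total_b, 2)
    )
  overall <- tibble::tibble(n = total_n, biomass_kg = total_b)
  list(species = species, groups = groups, overall = overall)
}
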