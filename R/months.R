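#' Calendar-month helpers
#'
#' All series in the package live on a monthly grid. A month is represented
#' as a `Date` pinned to its first day; regressions use an integer month
#' index counted from a configurable origin (the first survey month), so
#' that "month 1" is the origin month and indices run consecutively with no
#' gaps. The packaged defaults follow the Malabo study window: origin
#' October 1997, 156 months through September 2010.
#'
#' @param x A `Date`, or a string `"YYYY-MM"` / `"YYYY-MM-DD"`.
#' @return `as_month()` returns a `Date` on the first of the month.
#' @examples
#' as_month("1997-10")
#' month_index(as_month("2007-11"), origin = as_month("1997-10"))
#' @export
as_month <- function(x) {
  if (inherits(x, "Date")) {
    return(as.Date(format(x, "%Y-%m-01")))
  }
  x <- as.character(x)
  x <- ifelse(grepl("^\\d{4}-\\d{2}$", x), paste0(x, "-01"), x)
  out <- as.Date(x)
  if (anyNA(out)) {
    stop("cannot parse month(s): ", paste(x[is.na(out)], collapse = ", "))
  }
  as.Date(format(out, "%Y-%m-01"))
}

#' @rdname as_month
#' @param month,origin Months (coerced with [as_month()]).
#' @return `month_index()` returns the 1-based integer index of `month`
#'   counted from `origin`.
#' @export
month_index <- function(month, origin = study_origin()) {
  month <- as_month(month)
  origin <- as_month(origin)
  ym <- as.integer(format(month, "%Y")) * 12L + as.integer(format(month, "%m"))
  yo <- as.integer(format(origin, "%Y")) * 12L + as.integer(format(origin, "%m"))
  ym - yo + 1L
}

#' @rdname as_month
#' @param index Integer month index (1 = origin month).
#' @return `index_month()` returns the `Date` for an index.
#' @export
index_month <- function(index, origin = study_origin()) {
  origin <- as_month(origin)
  y <- as.integer(format(origin, "%Y"))
  m <- as.integer(format(origin, "%m")) + as.integer(index) - 1L
  as.Date(sprintf("%04d-%02d-01", y + (m - 1L) %/% 12L, (m - 1L) %% 12L + 1L))
}

#' @rdname as_month
#' @param from First month.
#' @param n Number of consecutive months.
#' @return `month_seq()` returns a `Date` vector of `n` consecutive months.
#' @export
month_seq <- function(from, n) {
  index_month(seq_len(n), origin = from)
}

#' @rdname as_month
#' @return `study_origin()` returns the default series origin,
#'   1 October 1997.
#' @export
study_origin <- function() as.Date("1997-10-01")

# Taxonomic aggregation groups used throughout the package.
taxon_groups <- function() {
  c("avian", "primate", "reptile", "rodent", "ungulate", "other")
}

# Evaluate an expression while muffling R's "essentially perfect fit"
# warning, which noise-free reference inputs trigger by design.
muffle_perfect_fit <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
}

# Derive a reproducible sub-seed for a named pipeline stage from one root
# seed. Kept below 2^31 so it is always a valid R integer seed.
substream_seed <- function(seed, stage) {
  offsets <- c(
    census = 101L, series = 211L, noise = 307L, bootstrap = 401L,
    anova = 503L, trend = 601L, pipeline = 701L
  )
  off <- offsets[[stage]]
  if (is.null(off)) stop("unknown seed substream: ", stage)
  as.integer((as.numeric(seed) * 1009 + off) %% 2147483647)
}
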