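#' Percentile by sorted-order linear interpolation
#'
#' With n sorted values x(1..n) and fraction p, the rank is
#' h = (n - 1) p + 1 and the result interpolates linearly between the
#' bracketing order statistics: x(floor(h)) + (h - floor(h)) *
#' (x(ceiling(h)) - x(floor(h))). The formula is stated explicitly so the
#' aggregation is environment-independent.
#'
#' @param values Non-empty numeric vector.
#' @param p Fraction in (0, 1); the study uses 0.05 (5th percentile).
#' @return The interpolated percentile.
#' @export
percentile <- function(values, p = 0.05) {
  values <- as.numeric(values)
  if (length(values) == 0 || all(is.na(values))) {
    abort("percentile of an empty value set is undefined")
  }
  if (anyNA(values)) {
    abort("percentile input contains missing values")
  }
  if (!(p > 0 && p < 1)) {
    abort("p must lie strictly between 0 and 1")
  }
  x <- sort(values)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

#' Geometric mean
#'
#' `exp(mean(log(values)))`; the standard location estimate for
#' multiplicative toxicological data. Non-positive values are an error -
#' they must be excluded upstream.
#'
#' @param values Numeric vector of strictly positive values.
#' @return The geometric mean.
#' @export
geometric_mean <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0 || anyNA(values) || any(values <= 0)) {
    abort("geometric mean requires a non-empty set of positive values")
  }
  exp(mean(log(values)))
}

#' Geometric standard deviation
#'
#' `exp(sd(log(values)))`; dimensionless spread factor paired with the
#' geometric mean. Returns `NA` for a single value.
#'
#' @param values Numeric vector of strictly positive values.
#' @return The geometric SD.
#' @export
geometric_sd <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0 || anyNA(values) || any(values <= 0)) {
    abort("geometric SD requires a non-empty set of positive values")
  }
  if (length(values) == 1) return(NA_real_)
  exp(sd(log(values)))
}

#' Round to significant digits (half-to-even)
#'
#' Thin, named wrapper around base `signif()` fixing the study's convention
#' of four significant digits applied after all statistics are computed on
#' unrounded values.
#'
#' @param x Numeric vector.
#' @param digits Number of significant digits (default 4).
#' @return Rounded values.
#' @export
signif_round <- function(x, digits = 4) {
  signif(x, digits)
}

# fields collapsed into one delimited string per category for later review
provenance_fields <- function() {
  c(raw_values = "conc_mg_L", endpoints = "endpoint", effects = "effect",
    measurements = "measurement", species = "latin_name",
    durations = "duration", reference_numbers = "reference_number")
}

#' Collapse per-record provenance into one string per category
#'
#' Joins, in input order, the raw mg/L values, endpoints, effects,
#' measurements, species, durations, and reference IDs of the records into
#' one `"; "`-delimited string per category; each collapsed field therefore
#' splits back into exactly n entries. The intra-field delimiter differs
#' from the CSV file delimiter, and the CSV writer quotes fields, so values
#' containing commas survive a file round trip.
#'
#' @param records Non-empty tibble of retained records carrying a
#'   `conc_mg_L` column.
#' @param sep Intra-field delimiter.
#' @return Named list of collapsed strings.
#' @export
collapse_provenance <- function(records, sep = "; ") {
  if (nrow(records) == 0) {
    abort("cannot collapse provenance of zero records")
  }
  duration <- paste0(records$duration_value, " ", records$duration_unit)
  src <- list(
    raw_values = as.character(records$conc_mg_L),
    endpoints = as.character(records$endpoint),
    effects = as.character(records$effect),
    measurements = as.character(records$measurement),
    species = as.character(records$latin_name),
    durations = duration,
    reference_numbers = as.character(records$reference_number)
  )
  lapply(src, paste, collapse = sep)
}

#' Aggregate the records of one chemical x BQE into summary statistics
#'
#' Computes n, the p-quantile (default the 5th percentile), the arithmetic
#' mean, the geometric mean, the median, the minimum, and the maximum of the
#' standardized mg/L concentrations, rounds each statistic to four
#' significant digits (rounding happens after all statistics are computed on
#' the unrounded values), and collapses the provenance fields.
#'
#' @param records Tibble of retained records for a single chemical and BQE,
#'   with a positive `conc_mg_L` column.
#' @param p Aggregation quantile.
#' @param bqe BQE label stored on the summary row (defaults to the records'
#'   ecotoxgroup).
#' @param id Internal chemical ID for the summary row (defaults to the CAS
#'   key).
#' @param digits Significant digits for rounding.
#' @return One-row tibble (an aggregate summary).
#' @export
summarize_chemical <- function(records, p = 0.05, bqe = NULL, id = NULL,
                               digits = 4) {
  if (nrow(records) == 0) {
    abort("no records to summarize")
  }
  if (length(unique(records$cas_number)) != 1) {
    abort("records span more than one chemical; summarize one at a time")
  }
  grp <- unique(records$ecotox_group)
  if (length(grp) != 1) {
    abort("records span more than one species group (BQE)")
  }
  x <- records$conc_mg_L
  if (anyNA(x) || any(x <= 0)) {
    abort("all concentrations must be positive mg/L values")
  }
  prov <- collapse_provenance(records)
  tibble::tibble(
    ID = id %||% records$cas_number[1],
    cas_number = records$cas_number[1],
    bqe = bqe %||% grp,
    n_data_points = length(x),
    EC_P5_mg_L = signif_round(percentile(x, p), digits),
    EC_mean_mg_L = signif_round(mean(x), digits),
    EC_geomean_mg_L = signif_round(geometric_mean(x), digits),
    EC_median_mg_L = signif_round(median(x), digits),
    EC_min_mg_L = signif_round(min(x), digits),
    EC_max_mg_L = signif_round(max(x), digits),
    !!!prov
  )
}

#' Aggregate a filtered set into one summary row per chemical
#'
#' Standardizes concentrations to mg/L (using the molecular-weight lookup for
#' molar units), drops records whose unit cannot be converted (tallied in the
#' `unsupported_units` attribute), and applies [summarize_chemical()] per
#' chemical. Output rows are sorted by internal ID.
#'
#' @param filtered A `filtered_set` from [apply_filters()], or a tibble of
#'   retained records.
#' @param chemicals Chemical list with `cas_key` and internal `ID` columns
#'   (optional; used to attach internal IDs).
#' @param mw Molecular-weight lookup tibble (`cas_key`, `average_mass`), see
#'   [read_mol_weight()].
#' @param p Aggregation quantile; defaults to the criteria's quantile when a
#'   `filtered_set` is given, else 0.05.
#' @return Tibble with one aggregate summary per chemical, plus attributes
#'   `unsupported_units` and `n_unconverted`.
#' @export
aggregate_bqe <- function(filtered, chemicals = NULL, mw = NULL, p = NULL) {
  records <- if (inherits(filtered, "filtered_set")) filtered$records
             else filtered
  if (is.null(p)) {
    p <- if (inherits(filtered, "filtered_set")) filtered$criteria$quantile
         else 0.05
  }
  if (nrow(records) == 0) {
    out <- tibble::tibble()
    attr(out, "unsupported_units") <- table(character(0))
    attr(out, "n_unconverted") <- 0L
    return(out)
  }
  mass <- if (is.null(mw)) NA_real_
          else mw$average_mass[match(records$cas_number, mw$cas_key)]
  conc <- to_mg_per_L(records$conc_value, records$conc_unit, mass)
  unsupported <- attr(conc, "unsupported_units")
  records$conc_mg_L <- as.numeric(conc)
  n_unconverted <- sum(is.na(records$conc_mg_L))
  records <- records[!is.na(records$conc_mg_L), , drop = FALSE]

  ids <- if (!is.null(chemicals)) {
    setNames(as.character(chemicals$ID), chemicals$cas_key)
  } else NULL
  out <- records |>
    dplyr::group_by(.data$cas_number) |>
    dplyr::group_split() |>
    purrr::map(function(chunk) {
      id <- if (!is.null(ids)) ids[[chunk$cas_number[1]]] else NULL
      summarize_chemical(chunk, p = p, id = id)
    }) |>
    dplyr::bind_rows() |>
    dplyr::arrange(.data$ID)
  attr(out, "unsupported_units") <- unsupported
  attr(out, "n_unconverted") <- n_unconverted
  out
}

#' Spread of data-point counts per chemical
#'
#' Reports, for a set of aggregate summaries, the total number of data
#' points and both spread conventions side by side: geometric mean /
#' geometric SD of the per-chemical counts and arithmetic mean / SD.
#'
#' @param summaries Tibble of aggregate summaries.
#' @return One-row tibble with `n_chemicals`, `total_data_points`,
#'   `geo_mean_n`, `geo_sd_n`, `mean_n`, `sd_n`.
#' @export
data_point_spread <- function(summaries) {
  n <- summaries$n_data_points
  tibble::tibble(
    n_chemicals = length(n),
    total_data_points = sum(n),
    geo_mean_n = if (length(n)) geometric_mean(n) else NA_real_,
    geo_sd_n = if (length(n) > 1) geometric_sd(n) else NA_real_,
    mean_n = if (length(n)) mean(n) else NA_real_,
    sd_n = if (length(n) > 1) sd(n) else NA_real_
  )
}
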