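#' Classify an effect concentration against the water-solubility limit
#'
#' Nominal effect concentrations far above a chemical's water solubility are
#' suspect because older studies dosed nominally without measuring exposure.
#' The solubility domain grades each effect concentration `ecx` (mg/L)
#' against the solubility `sw` (mg/L) in half-log steps:
#'
#' * class 3: `ecx <= sw` (within solubility - valid),
#' * class 2: `sw < ecx <= sw * 10^0.5` (up to half a log step above),
#' * class 1: `sw * 10^0.5 < ecx <= sw * 10^1`,
#' * class 0: `ecx > sw * 10^1` (use with caution).
#'
#' The half-log/full-log boundaries are configurable via `steps`.
#'
#' @param ecx Effect concentration(s) in mg/L, > 0.
#' @param sw Solubility in mg/L, > 0 or `NA` (yields `NA` class).
#' @param steps Two increasing log10 offsets delimiting classes 2 and 1.
#' @return Integer vector of classes in `{3, 2, 1, 0}`, `NA` where `sw` is
#'   missing.
#' @export
classify_domain <- function(ecx, sw, steps = c(0.5, 1.0)) {
  if (length(steps) != 2 || diff(steps) <= 0 || steps[1] <= 0) {
    abort("steps must be two increasing positive log10 offsets")
  }
  n <- max(length(ecx), length(sw))
  ecx <- rep_len(as.numeric(ecx), n)
  sw <- rep_len(as.numeric(sw), n)
  if (any(!is.na(ecx) & ecx <= 0) || any(!is.na(sw) & sw <= 0)) {
    abort("effect concentrations and solubilities must be > 0")
  }
  out <- rep(NA_integer_, n)
  ok <- !is.na(ecx) & !is.na(sw)
  out[ok & ecx <= sw] <- 3L
  out[ok & ecx > sw & ecx <= sw * 10^steps[1]] <- 2L
  out[ok & ecx > sw * 10^steps[1] & ecx <= sw * 10^steps[2]] <- 1L
  out[ok & ecx > sw * 10^steps[2]] <- 0L
  out
}

#' Amend aggregate summaries with solubility-domain classes
#'
#' Computes one class per aggregated statistic (P5, mean, geometric mean,
#' median, min, max) from the chemical's solubility profile and appends the
#' class columns to the summary rows. Chemicals without a profile get
#' missing classes. Because [classify_domain()] is non-increasing in the
#' effect concentration, classes weakly decrease from min to max within a
#' row.
#'
#' @param summaries Tibble of aggregate summaries ([aggregate_bqe()]).
#' @param profiles Tibble of solubility profiles with `cas_key` (or
#'   `cas_number`) and `Sw_mg_L` columns ([read_solubility_profiles()]).
#' @param steps Passed to [classify_domain()].
#' @return The summaries with `sol_class_*` columns filled.
#' @export
classify_summary <- function(summaries, profiles, steps = c(0.5, 1.0)) {
  if (nrow(summaries) == 0) return(summaries)
  key <- profiles[["cas_key"]] %||% profiles[["cas_number"]]
  sw <- profiles$Sw_mg_L[match(summaries$cas_number, key)]
  stat_cols <- c(P5 = "EC_P5_mg_L", mean = "EC_mean_mg_L",
                 geomean = "EC_geomean_mg_L", median = "EC_median_mg_L",
                 min = "EC_min_mg_L", max = "EC_max_mg_L")
  for (stat in names(stat_cols)) {
    summaries[[paste0("sol_class_", stat)]] <-
      classify_domain(summaries[[stat_cols[[stat]]]], sw, steps = steps)
  }
  summaries
}

#' Read solubility-predictor output into solubility profiles
#'
#' Parses the delimited export of a water-solubility QSAR (OPERA-style: one
#' row per compound with a log10 mol/L prediction and an applicability-domain
#' column), joins the molecular mass, and derives `Sw_mg_L` via
#' [sw_to_mg_per_L()]. Column names are configurable because predictor
#' exports differ.
#'
#' @param path CSV file.
#' @param mw Molecular-weight lookup (`cas_key`, `average_mass`) or `NULL`
#'   if the file already has a mass column named in `cols`.
#' @param cols Named list mapping the roles `id`, `cas`, `logSw`, `ad`, and
#'   optionally `mw` to column names in the file.
#' @return Tibble with `ID`, `cas_key`, `logSw`, `mw`, `Sw_mg_L`, `ad`.
#' @export
read_solubility_profiles <- function(path, mw = NULL,
                                     cols = list(id = "MoleculeID",
                                                 cas = "CAS",
                                                 logSw = "LogWS_pred",
                                                 ad = "AD_WS")) {
  df <- readr::read_csv(path, col_types = readr::cols(),
                        progress = FALSE, show_col_types = FALSE)
  for (role in c("id", "cas", "logSw")) {
    if (!cols[[role]] %in% names(df)) {
      abort(paste0("solubility output lacks column '", cols[[role]], "'"))
    }
  }
  key <- cas_key(df[[cols$cas]])
  mass <- if (!is.null(cols$mw) && cols$mw %in% names(df)) {
    as.numeric(df[[cols$mw]])
  } else if (!is.null(mw)) {
    mw$average_mass[match(key, mw$cas_key)]
  } else {
    NA_real_
  }
  logSw <- as.numeric(df[[cols$logSw]])
  tibble::tibble(
    ID = as.character(df[[cols$id]]),
    cas_key = key,
    logSw = logSw,
    mw = mass,
    Sw_mg_L = sw_to_mg_per_L(logSw, mass),
    ad = if (cols$ad %in% names(df)) as.character(df[[cols$ad]])
         else NA_character_
  )
}

#' Histogram of solubility-domain classes across summaries
#'
#' Counts, per statistic, how many chemicals fall into each solubility class
#' (the tabulation behind the per-BQE class distribution).
#'
#' @param summaries Classified summaries ([classify_summary()]).
#' @return Tibble with columns `statistic`, `class`, `n`.
#' @export
solubility_class_table <- function(summaries) {
  cls_cols <- grep("^sol_class_", names(summaries), value = TRUE)
  purrr::map_dfr(cls_cols, function(col) {
    cls <- summaries[[col]]
    tab <- table(factor(cls, levels = c(3, 2, 1, 0)), useNA = "ifany")
    tibble::tibble(
      statistic = sub("^sol_class_", "", col),
      class = names(tab),
      n = as.integer(tab)
    )
  })
}
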