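#' Record-selection criteria for one biological quality element
#'
#' Bundles every selection rule the acute-toxicity curation applies to joined
#' release records: water-based dosing, the allowed exposure-duration unit
#' codes and windows, the species group (ecotoxgroup) and habitat, the species
#' selection mode, the accepted effect codes, the acute endpoint families, and
#' the aggregation quantile. Defaults reproduce the published study settings;
#' see [default_criteria()] for the per-BQE presets.
#'
#' The three duration windows must stay mutually consistent
#' (5 d = 120 h = 7200 min) unless `allow_inconsistent_durations = TRUE`.
#'
#' @param ecotoxgroup One of `"Algae"`, `"Crustacean"`, `"Fish"`.
#' @param dosing_group Dosing group label records must carry.
#' @param duration_d,duration_h,duration_m Allowed unit codes counted as
#'   days, hours, and minutes.
#' @param min_d,max_d,min_h,max_h,min_m,max_m Closed duration windows per
#'   unit family.
#' @param habitat Required habitat label.
#' @param species_selection `"all"` or `"standard_test_species"`.
#' @param standard_species Species whitelist (Latin names) used in
#'   `standard_test_species` mode; defaults to the shipped OECD list.
#' @param effects Accepted effect codes (modifier-stripped).
#' @param endpoint_families Two-letter endpoint family prefixes accepted with
#'   a 1-99 level suffix.
#' @param special_endpoints Endpoint codes accepted verbatim.
#' @param quantile Aggregation quantile p in (0, 1).
#' @param drop_censored If `TRUE`, records with censored ("<", ">") or
#'   approximate ("~") concentration qualifiers are rejected at the
#'   concentration criterion (strict mode); default keeps them flagged.
#' @param allow_inconsistent_durations Skip the 5 d = 120 h = 7200 min
#'   consistency check.
#' @return A `filter_criteria` object (named list).
#' @export
filter_criteria <- function(ecotoxgroup,
                            dosing_group = "water_concentration",
                            duration_d = c("d", "dph", "dpf"),
                            duration_h = c("h", "ht", "hph", "hpf", "hv"),
                            duration_m = "mi",
                            min_d = 0, max_d = 5,
                            min_h = 0, max_h = 120,
                            min_m = 0, max_m = 7200,
                            habitat = "Water",
                            species_selection = c("all",
                                                  "standard_test_species"),
                            standard_species = standard_test_species(),
                            effects = c("MOR", "GRO", "POP", "REP", "MPH",
                                        "DEV"),
                            endpoint_families = c("EC", "ED", "EL", "IC",
                                                  "LC", "LD", "LL", "LT"),
                            special_endpoints = c("LOEC", "LETC"),
                            quantile = 0.05,
                            drop_censored = FALSE,
                            allow_inconsistent_durations = FALSE) {
  ecotoxgroup <- match.arg(ecotoxgroup, c("Algae", "Crustacean", "Fish"))
  species_selection <- match.arg(species_selection)
  if (!(quantile > 0 && quantile < 1)) {
    abort("quantile must lie strictly between 0 and 1")
  }
  if (!allow_inconsistent_durations &&
      !(isTRUE(all.equal(max_d * 24, max_h)) &&
        isTRUE(all.equal(max_h * 60, max_m)))) {
    abort(paste0("duration maxima are inconsistent (expect max_d*24 == ",
                 "max_h and max_h*60 == max_m); set ",
                 "allow_inconsistent_durations = TRUE to override"))
  }
  structure(
    list(
      ecotoxgroup = ecotoxgroup,
      dosing_group = dosing_group,
      duration_d = tolower(duration_d),
      duration_h = tolower(duration_h),
      duration_m = tolower(duration_m),
      min_d = min_d, max_d = max_d,
      min_h = min_h, max_h = max_h,
      min_m = min_m, max_m = max_m,
      habitat = habitat,
      species_selection = species_selection,
      standard_species = standard_species,
      effects = toupper(effects),
      endpoint_families = toupper(endpoint_families),
      special_endpoints = toupper(special_endpoints),
      quantile = quantile,
      drop_censored = drop_censored
    ),
    class = "filter_criteria"
  )
}

#' Study-default criteria per biological quality element
#'
#' `Algae`: all species, effects MOR/GRO/POP/REP/MPH/DEV. `Crustacean`:
#' standard test species, the same effects plus ITX (intoxication).
#' `Fish`: standard test species, same effects as algae. All three use
#' water-based dosing, habitat Water, a 0-5 day (0-120 h, 0-7200 min)
#' exposure window, and quantile 0.05.
#'
#' @param ecotoxgroup `"Algae"`, `"Crustacean"`, or `"Fish"`.
#' @param ... Overrides forwarded to [filter_criteria()].
#' @return A `filter_criteria` object.
#' @export
default_criteria <- function(ecotoxgroup, ...) {
  ecotoxgroup <- match.arg(ecotoxgroup, c("Algae", "Crustacean", "Fish"))
  base_effects <- c("MOR", "GRO", "POP", "REP", "MPH", "DEV")
  presets <- list(
    Algae = list(species_selection = "all", effects = base_effects),
    Crustacean = list(species_selection = "standard_test_species",
                      effects = c(base_effects, "ITX")),
    Fish = list(species_selection = "standard_test_species",
                effects = base_effects)
  )
  args <- utils::modifyList(
    c(list(ecotoxgroup = ecotoxgroup), presets[[ecotoxgroup]]),
    list(...)
  )
  do.call(filter_criteria, args)
}

#' Shipped standard-test-species whitelist
#'
#' The acute crustacean and fish selections restrict records to standard test
#' species. The published study relies on a companion whitelist that is not
#' printed; this default ships as an editable plain-text file
#' (`extdata/standard_test_species.txt`) seeded with OECD standard test
#' species, so results in `standard_test_species` mode are configuration-
#' dependent.
#'
#' @param path Optional path to an alternative whitelist (one Latin name per
#'   line, `#` comments allowed).
#' @return Character vector of Latin species names.
#' @export
standard_test_species <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "standard_test_species.txt",
                        package = "ecotoxcurate", mustWork = TRUE)
  }
  x <- readLines(path, warn = FALSE, encoding = "UTF-8")
  x <- trimws(sub("#.*$", "", x))
  x[nzchar(x)]
}

# strip trailing endpoint/effect modifier marks like "*" and "/"
strip_modifiers <- function(code) {
  toupper(sub("[*/~]+$", "", trimws(as.character(code))))
}

#' Does an endpoint code belong to the acute endpoint families?
#'
#' Accepts, after stripping trailing modifier characters (`*`, `/`), the
#' special codes LOEC and LETC, and any family code among EC, ED, EL, IC, LC,
#' LD, LL, LT followed by an integer level 1-99 (so `"LC50"` and `"EC50*"`
#' match, `"LC0"`, `"LC100"`, and `"NOEC"` do not).
#'
#' @param code Character vector of endpoint codes.
#' @param families Accepted family prefixes.
#' @param special Codes accepted verbatim.
#' @return Logical vector.
#' @export
match_endpoint <- function(code,
                           families = c("EC", "ED", "EL", "IC", "LC", "LD",
                                        "LL", "LT"),
                           special = c("LOEC", "LETC")) {
  x <- strip_modifiers(code)
  pat <- paste0("^(", paste(toupper(families), collapse = "|"),
                ")([1-9][0-9]?)$")
  out <- x %in% toupper(special) | grepl(pat, x)
  out[is.na(code)] <- FALSE
  out
}

#' Does an exposure duration fall inside the allowed acute window?
#'
#' True iff the unit code belongs to one of the criteria's day/hour/minute
#' code sets and the value lies in the corresponding closed interval.
#' Missing values or foreign unit codes never match.
#'
#' @param value Numeric duration values.
#' @param unit Duration unit codes.
#' @param criteria A [filter_criteria()] object.
#' @return Logical vector.
#' @export
match_duration <- function(value, unit, criteria) {
  u <- tolower(trimws(as.character(unit)))
  v <- as.numeric(value)
  in_window <- function(sel, lo, hi) sel & !is.na(v) & v >= lo & v <= hi
  out <- in_window(u %in% criteria$duration_d, criteria$min_d,
                   criteria$max_d) |
    in_window(u %in% criteria$duration_h, criteria$min_h, criteria$max_h) |
    in_window(u %in% criteria$duration_m, criteria$min_m, criteria$max_m)
  out & !is.na(u)
}

#' Does an effect code belong to the BQE's accepted set?
#'
#' @param code Character vector of effect codes; trailing modifier marks are
#'   stripped before comparison.
#' @param criteria A [filter_criteria()] object carrying the BQE-specific
#'   effect set (ITX only for Crustacean in the defaults).
#' @return Logical vector.
#' @export
match_effect <- function(code, criteria) {
  out <- strip_modifiers(code) %in% criteria$effects
  out[is.na(code)] <- FALSE
  out
}

# logical species/habitat/ecotoxgroup selector (vectorized over records)
species_selected <- function(records, criteria) {
  grp <- tolower(trimws(records$ecotox_group))
  hab <- tolower(trimws(records$habitat))
  keep <- !is.na(grp) & grp == tolower(criteria$ecotoxgroup) &
    !is.na(hab) & hab == tolower(criteria$habitat)
  if (criteria$species_selection == "standard_test_species") {
    if (length(criteria$standard_species) == 0) {
      abort("standard_test_species mode requires a non-empty whitelist")
    }
    keep <- keep & tolower(trimws(records$latin_name)) %in%
      tolower(criteria$standard_species)
  }
  keep
}

#' Select records by species group, habitat, and species whitelist
#'
#' Keeps records whose ecotoxgroup matches the criteria, whose habitat is the
#' configured one (Water in the defaults), and - in `standard_test_species`
#' mode - whose species is on the whitelist; in `"all"` mode there is no
#' species restriction.
#'
#' @param records Joined records (tibble with `ecotox_group`, `habitat`,
#'   `latin_name` columns).
#' @param criteria A [filter_criteria()] object.
#' @return The retained records.
#' @export
select_species <- function(records, criteria) {
  records[species_selected(records, criteria), , drop = FALSE]
}

#' Apply the full acute-selection rule set to joined records
#'
#' Retains records satisfying all criteria: CAS present in the chemical
#' list, water-based dosing group, species/habitat/ecotoxgroup selection,
#' accepted effect, acute endpoint family, exposure duration inside the
#' window, and a usable numeric concentration (> 0; censored/approximate
#' values are additionally rejected when the criteria say `drop_censored`).
#' Each rejected record is attributed to the first criterion it fails, in
#' the fixed order chemical, dosing, species, effect, endpoint, duration,
#' concentration, so that `retained + sum(rejections) == nrow(records)`.
#'
#' @param records Joined records ([join_records()]).
#' @param chemicals Chemical list ([read_chemical_list()]) or a character
#'   vector of canonical CAS keys.
#' @param criteria A [filter_criteria()] object.
#' @return A `filtered_set`: list with `records` (retained tibble),
#'   `rejections` (named integer vector in attribution order), and
#'   `criteria` (the snapshot used).
#' @export
apply_filters <- function(records, chemicals, criteria) {
  stopifnot(inherits(criteria, "filter_criteria"))
  cas_keys <- if (is.character(chemicals)) cas_key(chemicals)
              else chemicals$cas_key
  checks <- list(
    chemical = !is.na(records$cas_number) & records$cas_number %in% cas_keys,
    dosing = !is.na(records$dosing_group) &
      records$dosing_group == criteria$dosing_group,
    species = species_selected(records, criteria),
    effect = match_effect(records$effect, criteria),
    endpoint = match_endpoint(records$endpoint,
                              families = criteria$endpoint_families,
                              special = criteria$special_endpoints),
    duration = match_duration(records$duration_value,
                              records$duration_unit, criteria),
    concentration = !is.na(records$conc_value) &
      is.finite(records$conc_value) & records$conc_value > 0 &
      (!criteria$drop_censored | records$conc_qualifier == "none")
  )
  fail_at <- rep(NA_character_, nrow(records))
  for (crit in names(checks)) {
    fail_at[is.na(fail_at) & !checks[[crit]]] <- crit
  }
  rejections <- vapply(names(checks),
                       function(crit) sum(fail_at == crit, na.rm = TRUE),
                       integer(1))
  retained <- records[is.na(fail_at), , drop = FALSE]
  structure(
    list(records = retained, rejections = rejections, criteria = criteria),
    class = "filtered_set"
  )
}

#' @export
print.filtered_set <- function(x, ...) {
  cat("<filtered_set> ", nrow(x$records), " record(s) retained for ",
      x$criteria$ecotoxgroup, "\n", sep = "")
  rej <- x$rejections[x$rejections > 0]
  if (length(rej)) {
    cat("rejections:", paste(names(rej), rej, sep = "=", collapse = ", "),
        "\n")
  }
  invisible(x)
}
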