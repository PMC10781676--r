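#' Supported concentration-unit dialect
#'
#' The unit spellings the standardizer understands, after normalization
#' (lower case, micro sign folded to "u"). `kind` is `mass` for units that
#' convert with a fixed factor to mg/L (ppm and ppb are equated to mg/L and
#' ug/L under the dilute aqueous assumption) and `molar` for units that
#' additionally require the molecular mass in g/mol. The table is
#' configuration: pass an edited copy to [to_mg_per_L()] to extend the
#' dialect.
#'
#' @return Tibble with columns `unit`, `kind`, `factor` (mg/L per unit for
#'   `mass`; mg/L per unit per (g/mol) for `molar`).
#' @export
unit_dialect <- function() {
  tibble::tribble(
    ~unit,      ~kind,   ~factor,
    "mg/l",     "mass",  1,
    "g/l",      "mass",  1e3,
    "ug/l",     "mass",  1e-3,
    "ng/l",     "mass",  1e-6,
    "ppm",      "mass",  1,
    "ppb",      "mass",  1e-3,
    "mol/l",    "molar", 1e3,
    "mmol/l",   "molar", 1,
    "umol/l",   "molar", 1e-3,
    "nmol/l",   "molar", 1e-6,
    "mm",       "molar", 1,
    "um",       "molar", 1e-3
  )
}

normalize_unit <- function(unit) {
  u <- tolower(trimws(as.character(unit)))
  u <- gsub("µ|μ", "u", u)  # micro sign / greek mu
  gsub("\\s+", "", u)
}

# dosing group of a record, derived from its concentration unit:
# water-based units -> water_concentration; per-body-weight -> body_weight
classify_dosing_group <- function(unit, dialect = unit_dialect()) {
  u <- normalize_unit(unit)
  dplyr::case_when(
    u %in% dialect$unit ~ "water_concentration",
    grepl("/kg$", u) ~ "body_weight",
    is.na(u) | !nzchar(u) ~ NA_character_,
    TRUE ~ "other"
  )
}

#' Standardize concentration values to mg/L
#'
#' Mass-based units are rescaled (g/L x1000, ug/L x10^-3, ng/L x10^-6; ppm
#' and ppb treated as mg/L and ug/L); molar units are multiplied by the
#' molecular mass (mol/L -> x mw x 1000, mmol/L -> x mw, umol/L -> x mw x
#' 10^-3). A molar unit without a molecular mass, or a unit outside the
#' dialect, yields a missing value; the offending units are tallied in the
#' `unsupported_units` attribute so losses stay auditable.
#'
#' @param value Numeric vector, finite and strictly positive where not `NA`.
#' @param unit Character vector of unit codes (recycled if length 1).
#' @param mw Molecular mass in g/mol (recycled), `NA` where unknown.
#' @param dialect Unit dialect table, see [unit_dialect()].
#' @return Numeric vector of mg/L values (`NA` where unconvertible) with an
#'   `unsupported_units` attribute (named count vector, possibly empty).
#' @export
to_mg_per_L <- function(value, unit, mw = NA_real_, dialect = unit_dialect()) {
  n <- max(length(value), length(unit), length(mw))
  value <- rep_len(as.numeric(value), n)
  unit <- rep_len(as.character(unit), n)
  mw <- rep_len(as.numeric(mw), n)
  if (any(!is.na(value) & (!is.finite(value) | value <= 0))) {
    abort("concentration values must be finite and > 0")
  }
  u <- normalize_unit(unit)
  idx <- match(u, dialect$unit)
  kind <- dialect$kind[idx]
  fac <- dialect$factor[idx]

  out <- rep(NA_real_, n)
  mass <- !is.na(idx) & kind == "mass" & !is.na(value)
  out[mass] <- value[mass] * fac[mass]
  molar <- !is.na(idx) & kind == "molar" & !is.na(value) & !is.na(mw)
  out[molar] <- value[molar] * mw[molar] * fac[molar]

  unsupported <- u[is.na(idx) & !is.na(value)]
  attr(out, "unsupported_units") <-
    if (length(unsupported)) table(unsupported) else table(character(0))
  out
}

#' Convert a log10 solubility (mol/L) to mg/L
#'
#' Water solubility predictors report log Sw in log10 mol/L; the mg/L value
#' is `10^logSw * mw * 1000` with `mw` the average molecular mass in g/mol.
#'
#' @param logSw Numeric vector, log10 of the solubility in mol/L.
#' @param mw Molecular mass in g/mol, must be > 0 where present.
#' @return Solubility in mg/L (`NA` where `mw` is missing).
#' @export
sw_to_mg_per_L <- function(logSw, mw) {
  if (any(!is.na(mw) & mw <= 0)) {
    abort("molecular mass must be > 0")
  }
  ifelse(is.na(mw) | is.na(logSw), NA_real_, 10^logSw * mw * 1000)
}

#' Convert mg/L back to mmol/L
#'
#' Inverse bridge of [mmol_to_mg()]; exact to floating-point precision.
#'
#' @param value Concentration in mg/L, > 0.
#' @param mw Molecular mass in g/mol, > 0.
#' @return Concentration in mmol/L.
#' @export
mg_to_mmol <- function(value, mw) {
  if (any(!is.na(value) & value <= 0) || any(!is.na(mw) & mw <= 0)) {
    abort("values and molecular mass must be > 0")
  }
  value / mw
}
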