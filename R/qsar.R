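#' Back-transform the algae model's a-dimensional prediction to EC50
#'
#' The acute algae QSAR reports, besides a -log10(mmol/L) value, an
#' a-dimensional (box-cox-scale) prediction. A molecular-weight bug in the
#' deployed model version makes the logged value unreliable, so the EC50 is
#' recovered from the a-dimensional value by inverting the box-cox
#' transform with scale constant 0.07:
#' `EC50 [mmol/L] = (a * 0.07 + 1)^(1/0.07)`.
#'
#' @param a Numeric vector of a-dimensional predictions.
#' @return EC50 in mmol/L; `NA` with a warning where `a * 0.07 + 1 <= 0`
#'   (outside the transformation's domain).
#' @export
correct_algae <- function(a) {
  boxcox_backtransform(a, lambda = 0.07, exponent = 1 / 0.07,
                       model = "algae")
}

#' Back-transform the fish model's a-dimensional prediction to EC50
#'
#' Same inverse box-cox construction as [correct_algae()] but with scale
#' constant 0.11: `EC50 [mmol/L] = (a * 0.11 + 1)^exponent`. The published
#' correction prints the exponent 1.0/0.07 (identical to the algae
#' equation) even though box-cox symmetry would suggest 1.0/0.11; the
#' printed value is the default and `exponent = 1/0.11` selects the
#' symmetric reading.
#'
#' @param a Numeric vector of a-dimensional predictions.
#' @param exponent Back-transformation exponent.
#' @return EC50 in mmol/L; `NA` with a warning where the base is
#'   non-positive.
#' @export
correct_fish <- function(a, exponent = 1 / 0.07) {
  boxcox_backtransform(a, lambda = 0.11, exponent = exponent,
                       model = "fish")
}

boxcox_backtransform <- function(a, lambda, exponent, model) {
  a <- as.numeric(a)
  base <- a * lambda + 1
  bad <- !is.na(base) & base <= 0
  if (any(bad)) {
    warn(paste0(sum(bad), " ", model, " prediction(s) outside the ",
                "back-transformation domain (a*", lambda,
                "+1 <= 0); set to missing"))
  }
  out <- rep(NA_real_, length(a))
  ok <- !is.na(base) & base > 0
  out[ok] <- base[ok]^exponent
  out
}

#' Back-transform a -log10(mmol/L) prediction to EC50
#'
#' The acute Daphnia model reports -log10(mmol/L) and no correction equation;
#' its values are back-transformed directly: `EC50 = 10^(-pred)`.
#'
#' @param pred Numeric vector of -log10(mmol/L) predictions.
#' @return EC50 in mmol/L.
#' @export
daphnia_from_neglog <- function(pred) {
  10^(-as.numeric(pred))
}

#' Convert mmol/L to mg/L
#'
#' Unit bridge from the QSAR back-transformations to the mg/L output tables:
#' `mg/L = mmol/L * mw` with `mw` in g/mol.
#'
#' @param ec Concentration in mmol/L, > 0.
#' @param mw Molecular mass in g/mol, > 0; `NA` yields a missing result.
#' @return Concentration in mg/L.
#' @export
mmol_to_mg <- function(ec, mw) {
  n <- max(length(ec), length(mw))
  ec <- rep_len(as.numeric(ec), n)
  mw <- rep_len(as.numeric(mw), n)
  if (any(!is.na(ec) & ec <= 0) || any(!is.na(mw) & mw <= 0)) {
    abort("concentrations and molecular mass must be > 0")
  }
  ifelse(is.na(ec) | is.na(mw), NA_real_, ec * mw)
}

qsar_models <- function() c("algae_EC50", "daphnia_EC50", "fish_EC50")

#' Parse acute-toxicity QSAR outputs and apply the corrections
#'
#' Reads the delimited per-model exports (one row per compound with the
#' -log10(mmol/L) prediction, the a-dimensional value, and the
#' applicability-domain assessment), applies the model-specific
#' back-transformation ([correct_algae()], [correct_fish()],
#' [daphnia_from_neglog()]), and optionally converts to mg/L via the
#' molecular-weight lookup. Applicability-domain text passes through
#' verbatim. A compound absent from a model's output simply has no
#' prediction; a compound duplicated within one model file is an error.
#'
#' @param paths Named character vector or list mapping model labels
#'   (`algae_EC50`, `daphnia_EC50`, `fish_EC50`) to file paths.
#' @param mw Optional molecular-weight lookup (`cas_key`, `average_mass`).
#' @param cols Named list mapping roles `id`, `cas`, `neg_log`,
#'   `a_dimensional`, `ad` to column names in the files.
#' @param fish_exponent Exponent forwarded to [correct_fish()].
#' @return Tibble with one row per compound x model: `ID`, `cas_key`,
#'   `model`, `neg_log_mmol_L`, `a_dimensional`, `ad`, `EC50_mmol_L`,
#'   `EC50_mg_L` (`NA` without molecular mass).
#' @export
parse_qsar_outputs <- function(paths, mw = NULL,
                               cols = list(id = "ID", cas = "CAS",
                                           neg_log = "prediction",
                                           a_dimensional = "a_dimensional",
                                           ad = "AD"),
                               fish_exponent = 1 / 0.07) {
  paths <- as.list(paths)
  unknown <- setdiff(names(paths), qsar_models())
  if (length(unknown) > 0 || is.null(names(paths)) ||
      any(!nzchar(names(paths)))) {
    abort(paste0("unknown QSAR model label(s): ",
                 paste(unknown, collapse = ", "),
                 "; expected ", paste(qsar_models(), collapse = ", ")))
  }
  purrr::map_dfr(names(paths), function(model) {
    df <- readr::read_csv(paths[[model]], col_types = readr::cols(),
                          progress = FALSE, show_col_types = FALSE)
    for (role in c("id", "neg_log", "a_dimensional")) {
      if (!cols[[role]] %in% names(df)) {
        abort(paste0("QSAR output for ", model, " lacks column '",
                     cols[[role]], "'"))
      }
    }
    if (anyDuplicated(df[[cols$id]])) {
      abort(paste0("duplicated compound in ", model,
                   " output: ambiguous prediction"))
    }
    a <- as.numeric(df[[cols$a_dimensional]])
    ec_mmol <- switch(
      model,
      algae_EC50 = correct_algae(a),
      fish_EC50 = correct_fish(a, exponent = fish_exponent),
      daphnia_EC50 = daphnia_from_neglog(as.numeric(df[[cols$neg_log]]))
    )
    key <- if (cols$cas %in% names(df)) cas_key(df[[cols$cas]])
           else NA_character_
    mass <- if (!is.null(mw)) mw$average_mass[match(key, mw$cas_key)]
            else NA_real_
    tibble::tibble(
      ID = as.character(df[[cols$id]]),
      cas_key = key,
      model = model,
      neg_log_mmol_L = as.numeric(df[[cols$neg_log]]),
      a_dimensional = a,
      ad = if (cols$ad %in% names(df)) as.character(df[[cols$ad]])
           else NA_character_,
      EC50_mmol_L = ec_mmol,
      EC50_mg_L = ifelse(is.na(ec_mmol) | is.na(mass), NA_real_,
                         ec_mmol * mass)
    )
  })
}
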