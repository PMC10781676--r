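#' Read an ECOTOX-style release archive
#'
#' Loads the pipe-delimited ASCII tables of an ECOTOX knowledgebase release.
#' `path` may be the release `.zip` archive or an already-unpacked directory;
#' tables are located as `<name>.txt` anywhere below `path` (releases nest the
#' tables in a top-level folder named after the version). Files are read as
#' UTF-8 with a Latin-1 fallback for legacy releases, and all header names are
#' normalized to lower case.
#'
#' @param path Path to a `.zip` archive or a directory containing the tables.
#' @param tables Character vector of table names to load.
#' @param lenient If `FALSE` (default), a row whose field count does not match
#'   the header aborts with its line number; if `TRUE`, such rows are dropped
#'   and recorded in the `skipped` attribute of the affected table.
#' @return An object of class `raw_tables`: a named list with one tibble per
#'   requested table (all columns character) plus a `release_tag` field
#'   carrying the archive identifier.
#' @export
read_ecotox_archive <- function(path,
                                tables = c("tests", "results", "species",
                                           "chemicals", "references"),
                                lenient = FALSE) {
  if (!file.exists(path)) {
    abort(paste0("archive not found: ", path))
  }
  root <- path
  if (!dir.exists(path)) {
    root <- file.path(tempfile("ecotox_release_"))
    dir.create(root)
    utils::unzip(path, exdir = root)
  }
  available <- list.files(root, pattern = "\\.txt$", recursive = TRUE,
                          full.names = TRUE)
  names(available) <- sub("\\.txt$", "", basename(available))

  missing <- setdiff(tables, names(available))
  if (length(missing) > 0) {
    abort(paste0(
      "table(s) not found in archive: ", paste(missing, collapse = ", "),
      "; available: ", paste(sort(names(available)), collapse = ", ")
    ))
  }

  out <- lapply(tables, function(tab) {
    read_pipe_table(available[[tab]], lenient = lenient)
  })
  names(out) <- tables
  structure(
    c(out, list(release_tag = sub("\\.zip$", "", basename(path)))),
    class = "raw_tables"
  )
}

# Read one pipe-delimited table with strict field-count checking.
# ECOTOX releases quote embedded delimiters with double quotes.
read_pipe_table <- function(file, lenient = FALSE) {
  enc <- if (all(validUTF8(readLines(file, warn = FALSE,
                                     encoding = "bytes")))) {
    "UTF-8"
  } else {
    "latin1"
  }
  # field-count issues are handled explicitly via problems() below
  df <- suppressWarnings(readr::read_delim(
    file,
    delim = "|",
    quote = "\"",
    col_types = readr::cols(.default = readr::col_character()),
    locale = readr::locale(encoding = enc),
    trim_ws = TRUE,
    na = c("", "NA"),
    progress = FALSE,
    show_col_types = FALSE
  ))
  names(df) <- tolower(names(df))
  probs <- readr::problems(df)
  bad <- probs[grepl("columns", probs$expected), , drop = FALSE]
  if (nrow(bad) > 0) {
    if (!lenient) {
      abort(paste0(
        "malformed row(s) in ", basename(file), " at line(s): ",
        paste(bad$row + 1L, collapse = ", ")
      ))
    }
    df <- df[-bad$row, , drop = FALSE]
    attr(df, "skipped") <- bad$row + 1L
  }
  df
}

#' Join the release tables into one record per effect observation
#'
#' Joins `results` to `tests` by `test_id`, then attaches species, chemical,
#' and reference attributes by `species_number`, `cas_number`, and
#' `reference_number`. Rows whose keys do not resolve are dropped and counted
#' in the join report (real releases contain dangling keys); duplicated
#' primary keys in a lookup table are an error because the join would be
#' ambiguous. Concentration fields are split into a numeric value and a
#' qualifier flag (`none`, `censored_above` for ">", `censored_below` for
#' "<", `approximate` for "~"); non-numeric remnants such as "NR" become
#' missing values.
#'
#' @param raw A `raw_tables` object from [read_ecotox_archive()].
#' @return A tibble of joined records (class `joined_records`) with one row
#'   per resolvable results row, and a `join_report` attribute listing orphan
#'   counts per join step.
#' @export
join_records <- function(raw) {
  stopifnot(inherits(raw, "raw_tables"))
  tests <- raw$tests
  results <- raw$results
  species <- raw$species
  chemicals <- raw$chemicals
  references <- raw$references

  # real releases name the chemical key on tests "test_cas"
  if (!"cas_number" %in% names(tests) && "test_cas" %in% names(tests)) {
    tests <- dplyr::rename(tests, cas_number = "test_cas")
  }
  need <- function(df, cols, tab) {
    miss <- setdiff(cols, names(df))
    if (length(miss) > 0) {
      abort(paste0("table '", tab, "' lacks key column(s): ",
                   paste(miss, collapse = ", ")))
    }
  }
  need(results, "test_id", "results")
  need(tests, c("test_id", "cas_number", "species_number",
                "reference_number"), "tests")
  need(species, "species_number", "species")
  need(chemicals, "cas_number", "chemicals")
  need(references, "reference_number", "references")

  check_unique <- function(df, key, tab) {
    if (anyDuplicated(df[[key]])) {
      abort(paste0("duplicate ", key, " in lookup table '", tab,
                   "': join would be ambiguous"))
    }
  }
  check_unique(tests, "test_id", "tests")
  check_unique(species, "species_number", "species")
  check_unique(chemicals, "cas_number", "chemicals")
  check_unique(references, "reference_number", "references")

  n0 <- nrow(results)
  joined <- dplyr::inner_join(results, tests, by = "test_id",
                              suffix = c("", ".test"))
  orphan_tests <- n0 - nrow(joined)
  n1 <- nrow(joined)
  joined <- dplyr::inner_join(joined, species, by = "species_number",
                              suffix = c("", ".species"))
  orphan_species <- n1 - nrow(joined)
  n2 <- nrow(joined)
  joined <- dplyr::inner_join(joined, chemicals, by = "cas_number",
                              suffix = c("", ".chem"))
  orphan_chemicals <- n2 - nrow(joined)
  n3 <- nrow(joined)
  joined <- dplyr::inner_join(joined, references, by = "reference_number",
                              suffix = c("", ".ref"))
  orphan_references <- n3 - nrow(joined)

  conc <- parse_concentration(joined[["conc1_mean"]])
  out <- tibble::tibble(
    test_id = joined$test_id,
    cas_number = cas_key(joined$cas_number),
    species_number = joined$species_number,
    reference_number = joined$reference_number,
    ecotox_group = joined[["ecotox_group"]],
    habitat = joined[["habitat"]],
    latin_name = joined[["latin_name"]],
    endpoint = joined[["endpoint"]],
    effect = joined[["effect"]],
    measurement = joined[["measurement"]],
    conc_value = conc$value,
    conc_qualifier = conc$qualifier,
    conc_unit = joined[["conc1_unit"]],
    duration_value = suppressWarnings(
      as.numeric(joined[["obs_duration_mean"]])),
    duration_unit = joined[["obs_duration_unit"]]
  )
  out$dosing_group <- classify_dosing_group(out$conc_unit)
  attr(out, "join_report") <- list(
    input_results = n0,
    joined = nrow(out),
    orphans = c(tests = orphan_tests, species = orphan_species,
                chemicals = orphan_chemicals, references = orphan_references)
  )
  class(out) <- c("joined_records", class(out))
  out
}

#' Split concentration strings into numeric value and qualifier flag
#'
#' @param x Character vector as stored in the release (e.g. `"1.2"`,
#'   `">100"`, `"~5"`, `"NR"`).
#' @return A tibble with columns `value` (numeric, `NA` where not parseable)
#'   and `qualifier` (`none`, `censored_above`, `censored_below`,
#'   `approximate`).
#' @export
parse_concentration <- function(x) {
  x <- trimws(as.character(x))
  qualifier <- dplyr::case_when(
    grepl("^>", x) ~ "censored_above",
    grepl("^<", x) ~ "censored_below",
    grepl("^~", x) ~ "approximate",
    TRUE ~ "none"
  )
  stripped <- sub("^[><~]\\s*", "", x)
  stripped <- sub("[*/]+$", "", stripped)  # trailing annotation marks
  value <- suppressWarnings(as.numeric(stripped))
  value[!is.finite(value)] <- NA_real_
  qualifier[is.na(value)] <- "none"
  tibble::tibble(value = value, qualifier = qualifier)
}

#' Canonical CAS matching key
#'
#' Strips hyphens and any other non-digit characters so that `"1912-24-9"`
#' and `"1912249"` map to the same key. Leading zeros are preserved. Empty
#' results become `NA`.
#'
#' @param x Character or numeric vector of CAS registry numbers.
#' @return Character vector of digits-only keys.
#' @export
cas_key <- function(x) {
  key <- gsub("[^0-9]", "", as.character(x))
  key[!nzchar(key) | is.na(x)] <- NA_character_
  key
}

#' Read the study chemical list
#'
#' Reads a delimiter-separated chemical inventory (schema:
#' internal ID, name, CAS, PubChem CID, DTXSID, InChIKey, SMILES, QSAR-ready
#' SMILES, average molecular mass). CAS numbers are normalized to the
#' digits-only canonical key in a `cas_key` column; entries without a CAS are
#' retained (they simply cannot match release records).
#'
#' @param path CSV file with a header.
#' @param id_col Name of the internal identifier column.
#' @return Tibble of chemical entries.
#' @export
read_chemical_list <- function(path, id_col = "ID") {
  df <- readr::read_csv(path, col_types = readr::cols(),
                        progress = FALSE, show_col_types = FALSE)
  if (!id_col %in% names(df)) {
    abort(paste0("chemical list lacks identifier column '", id_col, "'"))
  }
  if (anyDuplicated(df[[id_col]])) {
    abort("duplicate internal IDs in chemical list")
  }
  cas_col <- intersect(c("CAS", "cas", "cas_number"), names(df))[1]
  if (is.na(cas_col)) {
    abort("chemical list lacks a CAS column (CAS/cas/cas_number)")
  }
  df$cas_key <- cas_key(df[[cas_col]])
  mass_col <- intersect(c("average_mass", "avg_mol_mass", "molecular_weight",
                          "mol_weight"), names(df))[1]
  if (!is.na(mass_col)) {
    df[[mass_col]] <- suppressWarnings(as.numeric(df[[mass_col]]))
    if (any(!is.na(df[[mass_col]]) & df[[mass_col]] <= 0)) {
      abort("molecular mass must be > 0 where present")
    }
  }
  df
}

#' Read the molecular-weight lookup table
#'
#' Expects the `ecotoxgroup_mol_weight.csv` layout: a CAS column and an
#' average molecular mass column (g/mol).
#'
#' @param path CSV file.
#' @return Tibble with `cas_key` and `average_mass` columns.
#' @export
read_mol_weight <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(),
                        progress = FALSE, show_col_types = FALSE)
  cas_col <- intersect(c("cas_number", "CAS", "cas"), names(df))[1]
  mass_col <- intersect(c("average_mass", "avg_mol_mass", "mol_weight",
                          "molecular_weight"), names(df))[1]
  if (is.na(cas_col) || is.na(mass_col)) {
    abort("molecular-weight table needs a CAS column and a mass column")
  }
  tibble::tibble(
    cas_key = cas_key(df[[cas_col]]),
    average_mass = as.numeric(df[[mass_col]])
  )
}

# column order of the published per-BQE tables (one column per statistic,
# one solubility class per statistic, collapsed provenance fields)
bqe_table_columns <- function() {
  c("ID", "cas_number", "bqe", "n_data_points",
    "EC_P5_mg_L", "EC_mean_mg_L", "EC_geomean_mg_L", "EC_median_mg_L",
    "EC_min_mg_L", "EC_max_mg_L",
    "sol_class_P5", "sol_class_mean", "sol_class_geomean",
    "sol_class_median", "sol_class_min", "sol_class_max",
    "raw_values", "endpoints", "effects", "measurements", "species",
    "durations", "reference_numbers")
}

#' Write a per-BQE aggregated toxicity table
#'
#' Writes the aggregate summaries as CSV following the published column
#' dictionary (one column per statistic, one solubility class per statistic,
#' collapsed provenance strings). Reading the file back with
#' [read_bqe_table()] reproduces the summaries exactly.
#'
#' @param summaries Tibble of aggregate summaries (rows sorted by internal
#'   ID), as produced by [aggregate_bqe()] / [classify_summary()].
#' @param path Output CSV path.
#' @export
write_bqe_table <- function(summaries, path) {
  cols <- bqe_table_columns()
  for (col in setdiff(cols, names(summaries))) {
    summaries[[col]] <- if (startsWith(col, "sol_class")) NA_integer_
                        else NA_character_
  }
  summaries <- summaries[, cols]
  readr::write_csv(summaries, path, na = "", progress = FALSE)
  invisible(path)
}

#' Read back a per-BQE aggregated toxicity table
#'
#' @param path CSV written by [write_bqe_table()].
#' @return Tibble with the same columns and types as the written summaries.
#' @export
read_bqe_table <- function(path) {
  readr::read_csv(
    path,
    col_types = readr::cols(
      ID = readr::col_character(),
      cas_number = readr::col_character(),
      bqe = readr::col_character(),
      n_data_points = readr::col_integer(),
      EC_P5_mg_L = readr::col_double(),
      EC_mean_mg_L = readr::col_double(),
      EC_geomean_mg_L = readr::col_double(),
      EC_median_mg_L = readr::col_double(),
      EC_min_mg_L = readr::col_double(),
      EC_max_mg_L = readr::col_double(),
      sol_class_P5 = readr::col_integer(),
      sol_class_mean = readr::col_integer(),
      sol_class_geomean = readr::col_integer(),
      sol_class_median = readr::col_integer(),
      sol_class_min = readr::col_integer(),
      sol_class_max = readr::col_integer(),
      .default = readr::col_character()
    ),
    na = "",
    progress = FALSE, show_col_types = FALSE
  )
}
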