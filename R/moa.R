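#' Controlled vocabularies for the annotation catalog
#'
#' The curated catalog constrains two columns to controlled vocabularies:
#' eight use-group categories and 32 broad mode-of-action categories. Both
#' ship as editable plain-text lists under `extdata/`; the broad-MoA defaults
#' are an illustrative system-level set since the full published vocabulary
#' travels with the catalog itself. Matching elsewhere is case- and
#' whitespace-insensitive but reported in this canonical casing.
#'
#' @param use_groups,moa_broad Optional paths to alternative vocabulary
#'   files (one entry per line, `#` comments allowed).
#' @return List with character vectors `use_groups` (8 entries) and
#'   `moa_broad` (32 entries).
#' @export
controlled_vocabulary <- function(use_groups = NULL, moa_broad = NULL) {
  read_vocab <- function(path, default) {
    if (is.null(path)) {
      path <- system.file("extdata", default, package = "ecotoxcurate",
                          mustWork = TRUE)
    }
    x <- readLines(path, warn = FALSE, encoding = "UTF-8")
    x <- trimws(sub("#.*$", "", x))
    x <- x[nzchar(x)]
    if (anyDuplicated(tolower(x))) {
      abort(paste0("vocabulary ", basename(path), " has duplicate entries"))
    }
    x
  }
  list(
    use_groups = read_vocab(use_groups, "use_group_categories.txt"),
    moa_broad = read_vocab(moa_broad, "moa_broad_categories.txt")
  )
}

#' Split a multi-value annotation field
#'
#' The catalog's separator grammar uses three levels: `","` separates broad
#' application domains (top level, e.g. several use groups), `"+"` separates
#' sectors within a details field (e.g. industrial chemical + insecticide),
#' and `"/"` separates multiple uses within one sector. Tokens are
#' whitespace-trimmed, empty tokens dropped, order preserved.
#'
#' @param field Character vector of raw field values.
#' @param level `"top"`, `"sector"`, or `"within_sector"`.
#' @return For a length-1 `field`, a character vector of tokens; otherwise a
#'   list of token vectors.
#' @export
split_multivalue <- function(field, level = c("top", "sector",
                                              "within_sector")) {
  level <- match.arg(level)
  sep <- switch(level, top = ",", sector = "+", within_sector = "/")
  out <- lapply(as.character(field), function(x) {
    if (is.na(x)) return(character(0))
    tok <- trimws(strsplit(x, sep, fixed = TRUE)[[1]])
    tok[nzchar(tok)]
  })
  if (length(field) == 1) out[[1]] else out
}

#' Read a curated annotation catalog
#'
#' Reads the catalog CSV (one row per compound: identifiers,
#' parent/transformation-product status, use groups, broad/specific MoA
#' lists, molecular targets, non-target alerts, source). The
#' `parent_or_TP` column is normalized to `parent`, `TP`, `parent + TP`
#' (tolerant of spacing around `+`), or `unknown`.
#'
#' @param path CSV file.
#' @param id_col Internal identifier column name.
#' @return Tibble of annotations.
#' @export
read_annotations <- function(path, id_col = "ID") {
  df <- readr::read_csv(path, col_types = readr::cols(),
                        progress = FALSE, show_col_types = FALSE)
  if (!id_col %in% names(df)) {
    abort(paste0("annotation table lacks identifier column '", id_col, "'"))
  }
  if ("parent_or_TP" %in% names(df)) {
    df$parent_or_TP <- normalize_parent_tp(df$parent_or_TP)
  }
  df
}

normalize_parent_tp <- function(x) {
  x <- tolower(gsub("\\s*\\+\\s*", " + ", trimws(as.character(x))))
  out <- dplyr::case_when(
    x == "parent" ~ "parent",
    x == "tp" ~ "TP",
    x == "parent + tp" | x == "tp + parent" ~ "parent + TP",
    TRUE ~ "unknown"
  )
  out
}

# analysis-level merge of the eight curated use groups into the categories
# used in the summary figures
merge_use_group <- function(token) {
  t <- tolower(trimws(token))
  dplyr::case_when(
    t %in% c("pesticide", "biocide") ~ "Pesticide/Biocide",
    t %in% c("pharmaceutical", "drug of abuse") ~
      "Pharmaceutical/Drug of abuse",
    t == "industrial chemical" ~ "Industrial Chemical",
    t == "natural" ~ "Natural",
    t == "food additive" ~ "Food additive",
    t == "metal" ~ "Metal",
    TRUE ~ NA_character_
  )
}

#' Count compounds per use-group category, split by parent vs TP
#'
#' Applies the analysis merges (biocides counted with pesticides, drugs of
#' abuse with pharmaceuticals), assigns compounds whose merged categories
#' still span more than one group to a single `"Multiple use"` bucket,
#' counts `parent + TP` compounds as parents, and tallies parents and
#' transformation products per category. Compounds without any use group
#' fall into `"Unknown"`. Tokens outside the vocabulary are collected in the
#' `unknown_tokens` attribute, never silently dropped.
#'
#' @param annotations Tibble from [read_annotations()].
#' @param vocab Controlled vocabulary list ([controlled_vocabulary()]).
#' @return Tibble with `category`, `parents`, `TPs`, plus attribute
#'   `unknown_tokens`.
#' @export
count_by_use_group <- function(annotations,
                               vocab = controlled_vocabulary()) {
  tokens <- split_multivalue(annotations$use_group, "top")
  if (nrow(annotations) == 1) tokens <- list(tokens)
  known <- tolower(vocab$use_groups)
  unknown_tokens <- character(0)

  category <- vapply(tokens, function(tok) {
    bad <- tok[!tolower(tok) %in% known]
    if (length(bad)) {
      unknown_tokens <<- c(unknown_tokens, bad)
    }
    merged <- unique(stats::na.omit(merge_use_group(tok)))
    if (length(merged) == 0) "Unknown"
    else if (length(merged) > 1) "Multiple use"
    else merged
  }, character(1))

  status <- if ("parent_or_TP" %in% names(annotations)) {
    normalize_parent_tp(annotations$parent_or_TP)
  } else {
    rep("unknown", nrow(annotations))
  }
  is_parent <- status %in% c("parent", "parent + TP")
  is_tp <- status == "TP"

  out <- tibble::tibble(category = category,
                        parent = is_parent, tp = is_tp) |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(parents = sum(.data$parent), TPs = sum(.data$tp),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$parents + .data$TPs))
  attr(out, "unknown_tokens") <- unique(unknown_tokens)
  out
}

#' Count compounds per mode-of-action category
#'
#' Two tabulations with the summary-figure semantics: `single` counts
#' compounds assigned to exactly one category (compounds with multiple or
#' unknown MoA are excluded, as in the published figures), `assignments`
#' counts every category assignment including multi-MoA compounds. `multi`
#' and `unknown` tally the excluded compounds, so
#' `sum(single$n) + multi + unknown == nrow(annotations)`.
#'
#' @param annotations Tibble from [read_annotations()].
#' @param level `"broad"` (column `MoA_broad`) or `"specific"`
#'   (`MoA_specific`).
#' @return List with `single` (tibble category/n), `assignments` (tibble
#'   category/n), `multi` (count), `unknown` (count).
#' @export
count_by_moa <- function(annotations, level = c("broad", "specific")) {
  level <- match.arg(level)
  col <- if (level == "broad") "MoA_broad" else "MoA_specific"
  if (!col %in% names(annotations)) {
    abort(paste0("annotation table lacks column '", col, "'"))
  }
  tokens <- split_multivalue(annotations[[col]], "top")
  if (nrow(annotations) == 1) tokens <- list(tokens)
  n_tok <- lengths(tokens)

  tally <- function(tok_list) {
    tok <- unlist(tok_list, use.names = FALSE)
    if (length(tok) == 0) {
      return(tibble::tibble(category = character(0), n = integer(0)))
    }
    tibble::tibble(category = tok) |>
      dplyr::count(.data$category, name = "n") |>
      dplyr::arrange(dplyr::desc(.data$n))
  }
  list(
    single = tally(tokens[n_tok == 1]),
    assignments = tally(tokens),
    multi = sum(n_tok > 1),
    unknown = sum(n_tok == 0)
  )
}

#' Validate an annotation catalog against its schema and vocabularies
#'
#' Report-only quality gate: flags use-group and broad-MoA tokens outside
#' the controlled vocabularies, transformation products without a `TP_of`
#' back-reference, duplicated internal IDs, and malformed separators
#' (empty tokens from doubled or dangling delimiters).
#'
#' @param annotations Tibble from [read_annotations()].
#' @param vocab Controlled vocabulary list.
#' @param id_col Internal identifier column name.
#' @return Tibble with columns `type`, `id`, `detail`; zero rows when clean.
#' @export
validate_annotations <- function(annotations,
                                 vocab = controlled_vocabulary(),
                                 id_col = "ID") {
  findings <- list()
  add <- function(type, id, detail) {
    findings[[length(findings) + 1]] <<-
      tibble::tibble(type = type, id = as.character(id), detail = detail)
  }
  ids <- annotations[[id_col]]
  for (dup in unique(ids[duplicated(ids)])) {
    add("duplicate_id", dup, "internal ID occurs more than once")
  }

  check_vocab <- function(col, voc, type) {
    if (!col %in% names(annotations)) return()
    toks <- split_multivalue(annotations[[col]], "top")
    if (nrow(annotations) == 1) toks <- list(toks)
    for (i in seq_along(toks)) {
      bad <- toks[[i]][!tolower(toks[[i]]) %in% tolower(voc)]
      for (b in bad) add(type, ids[i], paste0("token not in vocabulary: '",
                                              b, "'"))
    }
  }
  check_vocab("use_group", vocab$use_groups, "unknown_use_group")
  check_vocab("MoA_broad", vocab$moa_broad, "unknown_moa_broad")

  if (all(c("parent_or_TP", "TP_of") %in% names(annotations))) {
    status <- normalize_parent_tp(annotations$parent_or_TP)
    tp_of <- trimws(as.character(annotations$TP_of))
    incomplete <- status %in% c("TP", "parent + TP") &
      (is.na(tp_of) | !nzchar(tp_of))
    for (i in which(incomplete)) {
      add("tp_without_parent", ids[i],
          "transformation product lacks TP_of back-reference")
    }
  }

  sep_cols <- intersect(c("use_group", "MoA_broad", "MoA_specific"),
                        names(annotations))
  for (col in sep_cols) {
    raw <- as.character(annotations[[col]])
    malformed <- !is.na(raw) &
      grepl("(^\\s*,)|(,\\s*,)|(,\\s*$)", raw)
    for (i in which(malformed)) {
      add("malformed_separator", ids[i],
          paste0("empty token in '", col, "'"))
    }
  }
  if (length(findings) == 0) {
    return(tibble::tibble(type = character(0), id = character(0),
                          detail = character(0)))
  }
  dplyr::bind_rows(findings)
}
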