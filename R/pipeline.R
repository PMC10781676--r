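#' Assemble a pipeline configuration
#'
#' Collects every input path and tunable of one curation run: the release
#' archive (zip or directory), the study chemical list, the molecular-weight
#' lookup, optional solubility and QSAR outputs, an optional annotation
#' catalog, per-BQE selection criteria, and the output directory. Can also
#' be loaded from a YAML file with [read_pipeline_config()].
#'
#' @param archive Path to the release archive or directory.
#' @param chemical_list Path to the chemical-list CSV.
#' @param mol_weight Path to the molecular-weight CSV (optional).
#' @param solubility Path to the solubility-predictor CSV (optional).
#' @param qsar Named list/vector of QSAR output paths keyed by model label
#'   (optional).
#' @param annotations Path to the annotation-catalog CSV (optional).
#' @param out_dir Output directory.
#' @param criteria Named list of [filter_criteria()] per BQE; defaults to
#'   the study presets for Algae, Crustacean, and Fish.
#' @param solubility_steps Log10 boundary offsets for [classify_domain()].
#' @param fish_exponent Exponent for [correct_fish()].
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(archive, chemical_list, mol_weight = NULL,
                            solubility = NULL, qsar = NULL,
                            annotations = NULL, out_dir = "curated_output",
                            criteria = NULL,
                            solubility_steps = c(0.5, 1.0),
                            fish_exponent = 1 / 0.07) {
  if (is.null(criteria)) {
    criteria <- list(Algae = default_criteria("Algae"),
                     Crustacean = default_criteria("Crustacean"),
                     Fish = default_criteria("Fish"))
  }
  structure(
    list(archive = archive, chemical_list = chemical_list,
         mol_weight = mol_weight, solubility = solubility, qsar = qsar,
         annotations = annotations, out_dir = out_dir, criteria = criteria,
         solubility_steps = solubility_steps, fish_exponent = fish_exponent),
    class = "pipeline_config"
  )
}

#' Load a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()]; per-BQE criteria
#' overrides are given as nested key-value blocks under `criteria:` and are
#' forwarded to [default_criteria()].
#'
#' @param path YAML file.
#' @return A `pipeline_config` object.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  criteria <- NULL
  if (!is.null(y$criteria)) {
    criteria <- lapply(names(y$criteria), function(bqe) {
      do.call(default_criteria, c(list(ecotoxgroup = bqe), y$criteria[[bqe]]))
    })
    names(criteria) <- names(y$criteria)
  }
  pipeline_config(
    archive = y$archive, chemical_list = y$chemical_list,
    mol_weight = y$mol_weight, solubility = y$solubility,
    qsar = y$qsar, annotations = y$annotations,
    out_dir = y$out_dir %||% "curated_output",
    criteria = criteria,
    solubility_steps = y$solubility_steps %||% c(0.5, 1.0),
    fish_exponent = y$fish_exponent %||% (1 / 0.07)
  )
}

#' Run the full curation pipeline
#'
#' End-to-end composition of the curation stages: read and join the release
#' tables; per BQE, apply the selection criteria, standardize to mg/L, and
#' aggregate one summary row per chemical; classify each aggregated
#' statistic against predicted solubility; attach corrected QSAR
#' predictions; write one per-BQE output table plus an annotation validation
#' report and a machine-readable run report (record counts per stage, join
#' orphans, unsupported units, solubility class histogram).
#'
#' @param config A `pipeline_config`.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the per-BQE summary tibbles, the run
#'   report, and output file paths.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) inform(paste0(...))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  say("stage ingest: ", config$archive)
  raw <- read_ecotox_archive(config$archive)
  joined <- join_records(raw)
  join_report <- attr(joined, "join_report")
  chemicals <- read_chemical_list(config$chemical_list)
  mw <- if (!is.null(config$mol_weight)) read_mol_weight(config$mol_weight)
        else NULL
  profiles <- if (!is.null(config$solubility)) {
    read_solubility_profiles(config$solubility, mw = mw)
  } else NULL
  predictions <- if (!is.null(config$qsar)) {
    parse_qsar_outputs(config$qsar, mw = mw,
                       fish_exponent = config$fish_exponent)
  } else NULL

  summaries <- list()
  stage_report <- list()
  outputs <- character(0)
  for (bqe in names(config$criteria)) {
    crit <- config$criteria[[bqe]]
    say("stage filter/aggregate: ", bqe)
    fs <- apply_filters(joined, chemicals, crit)
    agg <- aggregate_bqe(fs, chemicals = chemicals, mw = mw)
    if (!is.null(profiles) && nrow(agg) > 0) {
      agg <- classify_summary(agg, profiles,
                              steps = config$solubility_steps)
    }
    if (nrow(agg) > 0) agg$bqe <- bqe
    path <- file.path(config$out_dir,
                      paste0("toxicity_", tolower(bqe), ".csv"))
    write_bqe_table(agg, path)
    outputs <- c(outputs, path)
    summaries[[bqe]] <- agg
    stage_report[[bqe]] <- list(
      input_records = nrow(joined),
      retained = nrow(fs$records),
      rejections = as.list(fs$rejections),
      chemicals_covered = nrow(agg),
      data_points = if (nrow(agg)) sum(agg$n_data_points) else 0L,
      unsupported_units = as.list(attr(agg, "unsupported_units")),
      solubility_classes = if (!is.null(profiles) && nrow(agg) > 0) {
        solubility_class_table(agg)
      } else NULL
    )
  }

  validation <- NULL
  moa_counts <- NULL
  if (!is.null(config$annotations)) {
    say("stage annotations: ", config$annotations)
    ann <- read_annotations(config$annotations)
    validation <- validate_annotations(ann)
    readr::write_csv(validation,
                     file.path(config$out_dir, "annotation_validation.csv"),
                     progress = FALSE)
    moa_counts <- list(
      use_group = count_by_use_group(ann),
      moa_broad = count_by_moa(ann, "broad")
    )
    readr::write_csv(moa_counts$use_group,
                     file.path(config$out_dir, "use_group_counts.csv"),
                     progress = FALSE)
    readr::write_csv(moa_counts$moa_broad$single,
                     file.path(config$out_dir, "moa_broad_counts.csv"),
                     progress = FALSE)
  }

  report <- list(join = join_report, stages = stage_report)
  jsonlite::write_json(
    report, file.path(config$out_dir, "run_report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)

  invisible(list(summaries = summaries, report = report,
                 predictions = predictions, validation = validation,
                 moa_counts = moa_counts, outputs = outputs))
}
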