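#' Specification of a seeded synthetic study
#'
#' Describes a miniature release archive with planted ground truth: per-BQE
#' survivor records with known concentrations, one deliberate violation of
#' each selection criterion, solubility profiles spanning all four domain
#' classes, and plans for the annotation and QSAR fixtures. The seed fully
#' determines every generated byte. Expected statistics in the manifest are
#' computed here with plain base R (`stats::quantile` type 7,
#' `exp(mean(log(x)))`, base `signif`), never with the pipeline's own
#' aggregation code, so fixture tests stay independent of the code they
#' check.
#'
#' @param seed Integer seed.
#' @param n_algae_rich Data points planted for the data-rich algae chemical
#'   (the published catalog's richest algae chemical has 475; default 10
#'   keeps tests fast and any value reproduces the layout).
#' @param n_crustacean,n_fish Data points for the crustacean and fish
#'   chemicals.
#' @param n_annotations Compounds in the annotation fixture.
#' @param n_qsar Compounds per QSAR model output.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1, n_algae_rich = 10, n_crustacean = 6,
                         n_fish = 8, n_annotations = 12, n_qsar = 5) {
  stopifnot(n_algae_rich >= 1, n_crustacean >= 1, n_fish >= 1,
            n_annotations >= 8, n_qsar >= 3)
  structure(
    list(seed = as.integer(seed), n_algae_rich = n_algae_rich,
         n_crustacean = n_crustacean, n_fish = n_fish,
         n_annotations = n_annotations, n_qsar = n_qsar),
    class = "fixture_spec"
  )
}

# format numbers so that read-back reproduces the double exactly
num_chr <- function(x) formatC(x, digits = 17, format = "g")

write_pipe <- function(df, path) {
  readr::write_delim(df, path, delim = "|", na = "", progress = FALSE)
}

# independent reference statistics: base R only, signif(4) applied last
reference_stats <- function(x, p = 0.05, digits = 4) {
  list(
    n = length(x),
    P5 = signif(unname(stats::quantile(x, p, type = 7)), digits),
    mean = signif(mean(x), digits),
    geomean = signif(exp(mean(log(x))), digits),
    median = signif(stats::median(x), digits),
    min = signif(min(x), digits),
    max = signif(max(x), digits)
  )
}

# independent solubility classification: direct inequality evaluation
reference_class <- function(ecx, sw) {
  if (is.na(sw)) return(NA_integer_)
  if (ecx <= sw) 3L
  else if (ecx <= sw * sqrt(10)) 2L
  else if (ecx <= sw * 10) 1L
  else 0L
}

#' Generate a miniature ECOTOX-style release with planted ground truth
#'
#' Writes the five pipe-delimited release tables plus the chemical list,
#' molecular-weight lookup, and solubility-predictor output into `dir`, and
#' returns (and writes as `manifest.json`) the planted truth: per-BQE
#' survivor and rejection counts, reference aggregate statistics per
#' chemical, and solubility classes per statistic.
#'
#' Four chemicals carry survivor records (a data-rich algae chemical, a
#' single-data-point algae chemical, one crustacean, one fish chemical);
#' seven additional fish-context records each violate exactly one selection
#' criterion (unlisted chemical, non-water dosing, non-standard species,
#' excluded effect, excluded endpoint, over-long duration, unparseable
#' concentration).
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @param zip_archive If `TRUE` additionally packs the five release tables
#'   into `release.zip` inside `dir` (requires the zip package).
#' @return Invisibly, the manifest list.
#' @export
generate_ecotox_fixture <- function(spec, dir, zip_archive = FALSE) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec$seed)

  chem <- tibble::tibble(
    ID = c("M1", "M2", "M3", "M4"),
    name = c("simetryn-like herbicide", "phenoxy herbicide",
             "organophosphate insecticide", "azole fungicide"),
    cas = c("1912-24-9", "93-65-2", "2921-88-2", "60207-90-1"),
    average_mass = c(215.68, 214.65, 350.59, 342.22)
  )
  chem$cas_key <- gsub("-", "", chem$cas)
  # an extra chemical present in the release but absent from the study list
  extra_cas <- "50-00-0"

  draw <- function(n, meanlog) signif(stats::rlnorm(n, meanlog, 1), 6)
  vals <- list(
    M1 = draw(spec$n_algae_rich, log(0.05)),  # mg/L
    M2 = draw(1, log(800)),                   # ug/L
    M3 = draw(spec$n_crustacean, log(0.2)),   # mixed mg/L + mmol/L
    M4 = draw(spec$n_fish, log(1.5))          # mg/L
  )
  mw <- setNames(chem$average_mass, chem$ID)
  # mg/L ground truth per chemical (unit conversions done inline)
  mg <- list(
    M1 = vals$M1,
    M2 = vals$M2 * 1e-3,
    M3 = {
      x <- vals$M3
      molar <- seq_along(x) <= min(2, length(x))
      ifelse(molar, x * mw[["M3"]], x)
    },
    M4 = vals$M4
  )

  species <- tibble::tibble(
    species_number = as.character(1:5),
    common_name = c("Green alga", "Water flea", "Zebrafish", "Pumpkinseed",
                    "Honey bee"),
    latin_name = c("Raphidocelis subcapitata", "Daphnia magna",
                   "Danio rerio", "Lepomis gibbosus", "Apis mellifera"),
    ecotox_group = c("Algae", "Crustacean", "Fish", "Fish", "Insect"),
    habitat = c("Water", "Water", "Water", "Water", "Land")
  )

  mk_rows <- function(id, values, units, species_number, endpoint, effect,
                      duration, dur_unit) {
    n <- length(values)
    tibble::tibble(
      chem_id = id, conc = as.character(values),
      unit = rep_len(units, n), species_number = species_number,
      endpoint = rep_len(endpoint, n), effect = rep_len(effect, n),
      duration = rep_len(as.character(duration), n),
      dur_unit = rep_len(dur_unit, n)
    )
  }
  surv <- dplyr::bind_rows(
    mk_rows("M1", num_chr(vals$M1), "mg/L", "1",
            c("EC50", "EC10", "LOEC"), c("POP", "GRO"), "72", "h"),
    mk_rows("M2", num_chr(vals$M2), "ug/L", "1", "EC50", "GRO", "3", "d"),
    mk_rows("M3", num_chr(vals$M3),
            c("mmol/L", "mmol/L", rep("mg/L", max(0, spec$n_crustacean - 2)))
            [seq_len(spec$n_crustacean)],
            "2", c("EC50*", "LC50"), c("ITX", "MOR"), "48", "h"),
    mk_rows("M4", num_chr(vals$M4), "mg/L", "3", c("LC50", "LC10"),
            c("MOR", "MOR/"), "96", "h")
  )
  surv$cas <- chem$cas_key[match(surv$chem_id, chem$ID)]

  viol <- tibble::tibble(
    chem_id = "V", cas = NA_character_,
    conc = num_chr(signif(stats::rlnorm(7, log(1), 0.5), 6)),
    unit = "mg/L", species_number = "3", endpoint = "LC50", effect = "MOR",
    duration = "96", dur_unit = "h",
    violates = c("chemical", "dosing", "species", "effect", "endpoint",
                 "duration", "concentration")
  )
  viol$cas <- gsub("-", "", chem$cas[4])
  viol$cas[viol$violates == "chemical"] <- gsub("-", "", extra_cas)
  viol$unit[viol$violates == "dosing"] <- "mg/kg"
  viol$species_number[viol$violates == "species"] <- "4"
  viol$effect[viol$violates == "effect"] <- "BEH"
  viol$endpoint[viol$violates == "endpoint"] <- "NOEC"
  viol$duration[viol$violates == "duration"] <- "144"
  viol$conc[viol$violates == "concentration"] <- "NR"

  all_rows <- dplyr::bind_rows(surv, viol[, names(surv)[names(surv) %in%
                                                          names(viol)]])
  all_rows$violates <- c(rep(NA_character_, nrow(surv)), viol$violates)
  n_rec <- nrow(all_rows)
  all_rows$test_id <- sprintf("T%03d", seq_len(n_rec))
  all_rows$result_id <- sprintf("R%03d", seq_len(n_rec))
  all_rows$reference_number <- as.character(1000 + (seq_len(n_rec) %% 3))

  tests <- tibble::tibble(
    test_id = all_rows$test_id,
    cas_number = all_rows$cas,
    species_number = all_rows$species_number,
    reference_number = all_rows$reference_number,
    exposure_type = "AQUA",
    test_location = "LAB"
  )
  results <- tibble::tibble(
    result_id = all_rows$result_id,
    test_id = all_rows$test_id,
    endpoint = all_rows$endpoint,
    effect = all_rows$effect,
    measurement = "MORT",
    conc1_type = "A",
    conc1_mean = all_rows$conc,
    conc1_unit = all_rows$unit,
    obs_duration_mean = all_rows$duration,
    obs_duration_unit = all_rows$dur_unit
  )
  chemicals_tab <- tibble::tibble(
    cas_number = c(chem$cas_key, gsub("-", "", extra_cas)),
    chemical_name = c(chem$name, "unlisted formaldehyde-like")
  )
  references <- tibble::tibble(
    reference_number = unique(all_rows$reference_number),
    author = paste0("Author", seq_along(unique(all_rows$reference_number))),
    title = "Acute toxicity study",
    source = "J Synth Ecotox",
    publication_year = "2001"
  )

  write_pipe(tests, file.path(dir, "tests.txt"))
  write_pipe(results, file.path(dir, "results.txt"))
  write_pipe(species, file.path(dir, "species.txt"))
  write_pipe(chemicals_tab, file.path(dir, "chemicals.txt"))
  write_pipe(references, file.path(dir, "references.txt"))

  readr::write_csv(chem[, c("ID", "name", "cas", "average_mass")] |>
                     dplyr::rename(CAS = "cas"),
                   file.path(dir, "chemical_list.csv"), progress = FALSE)
  readr::write_csv(
    tibble::tibble(cas_number = chem$cas, average_mass = chem$average_mass),
    file.path(dir, "mol_weight.csv"), progress = FALSE)

  # plant solubilities so every domain class occurs for any seed:
  # M1 fully soluble (class 3 everywhere), M2 a quarter log step above
  # solubility (class 2), M3 three quarter steps (class 1 at the maximum),
  # M4 one and a half log steps (class 0 at the maximum)
  stats_ref <- lapply(mg, reference_stats)
  sw_mg <- c(
    M1 = stats_ref$M1$max * 2,
    M2 = mg$M2[1] / 10^0.25,
    M3 = stats_ref$M3$max / 10^0.75,
    M4 = stats_ref$M4$max / 10^1.5
  )
  logSw <- log10(sw_mg / (mw[names(sw_mg)] * 1000))
  readr::write_csv(
    tibble::tibble(MoleculeID = names(sw_mg),
                   CAS = chem$cas[match(names(sw_mg), chem$ID)],
                   LogWS_pred = logSw,
                   AD_WS = "inside"),
    file.path(dir, "solubility.csv"), progress = FALSE)

  # independent first-fail attribution per BQE (plain loop, no pipeline code)
  standard <- c("daphnia magna", "ceriodaphnia dubia", "danio rerio",
                "pimephales promelas", "oncorhynchus mykiss")
  listed_cas <- chem$cas_key
  attribution <- function(bqe) {
    rej <- c(chemical = 0L, dosing = 0L, species = 0L, effect = 0L,
             endpoint = 0L, duration = 0L, concentration = 0L)
    kept <- 0L
    for (i in seq_len(n_rec)) {
      row <- all_rows[i, ]
      sp <- species[species$species_number == row$species_number, ]
      eff <- sub("[*/~]+$", "", row$effect)
      ep <- sub("[*/~]+$", "", row$endpoint)
      eff_set <- if (bqe == "Crustacean") {
        c("MOR", "GRO", "POP", "REP", "MPH", "DEV", "ITX")
      } else c("MOR", "GRO", "POP", "REP", "MPH", "DEV")
      dur <- suppressWarnings(as.numeric(row$duration))
      dur_ok <- !is.na(dur) &&
        ((row$dur_unit %in% c("d", "dph", "dpf") && dur <= 5) ||
         (row$dur_unit %in% c("h", "ht", "hph", "hpf", "hv") && dur <= 120) ||
         (row$dur_unit == "mi" && dur <= 7200)) && dur >= 0
    species_ok <- sp$ecotox_group == bqe && sp$habitat == "Water" &&
        (bqe == "Algae" || tolower(sp$latin_name) %in% standard)
      conc_ok <- !is.na(suppressWarnings(as.numeric(row$conc))) &&
        suppressWarnings(as.numeric(row$conc)) > 0
      fail <- if (!(row$cas %in% listed_cas)) "chemical"
        else if (row$unit == "mg/kg") "dosing"
        else if (!species_ok) "species"
        else if (!(eff %in% eff_set)) "effect"
        else if (!(ep %in% c("LOEC", "LETC") ||
                   grepl("^(EC|ED|EL|IC|LC|LD|LL|LT)[1-9][0-9]?$", ep)))
          "endpoint"
        else if (!dur_ok) "duration"
        else if (!conc_ok) "concentration"
        else NA_character_
      if (is.na(fail)) kept <- kept + 1L else rej[fail] <- rej[fail] + 1L
    }
    list(retained = kept, rejections = as.list(rej))
  }

  classes <- lapply(names(mg), function(id) {
    st <- stats_ref[[id]]
    lapply(st[c("P5", "mean", "geomean", "median", "min", "max")],
           reference_class, sw = sw_mg[[id]])
  })
  names(classes) <- names(mg)

  manifest <- list(
    seed = spec$seed,
    chemicals = chem$ID,
    bqe_of_chemical = list(M1 = "Algae", M2 = "Algae", M3 = "Crustacean",
                           M4 = "Fish"),
    filters = list(Algae = attribution("Algae"),
                   Crustacean = attribution("Crustacean"),
                   Fish = attribution("Fish")),
    statistics = stats_ref,
    mg_values = mg,
    sw_mg_L = as.list(sw_mg),
    solubility_classes = classes,
    n_records = n_rec
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  if (zip_archive) {
    if (!requireNamespace("zip", quietly = TRUE)) {
      abort("zip package required for zip_archive = TRUE")
    }
    tabs <- c("tests.txt", "results.txt", "species.txt", "chemicals.txt",
              "references.txt")
    zip::zip(file.path(dir, "release.zip"), tabs, root = dir,
             mode = "cherry-pick")
  }
  invisible(manifest)
}

#' Generate an annotation-catalog fixture with expected count tables
#'
#' Writes a catalog-style `annotations.csv` with a seeded random plan over
#' use groups, parent/TP status, and broad MoA categories (always including
#' one `parent + TP` compound, one biocide, one two-MoA compound, one
#' MoA-unknown compound, and one TP with a `TP_of` back-reference), plus the
#' expected use-group and MoA count tables computed by plain tallying.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory.
#' @return Invisibly, a list with the written annotations and the expected
#'   counts (also written as `annotation_manifest.json`).
#' @export
generate_annotation_fixture <- function(spec, dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec$seed + 1L)
  n <- spec$n_annotations

  moa_pool <- c("Neuroactive", "Endocrine", "Cardiovascular system",
                "Nucleic acid damage", "Photosynthesis inhibition")
  fixed <- tibble::tibble(
    ID = sprintf("A%03d", 1:8),
    parent_or_TP = c("parent", "parent + TP", "TP", "parent", "parent",
                     "parent", "TP", "parent"),
    TP_of = c(NA, "A001", "A001", NA, NA, NA, "A004", NA),
    use_group = c("Pesticide", "Natural", "Pharmaceutical", "Biocide",
                  "Pesticide, Pharmaceutical", "Industrial Chemical",
                  "Pesticide", NA),
    MoA_broad = c("Neuroactive", "Endocrine",
                  "Neuroactive, Cardiovascular system", "Neuroactive",
                  "Endocrine", NA, "Neuroactive", "Nucleic acid damage"),
    use_group_details = c("I/A", "H", "antibiotic", "H",
                          "I + antibiotic", "plasticizer/solvent", "H", NA)
  )
  extra_n <- n - 8L
  extra <- tibble::tibble(
    ID = sprintf("A%03d", 8L + seq_len(extra_n)),
    parent_or_TP = sample(c("parent", "TP"), extra_n, replace = TRUE,
                          prob = c(0.8, 0.2)),
    TP_of = NA_character_,
    use_group = sample(c("Pesticide", "Pharmaceutical",
                         "Industrial Chemical", "Natural"),
                       extra_n, replace = TRUE),
    MoA_broad = sample(c(moa_pool, NA), extra_n, replace = TRUE),
    use_group_details = NA_character_
  )
  extra$TP_of[extra$parent_or_TP == "TP"] <- "A001"
  ann <- dplyr::bind_rows(fixed, extra)
  ann$name <- paste0("compound ", ann$ID)
  ann$MoA_specific <- NA_character_
  ann$molecular_target <- NA_character_
  ann$source <- "synthetic"
  readr::write_csv(ann, file.path(dir, "annotations.csv"), progress = FALSE,
                   na = "")

  # expected counts by plain tallying
  merge_grp <- function(g) {
    if (g %in% c("Pesticide", "Biocide")) "Pesticide/Biocide"
    else if (g %in% c("Pharmaceutical", "Drug of abuse"))
      "Pharmaceutical/Drug of abuse"
    else g
  }
  cat_of <- character(nrow(ann))
  for (i in seq_len(nrow(ann))) {
    toks <- trimws(strsplit(ann$use_group[i] %||% "", ",")[[1]])
    toks <- toks[nzchar(toks)]
    if (is.na(ann$use_group[i]) || length(toks) == 0) {
      cat_of[i] <- "Unknown"
    } else {
      merged <- unique(vapply(toks, merge_grp, character(1)))
      cat_of[i] <- if (length(merged) > 1) "Multiple use" else merged
    }
  }
  is_parent <- ann$parent_or_TP %in% c("parent", "parent + TP")
  use_counts <- lapply(sort(unique(cat_of)), function(cat) {
    list(category = cat,
         parents = sum(cat_of == cat & is_parent),
         TPs = sum(cat_of == cat & ann$parent_or_TP == "TP"))
  })

  moa_tokens <- lapply(ann$MoA_broad, function(x) {
    if (is.na(x)) return(character(0))
    toks <- trimws(strsplit(x, ",")[[1]])
    toks[nzchar(toks)]
  })
  n_tok <- lengths(moa_tokens)
  singles <- unlist(moa_tokens[n_tok == 1])
  single_counts <- lapply(sort(unique(singles)), function(cat) {
    list(category = cat, n = sum(singles == cat))
  })
  expected <- list(
    use_group = use_counts,
    moa_single = single_counts,
    moa_multi = sum(n_tok > 1),
    moa_unknown = sum(n_tok == 0),
    n_annotations = nrow(ann)
  )
  jsonlite::write_json(expected, file.path(dir, "annotation_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(annotations = ann, expected = expected))
}

#' Generate QSAR-model output fixtures with expected corrected values
#'
#' Writes one CSV per acute model (algae, daphnia, fish) in the predictor's
#' export shape and an expectation table computed by direct evaluation of
#' the back-transformations (`exp(k * log(a * lambda + 1))` and
#' `10^(-pred)`), including one compound at a-dimensional 0 (expected EC50
#' exactly 1 mmol/L) and one outside the transformation domain (expected
#' missing).
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory.
#' @return Invisibly, a list with the file paths and the expected values
#'   (also written as `qsar_manifest.json`).
#' @export
generate_qsar_fixture <- function(spec, dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec$seed + 2L)
  n <- spec$n_qsar
  ids <- sprintf("Q%02d", seq_len(n))
  cas <- sprintf("100-%02d-5", seq_len(n))

  a_vals <- c(0, -20, round(stats::rnorm(n - 2, 0, 2), 4))
  neg_log <- round(stats::rnorm(n, 1, 1), 4)

  direct_eval <- function(a, lambda, k) {
    base <- a * lambda + 1
    out <- rep(NA_real_, length(a))
    ok <- base > 0
    out[ok] <- exp(k * log(base[ok]))
    out
  }
  expected <- list(
    algae_EC50 = direct_eval(a_vals, 0.07, 1 / 0.07),
    fish_EC50 = direct_eval(a_vals, 0.11, 1 / 0.07),
    daphnia_EC50 = 10^(-neg_log)
  )

  paths <- list()
  for (model in c("algae_EC50", "daphnia_EC50", "fish_EC50")) {
    path <- file.path(dir, paste0(model, ".csv"))
    readr::write_csv(
      tibble::tibble(ID = ids, CAS = cas, prediction = neg_log,
                     a_dimensional = a_vals,
                     AD = sample(c("inside", "outside"), n, replace = TRUE)),
      path, progress = FALSE)
    paths[[model]] <- path
  }
  manifest <- list(ids = ids, a_dimensional = a_vals, neg_log = neg_log,
                   expected = expected)
  jsonlite::write_json(manifest, file.path(dir, "qsar_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(list(paths = paths), manifest))
}
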