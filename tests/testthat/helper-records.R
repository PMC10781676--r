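# build a joined-records-style tibble with sensible defaults;
# override any field per record
make_records <- function(n = 1, ...) {
  defaults <- list(
    test_id = sprintf("T%03d", seq_len(n)),
    cas_number = "1912249",
    species_number = "3",
    reference_number = "1000",
    ecotox_group = "Fish",
    habitat = "Water",
    latin_name = "Danio rerio",
    endpoint = "LC50",
    effect = "MOR",
    measurement = "MORT",
    conc_value = 1.2,
    conc_qualifier = "none",
    conc_unit = "mg/L",
    duration_value = 96,
    duration_unit = "h"
  )
  args <- utils::modifyList(defaults, list(...))
  out <- tibble::as_tibble(lapply(args, rep_len, n))
  out$dosing_group <- ecotoxcurate:::classify_dosing_group(out$conc_unit)
  out
}

# one shared synthetic study per test run (generation is cheap but not free)
fixture_dir <- local({
  dir <- NULL
  function(seed = 42) {
    if (is.null(dir)) {
      dir <<- file.path(tempdir(), paste0("ecotox_fixture_", seed))
      generate_ecotox_fixture(fixture_spec(seed = seed), dir)
    }
    dir
  }
})

read_manifest <- function(dir) {
  jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
}
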