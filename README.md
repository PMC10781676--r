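# ecotoxcurate

Curation of aquatic effect concentrations and mode-of-action catalogs.

Risk assessment of chemicals in freshwater needs one robust effect
concentration per chemical and species group, but experimental records are
scattered over decades of heterogeneous studies. `ecotoxcurate` turns an
ECOTOX-style knowledgebase release (pipe-delimited ASCII tables) into
curated per-chemical acute toxicity summaries for the three biological
quality elements (BQEs) of the EU Water Framework Directive — algae,
crustaceans, and fish — and provides the data model and summary statistics
for curated use-group / mode-of-action (MoA) annotation catalogs.

The pipeline:

1. **joins** the `tests`, `results`, `species`, `chemicals`, and
   `references` tables by `test_id`, `cas_number`, `species_number`, and
   `reference_number`, dropping and counting dangling keys;
2. **filters** records per BQE: water-based dosing, habitat `Water`,
   standard test species for crustaceans/fish, effects MOR/GRO/POP/REP/
   MPH/DEV (+ ITX for crustaceans), acute endpoints (EC/ED/EL/IC/LC/LD/
   LL/LT 1–99, LOEC, LETC), exposure ≤ 5 d = 120 h = 7200 min, usable
   positive concentration — with each rejection attributed to the first
   failing criterion;
3. **standardizes** concentrations to mg/L (molar units via a molecular
   weight lookup);
4. **aggregates** per chemical: n, 5th percentile
   (rank `h = (n−1)p + 1` linear interpolation, p = 0.05), arithmetic and
   geometric mean, median, min, max — rounded to 4 significant digits
   after computation — plus collapsed provenance fields (raw values,
   endpoints, effects, measurements, species, durations, reference IDs);
5. **classifies** each statistic against predicted water solubility
   (class 3: `EC ≤ Sw`; 2: `≤ Sw·10^0.5`; 1: `≤ Sw·10`; 0: above);
6. **post-processes QSAR predictions**: algae
   `EC50 = (a·0.07+1)^(1/0.07)` mmol/L, fish `(a·0.11+1)^(1/0.07)`
   (exponent configurable to 1/0.11), Daphnia `10^(−pred)`; then mg/L via
   the molecular mass;
7. **summarizes annotation catalogs**: use-group counts (biocides merged
   with pesticides, drugs of abuse with pharmaceuticals, multi-use
   bucketed, `parent + TP` counted as parent) and broad/specific MoA
   counts with single/multi/unknown partitioning, plus a schema and
   vocabulary validation report.

A seeded synthetic-study generator (`fixture_spec()`,
`generate_ecotox_fixture()`, `generate_annotation_fixture()`,
`generate_qsar_fixture()`) emits miniature versions of every input with
planted ground truth, used throughout the test suite.

## Worked example

```r
library(ecotoxcurate)

dir <- tempfile()
spec <- fixture_spec(seed = 1)
generate_ecotox_fixture(spec, dir)

joined <- join_records(read_ecotox_archive(dir))
chem   <- read_chemical_list(file.path(dir, "chemical_list.csv"))
mw     <- read_mol_weight(file.path(dir, "mol_weight.csv"))

fs  <- apply_filters(joined, chem, default_criteria("Algae"))
fs
#> <filtered_set> 11 record(s) retained for Algae
#> rejections: chemical=1, dosing=1, species=19

agg <- aggregate_bqe(fs, chemicals = chem, mw = mw)
agg[, c("ID", "n_data_points", "EC_P5_mg_L", "EC_geomean_mg_L",
        "EC_max_mg_L")]
#> # A tibble: 2 × 5
#>   ID    n_data_points EC_P5_mg_L EC_geomean_mg_L EC_max_mg_L
#>   <chr>         <int>      <dbl>           <dbl>       <dbl>
#> 1 M1               10     0.0218          0.0571       0.246
#> 2 M2                1     3.63            3.63         3.63
```

The `Algae` run keeps the 11 algae records (10 for the data-rich chemical
M1, one for M2); the 21 other records are fish/crustacean records or
planted violations, attributed above to the first criterion each fails.
`EC_P5_mg_L` is the 5th percentile of the mg/L values; all statistics are
rounded to four significant digits. Attaching solubility profiles
(`classify_summary()`) adds one domain class per statistic, and
`run_pipeline()` wires all stages together from a single config (YAML via
`read_pipeline_config()`; a thin CLI lives at `inst/cli/ecotoxcurate`).

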