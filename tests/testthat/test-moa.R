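test_that("multi-value grammar splits per level and is idempotent", {
  expect_equal(split_multivalue("Pesticide, Pharmaceutical", "top"),
               c("Pesticide", "Pharmaceutical"))
  expect_equal(split_multivalue("I/A", "within_sector"), c("I", "A"))
  expect_equal(split_multivalue("I + antibiotic", "sector"),
               c("I", "antibiotic"))
  expect_equal(split_multivalue("", "top"), character(0))
  expect_equal(split_multivalue(NA, "top"), character(0))
  expect_equal(split_multivalue(" a ,, b ", "top"), c("a", "b"))
  # idempotent on the rejoined output
  toks <- split_multivalue("Pesticide, Natural", "top")
  expect_equal(split_multivalue(paste(toks, collapse = ", "), "top"), toks)
})

test_that("use-group counts apply the analysis merges and parent rules", {
  ann <- tibble::tibble(
    ID = paste0("A", 1:7),
    parent_or_TP = c("parent", "parent+TP", "TP", "parent", "parent",
                     "TP", "parent"),
    TP_of = c(NA, NA, "A1", NA, NA, "A4", NA),
    use_group = c("Biocide", "Pesticide", "Pharmaceutical",
                  "Drug of abuse", "Pesticide, Pharmaceutical", "Natural",
                  NA),
    MoA_broad = NA_character_
  )
  counts <- count_by_use_group(ann)
  get <- function(cat, col) counts[[col]][counts$category == cat]
  # biocide merged with pesticide; "parent + TP" tallied as parent
  expect_equal(get("Pesticide/Biocide", "parents"), 2)
  expect_equal(get("Pharmaceutical/Drug of abuse", "parents"), 1)
  expect_equal(get("Pharmaceutical/Drug of abuse", "TPs"), 1)
  expect_equal(get("Multiple use", "parents"), 1)
  expect_equal(get("Natural", "TPs"), 1)
  expect_equal(get("Unknown", "parents"), 1)
  expect_equal(sum(counts$parents) + sum(counts$TPs), nrow(ann))
})

test_that("unknown vocabulary tokens are reported, never dropped", {
  ann <- tibble::tibble(ID = "A1", parent_or_TP = "parent", TP_of = NA,
                        use_group = "Pesticide, Quackery",
                        MoA_broad = "Neuroactive")
  counts <- count_by_use_group(ann)
  expect_equal(attr(counts, "unknown_tokens"), "Quackery")
  expect_equal(sum(counts$parents), 1)  # still counted
})

test_that("MoA counts follow the figure semantics for multi and unknown", {
  ann <- tibble::tibble(
    ID = paste0("A", 1:6),
    parent_or_TP = "parent", TP_of = NA_character_, use_group = "Pesticide",
    MoA_broad = c("Neuroactive", "Neuroactive",
                  "Neuroactive, Cardiovascular system", "Endocrine", NA, "")
  )
  res <- count_by_moa(ann, "broad")
  expect_equal(res$single$n[res$single$category == "Neuroactive"], 2)
  expect_equal(res$single$n[res$single$category == "Endocrine"], 1)
  expect_equal(res$multi, 1)
  expect_equal(res$unknown, 2)
  # partition invariant
  expect_equal(sum(res$single$n) + res$multi + res$unknown, nrow(ann))
  # total assignments include the multi-MoA compound in both categories
  expect_equal(res$assignments$n[res$assignments$category == "Neuroactive"],
               3)
})

test_that("count tables are permutation-invariant over input order", {
  dir <- withr::local_tempdir()
  fx <- generate_annotation_fixture(fixture_spec(seed = 17), dir)
  ann <- fx$annotations
  shuffled <- ann[sample(nrow(ann)), ]
  c1 <- count_by_use_group(ann)
  c2 <- count_by_use_group(shuffled)
  expect_equal(dplyr::arrange(c1, category),
               dplyr::arrange(c2, category), ignore_attr = TRUE)
})

test_that("annotation validation flags schema and vocabulary violations", {
  dir <- withr::local_tempdir()
  fx <- generate_annotation_fixture(fixture_spec(seed = 29), dir)
  clean <- validate_annotations(fx$annotations)
  expect_equal(nrow(clean), 0)

  dirty <- tibble::tibble(
    ID = c("B1", "B1", "B2", "B3"),
    parent_or_TP = c("parent", "parent", "TP", "parent"),
    TP_of = c(NA, NA, NA, NA),
    use_group = c("Pesticide", "Pesticide", "Pharmaceutical",
                  "Pesticide,, Natural"),
    MoA_broad = c("Neuroactiv", NA, "Endocrine", "Narcosis")
  )
  report <- validate_annotations(dirty)
  expect_true("duplicate_id" %in% report$type)
  expect_true("tp_without_parent" %in% report$type)
  expect_true(any(report$type == "unknown_moa_broad" &
                    grepl("Neuroactiv", report$detail)))
  expect_true("malformed_separator" %in% report$type)
})

test_that("vocabularies load with expected sizes and reject duplicates", {
  vocab <- controlled_vocabulary()
  expect_length(vocab$use_groups, 8)
  expect_length(vocab$moa_broad, 32)
  dup <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("Neuroactive", "neuroactive"), dup)
  expect_error(controlled_vocabulary(moa_broad = dup), "duplicate")
})

test_that("annotation fixtures reproduce their emitted expectations", {
  dir <- withr::local_tempdir()
  fx <- generate_annotation_fixture(fixture_spec(seed = 101), dir)
  ann <- read_annotations(file.path(dir, "annotations.csv"))
  counts <- count_by_use_group(ann)
  for (exp_row in fx$expected$use_group) {
    expect_equal(counts$parents[counts$category == exp_row$category],
                 exp_row$parents, info = exp_row$category)
    expect_equal(counts$TPs[counts$category == exp_row$category],
                 exp_row$TPs, info = exp_row$category)
  }
  moa <- count_by_moa(ann, "broad")
  for (exp_row in fx$expected$moa_single) {
    expect_equal(moa$single$n[moa$single$category == exp_row$category],
                 exp_row$n, info = exp_row$category)
  }
  expect_equal(moa$multi, fx$expected$moa_multi)
  expect_equal(moa$unknown, fx$expected$moa_unknown)
})
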