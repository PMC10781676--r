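test_that("endpoint matcher agrees with an enumerated-code oracle", {
  families <- c("EC", "ED", "EL", "IC", "LC", "LD", "LL", "LT")
  valid <- c(paste0(rep(families, each = 99), 1:99), "LOEC", "LETC")
  expect_true(all(match_endpoint(valid)))
  expect_true(all(match_endpoint(paste0(valid, "*"))))
  expect_true(all(match_endpoint(paste0(valid, "/"))))
  invalid <- c(paste0(families, 0), paste0(families, 100), "NOEC", "NOEL",
               "BCF", "LT", "EC", "", NA, "XX50")
  expect_false(any(match_endpoint(invalid)))
  expect_true(match_endpoint("LC50"))
  expect_true(match_endpoint("EC50*"))
  expect_false(match_endpoint("LC0"))
  expect_false(match_endpoint("LC100"))
})

test_that("duration windows are closed intervals over the allowed units", {
  crit <- default_criteria("Fish")
  expect_true(match_duration(96, "h", crit))
  expect_true(match_duration(120, "h", crit))
  expect_false(match_duration(120.5, "h", crit))
  expect_true(match_duration(5, "d", crit))
  expect_false(match_duration(5.01, "d", crit))
  expect_true(match_duration(7200, "mi", crit))
  expect_false(match_duration(7201, "mi", crit))
  expect_true(match_duration(0, "d", crit))
  expect_true(match_duration(4, "dph", crit))
  expect_true(match_duration(24, "hpf", crit))
  expect_false(match_duration(96, "wk", crit))   # foreign unit
  expect_false(match_duration(NA, "h", crit))    # missing value
  expect_false(match_duration(-1, "h", crit))
})

test_that("effect sets are BQE-specific with ITX only for crustaceans", {
  crust <- default_criteria("Crustacean")
  fish <- default_criteria("Fish")
  algae <- default_criteria("Algae")
  expect_true(match_effect("ITX", crust))
  expect_false(match_effect("ITX", fish))
  expect_false(match_effect("ITX", algae))
  for (c in list(crust, fish, algae)) {
    expect_true(match_effect("MOR", c))
    expect_true(match_effect("MOR/", c))
    expect_false(match_effect("BEH", c))
  }
})

test_that("species selection honors habitat, group, and whitelist mode", {
  recs <- make_records(
    6,
    ecotox_group = c("Algae", "Fish", "Fish", "Fish", "Crustacean", "Fish"),
    habitat = c("Water", "Water", "Water", "Land", "Water", "Water"),
    latin_name = c("Raphidocelis subcapitata", "Danio rerio",
                   "Lepomis gibbosus", "Danio rerio", "Daphnia magna",
                   "Pimephales promelas")
  )
  algae <- select_species(recs, default_criteria("Algae"))
  expect_equal(algae$latin_name, "Raphidocelis subcapitata")
  fish <- select_species(recs, default_criteria("Fish"))
  # hand-filtered: rows 2 and 6 (standard fish, Water); row 3 not
  # whitelisted, row 4 wrong habitat
  expect_equal(fish$latin_name, c("Danio rerio", "Pimephales promelas"))
  crust <- select_species(recs, default_criteria("Crustacean"))
  expect_equal(crust$latin_name, "Daphnia magna")
  expect_error(
    select_species(recs, default_criteria(
      "Fish", standard_species = character(0))),
    "whitelist")
})

test_that("composite filter retains compliant records and attributes
           rejections to the first failing criterion", {
  chem <- c("1912249")
  crit <- default_criteria("Fish")
  keep <- make_records(1)
  fs <- apply_filters(keep, chem, crit)
  expect_equal(nrow(fs$records), 1)
  expect_true(all(fs$rejections == 0))

  # same record, duration 144 h -> rejected at duration
  fs2 <- apply_filters(make_records(1, duration_value = 144), chem, crit)
  expect_equal(nrow(fs2$records), 0)
  expect_equal(fs2$rejections[["duration"]], 1)

  # planted single violations, one per criterion
  planted <- dplyr::bind_rows(
    make_records(1),
    make_records(1, cas_number = "999999"),
    make_records(1, conc_unit = "mg/kg"),
    make_records(1, latin_name = "Lepomis gibbosus"),
    make_records(1, effect = "BEH"),
    make_records(1, endpoint = "NOEC"),
    make_records(1, duration_value = 200),
    make_records(1, conc_value = NA_real_)
  )
  fs3 <- apply_filters(planted, chem, crit)
  expect_equal(nrow(fs3$records), 1)
  expect_equal(unname(fs3$rejections),
               c(1L, 1L, 1L, 1L, 1L, 1L, 1L))
  expect_equal(sum(fs3$rejections) + nrow(fs3$records), nrow(planted))
})

test_that("filtering is idempotent and tightening criteria is monotone", {
  set.seed(101)
  n <- 200
  recs <- make_records(
    n,
    cas_number = sample(c("1912249", "93652", "999999"), n, TRUE),
    ecotox_group = sample(c("Fish", "Algae"), n, TRUE),
    habitat = sample(c("Water", "Land"), n, TRUE, prob = c(0.8, 0.2)),
    latin_name = sample(c("Danio rerio", "Lepomis gibbosus",
                          "Oncorhynchus mykiss"), n, TRUE),
    endpoint = sample(c("LC50", "EC10", "NOEC", "LOEC"), n, TRUE),
    effect = sample(c("MOR", "GRO", "BEH", "ITX"), n, TRUE),
    conc_value = stats::rlnorm(n),
    duration_value = sample(c(24, 96, 120, 144), n, TRUE),
    duration_unit = sample(c("h", "d", "wk"), n, TRUE, prob = c(.7, .2, .1))
  )
  chem <- c("1912249", "93652")
  base <- default_criteria("Fish")
  fs <- apply_filters(recs, chem, base)
  again <- apply_filters(fs$records, chem, base)
  expect_equal(again$records, fs$records)
  expect_true(all(again$rejections == 0))

  # fuzzed tightenings: each must not increase the retained count
  tighter <- list(
    default_criteria("Fish", max_h = 96, max_d = 4, max_m = 5760),
    default_criteria("Fish", effects = "MOR"),
    default_criteria("Fish", endpoint_families = c("LC", "EC"),
                     special_endpoints = character(0)),
    default_criteria("Fish", standard_species = "Danio rerio"),
    default_criteria("Fish", drop_censored = TRUE)
  )
  for (crit in tighter) {
    expect_lte(nrow(apply_filters(recs, chem, crit)$records),
               nrow(fs$records))
  }
  expect_lte(nrow(apply_filters(recs, "1912249", base)$records),
             nrow(fs$records))
})

test_that("criteria validate quantile and duration consistency", {
  expect_error(default_criteria("Fish", quantile = 0), "quantile")
  expect_error(default_criteria("Fish", quantile = 1), "quantile")
  expect_error(default_criteria("Fish", max_h = 100), "inconsistent")
  expect_s3_class(
    default_criteria("Fish", max_h = 100,
                     allow_inconsistent_durations = TRUE),
    "filter_criteria")
})
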