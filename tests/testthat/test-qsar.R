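test_that("box-cox back-transformations hit the direct-evaluation oracle", {
  expect_equal(correct_algae(0), 1)
  expect_equal(correct_algae(1), exp((1 / 0.07) * log(1.07)))
  expect_equal(correct_algae(1), 2.6288, tolerance = 1e-4)
  expect_equal(correct_algae(-10), 0.3^(1 / 0.07))
  expect_equal(correct_algae(-10), 3.37e-8, tolerance = 1e-3)

  expect_equal(correct_fish(0), 1)
  expect_equal(correct_fish(1), exp((1 / 0.07) * log(1.11)))
  expect_equal(correct_fish(1), 4.441, tolerance = 1e-4)
  # alternate-exponent reading
  expect_equal(correct_fish(1, exponent = 1 / 0.11),
               exp((1 / 0.11) * log(1.11)))
  expect_equal(correct_fish(1, exponent = 1 / 0.11), 2.582,
               tolerance = 1e-3)

  expect_equal(daphnia_from_neglog(0), 1)
  expect_equal(daphnia_from_neglog(3), 0.001)
  expect_equal(daphnia_from_neglog(-1.3), 19.95, tolerance = 1e-3)
})

test_that("out-of-domain predictions become missing with a warning", {
  expect_warning(res <- correct_algae(c(0, -20)), "domain")
  expect_equal(res, c(1, NA))
  expect_warning(res2 <- correct_fish(-10), "domain")  # base = -0.1
  expect_true(is.na(res2))
})

test_that("corrections are strictly increasing, continuous, and invertible", {
  a <- seq(-14, 20, length.out = 500)  # inside the algae domain
  ec <- correct_algae(a)
  expect_true(all(diff(ec) > 0))
  # inverse round trip: forward box-cox of ec recovers ec
  ec_pos <- stats::rlnorm(200, 0, 2)
  a_inv <- (ec_pos^0.07 - 1) / 0.07
  expect_equal(correct_algae(a_inv), ec_pos, tolerance = 1e-10)
  af <- seq(-9, 20, length.out = 500)
  expect_true(all(diff(correct_fish(af)) > 0))
})

test_that("mmol/mg bridge is exact and validated", {
  expect_equal(mmol_to_mg(1, 100), 100)
  expect_equal(mmol_to_mg(0.5, 200), 100)
  expect_equal(mmol_to_mg(2.6288, 78.11), 205.3, tolerance = 1e-3)
  expect_true(is.na(mmol_to_mg(1, NA)))
  expect_error(mmol_to_mg(-1, 10), "> 0")
  set.seed(3)
  ec <- stats::rlnorm(100)
  mw <- stats::runif(100, 10, 1000)
  expect_equal(mg_to_mmol(mmol_to_mg(ec, mw), mw), ec, tolerance = 1e-12)
})

test_that("QSAR outputs parse per model with corrections applied", {
  dir <- withr::local_tempdir()
  qf <- generate_qsar_fixture(fixture_spec(seed = 9), dir)
  suppressWarnings(
    pred <- parse_qsar_outputs(qf$paths)
  )
  expect_equal(nrow(pred), 3 * length(qf$ids))
  for (model in names(qf$expected)) {
    got <- pred$EC50_mmol_L[pred$model == model]
    expect_equal(got, qf$expected[[model]], tolerance = 1e-12,
                 info = model)
  }
  # a-dimensional zero -> exactly 1 mmol/L; out-of-domain -> missing
  algae <- pred[pred$model == "algae_EC50", ]
  expect_equal(algae$EC50_mmol_L[algae$a_dimensional == 0], 1)
  expect_true(is.na(algae$EC50_mmol_L[algae$a_dimensional == -20]))
  # AD text passes through verbatim
  expect_true(all(pred$ad %in% c("inside", "outside")))

  # unknown model label and duplicated compounds are errors
  expect_error(parse_qsar_outputs(list(frog_EC50 = qf$paths[[1]])),
               "unknown QSAR model")
  dup <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(ID = c("Q1", "Q1"), CAS = "1-11-1",
                                  prediction = c(1, 2),
                                  a_dimensional = c(0, 0), AD = "inside"),
                   dup)
  expect_error(parse_qsar_outputs(list(algae_EC50 = dup)), "ambiguous")

  # mg/L derivation via molecular mass
  mw <- tibble::tibble(cas_key = cas_key("100-01-5"), average_mass = 100)
  suppressWarnings(
    pred_mw <- parse_qsar_outputs(qf$paths["daphnia_EC50"], mw = mw))
  row <- pred_mw[pred_mw$ID == "Q01", ]
  expect_equal(row$EC50_mg_L, row$EC50_mmol_L * 100)
  expect_true(all(is.na(pred_mw$EC50_mg_L[pred_mw$ID != "Q01"])))
})
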