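test_that("percentile follows the (n-1)p+1 interpolation formula", {
  expect_equal(percentile(7, p = 0.05), 7)              # singleton
  expect_equal(percentile(1:100, p = 0.05), 5.95)       # h = 5.95
  expect_equal(percentile(c(10, 20), p = 0.05), 10.5)   # h = 1.05
  expect_equal(percentile(c(20, 10), p = 0.05), 10.5)   # order-free
  expect_error(percentile(numeric(0)), "empty")
  expect_error(percentile(1:3, p = 0), "between")
  expect_error(percentile(1:3, p = 1), "between")
})

test_that("percentile equals the independent order-statistic oracle", {
  set.seed(11)
  for (i in 1:200) {
    n <- sample(1:40, 1)
    x <- stats::rlnorm(n, 0, 2)
    p <- stats::runif(1, 0.01, 0.99)
    expect_equal(percentile(x, p),
                 unname(stats::quantile(x, p, type = 7)),
                 tolerance = 1e-12)
  }
  # limiting behavior: p -> 0 converges to the minimum
  x <- stats::rlnorm(9)
  expect_equal(percentile(x, 1e-9), min(x), tolerance = 1e-6)
  # p = 0.5 with odd n is the middle order statistic
  expect_equal(percentile(x, 0.5), sort(x)[5])
})

test_that("geometric mean and SD behave on exact cases", {
  expect_equal(geometric_mean(c(10, 1000)), 100)
  expect_equal(geometric_mean(42), 42)
  expect_equal(geometric_mean(c(2, 8)), 4)
  expect_error(geometric_mean(c(1, 0)), "positive")
  expect_error(geometric_mean(c(1, -2)), "positive")
  expect_equal(geometric_sd(c(1, 1, 1)), 1)
  expect_true(is.na(geometric_sd(5)))
})

test_that("significant-digit rounding matches a decimal-shift oracle", {
  expect_equal(signif_round(1), 1)
  expect_equal(signif_round(123456), 123500)
  expect_equal(signif_round(0.0123456), 0.01235)
  set.seed(5)
  x <- stats::rlnorm(100, 0, 5)
  shift <- function(v) {
    e <- floor(log10(abs(v)))
    round(v / 10^(e - 3)) * 10^(e - 3)
  }
  expect_equal(signif_round(x), vapply(x, shift, numeric(1)),
               tolerance = 1e-12)
})

test_that("single-chemical aggregation reproduces reference statistics", {
  # degenerate: one record
  r1 <- make_records(1, conc_value = 3.2)
  r1$conc_mg_L <- r1$conc_value
  s1 <- summarize_chemical(r1)
  stats_cols <- c("EC_P5_mg_L", "EC_mean_mg_L", "EC_geomean_mg_L",
                  "EC_median_mg_L", "EC_min_mg_L", "EC_max_mg_L")
  for (col in stats_cols) expect_equal(s1[[col]], 3.2, info = col)
  expect_equal(s1$n_data_points, 1)

  # planted 10-value fixture vs independently computed references
  set.seed(23)
  x <- stats::rlnorm(10, 0, 1.5)
  r <- make_records(10, conc_value = x)
  r$conc_mg_L <- x
  s <- summarize_chemical(r, p = 0.05)
  expect_equal(s$EC_P5_mg_L,
               signif(unname(stats::quantile(x, 0.05, type = 7)), 4))
  expect_equal(s$EC_mean_mg_L, signif(mean(x), 4))
  expect_equal(s$EC_geomean_mg_L, signif(exp(mean(log(x))), 4))
  expect_equal(s$EC_median_mg_L, signif(stats::median(x), 4))
  expect_equal(s$EC_min_mg_L, signif(min(x), 4))
  expect_equal(s$EC_max_mg_L, signif(max(x), 4))

  # two chemicals interleaved violate the precondition
  r2 <- make_records(4, cas_number = c("1", "2", "1", "2"))
  r2$conc_mg_L <- r2$conc_value
  expect_error(summarize_chemical(r2), "one chemical")
})

test_that("provenance collapses in input order with n entries per field", {
  r <- make_records(2, endpoint = c("LC50", "EC50"),
                    conc_value = c(1.5, 2.5))
  r$conc_mg_L <- r$conc_value
  prov <- collapse_provenance(r)
  expect_equal(prov$endpoints, "LC50; EC50")
  expect_equal(strsplit(prov$raw_values, "; ", fixed = TRUE)[[1]],
               c("1.5", "2.5"))

  n <- 475
  big <- make_records(n, conc_value = seq_len(n))
  big$conc_mg_L <- big$conc_value
  prov_big <- collapse_provenance(big)
  for (field in names(prov_big)) {
    expect_length(strsplit(prov_big[[field]], "; ", fixed = TRUE)[[1]], n)
  }
  expect_error(collapse_provenance(big[0, ]), "zero")
})

test_that("aggregate statistics are permutation-invariant and ordered", {
  set.seed(31)
  x <- stats::rlnorm(12, 1, 2)
  r <- make_records(12, conc_value = x)
  r$conc_mg_L <- x
  perm <- r[sample(12), ]
  s <- summarize_chemical(r)
  sp <- summarize_chemical(perm)
  stats_cols <- c("EC_P5_mg_L", "EC_mean_mg_L", "EC_geomean_mg_L",
                  "EC_median_mg_L", "EC_min_mg_L", "EC_max_mg_L")
  expect_equal(s[stats_cols], sp[stats_cols])
  expect_true(s$EC_min_mg_L <= s$EC_P5_mg_L)
  expect_true(s$EC_P5_mg_L <= s$EC_median_mg_L)
  expect_true(s$EC_median_mg_L <= s$EC_max_mg_L)
  expect_true(s$EC_geomean_mg_L <= s$EC_mean_mg_L)  # AM-GM
})

test_that("BQE aggregation converts units, drops the unconvertible, and
           reports data-point spread", {
  recs <- dplyr::bind_rows(
    make_records(3, cas_number = "1912249", conc_value = c(1, 2, 4)),
    make_records(2, cas_number = "93652", conc_value = c(500, 250),
                 conc_unit = "ug/L"),
    make_records(1, cas_number = "93652", conc_value = 3,
                 conc_unit = "drops/bucket")
  )
  mw <- tibble::tibble(cas_key = c("1912249", "93652"),
                       average_mass = c(215.68, 214.65))
  agg <- aggregate_bqe(recs, mw = mw)
  expect_equal(nrow(agg), 2)
  expect_equal(attr(agg, "n_unconverted"), 1)
  expect_equal(agg$EC_geomean_mg_L[agg$cas_number == "1912249"], 2)
  expect_equal(agg$EC_max_mg_L[agg$cas_number == "93652"], 0.5)
  expect_equal(
    as.integer(attr(agg, "unsupported_units")[["drops/bucket"]]), 1)

  spread <- data_point_spread(agg)
  expect_equal(spread$total_data_points, 5)
  expect_equal(spread$geo_mean_n, sqrt(3 * 2))
  expect_equal(spread$mean_n, 2.5)
})
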