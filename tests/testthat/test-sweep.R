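test_that("default sweep covers the full grid for both muscles", {
  sw <- flexor_sweep()
  expect_s3_class(sw, "flexor_sweep")
  expect_equal(nrow(sw), 32)
  expect_equal(attr(sw, "grid"), (5:20) / 10)
  expect_equal(sort(unique(sw$alpha)), (5:20) / 10)
  expect_setequal(unique(sw$muscle), c("BIC", "BRA"))
  expect_true(!anyNA(sw))
  # MA strictly increasing along the grid for each muscle
  for (m in c("BIC", "BRA"))
    expect_true(all(diff(sw$ma_cm[sw$muscle == m]) > 0))
})

test_that("degenerate grids are rejected and single-alpha sweeps behave", {
  expect_error(flexor_sweep(grid = c(1, 0.5)), "strictly increasing")
  expect_error(flexor_sweep(grid = c(0, 1)), "positive")
  sw1 <- flexor_sweep(grid = 1)
  expect_equal(nrow(sw1), 2)
  expect_equal(sw1$moment_incl_nm, sw1$moment_excl_nm)
  expect_error(summarize_table1(sw1), "0.5, 1.0 and 2.0")
  expect_error(ma_scaling_check(sw1), "at least 3")
})

test_that("sweep errors identify the offending muscle and alpha", {
  steep <- muscle_spec("steep", beta = 1, gamma = 1, phi = 1, theta_p0 = 60)
  expect_error(flexor_sweep(specs = list(steep), grid = c(0.5, 1, 1.6)),
               "muscle 'steep', alpha = 1.6")
})

test_that("three-condition summary matches the published table", {
  t1 <- summarize_table1(flexor_sweep())
  cell <- function(m, q, col)
    t1$cells[t1$cells$muscle == m & grepl(q, t1$cells$quantity, fixed = TRUE),
             col]
  expect_equal(cell("BIC", "MA length", "atrophy"), 1.63)
  expect_equal(cell("BIC", "MA length", "baseline"), 2.17)
  expect_equal(cell("BIC", "MA length", "hypertrophy"), 2.76)
  expect_equal(cell("BRA", "MA length", "atrophy"), 0.54)
  expect_equal(cell("BRA", "MA length", "baseline"), 0.75)
  expect_equal(cell("BRA", "MA length", "hypertrophy"), 1.03)
  expect_equal(cell("BIC", "ACSA", "baseline"), 11)
  expect_equal(cell("BIC", "ACSA", "hypertrophy"), 22)
  expect_equal(cell("BIC", "incl. MA", "atrophy"), 2.73)
  expect_equal(cell("BIC", "incl. MA", "baseline"), 7.07)
  expect_equal(cell("BIC", "incl. MA", "hypertrophy"), 16.17)
  expect_equal(cell("BRA", "incl. MA", "baseline"), 2.49)
  expect_equal(cell("BRA", "incl. MA", "hypertrophy"), 6.54)
  expect_equal(cell("BIC", "excl. MA", "atrophy"), 3.63)
  expect_equal(cell("BIC", "excl. MA", "hypertrophy"), 12.69)
  expect_equal(cell("BRA", "excl. MA", "atrophy"), 1.26)
  # delta columns are differences of the rounded cells
  expect_equal(cell("BIC", "MA length", "delta_ab"), -0.54)
  expect_equal(cell("BIC", "MA length", "delta_hb"), 0.59)
  expect_equal(cell("BRA", "MA length", "delta_hb"), 0.28)
  # summary() is the same thing
  expect_equal(summary(flexor_sweep())$cells, t1$cells)
})

test_that("moment-arm percent change uses the rounded-cell convention", {
  t1 <- summarize_table1(flexor_sweep())
  expect_equal(unname(t1$ma_pct_change["BIC"]), 27.2)
  expect_equal(unname(t1$ma_pct_change["BRA"]), 37.3)
  # full-precision convention differs slightly (not the published figure)
  expect_equal(unname(t1$ma_pct_change_full["BIC"]), 27.5, tolerance = 0.01)
  expect_equal(unname(t1$ma_pct_change_full["BRA"]), 37.6, tolerance = 0.01)
})

test_that("incl- and excl-MA moment curves cross only at baseline", {
  sw <- flexor_sweep()
  for (m in c("BIC", "BRA")) {
    sub <- sw[sw$muscle == m, ]
    d <- sub$moment_incl_nm - sub$moment_excl_nm
    expect_equal(d[sub$alpha == 1], 0)
    expect_true(all(d[sub$alpha < 1] < 0))
    expect_true(all(d[sub$alpha > 1] > 0))
  }
})

test_that("arcsine scaling characterization is near-constant but not asserted exact", {
  rep <- ma_scaling_check(flexor_sweep())
  for (m in c("BIC", "BRA")) {
    tab <- rep[[m]]$table
    expect_equal(nrow(tab), 16)
    expect_true(all(is.finite(tab$ratio)))
    expect_equal(tab$ratio[tab$alpha == 1], 1)    # exact at baseline
    expect_true(is.finite(rep[[m]]$constancy_cv))
    expect_gte(rep[[m]]$constancy_cv, 0)
  }
  # the shallower BRA tendon tracks the small-angle law more closely
  expect_lt(rep$BRA$constancy_cv, rep$BIC$constancy_cv)
})

test_that("sweep CSV output is deterministic", {
  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  write_sweep_csv(flexor_sweep(), f1)
  write_sweep_csv(flexor_sweep(), f2)
  expect_identical(readLines(f1), readLines(f2))
  hdr <- readLines(f1, n = 1)
  expect_match(hdr, "muscle")
  expect_match(hdr, "moment_incl_nm")
  t1 <- tempfile(fileext = ".csv")
  write_table1_csv(flexor_sweep(), t1)
  expect_equal(length(readLines(t1)), 9)  # header + 4 quantities x 2 muscles
  unlink(c(f1, f2, t1))
})
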