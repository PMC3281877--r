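test_that("the packaged default set reproduces the tabulated inputs exactly", {
  p <- read_params(default_params_path())
  expect_identical(p$global_rates$moc_to_pre, 0.03)
  expect_identical(p$global_rates$trc_to_pre, 0.20)
  expect_identical(p$global_rates$moc_to_inc, 0.25)
  expect_identical(p$global_rates$moc_to_unc, 0.34)
  expect_identical(p$global_rates$pre_to_dead, 0.0034)
  expect_identical(p$costs$contraception_moh, 14.67)
  expect_identical(p$costs$contraception_societal, 64.74)
  expect_identical(p$costs$pregnancy_moh, 96.65)
  expect_identical(p$costs$pregnancy_societal, 254.33)
  expect_identical(p$daly_per_pregnancy, 0.272)
  expect_identical(p$discount_rate_annual, 0.03)
  expect_identical(p$cycle_months, 9L)
  expect_identical(p$age_tables$nonuser_to_pre,
                   c(0.85, 0.85, 0.85, 0.83, 0.81, 0.69, 0.17))
  expect_identical(p$age_tables$nsa_stay,
                   c(0.80, 0.41, 0.34, 0.31, 0.39, 0.41, 0.47))
  expect_identical(p$age_tables$background_death_annual,
                   c(0.002, 0.003, 0.006, 0.009, 0.012, 0.011, 0.011))
  expect_identical(p$outcomes$miscarriage, 0.049)
  expect_identical(p$outcomes$abortion, 0.190)
  expect_equal(live_birth_probability(p), 0.73)
})

test_that("starting distributions are normalized and match the cohort survey shares", {
  p <- default_parameters()
  for (sc in c("ccp", "ncp")) {
    expect_equal(sum(p$starting_distribution[[sc]]), 1, tolerance = 1e-12)
  }
  # shares before renormalization: 80.3% inactive, 9.1% modern, 1.8%
  # traditional, 6.6% unmet need, 2.1% wanting to conceive
  expect_equal(p$starting_distribution$ccp[["UNC"]], 0.066, tolerance = 2e-3)
  expect_equal(p$starting_distribution$ccp[["MOC"]], 0.091, tolerance = 2e-3)
  expect_identical(p$starting_distribution$ncp[["TRC"]], 0)
  expect_identical(p$starting_distribution$ncp[["UNC"]], 0)
  # universal access: modern + traditional + unmet mass starts on modern
  expect_equal(p$starting_distribution$ncp[["MOC"]], 0.176, tolerance = 2e-3)
  # women wanting to conceive are the same group under both programs
  expect_equal(p$starting_distribution$ncp[["INC"]],
               p$starting_distribution$ccp[["INC"]], tolerance = 2e-3)
})

test_that("annual_to_cycle matches the closed form and composes", {
  expect_identical(annual_to_cycle(0, 9), 0)
  expect_identical(annual_to_cycle(1, 9), 1)
  expect_equal(annual_to_cycle(0.03, 9), 1 - 0.97^0.75, tolerance = 1e-15)
  expect_equal(annual_to_cycle(0.03, 9), 0.02258545, tolerance = 1e-7)
  # identity at 12 months, monotone in the annual probability
  ps <- seq(0, 1, by = 0.05)
  expect_equal(annual_to_cycle(ps, 12), ps, tolerance = 1e-12)
  expect_true(all(diff(annual_to_cycle(ps, 9)) > 0))
  expect_error(annual_to_cycle(1.2, 9), "0, 1")
})

test_that("serialization round-trips the default set", {
  f <- withr::local_tempfile(fileext = ".yaml")
  p <- default_parameters()
  write_params(p, f)
  expect_equal(read_params(f), p, tolerance = 1e-12)
})

test_that("validation rejects malformed sets and names the field", {
  p <- default_parameters()
  bad <- p
  bad$global_rates$moc_to_pre <- 1.3
  expect_error(validate_params(bad), "moc_to_pre")
  f <- withr::local_tempfile(fileext = ".yaml")
  write_params(p, f) # file-level: out-of-range probability caught on load
  txt <- sub("moc_to_pre: 0.03", "moc_to_pre: 1.3", readLines(f))
  writeLines(txt, f)
  expect_error(read_params(f), "moc_to_pre")

  bad <- p
  bad$costs <- NULL
  expect_error(validate_params(bad), "costs")

  bad <- p
  bad$starting_distribution$ccp[["NSA"]] <- 0.5
  expect_error(validate_params(bad), "starting_distribution")

  bad <- p
  bad$costs$contraception_societal <- 1 # below the MoH cost
  expect_error(validate_params(bad), "societal")

  # non-cumulative child mortality other than the tabulated triple warns
  odd <- p
  odd$outcomes$child_mortality <- 0.01
  expect_warning(validate_params(odd), "cumulative")
})

test_that("every probability of a validated set lies in [0, 1]", {
  for (seed in 1:20) {
    p <- random_parameter_set(seed)
    probs <- c(
      unlist(p$global_rates), unlist(p$outcomes), p$daly_per_pregnancy,
      unlist(p$starting_distribution),
      unlist(p$age_tables[setdiff(names(p$age_tables), "age_band")])
    )
    expect_true(all(probs >= 0 & probs <= 1))
    expect_equal(sum(p$starting_distribution$ccp), 1, tolerance = 1e-12)
    expect_equal(sum(p$starting_distribution$ncp), 1, tolerance = 1e-12)
  }
})
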