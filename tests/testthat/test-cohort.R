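test_that("age bands are half-open with a post-reproductive sentinel", {
  expect_identical(assign_band(15), "15-19")
  expect_identical(assign_band(19.9), "15-19")
  expect_identical(assign_band(20.25), "20-24")
  expect_identical(assign_band(49.5), "45-49")
  expect_identical(assign_band(60), "50+")
  expect_error(assign_band(14), ">= 15")
})

test_that("transition matrices carry the tabulated entries and structure", {
  p <- base_params
  M <- transition_matrix(p, "15-19", "ccp")
  q <- annual_to_cycle(0.002, 9) * (1 - p$maternal_death_share)
  # NSA self-transition before mortality scaling equals the tabulated 0.80
  expect_equal(M["NSA", "NSA"] / (1 - q), 0.80, tolerance = 1e-12)
  expect_identical(M["DEAD", "DEAD"], 1)
  expect_equal(unname(rowSums(M)), rep(1, 7), tolerance = 1e-12)
  # pregnancy is a tunnel state; no direct switches between methods; no
  # return to sexual inactivity except after pregnancy
  expect_identical(M["PRE", "PRE"], 0)
  expect_identical(M["MOC", "TRC"], 0)
  expect_identical(M["TRC", "MOC"], 0)
  expect_identical(unname(M[c("INC", "UNC", "MOC", "TRC"), "NSA"]),
                   rep(0, 4))
  bands <- c("15-19", "20-24", "25-29", "30-34", "35-39", "40-44", "45-49")
  for (b in bands) {
    for (sc in c("ccp", "ncp")) {
      expect_equal(unname(rowSums(transition_matrix(p, b, sc))), rep(1, 7),
                   tolerance = 1e-12)
    }
  }
  expect_error(transition_matrix(p, "50+"), "post-reproductive")
})

test_that("the universal-access scenario eliminates traditional use and unmet-need entry", {
  M <- transition_matrix(base_params, "25-29", "ncp")
  expect_identical(unname(M[, "TRC"]), rep(0, 7))
  # unmet need is only reachable through contraceptive discontinuation
  expect_identical(unname(M[c("NSA", "INC", "UNC", "PRE"), "UNC"]), rep(0, 4))
  expect_gt(M["MOC", "UNC"], 0)
  # the redirected mass lands on modern contraception
  Mc <- transition_matrix(base_params, "25-29", "ccp")
  expect_equal(M["NSA", "MOC"], Mc["NSA", "MOC"] + Mc["NSA", "UNC"] + Mc["NSA", "TRC"],
               tolerance = 1e-12)
})

test_that("two-cycle occupancies equal explicit matrix products", {
  p <- toy_fixture("two_cycle_hand")
  tr <- run_cohort(p, "ccp")
  expect_identical(nrow(tr), 3L)
  M <- transition_matrix(p, "15-19", "ccp")
  v0 <- p$starting_distribution$ccp
  v1 <- drop(v0 %*% M)
  v2 <- drop(v1 %*% M)
  occ <- as.matrix(tr[, c("nsa", "inc", "unc", "moc", "trc", "pre", "dead")])
  expect_equal(unname(occ[1, ]), unname(v0), tolerance = 1e-12)
  expect_equal(unname(occ[2, ]), unname(v1), tolerance = 1e-12)
  expect_equal(unname(occ[3, ]), unname(v2), tolerance = 1e-12)
})

test_that("an immortal cohort conserves its full mass at every cycle", {
  p <- toy_fixture("no_mortality")
  p$max_age <- 15 + 10 * 0.75
  for (sc in c("ccp", "ncp")) {
    tr <- run_cohort(p, sc)
    expect_equal(tr$dead, rep(0, nrow(tr)), tolerance = 1e-12)
    sums <- rowSums(tr[, c("nsa", "inc", "unc", "moc", "trc", "pre", "dead")])
    expect_equal(unname(sums), rep(1, nrow(tr)), tolerance = 1e-12)
  }
})

test_that("occupancy sums to one and death is monotone for random parameter sets", {
  for (seed in 1:100) {
    p <- random_parameter_set(seed)
    tr <- run_cohort(p, if (seed %% 2) "ccp" else "ncp")
    sums <- rowSums(tr[, c("nsa", "inc", "unc", "moc", "trc", "pre", "dead")])
    expect_equal(unname(sums), rep(1, nrow(tr)), tolerance = 1e-9)
    expect_true(all(diff(tr$dead) >= -1e-12))
    expect_true(all(tr$new_pregnancies >= 0))
  }
})

test_that("matching method efficacy makes the two programs equivalent", {
  p <- toy_fixture("equal_efficacy")
  tc <- run_cohort(p, "ccp")
  tn <- run_cohort(p, "ncp")
  expect_equal(expected_pregnancies(tc), expected_pregnancies(tn),
               tolerance = 1e-9)
  expect_equal(tc$new_pregnancies, tn$new_pregnancies, tolerance = 1e-9)
  expect_equal(life_expectancy(tc), life_expectancy(tn), tolerance = 1e-9)
})

test_that("discount factors follow per-cycle compounding of the annual rate", {
  tr <- run_cohort(base_params, "ccp")
  expect_equal(tr$discount, 1.03^(-0.75 * tr$cycle), tolerance = 1e-12)
})
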