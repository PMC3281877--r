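test_that("Beta moment matching is exact and round-trips", {
  ab <- beta_from_mean_se(0.5, 0.1)
  expect_equal(unname(ab), c(12, 12))
  # analytic mean and SD of the fitted Beta equal the inputs
  for (m in c(0.1, 0.272, 0.5, 0.9)) {
    for (se in c(0.01, 0.05)) {
      ab <- beta_from_mean_se(m, se)
      a <- ab[["alpha"]]; b <- ab[["beta"]]
      expect_equal(a / (a + b), m, tolerance = 1e-12)
      expect_equal(sqrt(a * b / ((a + b)^2 * (a + b + 1))), se,
                   tolerance = 1e-12)
    }
  }
  # concentration grows without bound as se -> 0
  expect_gt(beta_from_mean_se(0.5, 1e-6)[["alpha"]],
            beta_from_mean_se(0.5, 1e-3)[["alpha"]])
  expect_error(beta_from_mean_se(0.5, 0.6), "too large")
  expect_error(beta_from_mean_se(1.2, 0.1), "(0, 1)")
})

test_that("Beta draws at the DALY weight's range reproduce its mean", {
  # se from the one-way range 0.218-0.327 (range = 4 standard errors)
  se <- (0.327 - 0.218) / 4
  ab <- beta_from_mean_se(0.272, se)
  set.seed(99)
  x <- rbeta(1e5, ab[["alpha"]], ab[["beta"]])
  expect_equal(mean(x), 0.272, tolerance = 3 * se / sqrt(1e5) / 0.272)
})

test_that("sensitivity ranges bracket their base values", {
  rg <- sensitivity_ranges(base_params)
  expect_true(all(rg$low <= rg$base & rg$base <= rg$high))
  expect_true(all(rg$family %in% c("beta", "normal")))
  expect_true(all(rg$family[grepl("^costs", rg$id)] == "normal"))
  # the discount rate is a methods parameter and is never sampled
  expect_false(any(grepl("discount", rg$id)))
  # ranges follow the +/-50% (costs) rule
  i <- rg$id == "costs.contraception_societal"
  expect_equal(rg$low[i], 32.39, tolerance = 1e-2)
  expect_equal(rg$high[i], 97.16, tolerance = 1e-2)
})

test_that("tornado bars equal the analytic swing for linear cost parameters", {
  p <- base_params
  rg <- sensitivity_ranges(p, include_age_tables = FALSE)
  rg <- rg[rg$id %in% c("costs.contraception_societal",
                        "costs.pregnancy_societal"), ]
  torn <- tornado(p, "delta_cost_societal", ranges = rg)
  cea <- compare_programs(p)
  d <- cea$deltas[cea$deltas$perspective == "societal", ]
  # the incremental cost is linear in each unit cost; the slope is the
  # incremental person-time (program) or episode (medical) quantity
  slope_contra <- d$delta_program / p$costs$contraception_societal
  slope_preg <- d$delta_medical / p$costs$pregnancy_societal
  w <- setNames(torn$width, torn$id)
  expect_equal(w[["costs.contraception_societal"]],
               abs(slope_contra) * (97.16 - 32.39), tolerance = 1e-6)
  expect_equal(w[["costs.pregnancy_societal"]],
               abs(slope_preg) * (381.49 - 127.13), tolerance = 1e-6)
  # a degenerate range produces a zero-width bar
  rg0 <- rg[1, ]
  rg0$low <- rg0$base
  rg0$high <- rg0$base
  expect_equal(tornado(p, "delta_cost_societal", ranges = rg0)$width, 0)
})

test_that("incremental societal cost is most sensitive to the two unit costs", {
  torn <- tornado(base_params, "delta_cost_societal",
                  ranges = sensitivity_ranges(base_params,
                                              include_age_tables = FALSE))
  expect_setequal(torn$id[1:2], c("costs.pregnancy_societal",
                                  "costs.contraception_societal"))
  expect_true(all(diff(torn$width) <= 1e-12)) # sorted by descending width
})

test_that("a degenerate PSA reproduces the base case exactly", {
  p <- base_params
  rg <- sensitivity_ranges(p, include_age_tables = FALSE)
  rg$low <- rg$base
  rg$high <- rg$base
  psa <- run_psa(p, n_iter = 1, seed = 5, ranges = rg)
  cea <- compare_programs(p)
  d <- cea$deltas
  expect_equal(psa$delta_cost_societal,
               d$delta_cost[d$perspective == "societal"], tolerance = 1e-12)
  expect_equal(psa$delta_dale, d$delta_dale[1], tolerance = 1e-12)
})

test_that("PSA is reproducible under a fixed seed", {
  p <- base_params
  rg <- sensitivity_ranges(p, include_age_tables = FALSE)
  a <- run_psa(p, n_iter = 15, seed = 42, ranges = rg)
  b <- run_psa(p, n_iter = 15, seed = 42, ranges = rg)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- run_psa(p, n_iter = 15, seed = 43, ranges = rg)
  expect_false(identical(a$delta_cost_societal, c$delta_cost_societal))
})

test_that("the PSA mean tracks the base case within Monte-Carlo error", {
  p <- base_params
  psa <- run_psa(p, n_iter = 300, seed = 7,
                 ranges = sensitivity_ranges(p, include_age_tables = FALSE))
  cea <- compare_programs(p)
  d <- cea$deltas
  base_cost <- d$delta_cost[d$perspective == "societal"]
  mc_se <- sd(psa$delta_cost_societal) / sqrt(nrow(psa))
  expect_lt(abs(mean(psa$delta_cost_societal) - base_cost), 3 * mc_se)
  mc_se_d <- sd(psa$delta_dale) / sqrt(nrow(psa))
  expect_lt(abs(mean(psa$delta_dale) - d$delta_dale[1]), 3 * mc_se_d)
  # quadrants agree with the signs of the pairs
  expect_identical(psa$quadrant_societal == "SE",
                   psa$delta_dale >= 0 & psa$delta_cost_societal < 0)
})

test_that("the acceptability curve counts net-monetary-benefit wins", {
  hand <- tibble::tibble(
    iteration = 1:3,
    delta_cost_societal = c(-10, 5, 5),
    delta_cost_moh = c(-10, 5, 5),
    delta_le = c(0.1, 0.1, -0.1),
    delta_dale = c(0.1, 0.1, -0.1)
  )
  expect_equal(ceac(hand, 100)$probability, 2 / 3)
  # all cost-saving, all effective: certainty at every threshold
  sure <- tibble::tibble(iteration = 1:4,
                         delta_cost_societal = rep(-1, 4),
                         delta_cost_moh = rep(-1, 4),
                         delta_le = rep(0.1, 4), delta_dale = rep(0.1, 4))
  expect_equal(ceac(sure, c(0, 474, 1423))$probability, rep(1, 3))
  expect_error(ceac(sure, -5), ">= 0")
  expect_error(ceac(sure[0, ], 100), "empty")
})

test_that("the CEAC is non-decreasing when every draw gains DALE", {
  p <- base_params
  psa <- run_psa(p, n_iter = 60, seed = 21,
                 ranges = sensitivity_ranges(p, include_age_tables = FALSE))
  expect_true(all(psa$delta_dale > 0))
  curve <- ceac(psa, seq(0, 1423, by = 10))
  expect_true(all(diff(curve$probability) >= 0))
})
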