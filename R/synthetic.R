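#' Random structurally valid parameter sets
#'
#' Generates a parameter set with the same statistical structure as the
#' packaged model — row-stochastic age-specific transitions, episode-based
#' pregnancy outcomes with a live-birth residual, per-person-year and
#' per-episode costs with societal >= MoH, and a comparator/universal-access
#' scenario pair in which the universal-access starting distribution absorbs
#' the modern, traditional and unmet-need mass into modern use — but with
#' random values. Every generated set passes [validate_params()]; generation
#' is reproducible given `seed`.
#'
#' @param seed Integer seed.
#' @param config Optional list overriding generator bounds:
#'   `max_event_prob` (cap on per-cycle event probabilities, default 0.9),
#'   `cost_range` (log-uniform cost magnitude range, default `c(1, 1000)`),
#'   `max_loss_prob` (cap on the summed pregnancy-loss incidences, default
#'   0.5), `discount_range` (default `c(0, 0.1)`).
#' @return A validated `fpcea_params` object.
#' @examples
#' p <- random_parameter_set(42)
#' identical(p, random_parameter_set(42))
#' @export
random_parameter_set <- function(seed, config = list()) {
  cfg <- utils::modifyList(list(
    max_event_prob = 0.9,
    cost_range = c(1, 1000),
    max_loss_prob = 0.5,
    discount_range = c(0, 0.1)
  ), config)
  set.seed(seed)
  nb <- length(BAND_LABELS)
  runif_p <- function(n = 1, max = cfg$max_event_prob) runif(n, 0.01, max)

  # NSA outflow as a random stochastic row per band
  nsa <- matrix(rgamma_simplex(nb, 5), nrow = nb)
  age_tables <- tibble(
    age_band = BAND_LABELS,
    nsa_to_inc = nsa[, 1], nsa_to_unc = nsa[, 2],
    to_moc = nsa[, 3], to_trc = nsa[, 4], nsa_stay = nsa[, 5],
    nonuser_to_pre = sort(runif_p(nb), decreasing = TRUE), # fades with age
    unc_stay = runif_p(nb, 0.5),
    background_death_annual = sort(runif(nb, 0.0005, 0.05))
  )
  moc_out <- rgamma_simplex(1, 4)[1, ] * runif(1, 0.3, 0.9)
  trc_out <- rgamma_simplex(1, 4)[1, ] * runif(1, 0.3, 0.9)
  pre_route <- rgamma_simplex(1, 5)[1, ] * runif(1, 0.1, 0.3)
  losses <- rgamma_simplex(1, 4)[1, ] * runif(1, 0.05, cfg$max_loss_prob)
  child <- sort(runif(3, 0.005, 0.3))
  cost_moh <- exp(runif(2, log(cfg$cost_range[1]), log(cfg$cost_range[2])))
  start_ccp <- rgamma_simplex(1, 5)[1, ]
  names(start_ccp) <- c("NSA", "INC", "UNC", "MOC", "TRC")
  start_ccp <- c(start_ccp, PRE = 0, DEAD = 0)
  # universal access: modern + traditional + unmet mass all starts on
  # modern contraception; the mass wanting to conceive is unchanged
  start_ncp <- start_ccp
  start_ncp["MOC"] <- sum(start_ccp[c("MOC", "TRC", "UNC")])
  start_ncp[c("TRC", "UNC")] <- 0

  params <- structure(list(
    schema_version = 1L,
    age_tables = age_tables,
    global_rates = list(
      moc_to_pre = moc_out[1] / 4, # modern methods fail less than others
      trc_to_pre = moc_out[1],
      moc_to_inc = moc_out[2],
      moc_to_unc = moc_out[3],
      trc_to_inc = trc_out[1],
      trc_to_unc = trc_out[2],
      pre_to_nsa = 0,
      pre_to_inc = pre_route[1],
      pre_to_unc = pre_route[2],
      pre_to_moc = pre_route[3],
      pre_to_trc = pre_route[4],
      pre_to_dead = runif(1, 0, 0.02)
    ),
    outcomes = list(
      miscarriage = losses[1], ectopic = losses[2],
      abortion = losses[3], stillbirth = losses[4],
      neonatal_mortality = child[1],
      infant_mortality = child[2],
      child_mortality = child[3]
    ),
    costs = list(
      contraception_moh = cost_moh[1],
      contraception_societal = cost_moh[1] * runif(1, 1, 5),
      pregnancy_moh = cost_moh[2],
      pregnancy_societal = cost_moh[2] * runif(1, 1, 5)
    ),
    daly_per_pregnancy = runif(1, 0, 0.9),
    discount_rate_annual = runif(1, cfg$discount_range[1], cfg$discount_range[2]),
    cycle_months = 9L,
    start_age = 15,
    max_age = sample(60:110, 1),
    maternal_death_share = runif(1, 0, 0.3),
    post_reproductive_death_annual = runif(1, 0, 0.05),
    starting_distribution = list(ccp = start_ccp, ncp = start_ncp)
  ), class = "fpcea_params")
  validate_params(params)
}

# n random points on the 5-simplex (rows), via normalized gamma draws
rgamma_simplex <- function(n, k) {
  m <- matrix(stats::rgamma(n * k, shape = 2), nrow = n)
  sweep(m, 1, rowSums(m), "/")
}

#' Deterministic toy parameter sets for oracle tests
#'
#' Tiny fixed parameterizations with hand-computable behaviour:
#'
#' * `"two_cycle_hand"`: a 2-cycle horizon with round transition
#'   probabilities, so occupancies equal explicit matrix products.
#' * `"no_mortality"`: every death probability zero; the surviving fraction
#'   stays exactly 1.
#' * `"equal_efficacy"`: modern and traditional failure equal the non-user
#'   pregnancy probability, outflow rows sum exactly to one, identical
#'   starting distributions and zero costs — the comparator and
#'   universal-access scenarios then produce identical pregnancy streams.
#'
#' @param name Fixture id.
#' @return A validated `fpcea_params` object.
#' @export
toy_fixture <- function(name = c("two_cycle_hand", "no_mortality",
                                 "equal_efficacy")) {
  name <- match.arg(name)
  flat <- function(x, n = 7) rep(x, n)
  base <- structure(list(
    schema_version = 1L,
    age_tables = tibble(
      age_band = BAND_LABELS,
      nsa_to_inc = flat(0.1), nsa_to_unc = flat(0.1),
      to_moc = flat(0.2), to_trc = flat(0.1), nsa_stay = flat(0.5),
      nonuser_to_pre = flat(0.5), unc_stay = flat(0.2),
      background_death_annual = flat(0.01)
    ),
    global_rates = list(
      moc_to_pre = 0.1, trc_to_pre = 0.2,
      moc_to_inc = 0.1, moc_to_unc = 0.1,
      trc_to_inc = 0.1, trc_to_unc = 0.1,
      pre_to_nsa = 0, pre_to_inc = 0.1, pre_to_unc = 0.1,
      pre_to_moc = 0.1, pre_to_trc = 0.1,
      pre_to_dead = 0.01
    ),
    outcomes = list(
      miscarriage = 0.1, ectopic = 0.05, abortion = 0.1, stillbirth = 0.05,
      neonatal_mortality = 0.02, infant_mortality = 0.05,
      child_mortality = 0.1
    ),
    costs = list(contraception_moh = 10, contraception_societal = 20,
                 pregnancy_moh = 100, pregnancy_societal = 200),
    daly_per_pregnancy = 0.25,
    discount_rate_annual = 0.03,
    cycle_months = 9L,
    start_age = 15,
    max_age = 100,
    maternal_death_share = 0.1,
    post_reproductive_death_annual = 0,
    starting_distribution = list(
      ccp = c(NSA = 0.5, INC = 0.1, UNC = 0.2, MOC = 0.1, TRC = 0.1,
              PRE = 0, DEAD = 0),
      ncp = c(NSA = 0.5, INC = 0.1, UNC = 0, MOC = 0.4, TRC = 0,
              PRE = 0, DEAD = 0)
    )
  ), class = "fpcea_params")
  params <- switch(name,
    two_cycle_hand = {
      base$max_age <- 16.5 # exactly two 9-month cycles
      base
    },
    no_mortality = {
      base$age_tables$background_death_annual <- rep(0, 7)
      base$global_rates$pre_to_dead <- 0
      base$post_reproductive_death_annual <- 0
      base
    },
    equal_efficacy = {
      p <- 0.3
      base$global_rates$moc_to_pre <- p
      base$global_rates$trc_to_pre <- p
      base$age_tables$nonuser_to_pre <- rep(p, 7)
      # UNC outflow sums exactly to 1 so renormalization is a no-op and the
      # per-cycle pregnancy hazard is p from every at-risk state
      base$age_tables$unc_stay <- 1 - base$age_tables$to_moc -
        base$age_tables$to_trc - p
      base$costs <- list(contraception_moh = 0, contraception_societal = 0,
                         pregnancy_moh = 0, pregnancy_societal = 0)
      base$starting_distribution$ncp <- base$starting_distribution$ccp
      base
    }
  )
  validate_params(params)
}
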