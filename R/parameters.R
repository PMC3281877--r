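#' Probability conversion between time scales
#'
#' Converts an annual transition probability to the probability over one model
#' cycle under a constant-hazard assumption: `1 - (1 - p)^(m/12)` for a cycle
#' of `m` months.
#'
#' @param p_annual Annual probability (or vector), in `[0, 1]`.
#' @param cycle_months Cycle length in months (default 9).
#' @return Per-cycle probability, same length as `p_annual`.
#' @examples
#' annual_to_cycle(0.03, 9) # 1 - 0.97^0.75
#' @export
annual_to_cycle <- function(p_annual, cycle_months = 9) {
  if (any(p_annual < 0 | p_annual > 1, na.rm = TRUE)) {
    abort("`p_annual` must lie in [0, 1].")
  }
  1 - (1 - p_annual)^(cycle_months / 12)
}

#' Default model parameterization (Uganda, 2006 DHS)
#'
#' Builds the complete parameter set for the Ugandan contraceptive-access
#' analysis: age-specific transition probabilities (from the 2006 Uganda
#' Demographic and Health Survey), non-age-specific contraceptive failure and
#' discontinuation probabilities, post-pregnancy routing, pregnancy-outcome
#' incidences, maternal and child mortality, the per-pregnancy DALY weight,
#' aggregate contraception and pregnancy costs for the Ministry-of-Health and
#' societal perspectives, the discount rate, and the starting distribution of
#' the 15-year-old cohort under each program scenario.
#'
#' Two child-mortality parameterizations are shipped. `"printed"` (default)
#' carries the neonatal/infant/child values as tabulated in the source data
#' compilation (0.021/0.055/0.049); these are not cumulative-consistent
#' (child < infant) and are retained verbatim as the base case.
#' `"survey"` substitutes the published DHS 2006 rates per live birth
#' (29/76/137 per 1,000, cumulative), which reproduce the cohort-scale death
#' counts of the cost-consequences analysis. Child-death counts are reporting
#' outputs only; they never feed life expectancy, DALE or costs.
#'
#' @param child_mortality `"printed"` or `"survey"` (see Details).
#' @return A validated `fpcea_params` object.
#' @seealso [read_params()], [write_params()], [validate_params()]
#' @examples
#' p <- default_parameters()
#' p$global_rates$moc_to_pre
#' @export
default_parameters <- function(child_mortality = c("printed", "survey")) {
  child_mortality <- match.arg(child_mortality)
  cm <- switch(child_mortality,
    printed = c(neonatal = 0.021, infant = 0.055, child = 0.049),
    survey  = c(neonatal = 0.029, infant = 0.076, child = 0.137)
  )
  params <- structure(list(
    schema_version = 1L,
    # Age-specific per-cycle transition probabilities by five-year band.
    # background_death_annual is an annual all-cause probability (converted to
    # the cycle scale inside the engine); everything else is per 9-month cycle.
    age_tables = tibble(
      age_band     = BAND_LABELS,
      nsa_to_inc   = c(0.02, 0.17, 0.17, 0.12, 0.08, 0.05, 0.13),
      nsa_to_unc   = c(0.07, 0.21, 0.26, 0.29, 0.29, 0.27, 0.19),
      to_moc       = c(0.09, 0.17, 0.19, 0.22, 0.19, 0.21, 0.19),
      to_trc       = c(0.02, 0.03, 0.04, 0.04, 0.04, 0.06, 0.05),
      nsa_stay     = c(0.80, 0.41, 0.34, 0.31, 0.39, 0.41, 0.47),
      # probability of pregnancy for non-users, already menopause-adjusted
      nonuser_to_pre = c(0.85, 0.85, 0.85, 0.83, 0.81, 0.69, 0.17),
      unc_stay     = c(0.07, 0.05, 0.05, 0.05, 0.06, 0.16, 0.53),
      background_death_annual = c(0.002, 0.003, 0.006, 0.009, 0.012, 0.011, 0.011)
    ),
    global_rates = list(
      moc_to_pre = 0.03,   # weighted modern-method failure, per cycle
      trc_to_pre = 0.20,   # traditional-method failure, per cycle
      moc_to_inc = 0.25,   # intentional discontinuation of modern methods
      moc_to_unc = 0.34,   # unintentional discontinuation (loss of access)
      trc_to_inc = 0.26,
      trc_to_unc = 0.36,
      # Post-pregnancy routing of the non-live-birth mass. Live births go to
      # modern contraception (lactational amenorrhea); see transition_matrix().
      pre_to_nsa = 0,
      pre_to_inc = 0.03,
      pre_to_unc = 0.06,
      pre_to_moc = 0.04,
      pre_to_trc = 0.01,
      pre_to_dead = 0.0034 # maternal mortality per pregnancy
    ),
    outcomes = list(
      miscarriage = 0.049,
      ectopic     = 0.014,
      abortion    = 0.190,
      stillbirth  = 0.017,
      # live birth is the residual 1 - (miscarriage+ectopic+abortion+stillbirth)
      neonatal_mortality = unname(cm["neonatal"]),
      infant_mortality   = unname(cm["infant"]),
      child_mortality    = unname(cm["child"])
    ),
    costs = list(
      contraception_moh      = 14.67,  # 2010 US$ per person-year in MOC
      contraception_societal = 64.74,
      pregnancy_moh          = 96.65,  # 2010 US$ per pregnancy episode
      pregnancy_societal     = 254.33
    ),
    daly_per_pregnancy = 0.272,
    discount_rate_annual = 0.03,
    cycle_months = 9L,
    start_age = 15,
    max_age = 110,
    maternal_death_share = 0.13, # share of female deaths from maternal causes
    post_reproductive_death_annual = 0,
    life_expectancy_metadata = 51.7, # WHO life-table value; not used by the model
    starting_distribution = list(
      ccp = c(NSA = 0.803, INC = 0.021, UNC = 0.066, MOC = 0.091,
              TRC = 0.018, PRE = 0, DEAD = 0),
      ncp = c(NSA = 0.803, INC = 0.021, UNC = 0, MOC = 0.176,
              TRC = 0, PRE = 0, DEAD = 0)
    )
  ), class = "fpcea_params")
  validate_params(params)
}

#' Validate a parameter set
#'
#' Checks every probability field for the `[0, 1]` range, outflow-row sums
#' (within `0.05` of 1 before renormalization), cost non-negativity and
#' perspective ordering, and renormalizes each scenario's starting
#' distribution to sum exactly to 1. Violations raise errors naming the
#' offending field. A non-cumulative child-mortality triple raises a warning
#' only, and the tabulated base-case triple (which is itself non-cumulative)
#' is accepted silently.
#'
#' @param params An `fpcea_params` object (or plain list with the same shape).
#' @return The validated (and possibly renormalized) `fpcea_params` object.
#' @export
validate_params <- function(params) {
  need <- c("age_tables", "global_rates", "outcomes", "costs",
            "daly_per_pregnancy", "discount_rate_annual", "cycle_months",
            "start_age", "max_age", "starting_distribution")
  missing <- setdiff(need, names(params))
  if (length(missing) > 0) {
    abort(paste0("Parameter set is missing field(s): ",
                 paste(missing, collapse = ", ")))
  }
  at <- params$age_tables
  prob_cols <- setdiff(names(at), "age_band")
  for (col in prob_cols) {
    bad_probability(at[[col]], paste0("age_tables$", col))
  }
  if (nrow(at) != length(BAND_LABELS) || !identical(at$age_band, BAND_LABELS)) {
    abort("age_tables must have one row per band 15-19 ... 45-49, in order.")
  }
  nsa_sum <- at$nsa_to_inc + at$nsa_to_unc + at$to_moc + at$to_trc + at$nsa_stay
  if (any(abs(nsa_sum - 1) > 0.05)) {
    abort("age_tables: NSA outflow row must sum to 1 within 0.05 before renormalization.")
  }
  for (nm in names(params$global_rates)) {
    bad_probability(params$global_rates[[nm]], paste0("global_rates$", nm))
  }
  out <- params$outcomes
  for (nm in names(out)) bad_probability(out[[nm]], paste0("outcomes$", nm))
  if (out$miscarriage + out$ectopic + out$abortion + out$stillbirth > 1) {
    abort("outcomes: pregnancy-loss incidences exceed 1; no live-birth residual remains.")
  }
  cumulative <- out$neonatal_mortality <= out$infant_mortality &&
    out$infant_mortality <= out$child_mortality
  printed_triple <- isTRUE(all.equal(
    c(out$neonatal_mortality, out$infant_mortality, out$child_mortality),
    c(0.021, 0.055, 0.049)
  ))
  if (!cumulative && !printed_triple) {
    warn(paste("outcomes: neonatal/infant/child mortality are not cumulative",
               "(neonatal <= infant <= child); counts will be reported as given."))
  }
  cs <- params$costs
  if (any(unlist(cs) < 0)) abort("costs must be non-negative.")
  if (cs$contraception_societal < cs$contraception_moh ||
      cs$pregnancy_societal < cs$pregnancy_moh) {
    abort("costs: societal unit costs must be at least the MoH unit costs.")
  }
  if (params$discount_rate_annual < 0) abort("discount_rate_annual must be >= 0.")
  if (params$daly_per_pregnancy < 0) abort("daly_per_pregnancy must be >= 0.")
  bad_probability(params$daly_per_pregnancy, "daly_per_pregnancy")
  for (sc in names(params$starting_distribution)) {
    sd <- params$starting_distribution[[sc]]
    if (!identical(names(sd), STATES)) {
      abort(paste0("starting_distribution$", sc,
                   " must be named over the seven states in canonical order."))
    }
    bad_probability(sd, paste0("starting_distribution$", sc))
    s <- sum(sd)
    if (abs(s - 1) > 0.02) {
      abort(paste0("starting_distribution$", sc, " sums to ", signif(s, 4),
                   "; must be within 0.02 of 1."))
    }
    params$starting_distribution[[sc]] <- sd / s
  }
  if (!inherits(params, "fpcea_params")) class(params) <- "fpcea_params"
  params
}

bad_probability <- function(x, field) {
  if (any(!is.finite(x)) || any(x < 0 | x > 1)) {
    abort(paste0("`", field, "` must be a probability in [0, 1]."))
  }
  invisible(x)
}

#' Live-birth probability per pregnancy
#'
#' The residual after subtracting miscarriage, ectopic pregnancy, induced
#' abortion and stillbirth incidences from 1.
#'
#' @param params An `fpcea_params` object.
#' @return A single probability.
#' @export
live_birth_probability <- function(params) {
  o <- params$outcomes
  1 - o$miscarriage - o$ectopic - o$abortion - o$stillbirth
}

#' @export
print.fpcea_params <- function(x, ...) {
  cat("<fpcea_params> lifetime contraceptive-access Markov model parameters\n")
  cat(sprintf("  cycle: %d months; ages %d-%d; discount %.1f%%/yr; DALY/pregnancy %.3f\n",
              x$cycle_months, x$start_age, x$max_age,
              100 * x$discount_rate_annual, x$daly_per_pregnancy))
  cat(sprintf("  modern failure %.3f, traditional failure %.3f per cycle; live-birth prob %.3f\n",
              x$global_rates$moc_to_pre, x$global_rates$trc_to_pre,
              live_birth_probability(x)))
  cat(sprintf("  costs ($/yr MOC, $/pregnancy): MoH %.2f/%.2f, societal %.2f/%.2f\n",
              x$costs$contraception_moh, x$costs$pregnancy_moh,
              x$costs$contraception_societal, x$costs$pregnancy_societal))
  for (sc in names(x$starting_distribution)) {
    sd <- x$starting_distribution[[sc]]
    cat(sprintf("  start (%s): %s\n", sc,
                paste(sprintf("%s %.3f", names(sd)[sd > 0], sd[sd > 0]),
                      collapse = ", ")))
  }
  invisible(x)
}

#' Read / write parameter files
#'
#' Parameter sets serialize to YAML with a versioned schema. `read_params()`
#' validates on load and reports the offending field on failure;
#' a write/read round trip reproduces the parameter set exactly.
#'
#' @param path File path.
#' @param params An `fpcea_params` object.
#' @return `read_params()` returns a validated `fpcea_params`;
#'   `write_params()` returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' write_params(default_parameters(), f)
#' p <- read_params(f)
#' @export
read_params <- function(path) {
  if (!file.exists(path)) abort(paste0("Parameter file not found: ", path))
  raw <- yaml::read_yaml(path)
  at <- raw$age_tables
  params <- raw
  params$age_tables <- as_tibble(at)
  for (sc in names(params$starting_distribution)) {
    params$starting_distribution[[sc]] <-
      unlist(params$starting_distribution[[sc]])[STATES]
    names(params$starting_distribution[[sc]]) <- STATES
  }
  class(params) <- "fpcea_params"
  validate_params(params)
}

#' @rdname read_params
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "fpcea_params"))
  x <- unclass(params)
  x$age_tables <- as.list(params$age_tables)
  x$starting_distribution <- lapply(params$starting_distribution, as.list)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' Path to the packaged default parameter file
#'
#' @return File path of the installed `uganda_2006.yaml`.
#' @export
default_params_path <- function() {
  system.file("extdata", "uganda_2006.yaml", package = "fpcea", mustWork = TRUE)
}
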