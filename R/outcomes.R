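#' Life expectancy from a cohort trace
#'
#' Sums cycle-length years of survival, weighting each cycle's surviving
#' fraction by the per-cycle discount factor when `discounted = TRUE`. State
#' membership is evaluated at cycle start; no half-cycle correction is
#' applied.
#'
#' @param trace An `fpcea_trace` from [run_cohort()].
#' @param discounted Apply the trace's discount factors? Default `TRUE`.
#' @return Years per woman.
#' @export
life_expectancy <- function(trace, discounted = TRUE) {
  cycle_years <- trace$age[2] - trace$age[1]
  w <- if (discounted) trace$discount else 1
  sum(cycle_years * (1 - trace$dead) * w)
}

#' Expected pregnancies from a cohort trace
#'
#' @inheritParams life_expectancy
#' @return Pregnancies per woman (sum of discounted or undiscounted mass
#'   newly entering the pregnant state).
#' @export
expected_pregnancies <- function(trace, discounted = FALSE) {
  w <- if (discounted) trace$discount else 1
  sum(trace$new_pregnancies * w)
}

#' Disability-adjusted life expectancy
#'
#' Discounted life expectancy minus the per-pregnancy DALY loss times the
#' discounted pregnancy count. With a zero-pregnancy trace, DALE equals LE.
#'
#' @inheritParams life_expectancy
#' @param daly_per_pregnancy DALYs lost per pregnancy (default: value carried
#'   by the trace's parameter set).
#' @return Years per woman.
#' @export
disability_adjusted_life_expectancy <- function(trace, daly_per_pregnancy = NULL) {
  daly_per_pregnancy <- daly_per_pregnancy %||%
    attr(trace, "params")$daly_per_pregnancy
  life_expectancy(trace, discounted = TRUE) -
    daly_per_pregnancy * expected_pregnancies(trace, discounted = TRUE)
}

#' Pregnancy-outcome and child-mortality cascade
#'
#' Multiplies a per-woman (or per-cohort) pregnancy count through the
#' per-pregnancy outcome incidences; live births are the residual after
#' miscarriage, ectopic pregnancy, induced abortion and stillbirth.
#' Neonatal/infant/child deaths apply per live birth. These are reporting
#' counts only: they do not feed life expectancy, DALE or costs.
#'
#' @param pregnancies Pregnancy count (scalar, `>= 0`).
#' @param params An `fpcea_params` object (its `outcomes` element is used).
#' @return A one-row tibble: pregnancies, ectopics, miscarriages, abortions,
#'   stillbirths, live_births, neonatal_deaths, infant_deaths, child_deaths.
#' @examples
#' pregnancy_cascade(9.5, default_parameters())
#' @export
pregnancy_cascade <- function(pregnancies, params) {
  stopifnot(pregnancies >= 0)
  o <- params$outcomes
  lb <- pregnancies * live_birth_probability(params)
  tibble(
    pregnancies = pregnancies,
    ectopics = pregnancies * o$ectopic,
    miscarriages = pregnancies * o$miscarriage,
    abortions = pregnancies * o$abortion,
    stillbirths = pregnancies * o$stillbirth,
    live_births = lb,
    neonatal_deaths = lb * o$neonatal_mortality,
    infant_deaths = lb * o$infant_mortality,
    child_deaths = lb * o$child_mortality
  )
}

#' Accrue program and medical costs along a trace
#'
#' Only the modern-contraception and pregnant states bear costs. Program cost
#' accrues per discounted person-year of MOC occupancy at the annual
#' contraception cost; medical cost accrues per discounted pregnancy episode
#' at the pregnancy cost. All other states cost zero.
#'
#' @inheritParams life_expectancy
#' @param params Parameter set supplying unit costs (default: from the trace).
#' @param perspective `"societal"` or `"moh"`.
#' @return A one-row tibble with `perspective`, `cost_program`,
#'   `cost_medical`, `cost_total` (2010 US$ per woman).
#' @export
accrue_costs <- function(trace, params = NULL, perspective = c("societal", "moh")) {
  perspective <- match.arg(perspective)
  params <- params %||% attr(trace, "params")
  cs <- params$costs
  unit_contra <- switch(perspective, societal = cs$contraception_societal,
                        moh = cs$contraception_moh)
  unit_preg <- switch(perspective, societal = cs$pregnancy_societal,
                      moh = cs$pregnancy_moh)
  cycle_years <- trace$age[2] - trace$age[1]
  program <- sum(cycle_years * trace$moc * unit_contra * trace$discount)
  medical <- sum(trace$new_pregnancies * unit_preg * trace$discount)
  tibble(perspective = perspective, cost_program = program,
         cost_medical = medical, cost_total = program + medical)
}

#' Full per-woman expectations for one scenario
#'
#' Runs the cohort and condenses the trace into the scenario's headline
#' expectations: discounted life expectancy and DALE, undiscounted and
#' discounted pregnancies, total fertility (undiscounted live births), the
#' pregnancy-outcome cascade, and costs by perspective.
#'
#' @param params An `fpcea_params` object.
#' @param scenario `"ccp"` or `"ncp"`.
#' @return An `fpcea_result` tibble, one row per perspective (`"societal"`,
#'   `"moh"`), carrying the (perspective-independent) outcome columns and the
#'   perspective's cost columns. The trace is attached as attribute `trace`.
#' @examples
#' scenario_result(default_parameters(), "ccp")
#' @export
scenario_result <- function(params, scenario = c("ccp", "ncp")) {
  scenario <- match.arg(scenario)
  trace <- run_cohort(params, scenario)
  preg_u <- expected_pregnancies(trace, discounted = FALSE)
  preg_d <- expected_pregnancies(trace, discounted = TRUE)
  le <- life_expectancy(trace, discounted = TRUE)
  dale <- disability_adjusted_life_expectancy(trace)
  cascade <- pregnancy_cascade(preg_u, params)
  costs <- dplyr::bind_rows(
    accrue_costs(trace, params, "societal"),
    accrue_costs(trace, params, "moh")
  )
  out <- dplyr::bind_cols(
    tibble(scenario = scenario, perspective = costs$perspective,
           le_discounted = le, dale = dale,
           pregnancies = preg_u, pregnancies_discounted = preg_d,
           total_fertility = cascade$live_births),
    dplyr::bind_rows(cascade[-1], cascade[-1])[
      c("ectopics", "miscarriages", "abortions", "stillbirths",
        "neonatal_deaths", "infant_deaths", "child_deaths")],
    costs[c("cost_program", "cost_medical", "cost_total")]
  )
  structure(out, class = c("fpcea_result", class(out)), trace = trace)
}
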