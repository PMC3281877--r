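#' Incremental cost-effectiveness verdict
#'
#' Classifies an incremental (cost, effect) pair. A strategy that is cheaper
#' and more effective is `"dominant"`; costlier and less effective is
#' `"dominated"`; otherwise the incremental cost-effectiveness ratio
#' `delta_cost / delta_effect` is reported. A zero effect difference is
#' `"dominated"` when costs rise and `"dominant-or-equal"` otherwise.
#'
#' @param delta_cost Incremental cost (intervention minus comparator).
#' @param delta_effect Incremental effect, e.g. DALYs averted / DALE gained.
#' @return A one-row tibble with `verdict` (`"dominant"`, `"dominated"`,
#'   `"dominant-or-equal"` or `"icer"`) and `icer` (finite ratio, or `NA`).
#' @examples
#' icer(-38.89, 0.37) # dominant
#' icer(100, 1)       # $100 per effect unit
#' @export
icer <- function(delta_cost, delta_effect) {
  if (delta_effect == 0) {
    verdict <- if (delta_cost > 0) "dominated" else "dominant-or-equal"
    return(tibble(verdict = verdict, icer = NA_real_))
  }
  if (delta_cost < 0 && delta_effect > 0) {
    tibble(verdict = "dominant", icer = NA_real_)
  } else if (delta_cost > 0 && delta_effect < 0) {
    tibble(verdict = "dominated", icer = NA_real_)
  } else {
    tibble(verdict = "icer", icer = delta_cost / delta_effect)
  }
}

#' Willingness-to-pay classification of a verdict
#'
#' Applies the 1x / 3x GDP-per-capita rule: a dominant strategy, or an ICER
#' below one GDP per capita per DALY averted, is "highly cost-effective";
#' below three times GDP, "cost-effective"; otherwise "not cost-effective".
#' A dominated strategy is "not cost-effective".
#'
#' @param verdict A one-row tibble from [icer()] (or a verdict string plus
#'   `icer=` value).
#' @param gdp_per_capita GDP per capita in the costing currency (Uganda 2010:
#'   474 US$).
#' @return A classification string.
#' @export
classify_threshold <- function(verdict, gdp_per_capita = 474) {
  stopifnot(gdp_per_capita > 0)
  v <- if (is.data.frame(verdict)) verdict$verdict else verdict
  r <- if (is.data.frame(verdict)) verdict$icer else NA_real_
  if (v %in% c("dominant", "dominant-or-equal")) return("highly cost-effective")
  if (v == "dominated") return("not cost-effective")
  if (r < gdp_per_capita) "highly cost-effective"
  else if (r < 3 * gdp_per_capita) "cost-effective"
  else "not cost-effective"
}

#' Incremental comparison of two scenario results
#'
#' Computes intervention-minus-comparator differences in costs and effects,
#' comparator-minus-intervention "reductions" in adverse outcomes, the ICER
#' or dominance verdict per perspective, the net program cost (the
#' intervention's program cost minus the medical costs it averts), and the
#' willingness-to-pay classification.
#'
#' @param comparator,intervention `fpcea_result` objects from
#'   [scenario_result()], computed under the same parameter set.
#' @param gdp_per_capita Threshold anchor for [classify_threshold()].
#' @return An `fpcea_cea` object (list) with elements `deltas` (tibble, one
#'   row per perspective: delta_cost, delta_program, delta_medical,
#'   averted_medical, net_cost, delta_le, delta_dale, verdict, icer,
#'   threshold_class) and `reductions` (tibble of outcome reductions per
#'   woman).
#' @examples
#' p <- default_parameters()
#' cea <- compare_scenarios(scenario_result(p, "ccp"), scenario_result(p, "ncp"))
#' tidy(cea)
#' @export
compare_scenarios <- function(comparator, intervention, gdp_per_capita = 474) {
  stopifnot(inherits(comparator, "fpcea_result"),
            inherits(intervention, "fpcea_result"))
  if (!isTRUE(all.equal(attr(attr(comparator, "trace"), "params"),
                        attr(attr(intervention, "trace"), "params")))) {
    abort("Scenario results were not computed under the same parameter set.")
  }
  cc <- comparator
  nc <- intervention
  stopifnot(identical(cc$perspective, nc$perspective))
  deltas <- purrr::map_dfr(seq_len(nrow(cc)), function(i) {
    d_cost <- nc$cost_total[i] - cc$cost_total[i]
    d_dale <- nc$dale[i] - cc$dale[i]
    v <- icer(d_cost, d_dale)
    tibble(
      perspective = cc$perspective[i],
      delta_cost = d_cost,
      delta_program = nc$cost_program[i] - cc$cost_program[i],
      delta_medical = nc$cost_medical[i] - cc$cost_medical[i],
      averted_medical = cc$cost_medical[i] - nc$cost_medical[i],
      net_cost = nc$cost_program[i] - (cc$cost_medical[i] - nc$cost_medical[i]),
      delta_le = nc$le_discounted[i] - cc$le_discounted[i],
      delta_dale = d_dale,
      verdict = v$verdict,
      icer = v$icer,
      threshold_class = classify_threshold(v, gdp_per_capita)
    )
  })
  outcome_cols <- c("pregnancies", "total_fertility", "ectopics",
                    "miscarriages", "abortions", "stillbirths",
                    "neonatal_deaths", "infant_deaths", "child_deaths")
  reductions <- tibble(
    outcome = outcome_cols,
    reduction = purrr::map_dbl(outcome_cols, ~ cc[[.x]][1] - nc[[.x]][1])
  )
  structure(list(comparator = cc$scenario[1], intervention = nc$scenario[1],
                 deltas = deltas, reductions = reductions,
                 comparator_result = cc, intervention_result = nc),
            class = "fpcea_cea")
}

#' Run both scenarios and compare them
#'
#' Convenience wrapper: [scenario_result()] for the comparator and
#' intervention scenarios under one parameter set, then [compare_scenarios()].
#'
#' @param params An `fpcea_params` object.
#' @param comparator,intervention Scenario ids (defaults `"ccp"` vs `"ncp"`).
#' @inheritParams compare_scenarios
#' @return An `fpcea_cea` object.
#' @export
compare_programs <- function(params, comparator = "ccp", intervention = "ncp",
                             gdp_per_capita = 474) {
  compare_scenarios(scenario_result(params, comparator),
                    scenario_result(params, intervention),
                    gdp_per_capita = gdp_per_capita)
}

#' @export
print.fpcea_cea <- function(x, ...) {
  cat(sprintf("<fpcea_cea> %s vs %s\n", x$intervention, x$comparator))
  d <- x$deltas
  for (i in seq_len(nrow(d))) {
    lab <- if (d$verdict[i] == "icer") sprintf("ICER %.2f $/DALY", d$icer[i]) else d$verdict[i]
    cat(sprintf("  %-9s dCost %8.2f  dDALE %6.3f  %s (%s)\n",
                d$perspective[i], d$delta_cost[i], d$delta_dale[i], lab,
                d$threshold_class[i]))
  }
  invisible(x)
}

#' @rdname compare_scenarios
#' @param x An `fpcea_cea` object.
#' @param ... Unused.
#' @method tidy fpcea_cea
#' @export
tidy.fpcea_cea <- function(x, ...) {
  dplyr::bind_rows(
    x$deltas |>
      tidyr::pivot_longer(c("delta_cost", "delta_program", "delta_medical",
                            "averted_medical", "net_cost", "delta_le",
                            "delta_dale", "icer"),
                          names_to = "term", values_to = "estimate") |>
      dplyr::select("perspective", "term", "estimate"),
    x$reductions |>
      dplyr::transmute(perspective = NA_character_,
                       term = paste0("reduction_", .data$outcome),
                       estimate = .data$reduction)
  )
}

#' @rdname compare_scenarios
#' @method glance fpcea_cea
#' @export
glance.fpcea_cea <- function(x, ...) {
  d <- x$deltas
  tibble(
    comparator = x$comparator,
    intervention = x$intervention,
    delta_cost_societal = d$delta_cost[d$perspective == "societal"],
    delta_cost_moh = d$delta_cost[d$perspective == "moh"],
    delta_dale = d$delta_dale[1],
    delta_le = d$delta_le[1],
    verdict = d$verdict[d$perspective == "societal"],
    threshold_class = d$threshold_class[d$perspective == "societal"]
  )
}

#' Scale per-woman results to a cohort (cost-consequences analysis)
#'
#' Multiplies per-woman costs, outcomes and their differences by the cohort
#' size; scaling is exactly linear.
#'
#' @param cea An `fpcea_cea` object.
#' @param cohort_size Number of women (default 100,000).
#' @return A tibble with one row per quantity: `quantity`, `comparator`,
#'   `intervention`, `difference` (intervention minus comparator), all in
#'   cohort totals.
#' @examples
#' cost_consequences(compare_programs(default_parameters()), 100000)
#' @export
cost_consequences <- function(cea, cohort_size = 1e5) {
  stopifnot(inherits(cea, "fpcea_cea"), cohort_size > 0)
  cc <- cea$comparator_result
  nc <- cea$intervention_result
  rows <- list(
    c("societal_cost", "cost_total", "societal"),
    c("moh_cost", "cost_total", "moh"),
    c("pregnancies", "pregnancies", NA),
    c("discounted_life_years", "le_discounted", NA),
    c("discounted_dale_years", "dale", NA),
    c("ectopic_pregnancies", "ectopics", NA),
    c("induced_abortions", "abortions", NA),
    c("miscarriages", "miscarriages", NA),
    c("stillbirths", "stillbirths", NA),
    c("live_births", "total_fertility", NA),
    c("neonatal_deaths", "neonatal_deaths", NA),
    c("infant_deaths", "infant_deaths", NA),
    c("child_deaths", "child_deaths", NA)
  )
  purrr::map_dfr(rows, function(r) {
    pick <- function(res) {
      i <- if (is.na(r[3])) 1L else which(res$perspective == r[3])
      res[[r[2]]][i]
    }
    a <- pick(cc) * cohort_size
    b <- pick(nc) * cohort_size
    tibble(quantity = r[1], comparator = a, intervention = b,
           difference = b - a)
  })
}
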