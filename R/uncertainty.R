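#' Beta distribution from a mean and standard error
#'
#' Method-of-moments fit: `nu = mean(1-mean)/se^2 - 1`, `alpha = mean*nu`,
#' `beta = (1-mean)*nu`. Valid only while `se^2 < mean(1-mean)`; a larger
#' standard error cannot be represented by a Beta with that mean and signals
#' that the parameter needs a truncated fallback distribution.
#'
#' @param mean Mean in (0, 1).
#' @param se Standard error, `0 < se^2 < mean(1-mean)`.
#' @return Named numeric `c(alpha=, beta=)`.
#' @examples
#' beta_from_mean_se(0.5, 0.1) # alpha = beta = 12
#' @export
beta_from_mean_se <- function(mean, se) {
  if (mean <= 0 || mean >= 1) abort("`mean` must lie strictly in (0, 1).")
  if (se <= 0) abort("`se` must be positive.")
  if (se^2 >= mean * (1 - mean)) {
    abort("`se` too large for a Beta with this mean; use a truncated fallback.")
  }
  nu <- mean * (1 - mean) / se^2 - 1
  c(alpha = mean * nu, beta = (1 - mean) * nu)
}

# ---- parameter addressing ----------------------------------------------

#' Get or set a model parameter by id
#'
#' Flat ids address scalars inside a parameter set:
#' `"global_rates.moc_to_pre"`, `"outcomes.miscarriage"`,
#' `"costs.pregnancy_societal"`, `"daly_per_pregnancy"`, and age-table cells
#' as `"age_tables.<column>.<band>"` (e.g.
#' `"age_tables.nonuser_to_pre.15-19"`).
#'
#' @param params An `fpcea_params` object.
#' @param id Parameter id string.
#' @param value Replacement value (for `set_param`).
#' @return `get_param` returns the scalar; `set_param` the modified set
#'   (unvalidated: sensitivity analyses renormalize outflow rows inside the
#'   matrix construction rather than rejecting draws).
#' @export
get_param <- function(params, id) {
  parts <- strsplit(id, ".", fixed = TRUE)[[1]]
  if (parts[1] == "age_tables") {
    row <- match(parts[3], params$age_tables$age_band)
    if (is.na(row)) abort(paste0("Unknown age band in id: ", id))
    return(params$age_tables[[parts[2]]][row])
  }
  if (length(parts) == 1) return(params[[parts[1]]])
  params[[parts[1]]][[parts[2]]]
}

#' @rdname get_param
#' @export
set_param <- function(params, id, value) {
  parts <- strsplit(id, ".", fixed = TRUE)[[1]]
  if (parts[1] == "age_tables") {
    row <- match(parts[3], params$age_tables$age_band)
    if (is.na(row)) abort(paste0("Unknown age band in id: ", id))
    params$age_tables[[parts[2]]][row] <- value
  } else if (length(parts) == 1) {
    params[[parts[1]]] <- value
  } else {
    params[[parts[1]]][[parts[2]]] <- value
  }
  params
}

# Printed one-way ranges for the non-age-specific parameters (95% CIs where
# sources report them, otherwise +/-50% for costs and +/-20% for other
# parameters). The tabulated upper bound for the abortion incidence is
# rebuilt from the +/-20% rule (0.190 * 1.2) as the printed pair is
# inconsistent with its own base value.
PRINTED_RANGES <- tibble::tribble(
  ~id,                           ~base,   ~low,    ~high,   ~family,
  "global_rates.moc_to_pre",     0.03,    0.02,    0.03,    "beta",
  "global_rates.trc_to_pre",     0.20,    0.16,    0.24,    "beta",
  "global_rates.moc_to_inc",     0.25,    0.20,    0.29,    "beta",
  "global_rates.moc_to_unc",     0.34,    0.27,    0.41,    "beta",
  "global_rates.trc_to_inc",     0.26,    0.21,    0.31,    "beta",
  "global_rates.trc_to_unc",     0.36,    0.27,    0.41,    "beta",
  "global_rates.pre_to_inc",     0.03,    0.02,    0.04,    "beta",
  "global_rates.pre_to_unc",     0.06,    0.05,    0.08,    "beta",
  "global_rates.pre_to_moc",     0.04,    0.03,    0.05,    "beta",
  "global_rates.pre_to_trc",     0.01,    0.01,    0.02,    "beta",
  "global_rates.pre_to_dead",    0.0034,  0.0028,  0.0041,  "beta",
  "outcomes.miscarriage",        0.049,   0.039,   0.059,   "beta",
  "outcomes.ectopic",            0.014,   0.011,   0.017,   "beta",
  "outcomes.abortion",           0.190,   0.152,   0.228,   "beta",
  "outcomes.stillbirth",         0.017,   0.014,   0.020,   "beta",
  "outcomes.neonatal_mortality", 0.021,   0.017,   0.025,   "beta",
  "outcomes.infant_mortality",   0.055,   0.044,   0.067,   "beta",
  "outcomes.child_mortality",    0.049,   0.030,   0.120,   "beta",
  "daly_per_pregnancy",          0.272,   0.218,   0.327,   "beta",
  "costs.contraception_moh",     14.67,   7.34,    22.01,   "normal",
  "costs.contraception_societal", 64.74,  32.39,   97.16,   "normal",
  "costs.pregnancy_moh",         96.65,   48.32,   144.97,  "normal",
  "costs.pregnancy_societal",    254.33,  127.13,  381.49,  "normal"
)

#' Sensitivity ranges for every model parameter
#'
#' Builds the table of one-way ranges used by [tornado()] and (via
#' `se = (high - low) / 4`) the distributions used by [run_psa()]. Parameters
#' with published confidence intervals use them; all other probabilities get
#' +/-20% (clipped to `[0, 1]`) and costs +/-50%. Age-specific transition and
#' background-mortality entries are included per band. Parameters describing
#' the analysis method itself (discount rate, cycle length, horizon, cohort
#' starting distribution) are excluded. Parameters whose current value is
#' zero get a degenerate range and are dropped from sampling.
#'
#' @param params An `fpcea_params` object.
#' @param include_age_tables Include the per-band age-specific entries?
#'   Default `TRUE`.
#' @return A tibble: `id`, `base`, `low`, `high`, `family`
#'   (`"beta"`/`"normal"`).
#' @export
sensitivity_ranges <- function(params, include_age_tables = TRUE) {
  printed <- PRINTED_RANGES
  rows <- purrr::map_dfr(seq_len(nrow(printed)), function(i) {
    id <- printed$id[i]
    base <- get_param(params, id)
    if (isTRUE(all.equal(base, printed$base[i]))) {
      tibble(id = id, base = base, low = printed$low[i],
             high = printed$high[i], family = printed$family[i])
    } else {
      rule_range(id, base, printed$family[i])
    }
  })
  if (include_age_tables) {
    cols <- setdiff(names(params$age_tables), "age_band")
    age_rows <- purrr::map_dfr(cols, function(col) {
      purrr::map_dfr(params$age_tables$age_band, function(b) {
        id <- paste("age_tables", col, b, sep = ".")
        rule_range(id, get_param(params, id), "beta")
      })
    })
    rows <- dplyr::bind_rows(rows, age_rows)
  }
  dplyr::filter(rows, .data$high > .data$low)
}

rule_range <- function(id, base, family) {
  if (family == "normal") {
    tibble(id = id, base = base, low = base * 0.5, high = base * 1.5,
           family = family)
  } else {
    tibble(id = id, base = base, low = max(0, base * 0.8),
           high = min(1, base * 1.2), family = family)
  }
}

# Draw one value per row of a ranges table. Probabilities use a Beta matched
# to (base, se); if the se is too large for a Beta (or the base sits on a
# boundary) a normal truncated to [0, 1] stands in. Costs use a normal
# truncated at zero. Draws with se = 0 return the base.
draw_parameter_values <- function(ranges) {
  n <- nrow(ranges)
  out <- numeric(n)
  for (i in seq_len(n)) {
    base <- ranges$base[i]
    se <- (ranges$high[i] - ranges$low[i]) / 4
    if (se <= 0) { out[i] <- base; next }
    if (ranges$family[i] == "beta") {
      if (base > 0 && base < 1 && se^2 < base * (1 - base)) {
        ab <- beta_from_mean_se(base, se)
        out[i] <- rbeta(1, ab["alpha"], ab["beta"])
      } else {
        repeat {
          x <- rnorm(1, base, se)
          if (x >= 0 && x <= 1) break
        }
        out[i] <- x
      }
    } else {
      repeat {
        x <- rnorm(1, base, se)
        if (x >= 0) break
      }
      out[i] <- x
    }
  }
  out
}

#' One-way (tornado) sensitivity analysis
#'
#' Reruns the full two-scenario comparison with each parameter fixed at the
#' low and at the high end of its range, all others at base, and records the
#' swing in the chosen output. Entries are sorted by descending bar width.
#'
#' @param params An `fpcea_params` object (the base case).
#' @param output Output selector: one of `"delta_cost_societal"`,
#'   `"delta_cost_moh"`, `"delta_dale"`, `"delta_le"`, or a function taking
#'   an `fpcea_cea` and returning a scalar.
#' @param ranges Ranges tibble (default [sensitivity_ranges()]).
#' @return An `fpcea_tornado` tibble: `id`, `low_output`, `high_output`,
#'   `base_output`, `width`, sorted by decreasing `width`.
#' @examples
#' \donttest{
#' torn <- tornado(default_parameters(), "delta_cost_societal")
#' head(torn, 3)
#' }
#' @export
tornado <- function(params, output = "delta_cost_societal",
                    ranges = sensitivity_ranges(params)) {
  f <- output_selector(output)
  bad <- ranges$base < ranges$low | ranges$base > ranges$high
  if (any(bad)) {
    abort(paste0("Range does not bracket the base value for: ",
                 paste(ranges$id[bad], collapse = ", ")))
  }
  base_out <- f(compare_programs(params))
  res <- purrr::map_dfr(seq_len(nrow(ranges)), function(i) {
    lo <- f(compare_programs(set_param(params, ranges$id[i], ranges$low[i])))
    hi <- f(compare_programs(set_param(params, ranges$id[i], ranges$high[i])))
    tibble(id = ranges$id[i], low_output = lo, high_output = hi)
  })
  res$base_output <- base_out
  res$width <- abs(res$high_output - res$low_output)
  res <- dplyr::arrange(res, dplyr::desc(.data$width))
  structure(res, class = c("fpcea_tornado", class(res)), output = output)
}

output_selector <- function(output) {
  if (is.function(output)) return(output)
  switch(output,
    delta_cost_societal = function(cea)
      cea$deltas$delta_cost[cea$deltas$perspective == "societal"],
    delta_cost_moh = function(cea)
      cea$deltas$delta_cost[cea$deltas$perspective == "moh"],
    delta_dale = function(cea) cea$deltas$delta_dale[1],
    delta_le = function(cea) cea$deltas$delta_le[1],
    abort(paste0("Unknown output selector: ", output))
  )
}

#' Probabilistic sensitivity analysis
#'
#' Monte-Carlo propagation of parameter uncertainty: each iteration draws all
#' parameters independently from their distributions (Beta for probabilities
#' and the DALY weight, Normal truncated at zero for costs; standard errors
#' are one quarter of the one-way range), rebuilds the model (outflow rows
#' are renormalized during matrix construction), runs both scenarios and
#' records the incremental cost and effect pair. Methodological parameters
#' such as the discount rate are never drawn. Fully reproducible given
#' `seed`.
#'
#' @param params Base-case `fpcea_params`.
#' @param n_iter Number of Monte-Carlo iterations.
#' @param seed Integer seed for all randomness.
#' @param ranges Ranges/distribution table (default [sensitivity_ranges()]).
#' @return An `fpcea_psa` tibble with one row per iteration: `iteration`,
#'   `delta_cost_societal`, `delta_cost_moh`, `delta_le`, `delta_dale`, and
#'   cost-effectiveness-plane quadrants `quadrant_societal`/`quadrant_moh`
#'   (`"NE"`, `"SE"`, `"SW"`, `"NW"`; east means positive DALE gain).
#' @examples
#' \donttest{
#' psa <- run_psa(default_parameters(), n_iter = 50, seed = 1)
#' mean(psa$delta_dale > 0)
#' }
#' @export
run_psa <- function(params, n_iter = 10000, seed = 1,
                    ranges = sensitivity_ranges(params)) {
  stopifnot(n_iter >= 1)
  set.seed(seed)
  rows <- vector("list", n_iter)
  for (it in seq_len(n_iter)) {
    vals <- draw_parameter_values(ranges)
    p <- params
    for (j in seq_len(nrow(ranges))) p <- set_param(p, ranges$id[j], vals[j])
    cea <- compare_programs(p)
    d <- cea$deltas
    rows[[it]] <- tibble(
      iteration = it,
      delta_cost_societal = d$delta_cost[d$perspective == "societal"],
      delta_cost_moh = d$delta_cost[d$perspective == "moh"],
      delta_le = d$delta_le[1],
      delta_dale = d$delta_dale[1]
    )
  }
  out <- dplyr::bind_rows(rows)
  out$quadrant_societal <- quadrant(out$delta_dale, out$delta_cost_societal)
  out$quadrant_moh <- quadrant(out$delta_dale, out$delta_cost_moh)
  structure(out, class = c("fpcea_psa", class(out)), seed = seed)
}

quadrant <- function(delta_effect, delta_cost) {
  dplyr::case_when(
    delta_effect >= 0 & delta_cost >= 0 ~ "NE",
    delta_effect >= 0 & delta_cost < 0 ~ "SE",
    delta_effect < 0 & delta_cost < 0 ~ "SW",
    TRUE ~ "NW"
  )
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay threshold, the fraction of PSA samples whose
#' net monetary benefit `lambda * delta_effect - delta_cost` is positive.
#' The default grid runs from $0 to three times Uganda's 2010 GDP per capita
#' in $10 steps.
#'
#' @param samples An `fpcea_psa` tibble.
#' @param thresholds Willingness-to-pay values per DALY averted.
#' @param perspective `"societal"` or `"moh"`.
#' @return A tibble: `threshold`, `probability`.
#' @export
ceac <- function(samples, thresholds = seq(0, 1423, by = 10),
                 perspective = c("societal", "moh")) {
  perspective <- match.arg(perspective)
  if (nrow(samples) == 0) abort("`samples` is empty.")
  if (any(thresholds < 0)) abort("`thresholds` must be >= 0.")
  dcost <- samples[[paste0("delta_cost_", perspective)]]
  deff <- samples$delta_dale
  purrr::map_dfr(thresholds, function(l) {
    tibble(threshold = l, probability = mean(l * deff - dcost > 0))
  })
}
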