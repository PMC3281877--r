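#' Assign a five-year age band
#'
#' Bands are half-open: an exact age `a` belongs to the band whose limits
#' satisfy `lower <= a < upper + 1`. Ages of 50 and over return the
#' post-reproductive sentinel `"50+"`, in which no pregnancy or contraception
#' flows occur.
#'
#' @param age Exact age(s) in years, `>= 15`.
#' @return Character vector of band labels (`"15-19"`, ..., `"45-49"`, `"50+"`).
#' @examples
#' assign_band(c(15, 19.9, 20.25, 60))
#' @export
assign_band <- function(age) {
  if (any(age < 15)) abort("`age` must be >= 15 (cohort start age).")
  ifelse(age >= 50, "50+", BAND_LABELS[pmin(floor((age - 15) / 5) + 1, 7L)])
}

#' Build the per-cycle transition matrix for one age band and scenario
#'
#' Assembles the 7x7 row-stochastic matrix over the states NSA (not sexually
#' active), INC (intentional non-use), UNC (unintentional non-use / unmet
#' need), MOC (modern contraception), TRC (traditional contraception), PRE
#' (pregnant) and DEAD, for a given age band:
#'
#' * NSA row: the band's onset-of-activity split across INC/UNC/MOC/TRC plus
#'   staying inactive, proportionally renormalized to 1.
#' * INC row: the non-user pregnancy probability to PRE; remainder stays.
#' * UNC row: stay, uptake of modern/traditional methods, and the non-user
#'   pregnancy probability, proportionally renormalized.
#' * MOC/TRC rows: method failure to PRE, intentional discontinuation to INC,
#'   unintentional discontinuation to UNC, remainder stays. Direct switches
#'   between MOC and TRC are structural zeros.
#' * PRE row: the live-birth mass (outcome residual) together with the
#'   tabulated post-pregnancy modern-uptake rate goes to MOC (pregnancy
#'   during lactational amenorrhea is about as likely as on modern
#'   contraception); the non-live-birth mass routes to NSA/INC/UNC/TRC at the
#'   tabulated rates; the row is renormalized and maternal mortality assigned
#'   to DEAD. Pregnancy is a tunnel state: zero self-transition.
#' * Every non-DEAD row is then scaled by the band's background all-cause
#'   survival. The annual all-cause probability is converted to the 9-month
#'   cycle and reduced by the maternal share of female deaths (13%), since
#'   maternal mortality enters separately through the PRE row.
#'
#' Under the `"ncp"` (universal access) scenario, traditional contraception is
#' eliminated (all TRC-bound flows redirect to MOC) and unmet need is removed
#' at every entry point: UNC-bound flows from the NSA, INC, UNC and PRE rows
#' redirect to MOC. Unintentional discontinuation out of MOC is retained as a
#' one-cycle spell in UNC (from which women return to modern use), so
#' discontinuation-related pregnancy exposure persists under universal access.
#'
#' @param params An `fpcea_params` object.
#' @param band Band label (`"15-19"` ... `"45-49"`) or an exact age.
#' @param scenario `"ccp"` (status quo) or `"ncp"` (universal access).
#' @return A 7x7 matrix with `dimnames` the state labels and attributes
#'   `band` and `scenario`. Every row sums to 1 within 1e-12.
#' @export
transition_matrix <- function(params, band, scenario = c("ccp", "ncp")) {
  scenario <- match.arg(scenario)
  if (is.numeric(band)) band <- assign_band(band)
  if (band == "50+") {
    abort("No reproductive transition matrix exists for the post-reproductive band.")
  }
  b <- match(band, BAND_LABELS)
  if (is.na(b)) abort(paste0("Unknown age band: ", band))
  at <- params$age_tables[b, ]
  g <- params$global_rates
  M <- matrix(0, 7, 7, dimnames = list(STATES, STATES))

  r <- c(NSA = at$nsa_stay, INC = at$nsa_to_inc, UNC = at$nsa_to_unc,
         MOC = at$to_moc, TRC = at$to_trc)
  M["NSA", names(r)] <- r / sum(r)

  M["INC", "PRE"] <- at$nonuser_to_pre
  M["INC", "INC"] <- 1 - at$nonuser_to_pre

  r <- c(UNC = at$unc_stay, MOC = at$to_moc, TRC = at$to_trc,
         PRE = at$nonuser_to_pre)
  M["UNC", names(r)] <- r / sum(r)

  # method rows: failure + discontinuation, remainder stays; if the drawn
  # outflow exceeds 1 the row is proportionally rescaled (stay hits zero)
  out <- g$moc_to_pre + g$moc_to_inc + g$moc_to_unc
  sc <- if (out > 1) 1 / out else 1
  M["MOC", c("PRE", "INC", "UNC")] <-
    c(g$moc_to_pre, g$moc_to_inc, g$moc_to_unc) * sc
  M["MOC", "MOC"] <- max(0, 1 - out)

  out <- g$trc_to_pre + g$trc_to_inc + g$trc_to_unc
  sc <- if (out > 1) 1 / out else 1
  M["TRC", c("PRE", "INC", "UNC")] <-
    c(g$trc_to_pre, g$trc_to_inc, g$trc_to_unc) * sc
  M["TRC", "TRC"] <- max(0, 1 - out)

  w <- c(NSA = g$pre_to_nsa, INC = g$pre_to_inc, UNC = g$pre_to_unc,
         MOC = live_birth_probability(params) + g$pre_to_moc,
         TRC = g$pre_to_trc)
  w <- w / sum(w) * (1 - g$pre_to_dead)
  M["PRE", names(w)] <- w
  M["PRE", "DEAD"] <- g$pre_to_dead

  M["DEAD", "DEAD"] <- 1

  if (scenario == "ncp") {
    alive <- STATES[1:6]
    M[alive, "MOC"] <- M[alive, "MOC"] + M[alive, "TRC"]
    M[alive, "TRC"] <- 0
    redirect <- c("NSA", "INC", "UNC", "PRE")
    M[redirect, "MOC"] <- M[redirect, "MOC"] + M[redirect, "UNC"]
    M[redirect, "UNC"] <- 0
  }

  q <- annual_to_cycle(at$background_death_annual, params$cycle_months) *
    (1 - params$maternal_death_share)
  alive <- STATES[1:6]
  M[alive, ] <- M[alive, ] * (1 - q)
  M[alive, "DEAD"] <- M[alive, "DEAD"] + q

  structure(M, band = band, scenario = scenario)
}

#' Propagate the cohort over the lifetime horizon
#'
#' Initializes the state vector from the scenario's starting distribution at
#' `start_age` and applies the band-specific transition matrix each 9-month
#' cycle. At the first cycle reaching age 50 the surviving cohort moves to the
#' NSA state (any ongoing pregnancies deliver) and thereafter only the
#' optional post-reproductive background mortality acts
#' (`post_reproductive_death_annual`, default 0 — the base case carries no
#' mortality information beyond the last tabulated band). Iteration stops at
#' `max_age` or when the surviving fraction falls below 1e-9.
#'
#' @param params An `fpcea_params` object.
#' @param scenario `"ccp"` or `"ncp"`.
#' @return An `fpcea_trace` tibble with one row per cycle: `cycle` (0-based),
#'   `age` at cycle start, the seven state-occupancy fractions, all summing
#'   to 1, `new_pregnancies` (mass newly in PRE this cycle; PRE lasts one
#'   cycle so occupancy equals inflow), `deaths` (increment in DEAD), and
#'   `discount` (`(1+r)^(-y t)` for cycle length `y` years). Attributes carry
#'   `scenario` and the parameter set.
#' @examples
#' tr <- run_cohort(default_parameters(), "ccp")
#' sum(tr$new_pregnancies) # expected lifetime pregnancies per woman
#' @export
run_cohort <- function(params, scenario = c("ccp", "ncp")) {
  scenario <- match.arg(scenario)
  cycle_years <- params$cycle_months / 12
  v <- params$starting_distribution[[scenario]]
  if (is.null(v)) abort(paste0("No starting distribution for scenario ", scenario))
  n_cycles <- ceiling((params$max_age - params$start_age) / cycle_years)
  mats <- lapply(BAND_LABELS, function(b) transition_matrix(params, b, scenario))
  q_post <- annual_to_cycle(params$post_reproductive_death_annual %||% 0,
                            params$cycle_months)
  occ <- matrix(0, n_cycles + 1, 7, dimnames = list(NULL, STATES))
  occ[1, ] <- v
  kept <- n_cycles + 1
  for (t in seq_len(n_cycles)) {
    age <- params$start_age + cycle_years * (t - 1)
    if (age >= 50) {
      # post-reproductive: deliver/stop, everyone alive sits in NSA
      alive <- sum(v[1:6])
      v <- c(NSA = alive * (1 - q_post), INC = 0, UNC = 0, MOC = 0, TRC = 0,
             PRE = 0, DEAD = v[["DEAD"]] + alive * q_post)
    } else {
      b <- floor((age - 15) / 5) + 1
      v <- drop(v %*% mats[[min(b, 7L)]])
    }
    occ[t + 1, ] <- v
    if (1 - v[["DEAD"]] < 1e-9) { kept <- t + 1; break }
  }
  occ <- occ[seq_len(kept), , drop = FALSE]
  cycle <- seq_len(kept) - 1L
  trace <- as_tibble(occ)
  names(trace) <- tolower(STATES)
  trace <- dplyr::bind_cols(
    tibble(cycle = cycle, age = params$start_age + cycle_years * cycle),
    trace
  )
  trace$new_pregnancies <- trace$pre
  trace$deaths <- c(trace$dead[1], diff(trace$dead))
  trace$discount <- (1 + params$discount_rate_annual)^(-cycle_years * cycle)
  structure(trace,
            class = c("fpcea_trace", class(trace)),
            scenario = scenario, params = params)
}

#' @export
print.fpcea_trace <- function(x, ...) {
  cat(sprintf("<fpcea_trace> scenario %s: %d cycles, ages %.2f-%.2f\n",
              attr(x, "scenario"), nrow(x), min(x$age), max(x$age)))
  cat(sprintf("  surviving fraction at end: %.4f; lifetime pregnancies %.3f\n",
              1 - x$dead[nrow(x)], sum(x$new_pregnancies)))
  NextMethod()
}
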