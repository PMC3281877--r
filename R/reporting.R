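#' Report tables for a two-program comparison
#'
#' Three report shapes mirror the standard presentation of a
#' cost-effectiveness analysis of this kind:
#'
#' * `report_base_case()`: per-woman mean costs (total, program, medical) by
#'   perspective with incremental costs, DALE, incremental DALE, the
#'   ICER/dominance verdict and net costs.
#' * `report_cost_consequences()`: cohort-scale totals and differences for
#'   costs and every health outcome (a cost-consequences analysis).
#' * `report_incremental()`: per-woman incremental costs and outcome
#'   reductions in long form.
#'
#' Values are unrounded; round only for display.
#'
#' @param cea An `fpcea_cea` object from [compare_programs()].
#' @param cohort_size Cohort size for the cost-consequences table.
#' @return A tibble in the respective shape.
#' @export
report_base_case <- function(cea) {
  cc <- cea$comparator_result
  nc <- cea$intervention_result
  d <- cea$deltas
  purrr::map_dfr(c("societal", "moh"), function(ps) {
    i <- which(cc$perspective == ps)
    j <- which(d$perspective == ps)
    tibble(
      perspective = ps,
      total_cost_comparator = cc$cost_total[i],
      total_cost_intervention = nc$cost_total[i],
      incremental_cost = d$delta_cost[j],
      dale_comparator = cc$dale[i],
      dale_intervention = nc$dale[i],
      incremental_dale = d$delta_dale[j],
      icer = ifelse(d$verdict[j] == "icer", d$icer[j], NA_real_),
      verdict = d$verdict[j],
      program_cost_comparator = cc$cost_program[i],
      program_cost_intervention = nc$cost_program[i],
      incremental_program_cost = d$delta_program[j],
      medical_cost_comparator = cc$cost_medical[i],
      medical_cost_intervention = nc$cost_medical[i],
      averted_medical_cost = d$averted_medical[j],
      net_cost = d$net_cost[j]
    )
  })
}

#' @rdname report_base_case
#' @export
report_cost_consequences <- function(cea, cohort_size = 1e5) {
  cost_consequences(cea, cohort_size)
}

#' @rdname report_base_case
#' @export
report_incremental <- function(cea) {
  d <- cea$deltas
  dplyr::bind_rows(
    tibble(outcome = paste0("incremental_cost_", d$perspective),
           value = d$delta_cost),
    tibble(outcome = "incremental_life_expectancy", value = d$delta_le[1]),
    tibble(outcome = "incremental_dale", value = d$delta_dale[1]),
    tibble(outcome = paste0("reduction_in_", cea$reductions$outcome),
           value = cea$reductions$reduction)
  )
}

#' Run manifest
#'
#' A plain-text record of a model run: timestamp, parameter-file hash, seeds,
#' command and package version — one per output directory.
#'
#' @param path Output file path.
#' @param params_file Parameter file used (hashed if it exists).
#' @param seed Seed(s) used.
#' @param command Free-text command description.
#' @return The manifest lines, invisibly; written to `path`.
#' @export
write_manifest <- function(path, params_file = NULL, seed = NULL,
                           command = "") {
  hash <- if (!is.null(params_file) && file.exists(params_file)) {
    unname(tools::md5sum(params_file))
  } else {
    "none"
  }
  lines <- c(
    paste0("timestamp: ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    paste0("parameter_file: ", params_file %||% "builtin"),
    paste0("parameter_file_md5: ", hash),
    paste0("seed: ", paste(seed %||% "none", collapse = ",")),
    paste0("command: ", command),
    paste0("package_version: ", as.character(utils::packageVersion("fpcea")))
  )
  writeLines(lines, path)
  invisible(lines)
}
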