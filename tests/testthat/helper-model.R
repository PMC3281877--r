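# Shared fixtures for the suite. Tolerances here belong to the tests
# themselves; report tables are never rounded before comparison.

base_params <- default_parameters()

# a trace constructed by hand: immortal cohort, n cycles, optional columns
hand_trace <- function(n, moc = 0, pre = 0, r = 0, cycle_years = 0.75) {
  cycle <- seq_len(n) - 1
  tibble::tibble(
    cycle = cycle,
    age = 15 + cycle_years * cycle,
    nsa = 1 - moc - pre, inc = 0, unc = 0, moc = moc, trc = 0,
    pre = pre, dead = 0,
    new_pregnancies = pre,
    deaths = 0,
    discount = (1 + r)^(-cycle_years * cycle)
  )
}
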