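---
title: "A lifetime Markov cohort model of contraceptive access: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A lifetime Markov cohort model of contraceptive access: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fpcea)
```

## The question and the model

About two thirds of Ugandan women who want contraception lack access to
modern methods. `fpcea` asks what universal access would be worth: it
compares a hypothetical universal-access program (NCP), under which every
woman desiring contraception uses a modern method and none use traditional
methods, against the status quo (CCP), in which roughly 31% of such women
use modern methods, 8% traditional methods, and 61% go without.

The engine is a deterministic Markov cohort model. A closed cohort of
15-year-old women (the approximate age of sexual debut) is propagated over
9-month cycles — the length of a pregnancy — through seven states:

* **NSA** — not sexually active;
* **INC** — intentional non-use of contraception (wanting to conceive);
* **UNC** — unintentional non-use (unmet need for contraception);
* **MOC** — modern contraception;
* **TRC** — traditional contraception;
* **PRE** — pregnant (a tunnel state, occupied for exactly one cycle);
* **DEAD** — absorbing.

Transition probabilities are age-specific in five-year bands from 15–19 to
45–49, taken from the 2006 Uganda Demographic and Health Survey and
published failure/discontinuation studies. Each cycle the cohort vector is
multiplied by the band's 7×7 row-stochastic matrix; the trace records
occupancy, new pregnancies (the PRE inflow), deaths and the discount
factor. Outcomes and costs are expectations per woman:

* discounted life expectancy \(LE = \sum_t 0.75\,a_t (1+r)^{-0.75t}\),
  with \(a_t\) the surviving fraction and \(r = 3\%\) per year;
* disability-adjusted life expectancy
  \(DALE = LE - d \cdot P_{disc}\), where \(d = 0.272\) DALYs per pregnancy
  (maternal conditions) and \(P_{disc}\) the discounted pregnancy count;
* costs accrue only in MOC (per discounted person-year of use) and PRE
  (per discounted pregnancy episode), from a Ministry-of-Health and a
  societal perspective (2010 US$);
* the pregnancy-outcome cascade (ectopic pregnancy, miscarriage, induced
  abortion, stillbirth, live birth as the residual) and child deaths per
  live birth are reporting outputs only.

The incremental analysis compares NCP to CCP by incremental cost and
incremental DALE with dominance detection, classifies the result against
willingness-to-pay thresholds of one and three times Uganda's 2010 GDP per
capita ($474 and $1,423 per DALY averted), and scales per-woman results to
a 100,000-woman cohort for the cost-consequences table.

## Matrix construction

The row layouts follow the data's structure (see `transition_matrix()` for
the full rules). Three construction choices deserve explanation because
the sources underdetermine them:

**Row renormalization.** The tabulated outflow rows do not always sum to
one (rounding in the sources; the 45–49 sexual-activity row sums to 1.03,
and the unmet-need row mixes columns shared with other rows). Any outflow
row is proportionally rescaled to sum to one, which preserves the
tabulated ratios. The same rule revalidates parameter draws during
sensitivity analysis.

**The post-pregnancy row.** The sources state that women with live births
move to modern contraception, because pregnancy risk during lactational
amenorrhea is comparable to risk on modern methods, while non-live-birth
outcomes disperse to the other states. The live-birth probability (0.73,
the residual of the four adverse outcome incidences) plus the tabulated
post-pregnancy modern-uptake rate therefore route to MOC; the tabulated
rates into INC (0.03), UNC (0.06) and TRC (0.01) take the rest; maternal
mortality (0.0034 per pregnancy) goes to DEAD; and the row is
renormalized. Under this reading no state returns to NSA before
menopause. We also examined the alternative readings — routing the full
0.73 to NSA as literally tabulated, or dispersing the non-live-birth mass
like the sexual-activity row — and both understate lifetime pregnancies
and modern-use person-years by 7–25% against the published cohort
results; the live-births-to-MOC reading reproduces them within a few
percent, so it is the package default.

**The universal-access scenario.** Universal access is encoded
structurally: traditional use is eliminated (all TRC-bound flows redirect
to MOC) and unmet need is removed at every entry point — the flows into
UNC from sexual-activity onset, from intentional non-use and from the
post-pregnancy row all redirect to MOC, and the starting distribution
moves the modern + traditional + unmet-need mass (17.6%) into MOC.
Unintentional discontinuation out of MOC is, however, retained as a
one-cycle spell in UNC from which women return to modern use.
The alternative — redirecting discontinuation as well, so that MOC is
never left unintentionally — makes universal access too effective to be
consistent with the published scenario results (it understates
universal-access pregnancies by about 17% and costs by about 10%),
whereas the retained-discontinuation reading reproduces total costs
within 0.4% and leaves pregnancies about 11% high. Neither reading
matches everything: the published program-cost pattern favours the full
redirect while the published pregnancy count favours retained exposure;
we chose the reading that minimizes overall disagreement and note that
the scenario's pregnancy-side results carry that residual bias.

The 2.1% of women wanting to conceive start in INC under both programs: a
starting distribution must sum to one, and this group is defined
identically under either program.

## Mortality and the horizon

The background mortality row is an annual all-cause probability per band;
the engine converts it to the 9-month cycle
(`annual_to_cycle()`, constant hazard) and multiplies by 0.87, removing
the 13% of female deaths attributable to maternal causes, which enter
separately through the pregnancy state (0.0034 per pregnancy). Treating
the tabulated values as annual is deliberate: they match published
all-cause female mortality for Uganda at the annual scale, and treating
them as per-cycle overstates mortality enough to depress discounted life
expectancy by roughly 12% against the published value.

The mortality table ends at 45–49. The base case applies **no** excess
mortality beyond age 49; at the first post-reproductive cycle the
surviving cohort (including any ongoing pregnancies, which deliver) moves
to NSA, where it neither conceives nor uses contraception. Discounted
life expectancy then converges because of discounting alone, and the
default horizon caps at `max_age = 110` years — the conventional closure
age of period life tables. A user who wants post-reproductive mortality
can set `post_reproductive_death_annual`. This is the model's weakest
demographic assumption: undiscounted life expectancy is overstated, which
is why the package reports discounted quantities (insensitive to the tail
at 3% per year) and treats the published discounted values as the
regression surface. No half-cycle correction is applied; occupancy is
valued at cycle start.

## Sensitivity machinery

`sensitivity_ranges()` assembles one-way ranges: published 95% confidence
intervals where available, otherwise ±20% for probabilities (clipped to
[0, 1]) and ±50% for costs. The tabulated upper bound of the abortion
incidence range is inconsistent with its own base value (a transcription
slip in the source) and is rebuilt from the ±20% rule. Methodological
settings — the discount rate, cycle length, horizon, starting
distribution — are never varied. The tabulated post-pregnancy 0.73 is not
an independent parameter here (it is the live-birth residual), so its
uncertainty flows through the four outcome incidences.

`tornado()` reruns the full two-scenario comparison at each range
endpoint with everything else at base and sorts by swing. `run_psa()`
draws every parameter independently each iteration — Beta distributions
for probabilities and the DALY weight, moment-matched so the mean is the
base value and the standard error is one quarter of the one-way range;
Normal for costs, truncated at zero by redraw — then renormalizes rows
during matrix construction rather than rejecting draws (the sources
specify independent draws, not a joint row distribution). A Beta cannot
represent a standard error with `se² ≥ m(1−m)`; such parameters (none in
the default set) fall back to a [0, 1]-truncated Normal. All randomness
flows from a single user seed; runs are bit-reproducible.
`ceac()` counts net-monetary-benefit wins, `λ·ΔDALE − ΔCost > 0`, on a
$0–$1,423 grid in $10 steps by default.

At the default parameterization the base-case run takes a few
milliseconds, a 23-parameter PSA iteration about 35 ms; the shipped tests
use 200–1,000 iterations and the command-line default is 10,000.

## What the synthetic generator does and does not emulate

`random_parameter_set()` generates structurally valid parameterizations:
row-stochastic sexual-activity rows (Dirichlet-style), age-declining
non-user pregnancy probabilities, age-increasing background mortality,
episode-based pregnancy outcomes with a live-birth residual,
cost magnitudes log-uniform over [1, 1000] so that linearity properties
are exercised across scales, societal ≥ MoH unit costs, and a scenario
pair whose universal-access starting distribution absorbs the modern,
traditional and unmet-need mass into modern use. Property tests (mass
conservation, monotone mortality, cost linearity, comparison
antisymmetry, seeded reproducibility) run over hundreds of such sets.

The generator draws parameters, not survey microdata: it does not emulate
sampling error, reporting biases, age-pattern correlations, or secular
trends in fertility intentions, and the model itself assumes a constant
method mix and constant intentions over a lifetime. Passing property
tests therefore demonstrates the pipeline's internal correctness on the
model's own terms, not the realism of any particular parameterization.

One interaction is worth knowing: "universal access never increases
pregnancies" is *not* a theorem of this model. If modern methods are
abandoned (to intentional non-use) much faster than traditional methods,
universal access can route women into the highest-exposure state more
quickly than the comparator. The property suite asserts the monotonicity
only under the sufficient condition that modern methods have the lowest
pregnancy hazard and are not discontinued faster than traditional ones —
which the Ugandan parameterization satisfies.

## Numerical conventions

* Cycle length 0.75 years; ages advance from exactly 15; band membership
  uses half-open intervals `[lower, upper + 1)`.
* Discounting per cycle: `(1 + r)^(-0.75 t)` with `t` the 0-based cycle.
* Degenerate inputs: outflow rows exceeding one are proportionally
  rescaled (the residual "stay" probability floors at zero); starting
  distributions are renormalized when within 0.05 of one and rejected
  otherwise; a cohort is terminated early if the surviving fraction falls
  below 1e-9.
* Dominance verdicts partition the (ΔCost, ΔDALE) plane exhaustively;
  a zero effect difference yields "dominated" (cost increase) or
  "dominant-or-equal".
* Report tables are never rounded internally; all comparisons in the test
  suite use unrounded values with explicit tolerances.

## Known limitations

* Post-reproductive mortality is absent by default (above); undiscounted
  life expectancy and any outcome dominated by the post-49 tail should
  not be read off this model.
* The tabulated neonatal/infant/child mortality triple is not cumulative
  as documented (child < infant); the package ships it verbatim as the
  base case and offers `default_parameters(child_mortality = "survey")`
  with the published survey rates per live birth (29/76/137 per 1,000),
  which reproduce the published cohort-scale death counts. Child deaths
  never feed LE, DALE or costs, so the choice does not affect the
  cost-effectiveness verdict.
* The universal-access scenario's pregnancy-side outputs run ≈11% above
  the published values under the chosen structural reading (above); its
  cost totals, life expectancy, DALE and the dominance verdict are
  reproduced within a few percent.
* The model is a cohort expectation: no individual-level heterogeneity,
  no parameter correlation in the PSA beyond row renormalization, no
  time-varying method mix, and no benefits of contraception beyond
  maternal health are represented.
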