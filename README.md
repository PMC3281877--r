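# fpcea

**Lifetime Markov cohort cost-effectiveness analysis of family planning
programs**, parameterized for Uganda from the 2006 Demographic and Health
Survey.

About two thirds of Ugandan women who want contraception lack access to
modern methods. `fpcea` estimates what closing that gap would be worth: it
compares a hypothetical universal-access program (**NCP** — every woman
desiring contraception uses a modern method, none use traditional methods)
against the status quo (**CCP**), over the whole reproductive life of a
cohort of 15-year-old women, from both the Ministry-of-Health and the
societal perspective.

The package is for health economists and reproductive-health modellers who
want the analysis as a tested, reusable pipeline rather than a spreadsheet
or a proprietary decision-tree file: every stage — parameter file, cohort
engine, outcome accrual, incremental analysis, sensitivity analysis — is an
ordinary R function that takes and returns tibbles.

## The model

A deterministic Markov cohort model with seven states

> NSA (not sexually active), INC (intentional non-use), UNC (unintentional
> non-use / unmet need), MOC (modern contraception), TRC (traditional
> contraception), PRE (pregnant; one-cycle tunnel state), DEAD

propagated over 9-month cycles with age-specific (five-year band)
transition probabilities from ages 15–49. Per woman, the model accrues

- discounted life expectancy `LE = Σ 0.75 · aₜ · (1+r)^(−0.75 t)` at
  `r = 3%/yr`,
- disability-adjusted life expectancy
  `DALE = LE − 0.272 · (discounted pregnancies)`,
- pregnancies and the outcome cascade (ectopic, miscarriage, abortion,
  stillbirth; live births are the residual, 0.73 per pregnancy),
- costs in the MOC state ($64.74 societal / $14.67 MoH per person-year) and
  per pregnancy episode ($254.33 / $96.65), 2010 US$.

The incremental analysis reports ΔCost and ΔDALE with dominance detection
(`Δcost < 0` and `ΔDALE > 0` ⇒ the intervention *dominates*), classifies
ICERs against 1× and 3× Uganda's GDP per capita ($474/$1,423 per DALY), and
scales to a 100,000-woman cohort. One-way (tornado) and probabilistic
sensitivity analysis (independent Beta draws for probabilities, truncated
Normal for costs, SE = range/4) with cost-effectiveness acceptability
curves complete the pipeline. See the methods vignette
(`vignettes/model-methods.Rmd`) for construction details and design
decisions.

## Worked example

```r
library(fpcea)

params <- read_params(default_params_path())  # packaged Uganda 2006 set
ccp <- scenario_result(params, "ccp")
ccp[, c("perspective", "le_discounted", "dale", "pregnancies",
        "total_fertility", "cost_total")]
#> # A tibble: 2 × 6
#>   perspective le_discounted  dale pregnancies total_fertility cost_total
#>   <chr>               <dbl> <dbl>       <dbl>           <dbl>      <dbl>
#> 1 societal             28.2  26.6        9.37            6.84      1976.
#> 2 moh                  28.2  26.6        9.37            6.84       678.
```

Under the status quo a woman averages 9.37 pregnancies and 6.84 live births
(the national total fertility rate is 6.7, the model's validation
benchmark), lives 28.2 discounted years from age 15, loses 1.6 of them to
pregnancy-related disability, and costs society $1,976 in contraception and
pregnancy care over her lifetime.

```r
cea <- compare_programs(params)
cea
#> <fpcea_cea> ncp vs ccp
#>   societal  dCost   -29.40  dDALE  0.136  dominant (highly cost-effective)
#>   moh       dCost   -21.26  dDALE  0.136  dominant (highly cost-effective)

glance(cea)[, c("delta_cost_societal", "delta_dale", "verdict")]
#> # A tibble: 1 × 3
#>   delta_cost_societal delta_dale verdict
#>                 <dbl>      <dbl> <chr>
#> 1               -29.4      0.136 dominant
```

Universal access both saves money (−$29/woman societal, −$21 MoH) and adds
healthy life (+0.14 DALE years/woman): it **dominates** the status quo, so
no cost-effectiveness ratio is reported. Scaled to a 100,000-woman cohort
(`cost_consequences(cea, 1e5)`), that is ≈ $2.9 million saved and ≈ 55,000
pregnancies averted. For uncertainty:

```r
psa  <- run_psa(params, n_iter = 1000, seed = 1)
mean(psa$delta_dale > 0)          # 1: every draw gains healthy life
ceac(psa, 474)$probability        # ~1: accepted at Uganda's GDP per capita
plot_ce_plane(psa); plot_ceac(ceac(psa))
tornado(params, "delta_cost_societal") |> plot_tornado()
```

A thin command-line interface wraps the same functions:

```sh
Rscript inst/cli/fpcea.R compare --out results/
Rscript inst/cli/fpcea.R psa --n 10000 --seed 1 --out results/ --plots
```

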