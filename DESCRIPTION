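Package: fpcea
Title: Lifetime Markov Cohort Cost-Effectiveness Analysis of Family Planning Programs
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A deterministic seven-state Markov cohort model of women's
    reproductive lives for evaluating contraceptive access programs, with
    Uganda's 2006 Demographic and Health Survey parameterization built in.
    Propagates a cohort of 15-year-olds over 9-month cycles through states of
    sexual inactivity, intentional and unintentional non-use of contraception,
    modern and traditional contraceptive use, pregnancy and death; accrues
    discounted life expectancy, disability-adjusted life expectancy,
    pregnancies, the pregnancy-outcome cascade and costs from governmental and
    societal perspectives; and compares a universal-access program to the
    status quo by incremental cost-effectiveness with dominance detection,
    cost-consequences scaling, one-way (tornado) sensitivity analysis and
    probabilistic sensitivity analysis with cost-effectiveness acceptability
    curves. All results are tibbles; fitted comparisons have tidy() and
    glance() methods and ggplot2 visualisations.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
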