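# Default model parameterization: contraceptive access in Uganda.
# Monetary values are 2010 US$. Probabilities are per 9-month cycle unless
# noted. Sources: 2006 Uganda Demographic and Health Survey (sexual activity,
# contraceptive prevalence, unmet need, menopause, mortality), published
# method failure/discontinuation studies for East Africa, WHO life tables and
# burden-of-disease estimates, and costing studies of Ugandan reproductive
# health services.
#
# age_tables: per five-year band.
#   nsa_to_inc / nsa_to_unc  onset of sexual activity into intentional /
#                            unintentional non-use of contraception
#   to_moc / to_trc          uptake of modern / traditional methods (from
#                            inactivity or unmet need)
#   nsa_stay                 remaining sexually inactive
#   nonuser_to_pre           pregnancy probability of non-users, already
#                            adjusted for age-specific menopause prevalence
#   unc_stay                 remaining in unmet need
#   background_death_annual  ANNUAL all-cause female death probability; the
#                            engine converts it to the cycle scale and
#                            removes the maternal share (maternal_death_share)
# global_rates: method failure (moc/trc_to_pre), discontinuation
#   (moc/trc_to_inc, moc/trc_to_unc), post-pregnancy routing of non-live-birth
#   outcomes (pre_to_*), maternal mortality per pregnancy (pre_to_dead).
#   Live births route to modern contraception inside the engine (lactational
#   amenorrhea); pre_to_nsa is zero in this parameterization.
# outcomes: per-pregnancy incidences; live birth is the residual.
#   neonatal/infant/child mortality apply per live birth (reporting only).
# costs: contraception per person-year of modern use; pregnancy per episode.
schema_version: 1
age_tables:
  age_band:
  - 15-19
  - 20-24
  - 25-29
  - 30-34
  - 35-39
  - 40-44
  - 45-49
  nsa_to_inc:
  - 0.02
  - 0.17
  - 0.17
  - 0.12
  - 0.08
  - 0.05
  - 0.13
  nsa_to_unc:
  - 0.07
  - 0.21
  - 0.26
  - 0.29
  - 0.29
  - 0.27
  - 0.19
  to_moc:
  - 0.09
  - 0.17
  - 0.19
  - 0.22
  - 0.19
  - 0.21
  - 0.19
  to_trc:
  - 0.02
  - 0.03
  - 0.04
  - 0.04
  - 0.04
  - 0.06
  - 0.05
  nsa_stay:
  - 0.8
  - 0.41
  - 0.34
  - 0.31
  - 0.39
  - 0.41
  - 0.47
  nonuser_to_pre:
  - 0.85
  - 0.85
  - 0.85
  - 0.83
  - 0.81
  - 0.69
  - 0.17
  unc_stay:
  - 0.07
  - 0.05
  - 0.05
  - 0.05
  - 0.06
  - 0.16
  - 0.53
  background_death_annual:
  - 0.002
  - 0.003
  - 0.006
  - 0.009
  - 0.012
  - 0.011
  - 0.011
global_rates:
  moc_to_pre: 0.03
  trc_to_pre: 0.2
  moc_to_inc: 0.25
  moc_to_unc: 0.34
  trc_to_inc: 0.26
  trc_to_unc: 0.36
  pre_to_nsa: 0.0
  pre_to_inc: 0.03
  pre_to_unc: 0.06
  pre_to_moc: 0.04
  pre_to_trc: 0.01
  pre_to_dead: 0.0034
outcomes:
  miscarriage: 0.049
  ectopic: 0.014
  abortion: 0.19
  stillbirth: 0.017
  neonatal_mortality: 0.021
  infant_mortality: 0.055
  child_mortality: 0.049
costs:
  contraception_moh: 14.67
  contraception_societal: 64.739999999999995
  pregnancy_moh: 96.650000000000006
  pregnancy_societal: 254.330000000000013
daly_per_pregnancy: 0.272
discount_rate_annual: 0.03
cycle_months: 9
start_age: 15.0
max_age: 110.0
maternal_death_share: 0.13
post_reproductive_death_annual: 0.0
life_expectancy_metadata: 51.700000000000003
starting_distribution:
  ccp:
    NSA: 0.803803803803804
    INC: 0.021021021021021
    UNC: 0.066066066066066
    MOC: 0.091091091091091
    TRC: 0.018018018018018
    PRE: 0.0
    DEAD: 0.0
  ncp:
    NSA: 0.803
    INC: 0.021
    UNC: 0.0
    MOC: 0.176
    TRC: 0.0
    PRE: 0.0
    DEAD: 0.0
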