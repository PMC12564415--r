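# agestage

Age-stage, two-sex life table analysis and deterministic population
projection for insect cohorts, built around the starvation biology of the
endangered monophagous butterfly *Luehdorfia chinensis*: its larvae feed
only on *Asarum* herbs, and host-plant scarcity exposes dispersing larvae to
short-term starvation that depresses development, survival and fecundity.
The package turns individual daily rearing records (stage durations, stage
of death, sex, daily egg counts) into population-level demography and
projects the consequences over a two-year horizon.

## What it computes

For a cohort of `n` individuals censused daily:

- the age-stage survival matrix `s_xj` (adult stage split by sex) and
  age-stage fecundity `f_xj`, with `l_x = Σ_j s_xj` and
  `m_x = Σ_j s_xj f_xj / l_x`, conserving eggs exactly:
  `n · Σ_x l_x m_x` = total eggs recorded;
- the intrinsic rate of increase `r` solving the age-0-indexed Euler–Lotka
  equation `Σ_x exp(−r(x+1)) l_x m_x = 1` by bracketed bisection, plus
  `λ = e^r`, `R0 = Σ l_x m_x`, `GRR = Σ m_x`, `T = ln(R0)/r` and mean
  fecundity per female `F`;
- age-stage life expectancy `e_xj` and reproductive value `v_xj`
  (discounted future offspring; `v_{0,egg} = λ` exactly);
- bootstrap means, SEs, percentile intervals and a paired two-group
  bootstrap comparison of all parameters;
- an empirical daily transition schedule and a deterministic age-stage
  projection (`log10(N+1)` stage sizes, zero-safe daily growth rates, and
  the percent decline of one projected population relative to another).

A synthetic cohort generator emulates the control and pooled
larval-starvation treatments from the published summary statistics (stage
duration means ± SD, survival counts, sex ratio, fecundity), and a
calibration routine tunes a configuration so its analytic `(R0, T)` match
published values exactly. The full analysis — generation, life tables,
bootstrap comparison, 730-day projections, decline — runs in seconds with
no external data.

## Worked example

The canonical two-individual cohort ships as a CSV fixture: female A lives
2 d egg, 2 d larva, 2 d adult and lays 4 then 2 eggs; B dies entering the
larval stage at age 2.

```r
library(agestage)
sch <- stage_schema(c("egg", "larva", "adult"))
coh <- read_cohort(system.file("extdata", "toy_individuals.csv", package = "agestage"),
                   system.file("extdata", "toy_fecundity.csv", package = "agestage"),
                   sch)
population_parameters(build_life_table(coh))
#> <population_parameters>
#>   r      = 0.206860 /day
#>   lambda = 1.229810 /day
#>   R0     = 3.0000 offspring/individual
#>   GRR    = 6.0000
#>   T      = 5.311 days
#>   F      = 6.0000 eggs/female (N_f = 1 of N = 2)
```

Half the cohort reaches adulthood, so `R0 = F·N_f/N = 6·1/2 = 3` offspring
per newborn; the cohort would triple every generation (`T ≈ 5.3` d), i.e.
grow 23% per day (`λ = 1.23`). The full two-group scenario:

```r
sc <- run_decline_scenario(seed = 1)   # calibrate, generate n = 500/group, project 730 d
sc$parameters_control$r                # realized intrinsic rate, control cohort
#> [1] 0.00525564
sc$parameters_starvation$r
#> [1] 0.003285074
sc$decline                             # % decline of ST vs CG total population at day 730
#> [1] 72.5173
```

The decline statistic is seed-dependent (roughly 70–90% across seeds; the
methods vignette explains why day 730 sits inside a sharp generation
pulse).

## The analysis workflow

Numbered drivers under `analysis/` run the study-shaped analysis and write
tables under `results/`:

```sh
Rscript analysis/01_simulate_cohorts.R --seed 1   # calibrated CG/ST cohorts
Rscript analysis/02_life_tables.R                 # life tables, e_xj, v_xj, parameters
Rscript analysis/03_bootstrap_comparison.R --reps 2000 --seed 1
Rscript analysis/04_projection_decline.R          # 730-day projections and decline
```

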