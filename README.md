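# remeth

Quantitative analysis of **de novo DNA remethylation kinetics** in cancer
cell lines after treatment with a demethylating agent
(5-aza-2′-deoxycytidine, "5-AZA"). When cultured cell lines are globally
demethylated and then followed for weeks by bisulfite pyrosequencing,
percent methylation at each locus recovers along a sigmoid trajectory
whose shape differs systematically between CpG-island methylator
phenotype (**CIMP**) lines and non-CIMP lines: CIMP lines start
re-methylating immediately but slowly, non-CIMP lines show a delay
followed by a fast burst. `remeth` packages the full analysis of such
experiments for epigenomics groups running demethylation–recovery time
courses:

- **Curve fitting** — each run (one cell line × one locus) is fitted with
  the delayed-tanh recovery curve

  `f(t) = y0 + y1 · tanh(m·t − b)`

  where `m` (day⁻¹) is the remethylation rate, the dimensionless `b` is
  the onset (its time equivalent is the delay `b′ = b/m` in days),
  `y0 − y1·tanh(b)` is the post-treatment starting level and `y0 + y1`
  the target level. Runs are classified as successful or excluded
  (`base_too_low`, `insufficient_drop`, `no_reclimb`, `erratic`).
- **Correlation screen** — all pairs of fitted (`m`, `b`, `b′`, `y0`,
  `y1`, `y0+y1`) and directly read quantities (baseline `B`, post-drop
  level `A`, `(B−A)/B`, final level `L`, `L/B`) are tested with Pearson
  (two-sided t) and Spearman (t transform on average ranks)
  correlations, arranged as a symmetric p-value grid with sign
  annotations.
- **Mechanistic model** — a stiff ODE system in which a signalling
  cascade activates de novo methyltransferase (MTase) under negative
  feedback from methylated "sensor" loci; corrupting the feedback
  (constant low MTase production) reproduces CIMP-like kinetics, intact
  feedback reproduces the non-CIMP delay-then-burst.
- **Cell growth kinetics** — division and death rates estimated from
  live/dead counts via an exponential fit plus a closed-form
  interval-dead-count estimator (`division = g + d`).
- **Synthetic data** — a seeded generator that emulates the study
  design (4 lines × 7 loci, CIMP baselines high, a planted negative
  rate–baseline correlation), so the whole pipeline is testable without
  laboratory data.

## Worked example

```r
library(remeth)

panel <- simulate_methylation_panel(panel_config(seed = 42))
fits  <- fit_methylation_panel(panel)
table(fits$status)
#>    erratic successful
#>          1         27

headline_tests(fits)[, c("label", "n", "pearson_r", "p_pearson", "sign")]
#>               label  n pearson_r p_pearson sign
#> 1  rate vs baseline 27    -0.628  4.50e-04    -
#> 2 onset vs baseline 27    -0.724  1.94e-05    -
#> 3     rate vs onset 27     0.869  4.25e-09    +
#> 4 delay vs baseline 27    -0.747  7.76e-06    -
```

The screen recovers the structure planted by the generator: the
remethylation rate `m` correlates *negatively* with the baseline level
`B` (high-baseline CIMP lines re-methylate slowly), and `m` and `b` vary
together. `aggregate_by_cell_line(fits)` shows the same contrast as
group means, e.g. mean `m` of 0.07–0.11 day⁻¹ for the two CIMP lines
versus 0.14–0.20 day⁻¹ for the two non-CIMP lines under the default
generator settings.

The mechanistic model reproduces the same contrast from first
principles. With the reference parameter set, a 72-hour in-silico
treatment gives:

```r
non  <- recovery_metrics(simulate_treatment_response(ode_parameters()))
cimp <- recovery_metrics(simulate_treatment_response(ode_parameters(mode = "cimp")))
#>       mode onset_delay_days max_slope_pct_per_day final_level_pct
#> 1 non_cimp             0.55                 2.78             59.6
#> 2     cimp             0.00                 0.50             38.5
```

The feedback (non-CIMP) run recovers fast after a lag and stabilizes
*below* its pre-treatment level of 73.2% (its sensors demethylated less
than the locus, so feedback shuts MTase off early); the corrupted-
feedback (CIMP) run climbs immediately but ~6× slower. The untreated
non-CIMP steady state has the closed form
`100·(1 − (1 − c/k2)^(λ·k2/(γ·k1)))` = 73.21% of capacity, which the
integrator matches to < 0.01 percentage points,
independent of the cascade length.

`run_full_analysis(run_config(seed = 1), out_dir = "out")` executes every
stage and writes all tables (panel, per-run fits and statuses,
correlation screen, p-value grid, per-line means, model trajectories,
growth rates) plus a machine-readable `summary.json`; identical seeds
give byte-identical outputs.

## Package layout

| area | functions |
|---|---|
| synthetic data | `panel_config()`, `simulate_methylation_panel()`, `panel_truth()`, `simulate_cell_counts()` |
| curve fitting | `eval_tanh()`, `fit_tanh()`, `classify_run()`, `derive_run_summary()`, `fit_methylation_panel()` |
| correlation screen | `pairwise_correlations()`, `p_value_grid()`, `aggregate_by_cell_line()`, `headline_tests()` |
| mechanistic model | `ode_parameters()`, `treatment_protocol()`, `production_rate()`, `simulate_feedback_model()`, `simulate_treatment_response()`, `steady_state_fraction()`, `recovery_metrics()` |
| growth kinetics | `fit_growth_rate()`, `estimate_death_rate()`, `fit_growth_kinetics()`, `rates_vs_methylation()` |
| pipeline | `run_config()`, `read_run_config()`, `run_full_analysis()` |

Fitted objects support `tidy()`, `glance()` and `autoplot()`; the
methods vignette (`vignettes/remethylation-kinetics.Rmd`) documents the
models, the defaults and the numerical choices.
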