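# persisterkit

Quantitative analysis of bacterial antibiotic persistence driven by
alarmone-mediated GTP depletion.

A small fraction of genetically drug-susceptible bacteria survives prolonged
bactericidal treatment by switching into dormancy and regrowing once the drug
is gone. In *Bacillus subtilis* this switch runs through the stringent-response
alarmone (p)ppGpp: alarmone accumulation shuts down GTP biosynthesis, and when
a cell's GTP falls below a threshold it stops elongating, derepresses a
CodY-controlled "low-GTP" fluorescent reporter, and becomes refractory to
killing. persisterkit packages the full quantitative workflow around that
biology, for microbiologists analyzing time-kill, flow-cytometry and
time-lapse data:

* **Kill-curve decomposition** — fit the two-compartment killing model
  `S(t) = (1-f) e^(-k_s t) + f e^(-k_p t)` in log10-survival space with
  censored below-detection points, multi-start optimization and a
  single-exponential fallback (`fit_biphasic()`); estimate the persister
  fraction as fitted plateau or fixed-endpoint survival
  (`persister_fraction()`); quantify tolerance as MDK99 — the minimum
  duration of killing for 99% of the *persister-subtracted* population,
  `ln(100)/k_s` (`mdk99()`); compare conditions with log-scale t-tests
  (`compare_conditions()`).
* **Cytometry gating** — autofluorescence subtraction against a reporter-free
  control, the fivefold-above-mean bright gate for low-GTP cells
  (`gate_low_gtp()`), antibiotic-induced fractions by before/after
  subtraction (`induced_fraction()`), and an in-silico FACS sort-and-kill
  experiment (`sort_and_kill()`).
* **Single-cell analysis** — per-frame specific growth rate
  `mu = (1/l)(dl/dt)` bridged across divisions (`specific_growth_rate()`),
  dormancy-entrance detection with reporter-precedence and
  threshold-consistency statistics (`detect_entrance()`,
  `threshold_consistency()`, `precedence_fraction()`), and switch-versus-
  graded model comparison of the growth-fluorescence relationship
  (`fit_growth_fluorescence()`).
* **Condition sweeps** — replicate-level Pearson correlations across growth
  conditions that separate persistence (tracks the low-GTP outlier fraction)
  from tolerance (tracks population growth rate) (`build_condition_summary()`,
  `uncoupling_report()`).
* **A mechanistic generator** — a stochastic single-cell model of the
  (p)ppGpp–GTP circuit (Hill-type allosteric self-amplification with
  coefficient 3, GTP-synthesis inhibition, GTP-limited growth, OU extrinsic
  noise, CodY-repressed reporter) that produces every input the analyses
  consume: population trajectories (`simulate_cells()`), time-lapse lineage
  trees (`simulate_lineage()`), kill curves (`generate_kill_curve()`) and
  cytometry event tables (`generate_cytometry()`), under a table of ~18
  cited experimental scenarios (`scenario_table()`).

See the vignette `vignettes/persisterkit-methods.Rmd` for the model, its
assumptions, calibration and limitations.

## Worked example

Generate wild-type kill curves, fit them, and compare against the
alarmone-null mutant:

```r
library(persisterkit)

kc  <- generate_kill_curve("WT_exponential_VAN", n_reps = 3, seed = 10)
fits <- lapply(split(kc, kc$replicate), fit_biphasic)
fits[[1]]
#> <biphasic_fit> ok
#>   f = 0.0007942  k_s = 2.321/h  k_p = 4.734e-09/h  N0 = 9.834e+07
#>   MDK99 = 1.984 h  RSS(log10) = 0.007362  censored = 0/7

kc0  <- generate_kill_curve("ppGpp0_VAN", n_reps = 3, seed = 12)
fits0 <- lapply(split(kc0, kc0$replicate), fit_biphasic)
compare_conditions(fits0, fits, metric = "f")$fold_change
#> [1] 0.1557155

persister_fraction(kc[kc$replicate == 1, ], method = "endpoint")
#> [1] 0.0008020305
```

The fitted plateau `f` is the persister fraction (~0.1% of the wild-type
population), `k_s` the susceptible kill rate, MDK99 the persister-subtracted
time to 99% killing, and the endpoint estimator reads the same persister
level directly off the 5-h survival. The alarmone-null mutant carries an
order of magnitude fewer persisters (the fold change of 0.16 reflects the
free fit's plateau noise: `k_p` is weakly identified from a 5-h series and
trades off against `f`; passing an independently measured rate via
`fit_biphasic(..., k_p_fixed = )` stabilizes it — see the vignette).

Sort the brightest 0.1% of a synthetic reporter population and kill for 5 h:

```r
cy <- generate_cytometry("WT_exponential_VAN", n_events = 1e6, seed = 14)
sort_and_kill(cy$sample, top_fraction = 0.001, seed = 15)
#> # A tibble: 2 x 5
#>   fraction n_events n_dormant survivors survival
#>   <fct>       <int>     <int>     <int>    <dbl>
#> 1 bright       1000      1000       797 0.797
#> 2 dim        999000      1073       868 0.000869
```

Nearly all bright-sorted (low-GTP) cells survive as persisters (~80%), while
the dim fraction survives at the bulk persister level (~0.1%).

End-to-end reproduction recipes (`run_recipe("all", run_config(seed = 1))`)
write kill-curve fits, the carbon-source sweep with its uncoupling report,
the sort-and-kill table and the induction analysis into one directory, with
seeds and a config hash in every output. A thin command-line front end lives
at `inst/cli/persisterkit.R` (subcommands `fit-kill`, `gate`, `sweep`,
`recipe`).

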