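---
title: "Models and methods behind persisterkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind persisterkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(persisterkit)
```

persisterkit quantifies bacterial antibiotic **persistence** — the survival of
a small, phenotypically switched subpopulation through bactericidal treatment
— and separates it from population **tolerance** (slower killing of everyone).
Its analyses are built around the biology of *Bacillus subtilis*, where the
alarmone (p)ppGpp inhibits GTP biosynthesis; when single cells deplete GTP
below a threshold they stop growing, become refractory to killing, and light
up a CodY-repressed "low-GTP" fluorescent reporter. The package provides both
the analysis operations (kill-curve decomposition, cytometry gating,
single-cell entrance detection, condition-sweep correlation) and a stochastic
mechanistic model that generates all the synthetic inputs the analyses
consume, calibrated so that the emulated conditions reproduce the population
fractions the experimental system exhibits.

## The two-compartment killing model

A kill curve records CFU/ml during lethal antibiotic exposure. With a
persister subpopulation of fraction $f$, survival is biexponential:

$$S(t) = (1-f)\,e^{-k_s t} + f\,e^{-k_p t}, \qquad 0 \le k_p < k_s.$$

`fit_biphasic()` fits $\log_{10} S(t)$ by least squares — curves span five or
more decades, so equal weight per timepoint in log space is the appropriate
loss. Points below the plating detection limit are kept as one-sided censored
residuals (the model is penalized only if it predicts counts above the
limit); dropping them would bias the plateau upward. The optimizer uses eight
deterministic starts spanning $f \in [10^{-4}, 10^{-1}]$ on an unconstrained
parameterization ($\mathrm{logit} f$, $\log k_s$, a logit ratio forcing
$k_p < k_s$, $\log N_0$), followed by a Levenberg–Marquardt polish; ties are
broken by RSS, then by smaller $f$. A single-exponential fit runs alongside,
and when it wins on AIC the curve is reported as non-biphasic with $f$ at the
zero boundary, rather than returning a meaningless tiny plateau.

Two persister estimators are first-class, because published levels are
variously one or the other: the fitted plateau $f$ and the surviving fraction
at a fixed endpoint (default 5 h, configurable). On clean data with $k_p = 0$
they agree to three significant figures; with $k_p > 0$ the endpoint sits
below the plateau by $e^{-5 k_p}$.

**Two-stage fitting.** Over a 5-h series the plateau decay $k_p$ is informed
by only the last two or three points, so it is weakly identified and trades
off against $f$ along $f e^{-\bar t\, k_p} \approx$ const; freely fitted, this
tradeoff inflates the plateau-fraction CV several-fold. When an independent
estimate of $k_p$ exists — the kill curve of FACS-sorted persisters measures
it directly — `fit_biphasic(..., k_p_fixed = )` holds it fixed, and $f$
becomes a stable, nearly direct plateau readout. The benchmark analyses use
this two-stage route (sort-and-kill first, plateau fits second); the default
remains the free fit.

**MDK99 with persister subtraction.** Tolerance is quantified as the minimum
duration of killing for 99% of the population *after removing the persister
compartment*: $S_{\mathrm{adj}}(t) = (S(t) - f e^{-k_p t})/(1-f)$, solved for
$S_{\mathrm{adj}} = 0.01$. Algebraically $S_{\mathrm{adj}}(t) = e^{-k_s t}$,
so the estimator is a pure property of the logarithmic killing phase
($\ln(100)/k_s$) and invariant to $f$ — exactly the point of the subtraction:
tolerance should not be inflated by a surviving plateau.

## The stochastic alarmone–GTP feedback model

No mechanistic equations exist in the source experimental literature for this
circuit; the ODE/SDE system here is this package's construction, with every
term anchored to a qualitatively established mechanism. Per cell, with
alarmone $P$ (µM), GTP $G$ (mM), length $l$ (µm) and reporter $F$ (AU):

$$\frac{dP}{dt} = \Big[\underbrace{V_R\big(1 + a_R \tfrac{P}{K_B+P}\big)}_{\text{basal + alarmone-activated Rel}} + \underbrace{V_B \tfrac{P^{n_B}}{K_B^{n_B}+P^{n_B}}}_{\text{allosteric SasB feedback}} \Big] e^{\eta - \sigma_\eta^2/2} + V_A \cdot \mathbf{1}[\text{envelope stress}] - d_P P$$

$$\frac{dG}{dt} = \frac{v_G}{1 + P/K_i} - s_{PG}\,\mathrm{syn}_P - \mu G,
\qquad \mu = \mu_{max}\frac{G}{K_G+G}\,\max(0,\,1+\gamma_\mu \eta)$$

$$\frac{dF}{dt} = \frac{\alpha_F}{1 + (G/K_C)^{h_C}} - \mu F$$

The SasB term's Hill coefficient defaults to $n_B = 3$, matching the measured
allosteric cooperativity of the tetrameric synthase; the alarmone inhibits
GTP synthesis ($K_i$), consumes GTP as substrate ($s_{PG}$), and growth is
GTP-limited, which closes a double-positive feedback loop: more alarmone →
less GTP → slower growth → less dilution, while the allosteric term amplifies
alarmone synthesis directly. With $n_B \ge 3$ the deterministic $P$ dynamics
are bistable (growing state $P \approx 6$ µM, $G \approx 1.9$ mM; dormant
state $P \approx 130$ µM, $G \to 0$); with $n_B = 1$ (`graded_params()`) the
system is monostable and entry into low-GTP states is graded, emulating
mutants without allosteric self-amplification.

**Noise model.** One extrinsic Ornstein–Uhlenbeck factor $\eta$
(autocorrelation time $\tau_\eta = 30$ min, stationary s.d. $\sigma_\eta$)
drives rare switching. It multiplies alarmone synthesis as a mean-one
lognormal factor $e^{\eta - \sigma_\eta^2/2}$ and perturbs growth only weakly
($\gamma_\mu = 0.15$, i.e. a few percent CV on elongation rate). Putting the
full-strength factor on growth instead would make the growth-arrest dormancy
criterion fire on noise excursions at a rate orders of magnitude above the
true switching rate and would swamp every single-cell analysis; physically,
extrinsic fluctuations in enzyme abundance act on synthesis fluxes, while
elongation integrates over many processes and is much less noisy frame to
frame. Intrinsic molecule-number noise is omitted: the concentrations
involved are high. Measurement noise on recorded traces is multiplicative
(2% on length, 5% on fluorescence), matching segmentation-scale error.

**Integration.** Euler–Maruyama at fixed $dt$ (default 0.1 min) with an exact
OU update for $\eta$; a stability guard rejects steps coarser than one fifth
of the fastest timescale. Concentrations stepped below zero are clamped and
counted (`clamp_counts` attribute) — for dormant cells $G = 0$ *is* the
operating point (supply falls below alarmone-synthesis consumption), so a
large $G$ clamp count in a run containing dormant cells is expected, not an
error. Tests verify that halving $dt$ leaves the dormant fraction unchanged
within sampling error. Division occurs at length doubling with a 5% CV
symmetric split (nothing in the emulated system constrains division control,
so the simplest rule is used); concentrations are conserved across division.

**Dormancy.** A cell is flagged dormant when $\mu < \epsilon_\mu$
(0.002/min) has persisted for $\tau_{arrest} = 30$ min. In wild-type
ensembles, dormant cells sit at $G$ well below the threshold band
$G_{thr} = 0.15$ mM, and the reporter rises *before* arrest: the CodY
reporter derepresses around $G \approx 2 K_C = 0.6$ mM while growth only
collapses near $G \approx 0.04$ mM, and the GTP decay through that window
takes a couple of 15-min frames (set by $s_{PG}$). This ordering — reporter
first, arrest second — is a structural property of the causal chain (GTP
depletion causes arrest), and the test suite checks it holds in ≥ 90% of
entrances.

## Calibration

Three constants cannot be derived and are fixed by a calibration routine that
ships with the package (values live in `inst/extdata/model_params.yaml`, not
in code):

* `sigma_eta = 0.18` — set with `calibrate_entrance_rate()` so wild-type
  lineages produce on the order of 10 spontaneous entrances per 30,000
  division events (≈ 3×10⁻⁴ per division). The rate depends exponentially on
  $\sigma_\eta$ (it is a barrier-crossing rate), rising from 0 at
  $\sigma_\eta \le 0.1$ to ~10⁻² at 0.3, so this is the one genuinely
  sensitive dial in the model.
* `g_cal = 64` mM·AU — `calibrate_reporter_gtp()` anchors the median
  fluorescence at arrest to an estimated GTP of 0.15 mM via the synthetic
  conversion $G_{est} = g_{cal}/F$. The conversion is deliberately labeled
  synthetic: a real instrument calibration would come from an independent
  GTP measurement.
* Scenario tables (`inst/extdata/scenarios.yaml`) — each emulated condition's
  kill parameters and mixture weights are transcribed so the generated data
  reproduce that condition's published population fractions, with a citation
  anchor on every non-default number. Two derived conventions: the latent
  dormant cytometry weight is $2f$ with the brighter half captured by a
  top-0.1% sort (this single choice reproduces both the ~80% survival of
  sorted bright cells and the ~0.1% survival of the dim fraction), and the
  serially passaged scenario's $f$ is set so its 5-h *endpoint* equals the
  published 0.05% spontaneous level (the published number is a 5-h survivor
  count, and persisters themselves decay at $k_p$).

## Synthetic data: what is and is not emulated

`generate_kill_curve()` adds replicate-level lognormal inoculum scatter and
emulates serial-dilution plating: the countable dilution (30–300 colonies,
two technical plates) is Poisson-sampled and back-calculated, with a
detection limit of one colony undiluted; below-detection values carry the
limit and a flag, never zero. `generate_cytometry()` draws a lognormal bulk
reporter, a rare bright dormant component, and additive lognormal
autofluorescence, plus a matched reporter-free control; latent dormancy
labels are kept for the sort-and-kill emulation and are never consulted by
gating. `simulate_lineage()` grows a tree from one cell, records 15-min
frames, and bounds the live population (default 500) by uniformly subsampling
actively growing lineages — dormant cells and cells whose arrest clock is
already running are always retained, since culling a cell in its 30-min
confirmation window would silently delete an entrance event; this mirrors
following a finite field of view while never losing a cell of interest.

Not emulated: instrument drift and spectral spillover in cytometry, spatial
structure (biofilms), cell-to-cell mechanical interactions, resuscitation
kinetics after drug removal, and any distinction between ppGpp and pppGpp
(collapsed into one species; their separation matters only for the allosteric
site, which the Hill term captures). Passing tests on this generator
therefore show the analyses are correct and well-calibrated for data with
this statistical structure — not that real instruments produce such data.

## Analysis conventions worth knowing

* **Gating** uses the fivefold-above-mean rule on control-subtracted
  fluorescence. The mean (not median) anchors the gate; with a heavy bright
  tail the mean shifts and the gated fraction saturates, so the rule is meant
  for populations where bright cells are rare. Both the fold and the
  subtract-first convention are configurable, and the gate is scale-invariant.
* **Entrance detection** calls arrest when the measured per-frame growth rate
  $\mu = (1/l)(\Delta l/\Delta t)$ (centered differences, length record
  concatenated across divisions) stays below 10% of the population median for
  ≥ 2 frames with the reporter at/above the bright gate at arrest. On pooled
  time-lapse frames the gate's reference mean is computed over actively
  growing frames only: dormant traces persist for the rest of the movie while
  growing lineages are subsampled, so a naive pooled mean is inflated
  ~100-fold by the bright survivors. Rise onset is found by backward scan for
  the last frame below half the gate. Traces ending inside the confirmation
  window are censored, not counted.
* **Switch vs graded entry** is decided between $\mu = b_0 + b_1 F$ and
  $\mu = \mu_{top}/(1+(F/F_{half})^h)$ by AIC; the lower-AIC model is
  reported as preferred with a `decisive` flag requiring a margin of 2. The
  sigmoid nests near-linear shapes, so a *decisive linear* verdict is
  essentially unattainable — the meaningful contrast, and the one tested, is
  "decisive sigmoid" (wild type) versus "no decisive switch" (graded
  mutants). The sigmoid family itself is a package choice; the data it is fit
  to would equally support other threshold-like families.
* **Condition sweeps** correlate at replicate level (each row one replicate),
  with persistence and gated fractions on the log10 scale (they span decades)
  and growth rate and MDK99 linear. The headline verdict tuple —
  growth↔tolerance coupled, growth↔persistence uncoupled,
  low-GTP↔persistence coupled, low-GTP↔tolerance uncoupled — is stable
  across master seeds (a tested property of the default sweep). The 5-h
  endpoint estimator is only
  meaningful when the susceptible compartment is actually cleared by 5 h
  ($k_s \gtrsim 2$/h); with much slower killing the residual susceptibles
  contaminate the endpoint and artifactually couple persistence to growth,
  which constrains how tolerant the sweep's scenarios can be made.
* **Bimodality** of endpoint GTP is scored with Sarle's bimodality
  coefficient against the 5/9 reference. The check is run under strong
  starvation induction, where both basins hold substantial mass; under
  unstressed wild-type conditions the dormant mode is ~0.1% of cells and no
  unimodality test can resolve it (rarity, not graded entry, is why).

## Problem sizes and reproducibility

Default analysis sizes: 3 replicates × 7 timepoints per kill curve; 10⁵–10⁶
cytometry events; 30,000 division events (live-cell cap 500, $dt = 0.1$ min,
≈ 10 s of compute) for the lineage benchmark; ensembles of 500–5000 cells
for population properties. Every generator takes an integer seed, all
stage seeds derive from one master seed via `split_seed()`, and identical
(parameters, seed) pairs give byte-identical exported CSVs. `run_recipe()`
writes the resolved `run_config` (with hash) next to every output.

## Known limitations

The mechanistic parameter set is *a* calibration, not an inference: many
parameter combinations could produce the same calibrated fractions, and no
uncertainty is attached to them. The phenomenological and mechanistic
generators are linked only through the scenario table, not through a shared
likelihood. MDK99 confidence intervals are Wald-style from the fit curvature
and can be optimistic near boundaries. The entrance detector assumes frame
spacing is constant and that arrest is durable on the 30-min scale —
transient pauses shorter than two frames are invisible by design. Whether
the growth-rate switch is purely feedback-generated (as modeled) or partly
intrinsic to $\mu(G)$ is left open; both can be explored through
`model_params()` (e.g. steeper $K_G$ response), but only the
feedback-generated variant is calibrated and tested.
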