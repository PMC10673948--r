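---
title: "Population pharmacokinetics of avalglucosidase alfa: model, simulation and qualification methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population pharmacokinetics of avalglucosidase alfa: model, simulation and qualification methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avalpk)
```

## The model

Avalglucosidase alfa (AVAL) is an intravenously infused enzyme replacement
therapy for Pompe disease. This package implements a nonlinear mixed-effects
model of its plasma disposition and the simulation machinery built on top of
it: single-dose exposure metrics, virtual pediatric/adult cohorts with
bodyweight cut-off dosing rules, and qualification tools (visual predictive
checks, bootstrap, goodness-of-fit criteria).

### Structural model

Drug amounts (mg) in a central compartment $A_1$ (volume $V_1$) and two
concatenated peripheral compartments $A_2$ ($V_2$) and $A_3$ ($V_3$) evolve
as

$$
\begin{aligned}
\dot A_1 &= R(t) - CL\,C_1 - \frac{V_{max} C_1}{K_m + C_1}
            - Q_2 C_1 + Q_2 C_2 + Q_{pc} C_3,\\
\dot A_2 &= Q_2 C_1 - Q_2 C_2 - Q_3 C_2,\\
\dot A_3 &= Q_3 C_2 - Q_{pc} C_3,
\end{aligned}
$$

with $C_k = A_k / V_k$ (µg/mL ≡ mg/L). Elimination is the sum of a linear
route ($CL$) and a saturable Michaelis–Menten route ($V_{max}$, $K_m$), both
from the central compartment. The compartments are concatenated: a two-way
flow $Q_2$ between $V_1$ and $V_2$, a one-way flow $Q_3$ from $V_2$ into
$V_3$, and a slow back-redistribution $Q_{pc}$ from $V_3$ to the central
compartment. Each intercompartmental clearance acts on its *source*
compartment's concentration; with a one-way $Q_3$ and a return $Q_{pc}$ this
is the only mass-conserving reading, and the test suite asserts mass balance
directly.

### Allometric bodyweight scaling

$CL$, $V_1$ and $V_{max}$ scale with bodyweight as
$TV(P) = \theta_P \,(WT/70.5)^{x_P}$ around the 70.5 kg dataset median, with
estimated exponents 0.896, 0.661 and 0.463. $K_m$, $Q_{pc}$ and the fixed
peripheral parameters carry no weight effect. Weight may vary over study
time; typical values and weight-based dose amounts are re-evaluated at every
dose/weight breakpoint and held constant between (last observation carried
forward). A sensitivity variant with the conventional fixed exponents
(0.75 on clearances, 1 on the central volume) is available via
`fixed_allometry()`.

### Random effects and residual error

Inter-individual variability is log-normal on
$\{CL, V_1, V_{max}, K_m, Q_{pc}\}$: $P_i = TV(P)\,e^{\eta_P}$, $\eta \sim
N(0, \Omega)$ with diagonal $\Omega$ (the reference fit reports only
variances). Residual error is proportional, $y = f(1+\varepsilon)$,
$\varepsilon \sim N(0, \sigma^2)$; no additive term, matching the reference
analysis. The log-normal CV identity $CV\% = 100\sqrt{e^{\omega^2}-1}$ and
the proportional identity $CV\% = 100\sqrt{\sigma^2}$ are exposed as
`omega2_to_cv()` / `sigma2_to_cv()`.

### Default parameter values

`pop_params()` ships the published population estimates (CL 0.808 L/h, V1
3.37 L, Vmax 12 mg/h, Km 0.541 µg/mL, Q2 0.254, V2 296, Q3 1.87, V3 1.31
fixed, Qpc 0.0157 L/h; ω² 0.0907/0.0184/0.118/0.243/1.23; σ² 0.12), also
available as a flat YAML file under `inst/extdata/` for external tools.

## Dosing and exposure

Doses are weight-based (mg/kg) and infused with a stepped ramp: 1, 3 and
5 mg/kg/h for 30 min each, then 7 mg/kg/h until the planned amount is
delivered — 3.71 h in total for 20 mg/kg and 6.57 h for 40 mg/kg. For doses
at or below the 4.5 mg/kg the fixed steps deliver, the ladder is truncated
when the cumulative amount reaches the dose; the reference regimens never
dose below 5 mg/kg, so this extension only matters for user scenarios and is
configurable through the step definitions.

Exposure is computed after a single dose over the two-week dosing interval:
the profile is sampled every 0.1 h over 336 h, `cmax` is the grid maximum
(at this grid and hours-long infusions the interpolation bias is below
0.05%), and `auc_2w` is the trapezoidal integral — the grid is prescribed,
the quadrature is the natural one for it. Bodyweight-normalized apparent
clearance, $CL/WT = \mathrm{Dose}/(\mathrm{AUC_{2W}}\times WT)$, decreases
with age in this model because clearance scales less than proportionally
with weight.

## Numerical integration

Two integration paths solve the same piecewise-constant problem and are
cross-checked against each other and against an independent fixed-step RK4
oracle in the test suite:

* `simulate_profile()` uses `deSolve::lsoda` (stiff-capable) with a compiled
  right-hand side, restarting the integrator at every infusion-rate or
  parameter breakpoint so discontinuities are handled exactly.
* The estimation and VPC inner loops use a compiled adaptive Dormand–Prince
  5(4) integrator (`src/pk_sim.c`) over the same segment structure — one
  native call per subject simulation. This removes the per-segment solver
  call overhead that would otherwise dominate inner-loop cost; if the
  explicit integrator fails (it can, for absurd parameter combinations far
  outside the random-effect prior), the code falls back to the lsoda path.
  The Michaelis–Menten term is guarded at (numerically) negative central
  amounts to avoid the $K_m + C_1$ singularity.

Default tolerances are 1e-8 (profiles) and 1e-6 (estimation inner loop);
halving the output grid and tightening tolerances moves the two-week AUC by
well under 0.1%.

## Estimation

The reference analysis used FOCE-I in NONMEM; that algorithm is out of scope
here and objective values are comparable only between this package's own
fits. `fit_population()` offers:

* **laplace** (default): the marginal likelihood is approximated by the
  Laplace method around each subject's MAP $\hat\eta$ — the penalized
  deviance at the inner optimum plus a log-determinant curvature correction.
  The curvature uses the Gauss–Newton form
  $2J^\top V^{-1} J + 2\Omega^{-1}$ built from prediction sensitivities
  $J = \partial f/\partial \eta$, the standard approximation in
  conditional-estimation engines. Inner problems are solved by BFGS with an
  analytic sensitivity gradient and are warm-started across outer
  iterations; the random-effect search is kept inside ±6 prior standard
  deviations by a smooth quadratic penalty (beyond that the parameters are
  physiologically absurd and the ODE system needlessly stiff).
* **naive-pooled**: all $\eta = 0$; used where the data are generated
  without inter-individual variability and speed matters (e.g. covariate
  screening tests).
* **two-stage**: a single pass of per-subject MAP estimation under the
  initial values followed by $\hat\theta_P = \theta_P e^{\overline{\hat\eta_P}}$.
  Because this estimator is a function of per-subject statistics,
  `two_stage_fitter()` memoises the MAP step per subject, which makes
  case-resampling bootstraps cheap.

Observations below the 0.0125 µg/mL limit of quantitation are excluded from
all likelihoods (the reference analysis excluded its 241 such points);
likelihood-based censoring is deliberately not implemented.

Covariates enter multiplicatively: continuous ones as a power on the
median-normalized value (mirroring the bodyweight convention), categorical
ones as a proportional shift. `stepwise_select()` runs greedy forward
inclusion at $\alpha = 0.05$ (ΔOFV 3.84 for 1 df) and backward elimination
at $\alpha = 0.001$ (ΔOFV 10.83), recording every tested step. The
creatinine-clearance effect investigated and rejected in the reference
analysis is provided only as the illustrative `renal_cl_adjustment()`, with
its exponent back-derived from the reported clearance endpoints; it is not
part of the default model.

## Qualification tools

* **VPC / pcVPC**: replicates of the observed dataset are simulated on the
  original design (new $\eta$, new $\varepsilon$); records are grouped into
  equal-count bins by time after end of infusion (or bodyweight), and
  binwise 5th/50th/95th percentiles of the observations are compared with
  90% simulation bands. Prediction correction rescales each value by
  median(PRED in bin)/PRED of the record, the standard lower-bound-free
  form; the reference publication names the method without a formula.
  Equal-count binning (default 8 bins) is the package's choice — the
  reference figure does not state its binning — and bin edges are reported.
  Simulated values below the limit of quantitation are discarded before the
  binwise percentiles, mirroring the exclusion of BLQ records from the
  observed percentiles; otherwise the low percentile in trough bins would
  compare censored observations with uncensored simulations.
* **Bootstrap**: subjects are resampled with replacement (optionally
  stratified, e.g. by disease type), the model refit per replicate, and
  medians with nonparametric 95% CIs (2.5th–97.5th percentiles) reported
  over converged fits.
* **GOF criteria**: the reference analysis names bias, precision and AAFE
  without defining the first two; this package's declared conventions are
  mean percent prediction error for bias and root-mean-square percent error
  for precision (mean absolute percent error is also reported). AAFE is
  $10^{\mathrm{mean}|\log_{10}(pred/obs)|}$. Published values computed on
  the real study data are context, not targets, for these conventions.
* **Residuals**: individual weighted residuals $(y - f_i)/(\sigma f_i)$ and
  first-order population residuals replace FOCE-consistent conditional
  weighted residuals, which are out of scope with the estimation engine
  above.
* `condition_number()` is the largest-to-smallest eigenvalue ratio of an
  estimation covariance/correlation matrix.

## Synthetic studies

`generate_study()` emulates the structure of the four clinical trials the
reference dataset pooled: every-two-week stepped infusions, rich sampling
around selected dosing weeks (pre-dose, end of infusion, and fixed offsets),
an ascending-dose arm that switches to 20 mg/kg (default at week 27 — the
switch timing is not published; it is configurable), adult demographics
drawn from the published moments (75.9 ± 20.1 kg truncated to 38–129 kg) and
pediatric ones from 29.2 ± 15.4 kg truncated to 9.9–63.5 kg, proportional
residual noise, and censoring at the 0.0125 µg/mL limit of quantitation.
Pediatric bodyweight grows linearly at 2.5 kg/year by default — the
published analysis states that weight varied over time but not how; any
rule exercising the time-varying-weight code path serves, and the rate is a
parameter. Antidrug-antibody status, disease type and pretreatment are
generated as label columns with no PK effect, matching the reference
finding that no such covariate met the selection criteria, so covariate
screening can be exercised against a known-null truth.

What the generator deliberately does not emulate: ascending-titer antibody
dynamics, dropout and dosing compliance, assay batch effects, and any
misspecification of the structural model itself. Passing tests therefore
demonstrate that the pipeline inverts and qualifies data *from its own
model family* at realistic noise levels — not that the model is correct for
any particular real dataset.

## Virtual cohorts and cut-off scans

`build_cohorts()` generates the published band sizes exactly: 1002 (1 to
<2 y), 1000 (2 to <6 y), 1008 (6 to <12 y), 1008 (12 to <18 y) pediatric
subjects — 4018 in total — plus 1000 adults. Ages are staggered on an even
grid within each band (1, 1.5 y; then yearly), crossed with sex, with cell
sizes as even as possible; the published totals do not disclose their
internal split, so the grid is a declared convention. Pediatric weights are
drawn from a normal centered at the growth-chart median with
$sd = (P_{95}-P_5)/(2 z_{0.95})$, truncated to $[P_5, P_{95}]$ — the
published method states only the truncation bounds, this parameterization
is the package's convention. The packaged percentile file is a constructed
stand-in with plausible magnitudes for CDC-style weight-for-age charts
(marked `synthetic` in its name); any fixture in the same format can be
supplied, and no test depends on the exact percentile values, only on the
truncation contract. Adult weights use the published adult moments, also
overridable.

`run_cutoff_scenario()` doses pediatric subjects below the cut-off at
40 mg/kg and everyone else at 20 mg/kg (the ≥ rule applies at the boundary,
as published), simulates each subject's single 336 h profile, and
summarizes Cmax and AUC$_{2W}$ at the 10/25/50/75/90th percentiles per
band against the adult reference. `cutoff_scan()` repeats this over the
published 25/30/35/40 kg scan set.

## Problem sizes and reproducibility

Every stochastic routine takes an explicit seed, and identical seeds give
byte-identical outputs. The test suite and the acceptance script use desk
scale sizes chosen to exercise the full pipeline: parameter recovery on 50
richly sampled subjects, bootstrap at 100 replicates on 40 subjects with
the memoised two-stage fitter, VPC self-consistency at 200 replicates, and
cut-off scans on either the full 5018-subject cohort (acceptance script) or
a 10% cohort (`cohort_spec(scale = 0.1)`, tests). Reference-scale analyses
(1000 bootstrap or VPC replicates, repeated fits) use the same code with
larger `n`.

## Known limitations

* The estimation objective is a Laplace/Gauss–Newton approximation, not
  FOCE-I; OFVs are internally consistent but not numerically comparable to
  published NONMEM values, and data-dependent published results (OFVs,
  bootstrap medians, exposure tables, condition number 4.56) are not
  reproduction targets.
* $\Omega$ is diagonal and fixed at its published values during estimation
  by default; variance components are not estimated.
* BLQ data are excluded rather than likelihood-censored.
* Exposure is single-dose by design; steady-state accumulation is a
  non-goal (accumulation is negligible at the published terminal
  half-life relative to the two-week interval, but it is simply not
  computed).
* The growth-percentile fixture is synthetic; conclusions that depend on
  exact CDC weights (e.g. the published 12–55% / 13–63% pediatric exposure
  deficits at 20 mg/kg) are directionally but not numerically reproduced.
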