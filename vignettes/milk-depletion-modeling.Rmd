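---
title: "Population modelling of drug depletion in goat plasma and milk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population modelling of drug depletion in goat plasma and milk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(milkpk)
```

## The problem

Tulathromycin is a long-acting macrolide antibiotic labelled for cattle and
swine and used extra-label in goats. In lactating does the drug partitions
into milk, where any detectable residue is violative because no official
milk tolerance exists; the assay limit of detection (LOD) is the de facto
tolerance. The practical question is the **withdrawal time**: how many days
after the last injection must milk be withheld before residues fall below
the LOD in (say) 95% of the population.

`milkpk` implements a complete workflow for this question: a structural
pharmacokinetic model of plasma disposition and milk excretion,
noncompartmental analysis (NCA), FOCE-type nonlinear mixed-effects (NLME)
population estimation, a nonparametric subject bootstrap, and Monte Carlo
population simulation with a percentile-band withdrawal rule. A synthetic
study generator reproduces the statistical structure of the three source
study designs, so every stage is testable without the unpublished raw
individual-animal data.

## Structural model

The model is a two-compartment mammillary disposition model with
first-order absorption from a subcutaneous depot and a cumulative
milk-excretion compartment:

$$
\begin{aligned}
dA_a/dt &= -K_a A_a \\
dA_1/dt &= K_a A_a - Cl\,C - Cl_2 (C - C_2) - CL_{milk}\, C \\
dA_2/dt &= Cl_2 (C - C_2) \\
dA_{milk}/dt &= CL_{milk}\, C
\end{aligned}
$$

with $C = A_1/V$ and $C_2 = A_2/V_2$. Amounts are in ng, volumes in mL,
clearances in mL/h, so concentrations are natively ng/mL. The milk
compartment is purely cumulative: the model predicts the running total of
drug excreted into milk, and per-milking concentrations are reconstructed
afterwards by dividing interval amounts by the milk volume produced in the
interval. The fraction of the dose ultimately excreted in milk is exactly
$CL_{milk}/(Cl + CL_{milk})$.

Because the system is linear, `milkpk` evaluates it in closed form: the
disposition exponents are the roots of the standard two-compartment
quadratic (`micro_constants()`), absorption convolves each exponential
term analytically, and multi-dose regimens superpose time-shifted
single-dose responses. `solve_ode()` integrates the same equations
numerically (via `deSolve`, with an explicit eliminated-mass state) and
serves purely as the brute-force oracle: the test suite requires closed
form and ODE to agree to 1e-6 relative over a 64-day grid for 100 random
parameter sets, with the comparison restricted to concentrations above
1e-6 of the curve maximum — below that support floor the ODE solution is
itself limited by its absolute-error tolerance (`atol = 1e-6` ng,
`rtol = 1e-11`). When the absorption constant collides with a disposition
exponent (a measure-zero confluent case) $K_a$ is perturbed by 1e-8
relative rather than switching to the $t e^{-kt}$ solution. One- and
three-compartment variants share the same machinery (the one-compartment
reduction is $Cl_2 = 0$; the three-compartment variant adds a second
peripheral pair and obtains its exponents by eigendecomposition).

```{r}
p <- do.call(pk_params, as.list(table3_population()$theta))
micro_constants(p)[c("k10", "k21", "beta")]
terminal_halflife(p)  # hours; ln 2 over the slowest exponent
```

## Noncompartmental analysis

`nca_summary()` reports the conventional quantities: observed Cmax/Tmax,
terminal slope $\lambda_z$, half-life, AUC to the last sample and AUC
extrapolated to infinity. Two conventions needed fixing where the field's
software leaves them configurable:

* **Terminal-phase selection**: among all contiguous terminal windows of
  at least three positive points after (and excluding) Tmax, the window
  with the best adjusted $R^2$ of the log-linear regression wins; a longer
  window within 1e-4 of the best adjusted $R^2$ is preferred. This mirrors
  the common WinNonlin "best fit" default.
* **AUC rule**: linear trapezoid by default; `linup_logdown` applies the
  logarithmic rule on strictly decreasing positive segments (exact for
  mono-exponential decay) and falls back to linear elsewhere. On the
  packaged average milk curve the linear rule lands ~0.5% above and the
  log-down rule ~0.9% below the published first-injection AUClast —
  consistent with the published value being an average of per-animal NCAs
  rather than an NCA of the average curve; the exact rule used there is
  not stated.

For profiles that start after the dose, a zero concentration is inserted
at the dose time (extravascular convention). For the two-injection milk
data the first-injection window is truncated at the second dose time.

## Population estimation

Individual parameters follow the exponential inter-individual variability
(IIV) model $P_i = \theta \exp(\eta_i)$ with independent (diagonal)
Gaussian random effects on all six structural parameters. Residual error
is proportional for both observation kinds by default — plasma
concentrations and cumulative milk amounts — with additive and combined
models available for the error-model comparison. The published IIV column
is read as the **variance** of the log-scale random effect by default; the
source table does not state the scale, and a `iiv_scale = "sd"` switch is
provided. The variance reading is the one consistent with the published
withdrawal simulations (the sd reading implies absurd absorption
heterogeneity).

The marginal likelihood is approximated subject-by-subject by a Laplace
expansion at the conditional mode of $\eta$ (FOCE-style), with the
residual variance evaluated at the conditional prediction ("with
interaction"). The inner problem is solved by a Levenberg-damped Newton
iteration using the expected-information Hessian
$2 J^T V^{-1} J + (\partial v)^T V^{-2} (\partial v) + 2\Omega^{-1}$,
always started from $\eta = 0$ so the objective is a deterministic,
history-free function of the population parameters. The test suite checks
the approximation against adaptive numerical quadrature on one- and
two-random-effect toy subjects (agreement within 2%) and verifies the
exact degenerate identity: with all IIV variances zero the objective
equals the naive pooled $-2$ log-likelihood.

The outer problem optimises log-transformed fixed effects, IIV variances
and residual magnitudes with a quasi-Newton method (`nlminb`), relative
tolerance 1e-6, at most a few hundred iterations. Default starting values
(`default_init()`) are generic mid-range ruminant macrolide values with
all IIV variances at 0.1, deliberately far from any particular published
estimate so that fits demonstrate genuine convergence. Market-goat subjects
contribute plasma likelihood only; lactating subjects contribute plasma
and cumulative-milk likelihood simultaneously. Below-LOD observations are
excluded from the likelihood by default (the common M1 policy; `zero` and
`half_lod` policies are provided), and milk concentration records are
converted to the cumulative excreted-amount series before fitting.

Model selection across 1/2/3-compartment candidates uses AIC
(`compare_models()`), with $-2LL$ and BIC reported alongside.

A note on identifiability: with an absorption-rate IIV variance above 6
(the published value), the population curve is dominated by slow-absorbing
("flip-flop") individuals and the likelihood develops a long, shallow
ridge trading $V$, $K_a$ and their variability against each other. On
synthetic data at the pooled 26-subject design scale the milk clearance
$CL_{milk}$ — anchored directly by the cumulative milk amounts — is
recovered closely, while $V$, $V_2$ and $K_a$ drift substantially along
the ridge without materially changing the likelihood, and the systemic
clearance $Cl$ is pulled below its generating value (deviations around
15–25% are typical): on the ridge the Laplace curvature term rewards
inflating the volume and absorption variability, and a flatter apparent
terminal phase trades against $Cl$. Optimising harder does not help —
points deeper in the approximate likelihood lie further from the
generating values — so population estimates of $Cl$ from designs like
these should be read with that caveat. `fit_sequential()` offers the
two-stage (plasma first, then simultaneous) construction; it shares the
same ridge. Between-occasion variability and covariates are out of scope
(the final published model contains neither).

## Bootstrap

`bootstrap_ci()` resamples subjects with replacement, stratified by study
label so that each replicate preserves the per-study subject counts —
without stratification a replicate could contain no milk data at all. The
stratification choice is conservative; the source analysis does not state
whether it stratified. Intervals are empirical 2.5/97.5 percentiles
(linear interpolation) over converged replicates; replicate failures are
counted and excluded, and more than 50% failures abort. All resampling
indices are drawn up front from the seed, so failures do not shift the
random stream and results are reproducible bit-for-bit.

## Monte Carlo simulation and withdrawal time

`simulate_replicates()` draws one individual per replicate (100 by
default), evaluates plasma and cumulative-milk trajectories in closed
form on a 12-h grid, and reconstructs milk concentrations from interval
amounts and milking volumes. The default simulated subject is an 88-kg
doe producing 10.8 lbs/day of milk split over twice-daily milkings —
the mean animal of the source population; all of this is configurable.
The percentile band reflects IIV only; a residual-error layer can be
switched on but is off by default, since the published simulations are
drawn from the population model.

`withdrawal_time()` reports the smallest whole day after the last dose at
which the chosen percentile (95th by default, matching the published
figure legend; 97.5th available) stays below the tolerance at every later
grid point. Day granularity follows regulatory convention; the grid is
12-hourly internally. If the band has not settled below tolerance by the
end of the grid the estimate is flagged undefined rather than truncated.
Milk-based estimates carry a non-definitive flag: reconstructed milk
concentrations fluctuate at the terminal phase (finite milking volumes
divide a noisy small increment), which is precisely why the source study
declined to fix a milk withdrawal time.

With 100 replicates the day estimate is itself a Monte Carlo quantity with
appreciable seed-to-seed spread (several days), because the upper
percentile is governed by the heavy log-normal tail of the absorption
constant. The package therefore treats any single-seed value as one
realisation, and the acceptance checks average over a small set of seeds.

## Synthetic data generator

`study_design()` transcribes the three source designs: two-dose lactating
(n = 8, 73–109 kg, doses at 0 h and 168 h, milk sampled 12–1536 h, plasma
180–348 h), single-dose lactating (n = 8, 72.5–89 kg, milk 12–1080 h,
plasma 12–168 h) and market-age goats (n = 10, plasma only, 28 samples
from 1 min to 360 h). `generate_study()` draws body weight and daily milk
yield uniformly within the published ranges (no distributional detail is
published), individual parameters log-normally, applies proportional
residual noise (0.485 plasma, 0.0234 milk cumulative amounts), floors
interval milk amounts at zero, and flags below-LOD values.

Choices worth knowing about:

* Market-goat body weight is not published anywhere; the generator uses
  30 kg, configurable. Doses scale linearly with weight, so this only
  scales amounts.
* Milking volumes derive from the daily yield spread over each sampling
  interval at a fixed milk density of 1.03 g/mL; real per-milking volumes
  are unpublished, so milk-concentration levels are matched only
  approximately by construction.
* Milkings sit on an even 12-h clock anchored 12 h post-dose rather than
  the literal 6:30/17:30 farm clock, matching the packaged average-curve
  time grid.

What passing tests on these data do **not** show: robustness to assay
drift, time-varying milk yield, diseased-animal physiology, or model
misspecification — the generator simulates exactly the structural model
being fitted, so recovery tests validate the estimation machinery, not
the model's biological adequacy.

## Problem sizes and runtimes

The packaged defaults keep every stage desk-scale: 26 synthetic subjects
(~1300 observations) for the population fit, 100 Monte Carlo replicates
on a 12-h grid for simulations, and 100 bootstrap replicates (reduced in
the test suite, where small plasma-only datasets exercise the same code
paths). A full 26-subject FOCE fit takes a few minutes on one core; the
simulations take seconds.

## Limitations

* No covariate modelling (the source data lack consistent covariate
  records) and no between-occasion variability; the second injection is
  pure superposition with identical individual parameters.
* No saturable elimination, enterohepatic recirculation or protein-binding
  submodel.
* The withdrawal rule is the percentile-band rule of the source analysis,
  not the formal regulatory tolerance-limit method.
* Exact reproduction of the published population estimates by refitting is
  impossible without the raw individual data; the packaged estimates serve
  as generator ground truth and simulation inputs.
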