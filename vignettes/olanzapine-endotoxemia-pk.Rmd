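---
title: "Methods: joint parent-metabolite pharmacokinetics under sparse sampling"
author: "olzpk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint parent-metabolite pharmacokinetics under sparse sampling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(olzpk)
```

# Setting

Acute inflammation (modelled in mice by a lipopolysaccharide challenge)
changes how olanzapine and its CYP1A2-formed metabolite
4'-N-desmethylolanzapine (DMO) are absorbed, metabolized, distributed to the
brain and eliminated. Quantifying those changes requires a study design that
mouse physiology forces to be sparse: animals are small, so plasma profiles
are assembled from destructive sampling (each animal contributes two samples,
the second terminal) in the oral arm and from three-sample serial schedules
in the IV arms. `olzpk` implements the full analysis chain for this design —
structural model, design-aware exposure statistics, binding corrections,
penetration ratios, group fitting, and expression quantification — together
with a synthetic-study generator so the chain is testable end to end.

# The structural model

## States and transfers

Both compounds get a two-compartment disposition: central and peripheral
amounts connected by an intercompartmental clearance, and first-order
elimination from the central compartment. A unidirectional first-order
transfer at rate `k_pm` (1/h) converts central parent into central
metabolite. Oral dosing feeds two depots: of the systemically available dose
fraction `F_po_total`, a part `F_d` is absorbed as parent (rate `ka`) and
`1 - F_d` as presystemically formed metabolite (rate `ka_dmo`). Absolute
oral bioavailability of the parent is the product `F_po = F_po_total * F_d`.

Two cumulative elimination ledgers complete the state vector so that mass
balance can be audited at any time: amounts in all compartments plus both
ledgers must equal the total bioavailable dose. Mass converted from parent
to metabolite moves from the parent ledger's scope to the metabolite's.

## Total versus partial clearance

`CL` is the *total* plasma clearance of the parent, of which the partial
metabolic clearance to DMO, `CL_parent_to_dmo = V1 * k_pm`, is one
component; elimination by all other routes proceeds at `CL/V1 - k_pm`. This
reading — rather than treating the conversion as additive on top of `CL` —
is the package's design choice because the field calls `V1 * k_pm` a
*partial* metabolic clearance and because the group-median values used as
fixtures satisfy `V1 * k_pm < CL` in both groups. The constructor enforces
`CL / V1 >= k_pm` as a validity invariant.

## Units and the molar-mass question

The model is parametrized per kilogram of body weight throughout (doses in
mg/kg, volumes in L/kg, clearances in L/h/kg); individual body weights are
never modelled. Concentration in ng/mL is central amount (ng/kg) divided by
the central volume (L/kg) and by 1000.

Demethylation sheds about 4.5% of the parent's molar mass
(312.4 → 298.4 g/mol). Because both compounds are assayed in mass units and
the conversion is reported as a mass-transfer clearance, the correction
defaults **off**; `pk_solve(..., molar_mass_ratio = 298.4/312.4)` turns it
on, scaling the conversion transfer and booking the shed mass on the parent
elimination ledger so the balance audit still closes.

## Solving the system

Between dose events the system is linear and time-invariant, so the default
solver is analytic: an eigendecomposition of the rate matrix evaluated at
the requested times. If the eigenvector basis is ill-conditioned (reciprocal
condition below 1e-10, e.g. exactly coincident rate constants) the solver
falls back to a matrix exponential per time step (`Matrix::expm`). A
stiff-capable adaptive integrator (`deSolve::lsoda`, relative tolerance
1e-10) is retained as an independent numerical route and the two are tested
against each other. Amounts below 1e-9 of the dose scale are clamped to zero
to remove the O(eps) negative residue analytic propagation leaves in
structurally zero states. Predose concentrations are structurally zero: the
time origin is the dose time and the studies are single-dose.

# Exposure estimation for sparse designs

## Point estimate and variance

`batch_auc()` estimates AUC from time 0 (or the first sampled time) to the
last sampled time. Animals are grouped into *batches* by their
sampling-time pattern. With trapezoid weights `w_j` over the schedule, the
point estimate is `sum_j w_j * mean_j`, the weighted sum of per-time mean
concentrations. Its variance is `sum_{j,k} w_j w_k cov_jk`, where `cov_jk`
is the within-batch-pooled sample covariance of concentrations at times `j`
and `k` divided by the number of animals observed at both times, and zero
when no batch covers the pair. This is the estimator's documented contract
for incomplete designs (the exact variance rule of legacy tools for
two-samples-per-animal batches is not published); on complete data it
reduces *exactly* to the mean and variance of per-animal trapezoid AUCs,
which is the oracle the tests check against. Batches of size one cannot
contribute covariance and are dropped from the variance with a warning.

## Bootstrap-t interval

The 95% interval resamples animals — not samples — with replacement within
their batches, preserving each animal's time pattern and hence the
within-animal correlation the design creates. For each of `B` replicates
(default 2000; the seed is a required argument) the studentized statistic
`t* = (AUC* - AUC)/se*` is formed, and the interval is
`[AUC - se * q*(0.975), AUC - se * q*(0.025)]`. Replicates with a
degenerate (zero or non-finite) `se*` are dropped from the quantile
computation. The resampling is implemented as multinomial counts over each
batch, which lets all `B` replicates be computed with matrix algebra.

## Below-limit records and ratios

The default censoring rule sets below-limit values to 0 at or before the
time of the mean curve's maximum and excludes them after it; `LLOQ/2`
imputation and full exclusion are available alternatives, since the field
has no single convention. Predose time-0 records enter oral-arm AUCs as
true zeros. Exposure ratios (metabolic ratios, brain-to-plasma ratios) are
plain ratios of point estimates with no interval propagation, and are
rounded only for display.

# Binding and brain penetration

Equilibrium dialysis yields `fu = c(buffer)/c(matrix)`. For brain
homogenate, diluted D-fold, the apparent fraction is corrected back to
undiluted tissue by

`fu_brain = (1/D) / ((1/fu_diluted - 1) + 1/D)`

The correction is validated structurally rather than against a printed
value: it is the identity at `D = 1`, strictly increasing in `fu_diluted`,
strictly decreasing in `D` below saturation, and exactly invertible — all
of which are tested. The default `D = 5` is a typical brain-homogenate
dialysis dilution and is configurable per measurement. Unbound fractions
above 1 (assay noise) are reported unclipped with a warning so QC surfaces
them. Penetration combines exposures and binding:
`Kp = AUC_brain/AUC_plasma`, `Kp_uu = Kp * fu_brain/fu_plasma`, with the
product identity holding to machine precision by construction.

# Group fitting

## Pooled maximum likelihood, not a population model

The reference analyses for this design were run in population software
(SAEM with empirical-Bayes individual estimates). This package deliberately
replaces that machinery with a *naive-pooled* maximum-likelihood fit per
group: with at most three observations per animal the destructive design
carries little individual-level information, the quantities of interest are
group-level parameters and contrasts, and a pooled fit is reproducible and
testable at desk scale. This is a documented deviation, and parameter
recovery is validated against the synthetic generator's truth, not against
any published individual-level estimates.

## Objective and optimization

Observed (quantifiable, post-dose, plasma) concentrations from all three
arms enter one lognormal likelihood with a shared residual standard
deviation, so the MLE minimizes the residual sum of squares on the log
scale. Below-limit records are excluded by default (LLOQ/2 imputation is
available). Parameters are transformed — log scale for positive parameters,
logit for `F_po_total` and `F_d`, and the conversion carried as the
metabolized fraction `fm = k_pm * V1/CL` on the logit scale, which enforces
the clearance-partition invariant automatically. Optimization uses
`nlminb` with multistart (default 8 starts: the initials plus jittered
copies, jitter SD 0.2 on the transformed scale, seeded); the best objective
wins and ties are broken by distance to the initials. Convergence is
reported, never silent.

## Identifiability

The three arms play distinct roles: the IV-metabolite arm pins the
metabolite's disposition (`CL_dmo`, volumes, `Q_dmo`); the IV-parent arm
separates parent clearance from bioavailability and informs `k_pm` through
the metabolite it generates; the oral arm informs the absorption and split
parameters. A fit attempted without an arm raises an error naming the
confounded parameters unless they are fixed explicitly.

# Relative expression

`ddct()` averages technical duplicates arithmetically on the Ct scale,
forms `dCt = Ct_target - Ct_reference` per sample, subtracts the arithmetic
mean `dCt` of the calibrator group, and reports `2^-ddCt`. Calibration is
per time stratum by default — each time point's saline controls calibrate
that time point, matching per-time-point group comparisons — with a single
global calibrator available (`by_time = FALSE`). Whether the calibrator
mean should be per-time or global is genuinely underdetermined in this
field's reporting; the per-time default is this package's choice. By
construction the calibrator group's geometric mean relative expression is 1
in every stratum, which is tested exactly. Downstream ANOVA machinery is
out of scope: the output is a tidy table ready for standard tools.

# The synthetic generator

## What it emulates

`default_study_design()` reproduces the reference design: two groups; an
oral 4 mg/kg arm with 18 animals per group sampled destructively — 12
schedule times (predose 0 and 0.25–24 h), three animals per time, two
samples per animal, with early time `j` paired to terminal time `j + 6` —
and two IV arms (0.5 mg/kg parent or metabolite, 10 animals per group)
sampled serially at 11 times (3 min–6 h), three samples per animal in
overlapping triplet patterns `(1,2,3), (3,4,5), ...` so that batches retain
at least two animals and every time is covered. Schedule assignment is
deterministic; one seed governs parameter draws then residual draws in a
fixed order (groups in design order, arms within group, plasma before
brain), so a seed fixes the whole table.

Individual parameters are drawn lognormally around the group medians
(`meanlog = log(median)`, so medians are preserved); fractions are drawn on
the logit scale, which keeps them in (0,1) and preserves the median. Draws
violating the clearance-partition invariant are redrawn. Residual error is
multiplicative mean-one lognormal (`exp(eps - sdlog^2/2)`), so observed
concentrations are unbiased for the model prediction — the property the
mean-based AUC estimator needs. Censoring flags records below the LLOQ
(defaults 0.2 ng/mL plasma; 0.2 ng/g brain, the brain detection limit);
predose zeros are structural, not censored.

Brain concentrations are *not* mechanistic: brain is not a model
compartment (the analysis treats penetration through AUC ratios, not a CNS
model), so the generator produces terminal-time brain records as plasma
concentration times a configurable true partition ratio with independent
residual error. Fixture ratios: parent 6.3 (control) / 8.5 (LPS),
metabolite 0.077 / 0.039.

## Fixture parameter values

Group medians mix printed-derived and plausible values, chosen once and
documented here:

| parameter | control | LPS | provenance |
|---|---|---|---|
| CL (L/h/kg) | 2.84 | 1.85 | reported group medians |
| k_pm (1/h) | 0.13 | 0.0675 | so that V1·k_pm = 0.26 / 0.135 (reported) with V1 = 2 |
| F_d | 0.74 | 0.86 | 1 − F_d = 0.26 / 0.14 (reported) |
| F_po_total | 0.1014 | 0.2733 | so that F_po = 0.075 / 0.235 (reported) |
| CL_dmo (L/h/kg) | 0.60 | 0.126 | fixture: ~5-fold below parent CL; 79% LPS attenuation |
| V1, V2 (L/kg) | 2, 4 | 2, 4 | plausible fixtures |
| Q (L/h/kg) | 2 | 2 | plausible fixture |
| ka, ka_dmo (1/h) | 1, 1 | 1, 1 | plausible fixtures |
| V1_dmo, V2_dmo (L/kg) | 1.5, 2 | 1.5, 2 | plausible fixtures |
| Q_dmo (L/h/kg) | 1 | 1 | plausible fixture |

Between-animal CV defaults to 0.25 and proportional residual CV to 0.15 —
magnitudes a pharmacometrician would call typical for small-rodent PK; the
reference analysis's actual variability magnitudes are not published in the
accessible text, so these are fixtures, and all recovery claims are defined
against the generator's own truth.

## What passing tests do and do not show

The generator has no inter-occasion variability, no covariates or body
weights, no assay drift, no correlated parameter variability, and
proportional-only error by default. Tests passing on it demonstrate that
the estimators and fitting machinery are correct under the stated design
and error model; they do not demonstrate robustness to model
misspecification in real data (nonlinear elimination, enterohepatic
recirculation, or a mechanistic brain compartment are explicitly out of
scope).

# Operating characteristics and problem sizes

The simulation experiments in the test suite use these sizes, chosen as the
package's own desk-scale defaults:

- **Bootstrap-t coverage**: 1000 simulated destructive studies of the oral
  design (12 times, 18 animals, 3 per time), proportional error CV 0.15,
  B = 2000; observed coverage is required to fall in 93–97%.
- **Estimator bias**: 2000 simulated studies; the mean estimate must be
  within 2% of truth.
- **Parameter recovery**: 20 seeded three-arm studies with 15% proportional
  error; pooled fits must recover CL, CL_dmo, F_po and CL_parent_to_dmo
  with mean relative bias within 15%.

In the coverage and bias experiments the between-animal CV is set to 0
(fixed truth, proportional error) and "truth" is the trapezoid AUC of the
noise-free curve on the schedule. This isolates the estimator and bootstrap
machinery from trapezoid discretization bias, which on this schedule is
about 4–5% of the quadrature AUC — a property of the schedule, not of the
estimator, and one a mean-based trapezoid estimator cannot remove.

# Numerical choices, in one place

- Eigendecomposition fast path with `expm` fallback at reciprocal condition
  1e-10; `lsoda` cross-check at rtol 1e-10.
- Quadrature AUCs via `stats::integrate` at rel.tol 1e-9.
- `nlminb` iteration/evaluation caps 1000/2000; multistart ties broken by
  parameter-distance to initials; non-convergence flagged in the result.
- Bootstrap replicates with zero or non-finite `se*` dropped (counted in
  `B_used`); quantiles are the default empirical type.
- Below-limit rule: zero before the mean-curve maximum, excluded after;
  configurable.
- Welch t-tests via `stats::t.test`; a degenerate zero-variance comparison
  errors unless both groups are identical (then p = 1).

# Known limitations

Pooled fitting ignores between-animal variability, so its standard errors
(if bootstrapped) describe the pooled objective, not a population model;
the brain is simulated, not modelled; the dilution-correction formula is
validated structurally, not against a reference measurement; and ratios
carry no uncertainty. These are deliberate scope boundaries, not accidents.
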