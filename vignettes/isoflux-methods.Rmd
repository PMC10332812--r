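---
title: "Quantifying metabolic fluxes in proliferating cell cultures with isoflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying metabolic fluxes in proliferating cell cultures with isoflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isoflux)
```

# Overview

`isoflux` implements a complete analysis chain for quantifying central-carbon
metabolic fluxes in proliferating primary cell cultures from ^13^C labeling
experiments:

1. **Extracellular fluxes** from culture time courses, under an
   exponential-growth mass balance with evaporation and spontaneous
   degradation corrections.
2. **Mass isotopomer distribution (MID) processing**: natural-isotope-
   abundance correction of measured isotopologue fractions.
3. **Network modeling**: a compartmented carbon-transition network with
   elementary metabolite unit (EMU) decomposition.
4. **Labeling simulation** at isotopic steady state and during the
   nonstationary approach to it.
5. **Flux fitting** by multi-start weighted least squares with a chi-square
   goodness-of-fit test and confidence intervals from the sensitivity of
   the sum of squared residuals (SSR).
6. **Metabolomics quality control** for untargeted LC-MS batches.
7. A **synthetic-data generator** that produces culture, labeling and
   metabolomics data with known ground truth, so every stage has a
   parameter-recovery test surface.

This vignette documents the models, their assumptions, the tunable
parameters, and the numerical choices, in enough detail to judge what a
passing test suite does and does not demonstrate about real data.

# Extracellular flux model

Cell growth and medium metabolite mass are modeled as

$$\frac{dX}{dt} = \mu X, \qquad \frac{dM}{dt} = -kM + vX,$$

with $X$ the cell count, $\mu$ the growth rate (1/h), $M$ the metabolite
mass in the medium (nmol), $k$ a first-order spontaneous
degradation/accumulation rate (1/h), and $v$ the per-cell flux
(fmol·cell^-1^·h^-1^; negative values denote consumption). The solution is

$$X = X_0 e^{\mu t}, \qquad
  M e^{kt} = \frac{v X_0}{\mu + k}\left(e^{(\mu + k)t} - 1\right) + M_0.$$

Estimation proceeds exactly along this algebra:

* `fit_growth_rate()` — robust linear fit of $\ln X$ on $t$. "Robust" means
  Huber M-estimation with tuning constant 1.345, the conventional default
  of the robust-regression literature. When the fit is numerically exact
  (noiseless synthetic data) the robust scale estimate degenerates, so the
  implementation falls back to ordinary least squares, which is the
  M-estimate in that case.
* `estimate_evaporation()` — dish weights from cell-free wells are
  interpolated linearly in time (the weighing protocol is daily, and no
  functional form is known a priori) and converted to volume at medium
  density 1.00 g/mL. Volumes are clamped to be monotone non-increasing.
* `estimate_degradation()` — robust fit of $\ln M$ on $t$ in unconditioned
  (cell-free) medium gives $k$ as the *negated* slope, so that a positive
  $k$ means degradation, consistent with the governing balance
  ($M \propto e^{-kt}$ when cells are absent); a t-test on the slope at
  $\alpha = 0.05$ decides whether the rate is used downstream ($k := 0$
  otherwise). The exponential form follows from the first-order model;
  rates estimated on a log scale are also scale-free across metabolites.
* `estimate_flux()` — robust regression of $M e^{kt}$ on
  $e^{(\mu+k)t} - 1$; the slope $s$ gives $v = s(\mu + k)/X_0$. The
  degenerate case $\mu + k = 0$ uses the analytic limit ($M e^{kt}$ linear
  in $t$ with slope $vX_0$), selected at $|\mu + k| < 10^{-10}$; this is an
  exact branch, not a numerical epsilon in a denominator.

Fits may weight replicates individually (default) or on per-time means;
per-replicate weighting uses all information and propagates replicate
scatter into the standard errors.

# Natural-abundance correction

A measured isotopologue distribution convolves the tracer-derived labeling
with the natural isotope envelope of every atom in the measured ion.
`build_correction_matrix()` constructs the matrix whose column $j$ is the
expected measured MID of a species with exactly $j$ tracer-element labels;
`correct_natural_abundance()` then solves the linear system by nonnegative
least squares (NNLS) and renormalizes. NNLS is chosen over the
unconstrained inverse because noisy data can otherwise produce negative
fractions; the constrained solution always lies on the probability
simplex. Natural abundances are IUPAC representative values (^13^C 0.0107,
^2^H 0.000115, ^15^N 0.00364, ^17^O 0.00038, ^18^O 0.00205). Mass shifts
beyond the carbon count are truncated, matching selected-ion-monitoring
windows that span M0..Mn.

Tracer isotopic impurity is deliberately *not* removed here: it is part of
the forward model (`apply_tracer_impurity()`, default purity 0.99), so
correction removes only natural abundance. A pass-through hook
(`apply_mass_bias()`) accepts per-mass transmission factors for
instruments that need a quadrupole-bias adjustment; no specific factor set
is bundled because such corrections are instrument calibrations.

# The carbon-transition network

The packaged network (`isoflux_network_file()`) describes central carbon
metabolism of proliferating primary cells: glycolysis, the pentose
phosphate pathway, the TCA cycle, anaplerotic reactions, serine/glycine
metabolism, and a biomass drain, over 48 chemical reactions with seven
extracellular substrates (aspartate, cystine, glucose, glutamine, glycine,
pyruvate, serine) and five products (alanine, biomass, glutamate, lactate,
lipid). Two variants ship with the package, differing only in biomass
coefficients: lung fibroblasts (LF) and pulmonary artery smooth muscle
cells (PASMC). Modeling assumptions, all standard for this class of model:

* Metabolism is at steady state; the stoichiometric matrix over balanced
  metabolites defines the feasible flux space.
* CO~2~ released by decarboxylation leaves the system; carboxylation (PC,
  GLYS) draws unlabeled CO~2~.
* Pyruvate and acetyl-CoA are compartmented into cytosolic and
  mitochondrial pools; aspartate, fumarate, malate and oxaloacetate
  exchange freely between compartments and are modeled as single pools.
* Succinate and fumarate are rotationally symmetric: production into these
  pools is split 50/50 over the two orientations, which makes simulated
  MIDs invariant to the orientation convention.
* The measured pyruvate signal is a mixture of the cytosolic and
  mitochondrial pools; mixing weights are pseudo-reaction fluxes
  constrained to the unit simplex by the stoichiometry itself (the mixed
  pool's balance forces the weights to sum to the fixed unit outflow).
* Fatty-acid oxidation is a lumped unlabeled acetyl-CoA source; cystine
  contributes unlabeled cysteine.

Atom maps are written in a plain-text dialect (`parse_network()`):
lowercase letters map carbons one-to-one across the arrow, `<->` marks
reversible reactions carrying net and exchange fluxes, `.x`/`.c`/`.m`
suffixes tag compartments, and directives list unbalanced, symmetric and
pseudo species. The atom transitions follow standard biochemistry (e.g.
aldolase FBP(abcdef) → DHAP(cba) + GAP(def); citrate synthase
OAC(abcd) + AcCoA(ef) → CIT(dcbfea), so the acetyl carbons become C4–C5 of
2-oxoglutarate and the first two released CO~2~ derive from oxaloacetate).
Published solutions for both cell types and three treatment contrasts are
bundled as fixtures and satisfy mass balance on this network to well
within the 2% tolerance implied by their three-significant-figure
rounding — a strong end-to-end check on the reconstructed stoichiometry.

Reversible transport of products whose medium pool is not a declared
substrate (e.g. lactate re-uptake) is modeled as non-diluting: the
backward flux carries the intracellular MID. This matches a medium pool
that is initially empty and filled by the cells' own export; a medium pool
with independent composition should instead be declared as a substrate
with its own tracer specification.

# EMU simulation

`emu_decomposition()` reduces the network to the minimal set of elementary
metabolite units that determine the observed fragments, layered by size.
At isotopic steady state each size-$k$ layer satisfies a linear system
$A(v)X = B(v)Y$ whose inputs $Y$ stack tracer MIDs and convolutions of
smaller solutions; `simulate_steady_state_mids()` solves the cascade.
Reversible reactions enter with one-way fluxes
$f_{\text{fwd}} = \max(v,0) + x$ and $f_{\text{bwd}} = \max(-v,0) + x$
where $x$ is the exchange flux. A singular layer matrix indicates an EMU
pool with zero throughput and raises an error naming the EMU.

`simulate_inst_mids()` integrates the nonstationary labeling ODEs
$P\,dX/dt = A(v)X + B(v)Y$ layer by layer: each size is a
constant-coefficient linear system whose forcing depends only on smaller
sizes, interpolated from a dense solution grid (a 201-point quadratically
spaced grid plus the requested times). The integrator is `lsoda` with an
analytic Jacobian per layer, relative tolerance 1e-8 and absolute 1e-10;
trajectories are renormalized to the simplex only on output. Pool sizes
(fmol/cell) time-scale the dynamics — multiplying all pools by $c$ dilates
the labeling curves by exactly $c$ — and are free parameters in
nonstationary fitting since they are rarely known independently.

Both simulators are validated against `brute_force_isotopomer_oracle()`,
a genuinely independent implementation that iterates the full
positional-isotopomer balance (damped fixed point over distributions of
$2^n$ states per metabolite) and marginalizes to MIDs. The oracle refuses
networks beyond 12 total carbons by default; the limit is a guard against
accidental exponential blow-up, not a hard algorithmic bound.

# Flux fitting

`fit_fluxes()` estimates fluxes by weighted least squares against MID and
extracellular-flux measurements:

$$\mathrm{SSR}(\theta) = \sum_i \left(\frac{s_i(\theta) - m_i}{\sigma_i}\right)^2.$$

The parameterization (`free_flux_parameterization()`) expresses net fluxes
as a particular solution plus free coordinates of the stoichiometric null
space (column-pivoted QR), with the unit mixing outflow pinned by an
equality constraint; exchange fluxes are fitted as $10^\theta$, capped at
1e7 — effectively infinite relative to the net fluxes, matching how
unresolvable exchanges are conventionally reported. Per-fraction MID
standard deviations are floored at 0.003 mol fraction, a common
instrument-precision floor for orbitrap isotopologue measurements;
extracellular flux SDs come from the regression standard errors of the
extracellular stage.

Because peak areas cannot be negative, measured MID fractions arise from
noise that is truncated at zero and renormalized, which biases near-zero
fractions upward. A plain Gaussian fit to such data acquires systematic
flux biases several standard errors large (the fit invents dilution
pathways to explain the excess signal in empty mass channels). Declaring
`noise_model = "truncated"` in `measurement_set()` makes the estimator
use the correct measurement expectation — model fractions are passed
through $E[\max(m+\varepsilon,0)] = m\,\Phi(m/\sigma) +
\sigma\,\varphi(m/\sigma)$ and renormalized before residuals are formed —
which removes the bias and restores the chi-square calibration of the
SSR. The synthetic generator produces exactly this noise process, so the
validation studies declare it; for real data the choice belongs to the
analyst.

Optimization is bounded Levenberg–Marquardt on the residual vector with
*analytic* first derivatives obtained by implicit differentiation of each
EMU layer ($A\,dX = -(dA\,X + dB\,Y + B\,dY)$, reusing the factorization
of $A$) — finite differencing 40+ parameters through the cascade would
dominate the run time and is also less accurate near the irreversibility
boundary. Three choices keep the objective differentiable and the
optimizer moving:

* During fitting the one-way split of *reversible* reactions uses a
  softplus of width 0.2 fmol·cell^-1^·h^-1^ instead of the hard
  $\max(v, 0)$: $f_{\text{fwd}} = s\,\mathrm{sp}(v/s) + x$,
  $f_{\text{bwd}} = s\,\mathrm{sp}(-v/s) + x$. Since
  $\mathrm{sp}(z) - \mathrm{sp}(-z) = z$ the net flux, and with it mass
  balance, is preserved exactly; the smoothing only adds a vanishing
  pseudo-exchange near the sign change (simulated MIDs at a typical
  solution differ from the exact split by under 1e-5). Irreversible
  reactions keep the exact clamp with its right-derivative at zero —
  smoothing them would inflate small fluxes such as the biomass drain,
  whose large stoichiometric coefficients amplify any spurious flux.
* Irreversibility of dependent net fluxes is enforced by a smooth
  softplus penalty (weight 20, width 0.1) rather than a hard hinge.
* Each start alternates Levenberg–Marquardt with L-BFGS-B on the scalar
  SSR (sharing the analytic gradient, with `parscale` set to the current
  parameter magnitudes); either method alone stalls on this landscape,
  the alternation descends reliably. Rounds stop when the relative SSR
  improvement drops below 0.5%. With many restarts, one round is run
  from every start and only the most promising (`beam`) continue to
  convergence.

Random restarts draw free net fluxes uniformly, mixing weights uniformly
on [0,1], and exchange fluxes log-uniformly over [1e-2, 1e2] — moderate
exchange magnitudes, because starts in the fully scrambled regime
(exchange orders of magnitude above the nets) sit on plateaus that carry
no gradient information. Each random draw is first projected into the
irreversibility polytope (cheap least squares on the violations) and then
anchored to the extracellular-flux and growth measurements (a presolve
that involves no labeling simulations); the labeled fit then starts from
a feasible, data-consistent point with randomized internal splits. The
published protocol repeats estimation from at least 50 random starts;
that remains the package default for real data, while the validation
suite uses fewer restarts per fit (documented in each test) because the
presolved starts converge far more reliably than naive draws.

Goodness of fit uses the chi-square acceptance interval at the model's
degrees of freedom (number of fitted residuals minus number of free
parameters, always computed, never hard-coded):
`chi2_acceptance_interval(dof)` returns the 2.5% and 97.5% quantiles, and
a fit is accepted when its SSR falls inside. Confidence intervals come in
two flavors:

* `method = "wald"` (default): linearization at the optimum,
  $\mathrm{cov}(\theta) = (J^\top J)^{-1}$, propagated to fluxes, with
  standard errors scaled by $\max(1, \sqrt{\mathrm{SSR}/\mathrm{dof}})$
  so residual misfit beyond the nominal measurement SDs widens the
  intervals (standard weighted-least-squares practice). Exact when the
  SSR surface is quadratic; fast enough to run for every flux in a
  recovery study.
* `method = "profile"`: the SSR-sensitivity construction — scan each flux,
  re-optimizing all other parameters, until the SSR exceeds
  $\mathrm{SSR}_{\min} + \chi^2_{0.95,1} = 3.84$; a bound that never
  crosses the threshold within the box is reported as infinite. This is
  the method of record for irregular surfaces; the Wald intervals are
  verified against it on quadratic cases in the test suite.

Ratio tables (`flux_ratio_table()`) divide condition B by condition A per
reaction, omit ratios whose reference flux is below 1e-6 (ratios at
near-zero fluxes are meaningless), and flag reactions whose confidence
intervals do not overlap. `growth_normalized_fluxes()` divides fluxes by
the growth rate, converting fmol·cell^-1^·h^-1^ to fmol per cell produced;
this is the scale on which a slower-growing condition can show a relative
increase despite an absolute decrease.

# Metabolomics QC

The untargeted-metabolomics chain runs in a fixed order — drift correction,
feature filtering, imputation, probabilistic quotient normalization (PQN):

* `drift_correct()` fits, per feature, a cubic smoothing spline of pooled-
  QC peak area against injection order (stiffness by generalized
  cross-validation; no knot rule is imposed) and divides all injections by
  the prediction, rescaling to the median QC level. Fewer than four QC
  points fall back to a linear model with a warning. One spline per
  feature is standard practice; a shared model would force a common drift
  shape that real instruments do not honor.
* `filter_features()` removes features with QC relative standard deviation
  above 0.2 or dispersion ratio (QC spread over biological-sample spread,
  `sd(QC)/sd(sample)`) above 0.4; a MAD-based robust variant is available
  by flag. Retained features are never altered.
* `impute_missing()` is a pluggable hook: an iterative random-forest
  imputer (the default, seeded and deterministic), k-nearest samples, or
  half-minimum.
* `pqn_normalize()` computes each sample's dilution quotient as the median
  feature-wise ratio to a reference spectrum (median QC spectrum by
  default) and divides by it. PQN recovers constructed dilutions exactly,
  is robust to a minority of truly changing features, and is idempotent.

# The synthetic-data generator

`ground_truth()` bundles every parameter of the forward models. Its
defaults are the study conditions of the motivating experimental design:
25,000 cells seeded per 35 mm dish, ~2 mL of medium, sampling every 24 h
for 72 h, growth rates near 0.024 1/h (normoxia) and 0.017 1/h (hypoxia),
glucose ~8 mM and glutamine ~1–2 mM initial medium composition, pooled QC
injections bracketing every four samples. Where the design does not state
a value the defaults are chosen once as field-typical and documented
here: MID measurement SD 0.003 mol fraction, concentration CV 5%,
cell-count lognormal CV 5%, evaporation 0.003 g/h. They are configurable,
and none is claimed as a measured property of the original instruments.

The reference flux map for labeling simulations is the published LF 21%
O~2~ net solution projected onto exact mass balance (a magnitude-weighted
least-squares correction of the three-significant-figure rounding), with
exchange fluxes clipped to 1e3 fmol·cell^-1^·h^-1^: exchanges far above
the largest net flux are experimentally indistinguishable from infinite,
so an identifiable ground truth is the meaningful target for a recovery
study. A single global seed fans out to fixed per-operation substreams,
so growth, medium, labeling and metabolomics draws are independently
reproducible.

The recovery study (`recovery_study()`) repeats, per seed, the full
cycle generate–fit–interval and scores coverage of the generating
fluxes. Two protocol details matter. First, a net flux counts as *well
determined* when its magnitude exceeds 1 fmol·cell^-1^·h^-1^ and its
95% interval is finite and no wider than half the estimate: fluxes
failing this are by definition unresolved by the measurements, and
fluxes pinned to the polytope boundary (a mixing weight of exactly 1,
near-zero pathways) have one-sided uncertainty that a symmetric
interval cannot represent. Second, only the first seed pays for a full
multi-start search; subsequent seeds start from the first seed's
solution and re-fit — their data differ only in the noise draw, so the
warm start is a computational shortcut that carries no information
about the later replicates. The study problem size (20 noise replicates,
single-replicate MIDs per tracer, one multi-start seed) was chosen once
as the smallest design that exercises every stage meaningfully.

What the generator does *not* emulate: chromatographic peak shape and
integration, retention-time drift, ion suppression, quadrupole mass bias,
DNA-to-cell-count calibration error, and biological replicate-to-replicate
flux variability (a fitted flux map is a property of the condition, not
of the well). Passing recovery tests therefore demonstrate correctness of
the estimators under the stated statistical model, not robustness to every
real-world artifact.

# Numerical choices and edge cases

* Steady-state balance is checked before simulation at relative tolerance
  1e-6 (residual over max(inflow, outflow) per metabolite); published
  tables rounded to 3 significant figures are validated at 2%.
* The $\mu + k = 0$ branch activates below 1e-10; the balancing projection
  for printed solutions is magnitude-weighted so near-zero fluxes move
  least, and pins any irreversible flux driven negative to zero before
  re-projecting.
* EMU solutions are clipped at zero (values can undershoot by rounding)
  and observed fragments renormalized; the renormalization is propagated
  through the analytic Jacobian by the quotient rule.
* Exchange-flux gradients are kept nonzero at the cap so a parameter
  pushed onto the bound still sees the direction leading away from it;
  the box bound itself is what limits the step.
* Ties and degenerate inputs error early with informative messages:
  non-positive counts before logs, all-zero peak areas, evaporation
  drying a well inside the horizon (with the depletion time), fragments
  larger than their metabolite, missing reaction values in a flux map.

# Known limitations

* The fitting landscape of a 48-reaction network with 40+ parameters is
  multimodal; no finite restart count guarantees the global optimum. The
  restart protocol plus presolve converges reliably on synthetic data at
  the study's noise levels, but real data with model misspecification may
  need more restarts and inspection of the restart table.
* Wald intervals understate uncertainty when a flux sits on a bound or the
  surface is strongly non-quadratic; use the profile method for final
  reporting of individual fluxes of interest.
* Only carbon tracers are supported; the correction matrix handles other
  elements' natural abundance but not deuterium or nitrogen tracing.
* The nonstationary integrator assumes constant pool sizes over the
  labeling window (metabolic, not isotopic, steady state) — the standard
  assumption of this experiment class.
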