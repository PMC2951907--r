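---
title: "Biophysical models of the mitochondrial Ca2+ uniporter: flux, constraints, and staged estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biophysical models of the mitochondrial Ca2+ uniporter}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcuflux)
```

## The transport model

The mitochondrial Ca2+ uniporter carries Ca2+ down its electrochemical
gradient into the matrix of respiring mitochondria. Both model formulations
in this package share a carrier scheme in which two Ca2+ ions bind
cooperatively to the transporter and the doubly-occupied complex (net charge
+4) is translocated across the inner membrane. With
$\tilde\varphi = F\Delta\Psi/(RT)$ the reduced membrane potential
($\Delta\Psi = \Psi_e - \Psi_x$, outside minus matrix, about +190 mV in
substrate-energized, ADP-free "state 2" mitochondria), the net flux is

$$
J \;=\; \frac{k_{in}(\tilde\varphi)\,\bigl([\mathrm{Ca}^{2+}]_e/K_e\bigr)^2
        \;-\; k_{out}(\tilde\varphi)\,\bigl([\mathrm{Ca}^{2+}]_x/K_x\bigr)^2}
       {D},
$$

in nmol per mg mitochondrial protein per second (the carrier density is
absorbed into the rate constants). The denominator encodes carrier
saturation: Model 1 (fully cooperative binding) keeps only the empty and
doubly-occupied states, $D_1 = 1 + (c_e/K_e)^2 + (c_x/K_x)^2$, while
Model 2 (partial cooperativity) adds the singly-occupied terms,
$D_2 = D_1 + c_e/K_e + c_x/K_x$. Only the denominator differs between the
variants; the translocating species — and hence the numerator — is the same.

### Eyring-barrier formulation

The older formulation treats translocation as passage over a single
free-energy barrier and binding as partial movement of each ion into the
membrane potential profile:

$$
K_e = K_{e,0}\,e^{-2\alpha_e\tilde\varphi},\qquad
K_x = K_{x,0}\,e^{+2\alpha_x\tilde\varphi},\qquad
k_{in} = k_{in,0}\,e^{+4\beta_e\tilde\varphi},\qquad
k_{out} = k_{out,0}\,e^{-4\beta_x\tilde\varphi}.
$$

The factors of 2 and 4 are the charges moved (one Ca2+ per binding step,
the +4 complex in translocation). Requiring zero net flux at the
divalent-ion Nernst ratio $[\mathrm{Ca}]_x/[\mathrm{Ca}]_e =
e^{2\tilde\varphi}$ for every potential forces two exact relations
(`constraint_residuals()`):

* kinetic: $k_{in,0}K_{x,0}^2 = k_{out,0}K_{e,0}^2$,
* thermodynamic: $\alpha_e + \alpha_x + \beta_e + \beta_x = 1$
  (the displacement parameters tile the membrane).

`apply_case()` builds parameter sets with these constraints imposed by
construction; Case 1 assumes equal constants on the two faces
($K_{e,0}=K_{x,0}$, $k_{in,0}=k_{out,0}$, 4 free parameters) and Case 2
allows distinct internal constants (5 free parameters). Case 2 is retained
only as an identifiability diagnostic: scaling $K_{x,0}\to mK_{x,0}$,
$k_{out,0}\to m^2 k_{out,0}$ (`case2_family()`) preserves both constraints,
leaves the efflux numerator term exactly invariant, and under uptake
conditions (matrix Ca2+ in the hundreds of nM, far below $K_{x,0}$) changes
the flux by less than $10^{-3}$ relative for $m$ anywhere in $[0.5, 2]$ —
so Case 2 is not an estimable, distinct hypothesis, and the packaged Case-2
values are the $m=1$ member of the family.

### Generalized-GHK formulation

The newer formulation replaces the constant barrier parameters with a
generalized, nonlinear Goldman-Hodgkin-Katz (constant-field) treatment of
translocation. Both rate constants share an even translocation factor

$$
\Phi(\tilde\varphi; n_H) =
 \left[\frac{2\tilde\varphi/n_H}{\sinh(2\tilde\varphi/n_H)}\right]^{n_H},
\qquad
k_{in/out} = k_0\,\Phi(\tilde\varphi; n_H)\,e^{\pm 2\tilde\varphi},
$$

with a single shape parameter $n_H > 0$: at $n_H = 1$, $\Phi e^{\pm
2\tilde\varphi}$ is exactly the standard constant-field rate coefficient for
the charge-4 complex, and as $n_H \to \infty$ the factor flattens toward a
symmetric Eyring barrier. Detailed balance is built in (the ratio
$k_{in}/k_{out} = e^{4\tilde\varphi}$ holds identically), so with equal
binding constants ($K_{e,0}=K_{x,0}=K_0$, the Case-1 conclusion) the model
is thermodynamically consistent for any $n_H$. Equating the two
formulations' rate constants gives analytic, potential-dependent barrier
parameters (`beta_effective()`)

$$
\beta_e(\tilde\varphi) = \tfrac12 +
  \frac{\ln\Phi(\tilde\varphi;n_H)}{4\tilde\varphi},\qquad
\beta_x(\tilde\varphi) = 1 - \beta_e(\tilde\varphi),
$$

smooth through $\Delta\Psi = 0$, in contrast to the constant published
values (0.113/0.887), which swap across zero by mirror symmetry and kink the
potential-dependent flux factor there (`beta_and_e_curves()` tabulates the
contrast; the constant-parameter curves are rendered exactly as the
published constants evaluate, for diagnosis only).

When the binding-site displacement is allowed to be positive
($\alpha = \alpha_e = \alpha_x > 0$), the translocation step spans only the
fraction $s = 1 - 2\alpha$ of the potential, and the package applies the
factor over that span, $k_{in/out} = k_0\,\Phi(s\tilde\varphi;
n_H)\,e^{\pm 2 s\tilde\varphi}$, which preserves detailed balance exactly
for every $\alpha$ and reduces to the form above at the fitted value
$\alpha = 0$.

### Numerical choices

* $\Phi$ and $\ln\Phi$ are evaluated in log space;
  $x/\sinh x$ switches to a fourth-order series below $|x| < 10^{-4}$
  (relative switch error below $10^{-12}$), so `phi_factor(0, nH)` is
  exactly 1 and fluxes are finite at $\Delta\Psi = 0$. The same series
  treatment makes `beta_effective()` smooth through zero
  ($\beta_e \approx 1/2 - \tilde\varphi/(6 n_H)$ near the origin).
* Physical constants: $F = 96485$ C/mol, $R = 8.314$ J/(mol K); the
  temperature is exposed in `thermo_context()` with a default of 298.15 K
  (the sources do not state one; the fitted rate-constant ratios between
  the two formulations are consistent with this choice to within 0.1%).
* Units: all concentrations are molar internally; file I/O columns carry
  unit suffixes (`ca_e_uM`, `ca_x_nM`, `dpsi_mV`, `rate_nmol_mg_s`) because
  the published tables mix molar and micromolar conventions. Matrix Ca2+
  defaults to 250 nM, the fitting convention of the source data.
* Constraint tolerance: $10^{-9}$ relative; the relations are exact, the
  tolerance only absorbs floating-point noise.

## Synthetic protocols

The three source datasets (initial Ca2+ uptake rates in rat heart and rat
liver mitochondria versus external Ca2+ at 190 mV, and in rat liver versus
membrane potential at 0.5/1.0/1.5 uM external Ca2+) were published in the
1970s-80s as figures and are not deposited. `make_protocol()` /
`generate_dataset()` therefore emulate the three designs: Ca2+ titrations
use 20 log-spaced points over 1-150 uM (bracketing the plotted ranges), the
potential titration 15 points over 60-190 mV at each of the three Ca2+
levels, all at 250 nM matrix Ca2+. Measurement noise is multiplicative
Gaussian with a default CV of 5% — the sources report no error model, and a
relative noise model respects the order-of-magnitude span of rates across
conditions. Every stochastic path takes an explicit seed, recorded in the
dataset provenance, and the global RNG stream is left untouched.

What the generator does *not* emulate: the malonate-titration chemistry
used experimentally to set the potential (here $\Delta\Psi$ is specified
directly), Mg2+ competition (absorbed into the per-preparation rate
constants, as in the published fits), matrix Ca2+ drift during uptake, and
any systematic digitization error. Passing recovery tests on these
synthetic data therefore demonstrates the estimator's statistical behavior
under the stated conditions, not fidelity of the model to new experiments.

## Staged estimation

`mcu_objective()` implements the normalized mean residual error

$$
E(\theta) = \frac{1}{N_{exp}} \sum_j \frac{1}{N_{data,j}} \sum_i
  \left(\frac{J^{data}_{ij} - J^{model}_{ij}(\theta)}{J^{max}_j}\right)^2 ,
$$

with $J^{max}_j$ the maximum measured rate of experiment $j$. The
normalization is per-experiment by default (each experiment contributes on
a comparable scale regardless of its absolute rates); a global maximum is
available via `jmax = "global"`. Residuals are otherwise unweighted.

`staged_fit_present()` and `staged_fit_previous()` follow a three-step
modular scheme: (1) the binding constant of each tissue from its Ca2+
titration (the rate constant is provisional there — at fixed potential it
only scales the amplitude, so the shape parameters can be held at arbitrary
constraint-satisfying values without biasing the binding constant); (2)
with the liver binding constant fixed, the potential-titration rate
constant and the shape/barrier parameters from the potential-titration
data; (3) the preparation-specific rate constants of the Ca2+ titrations
with everything else fixed. Each stage minimizes $E$ by bounded
Levenberg-Marquardt (`minpack.lm::nls.lm`) restarted from 8 seeded
log-uniform initial guesses inside the bounds (`fit_stage()`); the staged
objectives are initial-guess sensitive, so multistart is integral, and the
whole pipeline is deterministic given the datasets and the seed. Default
bounds: $K_0 \in [1, 1000]$ uM, Ca2+-titration rate constants in
$[10^{-4}, 100]$ nmol/mg/s (wider, $[10^{-4}, 10^{3}]$, for the
potential-titration dataset whose published value is 44.5), $n_H \in [0.2,
10]$, $\alpha \in [0, 0.45]$ (the upper bound keeps the translocation span
positive), $\beta_e \in [0, 1]$ with $\beta_x = 1 - 2\alpha - \beta_e$ by
constraint.

### The binding-site displacement and identifiability

A structural feature of uptake-protocol data drives the one genuinely open
design decision in the pipeline. In both formulations the displacement
$\alpha$ multiplies the influx term by $e^{4\alpha\tilde\varphi}$ through
the binding constant and divides it by (previous) $e^{4\alpha\tilde\varphi}$
through the thermodynamic constraint on $\beta_x$, or (present) rescales
the argument of $\Phi$: to first order its influx effect cancels, leaving
only a second-order signature in the denominator saturation and the
curvature of $\Phi$. With 5% measurement noise the stage-2 objective
therefore has a noise-tilted, nearly flat valley along which $\alpha$
trades against $\beta_e$ (previous) or $n_H$ (present); an unconditional
minimizer occasionally reports, for example, $\hat\beta_e \approx 0$ with
$\hat\alpha \approx 0.11$ — an excursion along the valley, not information.

Stage 2 therefore fits the reduced model ($\alpha = 0$, the published
estimate) and the $\alpha$-free model, and retains a positive displacement
only when a likelihood-ratio (F) comparison rejects $\alpha = 0$ at the
0.001 level (doubled per the 50:50 boundary mixture of the null
distribution for a parameter on its bound). This mirrors how the
indistinguishable-Cases and $m$-family degeneracies are treated: parsimony
unless the data are decisive. The selected model, the F statistic and both
candidate fits are kept in the stage-2 diagnostics, and
`parameter_sensitivity()` reports near-zero sensitivity of $E$ along the
$m$ direction of Case-2 fits (the quantitative form of the degeneracy),
strictly positive sensitivity to $n_H$ on potential-titration data, and
nonnegative perturbation responses at any optimum.

Two consequences are documented rather than hidden. First, exact recovery
(noise-free data reproduce the generating parameters to better than
$10^{-4}$ relative) holds for the packaged, $\alpha = 0$ generating sets;
for hypothetical $\alpha > 0$ generators the three-step scheme is
structurally inconsistent (stage 1 interprets the 190 mV binding constant
as the zero-potential one), and no exact-recovery claim is made. Second,
the stage-3 rate constants inherit the stage-1 binding-constant error
roughly squared (the identified combination at sub-saturating Ca2+ is
$k_0/K_0^2$) plus the $n_H$ error through the 190 mV flux factor
(elasticity $\approx 3.7$ at the liver values), so their sampling error is
a multiple of the binding constant's — about 6-8% SD under the default
study conditions, versus about 3% for $K_0$ itself. Single-realization
recovery of a rate constant to 5% is therefore not a reliable property of
the published staged scheme at this noise level; users who need tighter
rate constants should average replicate datasets or fit $K_0$ and $k_0$
jointly on richer designs.

## Sensitivity analyses

`matrix_ca_envelope()` sweeps matrix Ca2+ over 100-500 nM (17 log-spaced
points by default) at every protocol condition and reports the worst-case
relative flux spread. For the generalized-GHK model with the packaged
parameters the metric is below $10^{-3}$ for all three default protocols —
the executable form of the robustness claim that motivated the
reformulation: with equal binding constants, the back-flux and
matrix-side saturation terms are bounded by $(c_x/K_0)^2 \lesssim 10^{-4}$.
A negative internal displacement (as in the originally published
unconstrained Case-2 fits) inflates the matrix-side term exponentially and
the envelope opens up; the test suite reproduces this pathology
qualitatively rather than asserting a specific published number.
`dpsi_family()` evaluates the flux surface over external Ca2+ (10-150 uM)
and potential (100-210 mV) grids pointwise (50 points per axis by default
for plotting; envelopes use 17); all sweep outputs are pure functions of
their arguments and serialize to tidy, provenance-headed CSV.

## Problem sizes and runtimes

The packaged study conditions are deliberately desk-scale: 20-point Ca2+
titrations, 45-point potential titrations, staged fits with 8 multistarts
(a few seconds each), property suites with $10^3$ random
constraint-satisfying parameter draws, and 20-replicate seeded Monte Carlo
checks of median recovery error. These sizes are the package's test
conditions, chosen to make every empirical statement in this vignette
reproducible in seconds; all grids, replicate counts and multistart budgets
are arguments.

## Known limitations

* No Mg2+ competition or inhibition term, no pH or surface-potential
  corrections, no time-dependent gating: the model describes initial-rate
  uptake kinetics with per-preparation rate constants.
* The original experimental grids and error structure are unknown; the
  synthetic protocols are a documented stand-in, not a digitization.
* Case 2 and $\alpha > 0$ are supported as diagnostics, but the uptake
  protocols cannot identify them; conclusions about internal binding
  asymmetry require qualitatively different data (e.g., reverse-mode or
  matrix-side titrations).
* The potential-titration rate constant (published value 44.5 nmol/mg/s
  against 0.30 for the same tissue's Ca2+ titration) absorbs large
  preparation differences; comparisons across datasets are only meaningful
  through the shared binding and shape parameters.
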