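---
title: "Assay models and fitting methods in readerscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assay models and fitting methods in readerscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(readerscreen)
```

This vignette documents the quantitative models behind each analysis
module, the rationale for the default parameters, and what the seeded
simulators do and do not emulate.

# Plate-level quantitation

For a displacement plate with maximum-signal (uninhibited) controls and
minimum-signal (fully displaced) controls, the standard readouts are

- percent inhibition
  $I = 100\,\bigl(1 - (A_I - \mu_{\min}) / (\mu_{\max} - \mu_{\min})\bigr)$,
- percent quench $Q = 100\,(1 - A_I / \mu_{\max})$, which ignores the
  residual minimum and is used as a counter-screen statistic,
- the Z′-factor
  $Z' = 1 - (3\sigma_{\max} + 3\sigma_{\min})/|\mu_{\max} - \mu_{\min}|$.

`percent_inhibition()` is invariant to affine transformations of the
signal scale (gain and offset); `percent_quench()` is invariant to gain
only. Both properties are enforced by the test suite.

Dose–response series are fitted with a four-parameter logistic
$y = b + (t - b) / (1 + (x/\mathrm{IC}_{50})^{h})$ via
`minpack.lm::nlsLM`, with self-starting values from the data range and
the half-response crossing. `fit_4pl()` reports convergence and
standard errors; a flat series is reported as non-converged rather than
given an arbitrary IC50.

## Hook effect

In bead-based proximity assays each bead type has a finite binding
capacity. Once the titrated component exceeds the capacity of its bead,
additional material competes free in solution and the signal *falls*
with increasing concentration — the "hook". `alpha_bead_model()`
captures this with a donor capacity (default 50 nM, the streptavidin
capacity for a biotinylated peptide) and an acceptor capacity (default
1 µM for the His-tagged protein). Because the two capacities differ by
20-fold, a cross-titration over the same concentration range hooks on
the peptide axis but not on the protein axis; `hook_point()` locates
the interior maximum and returns `NA` for monotone series.

# Binding equilibria

For receptor $R$, labelled probe $P$ and competitor $C$ with
dissociation constants $K_P$ and $K_C$, mass action and conservation
reduce to a single scalar equation in the free receptor concentration
$r$:

$$f(r) = r\left(1 + \frac{p_t}{K_P + r} + \frac{c_t}{K_C + r}\right) - r_t = 0.$$

$f$ is strictly increasing on $[0, r_t]$ with $f(0) \le 0$ and
$f(r_t) \ge 0$, so the root is unique. `solve_competitive()` brackets
it with `uniroot` and polishes with Newton steps; internal conservation
residuals are verified to $10^{-8}\,r_t$ against an independent
bisection oracle in the tests. `solve_1to1()` uses the stable quadratic
closed form. `displacement_curve()` maps competitor dose to the bound
probe fraction and `half_displacement_dose()` inverts it, giving the
theoretical IC50 implied by a set of totals and affinities — useful for
calibrating simulations and for converting IC50s to $K_i$-like
quantities without the approximations of algebraic corrections.

# Fluorescence polarization

Polarization from the parallel (S) and perpendicular (P) channels is

$$mP = 1000\,\frac{I_S - G\,I_P}{I_S + G\,I_P},$$

with total intensity $2 I_P + I_S$ (the perpendicular channel is
counted twice for the two orthogonal detection axes). The G-factor is
calibrated from a free-fluorophore reference of known polarization
(`calibrate_g_factor()`), and `intensities_from_mp()` provides the
exact inverse used by the simulators.

Binding-induced polarization sits on top of a nonspecific component
from light scattering and viscosity at high protein. With references
$P_D^*$ (probe alone, default 25 mP) and $P_D^*R$ (probe saturated
with receptor, default 225 mP):

- bound fraction $F_B = (P_M - P_D^*)/(P_D^*R - P_D^*)$,
- nonspecific $P_{NS} = (P_I - P_D^*)(1 - F_B)$, where $P_I$ is the
  matched titration with an inert (non-binding) protein,
- specific $P_S = P_M - P_{NS}$, so that $P_S + P_{NS} = P_M$ holds
  identically.

`fit_probe_kd()` fits the hyperbola $Y = B_{\max} R/(K_D + R)$ to the
corrected signal. Two modes are offered:

- `"total"` treats the nominal receptor concentration as free. This is
  the conventional treatment and the package default, but it biases
  $K_D$ upward when the probe concentration is not far below $K_D$
  (ligand depletion).
- `"depletion"` solves the 1:1 equilibrium inside the model function so
  the fitted $K_D$ is exact at any probe concentration. Use this when
  the probe is within ~3-fold of the expected $K_D$ (e.g. a 10 nM probe
  against a ~31 nM site).

The bias is demonstrated quantitatively in the tests: with a 60 nM
probe against a 31 nM site, total mode is >20 % off while depletion
mode recovers the truth.

# FTSA / DSF

Melting curves are fitted with a Boltzmann sigmoid
$F = b + (t - b)/(1 + e^{(T_m - T)/s})$ after truncating points past
the post-transition fluorescence maximum (aggregation quenching).
`dh_u_from_steepness()` converts the slope parameter to a van 't Hoff
unfolding enthalpy, $\Delta H_U = R\,T_K^2 / s$.

Dose-dependent $T_m$ shifts are interpreted with a coupled
unfolding–binding model. The unfolding constant follows
Gibbs–Helmholtz anchored at the reference midpoint $T_r$
($\Delta G_U(T_r) = 0$):

$$\Delta G_U(T) = \Delta H_U\,(1 - T/T_r) + \Delta C_{p,U}\,\bigl(T - T_r - T \ln(T/T_r)\bigr),$$

and the binding constant follows van 't Hoff from its value at a
reference temperature $T_0$. At the observed midpoint, half the
protein is unfolded, which yields the ligand total required to place
the midpoint at $T$:

$$L_t(T) = (K_U(T) - 1)\left(\frac{1}{K_b(T)} + \frac{M_t}{2 K_U(T)}\right),$$

with $M_t$ the total protein concentration. `fit_kd_from_dosing()`
inverts this relation by nonlinear least squares on the measured
$(L_t, T_m)$ pairs with $K_D(T_0)$ as the free parameter;
`ftsa_species()` exposes the full species balance so the half-unfolded
condition can be verified at any fitted dose. Flat $T_m$ series are
flagged `non_binder` instead of being forced through the model.

Default thermodynamic parameters in `thermo_params()`:

- $\Delta C_{p,U} = 8$ kJ/(mol K): a typical unfolding heat-capacity
  increment for a small (~25 kDa) domain.
- $\Delta H_b = -42$ kJ/(mol K), $\Delta C_{p,b} = 0$: a generic
  exothermic binding enthalpy with negligible heat-capacity change,
  adequate over the ~15 °C span of a melt experiment.
- $T_0 = 37$ °C: the temperature at which reported $K_D$s apply.
- Protein totals follow the assay setup: 0.1 mg/ml Spindlin1
  corresponds to 3.88 µM; a JMJD2C-Td setup uses 27 µM.

These defaults matter only for converting $T_m$ shifts to affinities;
the melt fits themselves are model-free.

# BLI kinetics

The 1:1 Langmuir model gives association

$$R(t) = R_{eq}\,(1 - e^{-(k_a C + k_d) t}), \qquad
  R_{eq} = \frac{R_{\max}\,k_a C}{k_a C + k_d},$$

and exponential dissociation from the association end-point.
`global_fit_1to1()` fits $k_a$, $k_d$ and $R_{\max}$ globally across
analyte concentrations after reference-sensor subtraction
(`reference_subtract()`, which removes shared drift exactly) and
re-zeroing at the association start. $K_D = k_d / k_a$
(`kd_from_rates()`). When the dissociation phase decays too little to
constrain $k_d$ (very slow off-rates), the fit flags `kd_reliable =
FALSE` instead of reporting a spuriously precise constant.

Competitive readouts: `report_point_displacement()` converts late
association report points to percent displacement against a
no-competitor control, and `dissociation_shift()` quantifies
ternary-complex-induced changes in off-rate. `regeneration_qc()`
checks signal retention across regeneration cycles.

# CETSA

Band intensities are normalized per condition either to the
lowest-temperature point (`"relative_to_lowest_temp"`) or min–max
(`"min_max"`); both are invariant to exposure (overall gain) so that
blots developed differently remain comparable. `fit_tagg()` fits a
*decreasing* Boltzmann and reports the aggregation midpoint $T_{agg}$;
increasing series are rejected and flat series flagged as having no
transition. `delta_tagg()` subtracts control from treated midpoints;
`fit_tagg_replicates()` averages across replicates.

# Simulators

Every simulator (`simulate_displacement_plate()`,
`simulate_alpha_matrix()`, `simulate_fp_titration()`,
`simulate_ftsa()`, `simulate_bli()`, `simulate_cetsa()`) draws all
randomness from an explicit `seed`, restores the caller's RNG state,
and returns a `sim_truth` object carrying the generating parameters, so
analyzers can be validated by parameter recovery.

Noise models: plate signals use multiplicative log-normal noise with
unit mean and a specified CV (`noise_cv`); FP adds Gaussian mP noise;
BLI adds Gaussian response noise plus optional linear drift; FTSA
applies CV noise to fluorescence. FP titrations include a linear
nonspecific-polarization component (default scaled to contribute 5 mP
at the top of the dose range) and a matched inert-protein series so the
full correction chain is exercised.

What the simulators do **not** emulate: dispensing errors, edge
effects, inner-filter effects, bead settling, photobleaching,
mass-transport limitation in BLI, or aggregation kinetics beyond the
simple post-transition quench in FTSA. They are designed to test the
analysis chain, not to replace instrument characterization.

# Problem sizes and performance

All fits are small nonlinear least-squares problems (tens of points,
2–4 parameters) solved in milliseconds with `minpack.lm`. The
equilibrium solvers are scalar root finds; a full simulate-and-analyze
cycle for any assay runs in well under a second, and the entire test
suite (including 50-seed recovery studies for five assays and 1000
randomized solver cross-checks) completes in under half a minute on one
CPU.
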