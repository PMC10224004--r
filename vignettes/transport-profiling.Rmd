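---
title: "Methods: dissolution, distribution, complexation and permeation profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dissolution, distribution, complexation and permeation profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(partperm)
```

`partperm` chains four classical physicochemical analyses — dissolution
thermodynamics, two-phase distribution, cyclodextrin complexation by the
phase-distribution method, and Franz-cell permeability — into one tested
pipeline, with synthetic-experiment generators that reproduce the
statistical structure each estimator assumes. This vignette is the
package's account of the underlying models, the choices that were
genuinely open, and what the tests do and do not demonstrate.

## Dissolution thermodynamics

Shake-flask solubilities arrive as molar concentrations $S_2$ (mol/L).
Thermodynamic analysis needs the mole fraction $X_2$, which requires the
solvent density $\rho$ (g/cm³). Two algebraic variants of the conversion
are provided:

$$X_2 = \frac{M_2 S_2}{S_2 (M_1 - M_2) + 1000\,\rho}
\qquad\text{(as\_printed)}$$

$$X_2 = \frac{M_2 S_2}{1000\,\rho - S_2 (M_1 - M_2)}
\qquad\text{(mass\_balance)}$$

with $M_1$, $M_2$ the solute and solvent molar masses. The second form
is what a mass balance gives when the solution density is approximated
by the solvent density (solvent mass = solution mass − solute mass); the
first is the form conventionally printed in solubility papers, which
differs in the sign of the correction term. For the dilute systems this
package targets the difference is below ~4%, and both modes are strictly
increasing in $S_2$ on their valid domain. The default is `as_printed`
for fidelity to the published convention; neither mode models the true
solution density, which is the dominant unquantified approximation.
Default densities (1-octanol 0.8262, n-hexane 0.6548 g/cm³) are
pure-solvent literature values at 298 K, held temperature-independent
over the narrow 290–313 K working interval; both are overridable via
`solvent_spec()` or the YAML config.

The van't Hoff fit is unweighted OLS of $\ln X_2$ on $1/T$
(natural logs here; the complexation module below deliberately uses
base-10 — the two conventions coexist in the field and are kept explicit
in code and docs):

$$\ln X_2 = A + B/T, \qquad
\Delta H^0 = -R B, \quad
\Delta G(T) = -RT\,(A + B/T), \quad
T\Delta S = \Delta H - \Delta G = RTA$$

with $R = 8.314$ J mol⁻¹ K⁻¹. Energies are computed in J/mol and
reported in kJ/mol to one decimal. The single-slope form assumes
$\Delta C_p = 0$ over the interval (linear van't Hoff behaviour); no
activity-coefficient correction is applied. The enthalpy fraction
$\zeta_H = |\Delta H| / (|\Delta H| + |T\Delta S|)\cdot 100\%$ summarises
which term drives the process; it is undefined (and signalled as
degenerate) only when both terms vanish. Transfer functions between two
solvents are component-wise differences of the dissolution functions and
are exactly antisymmetric under solvent exchange.

Unweighted fitting was chosen because published per-line summaries (one
correlation coefficient, one residual scatter) imply it, and per-point
uncertainties are rarely available on the mole-fraction scale. Reported
uncertainties of derived quantities are first-order propagations of the
fit standard errors ($se_{\Delta H} = R\,se_B$,
$se_{T\Delta S} = RT\,se_A$, $se_{\Delta G}$ from the full coefficient
covariance); no replicate-level data enter.

One reconstruction limit worth knowing: converting the packaged molar
solubility table with the default densities and refitting does **not**
exactly reproduce the study's reported coefficients (it gives
$A \approx 5.0$–$5.5$ depending on the conversion mode, versus the
reported 5.79 for 1-octanol). The original density values and unrounded
solubilities are not available, so analyses that start from the reported
coefficients use them directly (`vant_hoff_fit()` accepts coefficients
as inputs; `ipn_vant_hoff_coefficients()` ships them).

## Distribution and Δlog D

The apparent distribution coefficient is computed in one of two modes:

* `mass_balance` (default): only the aqueous phase is assayed, and the
  organic amount follows by conservation from the stock concentration,
  $D = (C^0_{aq} - C_{aq}) V_{aq} / (C_{aq} V_{org})$. This is standard
  shake-flask practice and is the dimensionally consistent reading of
  the volume-bearing working equation used in the source experiments.
* `direct_ratio`: both phases assayed, $D = C_{org}/C_{aq}$.

The two agree exactly whenever $C_{org}$ itself satisfies the same
conservation relation (a closure the tests enforce). No ionization
correction is applied: the compounds this package was built around are
un-ionized at pH 7.4, so apparent D is treated as P-like. Replicates are
averaged arithmetically with the sample standard deviation as the
uncertainty. $\Delta \log D = \log D_{oct} - \log D_{hex}$ indexes
hydrogen-bonding capacity, since the alkane phase offers only
non-specific interactions.

## Cyclodextrin association constants

A 1:1 inclusion complex holds drug in the aqueous phase, suppressing the
distribution coefficient as $D(C) = D_0/(1 + K_C C)$. (The study's
working relation is printed with the ratio inverted, which would make
$D$ *increase* with host concentration and contradicts its own
measurements; the package's exact model uses the physically consistent
orientation. The log-log linearization below is implemented verbatim.)

$$\log_{10}\!\frac{D_0 - D}{D_0} = \log_{10} K_C + \alpha \log_{10} C_{CD}$$

fitted by unweighted OLS. The intercept estimates $\log_{10} K_C$ and
the slope $\alpha$ the stoichiometry exponent ($\alpha \approx 1$ for
1:1 binding). Base-10 logarithms are used throughout this module,
consistent with intercepts of order 0.5–1.5 in the published tables.
Published association tables sometimes print the intercept itself under
the symbol $K_C$, so `fit_kc()` always reports both the intercept and
its antilog. $C_{CD}$ is the total host concentration (free-host
correction is negligible for such weak complexes), and host partitioning
into the organic phase is not modelled.

Diagnostics: $R$ is the pair correlation of the transformed points,
and the Fisher criterion is $F = R^2 (n-2)/(1 - R^2)$, returned as
`Inf` on an exact fit. With the usual three host concentrations both are
hypersensitive to input rounding and should be read qualitatively.

`fit_kc_nonlinear()` fits the exact 1:1 model by least squares over
$K_C \ge 0$ (one-dimensional, solved with `stats::optimize` on a
data-driven bracket) and serves as the independent oracle: in the
small-saturation limit the linearization converges to it. One caution
the tests encode: the linearization's intercept is an extrapolation to
$C_{CD} = 1$ M, far outside the usual 0.01–0.05 M working range, so the
$O(K_C C/\ln 10)$ curvature term is amplified roughly by
$|\overline{\log_{10} C}|$. Agreement with the exact model to within
0.03 in both parameters therefore needs $K_C C \lesssim 0.02$; at
$K_C C = 0.05$ the intercept bias already reaches ~0.05 even though the
slope is still within 0.03.

## Franz-cell permeability

Periodic withdrawal of acceptor aliquots removes analyte and dilutes the
compartment, so the cumulative permeated amount must be reconstructed
before any flux fit:

$$Q_k = C_k V_{acc} + \sum_{i<k} C_i V_{sample}$$

(volumes in litres; replacement buffer is analyte-free). Concentrations
are understood as measured at withdrawal, pre-replacement — standard
assay practice. Inputs whose concentrations fall faster than replacement
dilution alone can explain are flagged with a warning, not rejected.

Two P_app estimators are provided:

* **Flux route** (default): $J$ = OLS slope of $Q/A$ versus $t$ (s),
  $P_{app} = J / (C_0/1000)$ (cm/s for $C_0$ in mol/L). The intercept is
  free, so a lag offset never biases the slope; `window = "auto"` can
  additionally drop leading lag points while doing so improves the fit
  correlation (≥ 3 points must remain). This is exact under a perfect
  sink but biased low by the mean acceptor/donor ratio otherwise — a few
  per cent at the default geometry when the 10% sink rule holds.
* **Non-sink route** (`method = "nonsink"`): between samplings a small
  acceptor obeys $dC/dt = k (C_0 - C)$ with
  $k = P_{app} A / V_{acc}$, so each interval inverts to
  $k_i = -\ln\!\big((C_0 - C_i)/(C_0 - C'_{i-1})\big)/\Delta t$ with
  $C'_{i-1}$ the post-replacement concentration, and $P_{app}$ is the
  mean over intervals. This is the standard non-sink correction for
  small-acceptor cells; it assumes a constant donor concentration and
  removes the back-diffusion bias entirely. Simulation closure tests use
  this route, which recovers generating permeabilities within 1% across
  1e-6 to 1e-4 cm/s at the default geometry, a range over which the
  uncorrected flux route degrades from −0.2% to about −17%.

The sink check reports whether the acceptor ever exceeded 10% of the
donor concentration, with the worst ratio. The donor is treated as
constant in both estimators (donor depletion exists only in the
simulator, where it can be switched on).

Default geometry: 0.785 cm² area, 7 mL donor, 1 mL acceptor, 0.5 mL
withdrawn every 30 min over 5 h (ten samples).

## What the generators emulate — and what they do not

All three generators are pure functions of (parameters, seed): seeded
runs are bit-reproducible and leave the caller's RNG untouched
(`withr::with_seed`). The default noise model is multiplicative
lognormal with σ = 3%, the midpoint of the 2–4% accuracy typical of
spectrophotometric assays; `none` and additive-Gaussian variants exist.
With `none`, every downstream estimator is exact to its stated
tolerance.

* `simulate_solubility_series()` draws $X_2 = e^{A + B/T}$ — exactly the
  estimator's model. Passing its round trip shows estimator correctness,
  not that real systems are van't Hoff-linear.
* `simulate_cd_suppression()` draws from the exact 1:1 model. Real data
  can hide 1:2 binding or host self-association, which the package
  deliberately does not model.
* `simulate_franz_cell()` integrates the two-compartment model on a
  fixed 1-minute Euler grid with flux proportional to
  $(C_{donor} - C_{acceptor})$, withdraws and replaces at each sampling
  time, and records pre-replacement concentrations. At the rate
  constants of interest the Euler discretisation error is below 0.3%
  (worst case, 1e-4 cm/s), negligible against the 1% closure tolerance;
  the grid is intentionally not configurable below 1 min. Each simulated
  run carries an audit trail (true concentrations, withdrawn amounts,
  compartment totals) against which mass conservation holds to 1e-9
  relative — in practice to machine precision. Membrane lag time,
  partition-into-membrane kinetics and host–membrane interactions are
  out of scope, so the simulator cannot validate estimators against
  those effects.

## Numerical and statistical choices

* Degenerate designs fail loudly and specifically: fewer than two
  points, a single repeated temperature, zero suppression, non-positive
  mole-fraction denominators and acceptor ≥ donor all raise classed
  errors rather than propagating NaN.
* On exact data, `lm`'s "essentially perfect fit" chatter is
  suppressed; the $F$ statistic switches to `Inf` when the residual sum
  of squares is numerically zero relative to the total.
* Coverage of noisy van't Hoff refits is assessed with the 95%
  confidence interval $B \pm t_{0.975,\,n-2}\,se_B$: with $n = 5$ a
  ±1 SE band would cover only ~60–65% of replicates and is not a
  meaningful target.
* Problem sizes used by the test suite: 500 seeded replicates for the
  van't Hoff coverage property, 200 for the Franz-cell noise property,
  five-temperature series and three-concentration suppression series
  matching the reference experiments. The full suite runs in a few
  seconds.

## Known limitations

* The mole-fraction conversion ignores the solute's contribution to the
  solution density; for highly soluble compounds (mole fractions above
  ~0.1, as for iproniazid in 1-octanol) this is the leading error and
  differs between the two conversion modes.
* Thermodynamic uncertainties propagate only regression standard
  errors; inter-replicate variability of the underlying solubilities is
  not represented.
* The phase-distribution method needs strict suppression ($D < D_0$) at
  every usable concentration; weak binders at low host concentrations
  can fail this within noise, and such points are excluded with a
  warning rather than imputed.
* Reported permeabilities from the flux route inherit the sink
  approximation; when the sink flag is false, prefer the non-sink
  estimator or redesign the sampling schedule.
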