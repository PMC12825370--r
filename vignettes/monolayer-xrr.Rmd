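---
title: "Slab-model XRR analysis of surfactant monolayers: models, choices, limitations"
author: "monofilm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Slab-model XRR analysis of surfactant monolayers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(monofilm)
```

# The physical model

Specular X-ray reflectivity measures the intensity ratio of reflected to
incident X-rays as a function of the wave-vector transfer normal to the
surface, $Q_z = (4\pi/\lambda)\sin\alpha$. It is sensitive to the laterally
averaged electron-density profile $\rho(z)$ across the interface, with
Ångström-scale resolution. For a surfactant film on water we model
$\rho(z)$ as a stack of homogeneous slabs — each with thickness $d_i$
(Å), electron density $\rho_i$ (e⁻/Å³), and interfacial roughness
$\sigma$ (Å) — smoothed by error functions:

$$\rho(z) = \frac{1}{2}\sum_{i} \operatorname{erf}\!\left(
  \frac{z - z_i}{\sqrt{2}\,\sigma_i}\right)(\rho_i - \rho_{i+1})
  + \frac{\rho_0 + \rho_N}{2},$$

where $z_i$ are the interface positions (partial sums of the $d_i$),
$\rho_0$ is the subphase density and $\rho_N$ the air density. Because
$\operatorname{erf}(\pm\infty) = \pm 1$, only the *average*
$(\rho_0+\rho_N)/2$ as the constant term yields the correct asymptotes
($\rho \to \rho_N$ in air, $\rho \to \rho_0$ in water); a difference term
would shift the whole profile. `build_edp()` therefore implements the
average. The roughness physically lumps capillary-wave broadening and
intrinsic density gradients; one shared $\sigma$ per sample is the default
fitting mode (`shared_sigma`), with per-interface overrides available.

Two useful identities are exposed as functions because they make good
consistency checks:

* the areal excess $\int [\rho(z) - \rho_{\rm step}(z)]\,dz
  = \sum_i d_i(\rho_i - \rho_0)$ is independent of $\sigma$
  (`film_excess_integral()` vs `slab_excess()`), and
* a slab with $\rho = \rho_0$ is invisible to reflectivity.

## Reflectivity

`parratt_reflectivity()` evaluates the Parratt recursion for the reflected
amplitude, with roughness as Névot–Croce damping of each interface's
Fresnel coefficient. Absorption is neglected (imaginary scattering density
zero): for organic films and water at hard X-ray wavelengths around 1.3 Å
the absorptive part of the scattering-length density is several orders of
magnitude below the real part and has no visible effect over the
$Q_z \le 0.6$ Å⁻¹ range analyzed here.

The damping-factor picture assumes the roughness profiles of neighboring
interfaces do not overlap. When $\max\sigma$ exceeds half the thinnest
slab thickness (threshold configurable), the engine automatically renders
the smoothed profile into 0.25 Å sharp slices and runs the same recursion
— this reproduces the erf-profile physics for rough thin layers where the
closed-form damping is inaccurate. The two renderings are also the basis
of the validation strategy below.

Measured curves are conventionally displayed as $R/R_F$, the reflectivity
normalized to the Fresnel reflectivity of an ideally sharp bare interface

$$R_F = \left|\frac{q - \sqrt{q^2 - q_c^2}}{q + \sqrt{q^2 - q_c^2}}
\right|^2, \qquad q_c = 4\sqrt{\pi r_e \Delta\rho},$$

which removes the steep $q^{-4}$ decay ($q_c \approx 0.0217$ Å⁻¹ for
water against air). `normalize_to_fresnel()` and its inverse are exact
reciprocals.

Instrumental resolution smearing is off by default — analyzed curves from
liquid-surface reflectometers are usually already corrected, and no
resolution width is assumed. A Gaussian $dq/q$ smearing flag is available
(7-point Gauss–Hermite convolution) for raw data.

## Validation of the engine

Two independent routes compute the same physics: the Parratt ratio
recursion and an Abelès transfer-matrix product (`matrix_reflectivity()`),
the latter always on a finely sliced erf profile. The suite checks

* algebraic equivalence (identical slicing) to $10^{-12}$ relative,
* Névot–Croce vs sliced-profile agreement to 0.5% on seeded random stacks
  with $\sigma \le 2$ Å — the regime where the damping factor is an
  accurate rendering of Gaussian roughness (beyond this the engine slices
  anyway),
* exact Fresnel recovery for the bare interface, total external reflection
  below $q_c$, and the energy bound $R \le 1$.

# Fitting and uncertainties

The likelihood is Gaussian in **log-reflectivity**,
$\chi^2 = \sum_j [(\log R_{\rm model} - \log R_{\rm data})/\sigma_{\log}]^2$
with $\sigma_{\log} = dR/R$. A reflectivity curve spans roughly eight
decades; a linear-space likelihood would let the total-reflection plateau
dominate and ignore the high-$q$ fringes that carry the thickness
information, while log-space weights relative errors evenly — the natural
choice when the noise is multiplicative, which is how counting statistics
behave after footprint and background correction. The point estimate uses
box-constrained quasi-Newton (L-BFGS-B) followed by a Levenberg–Marquardt
polish; parameters landing on a bound are flagged, never silently clipped.

Posterior sampling uses the Goodman–Weare affine-invariant stretch move
(ensemble of $4\times$ the parameter count walkers, stretch scale $a=2$),
with flat priors inside the bounds. Defaults: 600 steps, first 25%
discarded as burn-in. Walkers are initialized from mildly overdispersed
Laplace (Gauss–Newton) scales at the least-squares optimum, so the
ensemble starts near the stationary distribution; with the tiny-ball
initialization common elsewhere, chains of this length visibly
underestimate interval widths. Everything is seeded: identical seeds give
bit-identical chains.

Reported uncertainties follow the asymmetric-interval convention: the 16th
and 84th posterior percentiles about the median, quoting the **larger** of
the two bounds as the conservative error. Derived quantities (areas,
excesses, ratios) get first-order error propagation for independent
variables, $\sigma_f^2 = \sum_i (\partial f/\partial x_i)^2 \sigma_i^2$,
with central finite differences (relative step $10^{-6}$). Treating fitted
$d$ and $\rho$ as independent underestimates the error of products like
$\rho d$ when the posterior correlates them (it usually anticorrelates
them); this is a known limitation of the convention, kept for
comparability, and the full chains are returned for anyone who wants
correlated propagation.

# Composition from electron balances

The film's composition follows from per-slab electron balances. With
$n_s$ molecules per Å² of species $s$, and $E_{s,i}$ electrons of the
species' fragment assigned to slab $i$,

$$\rho_i d_i = \sum_s n_s E_{s,i},$$

one equation per slab. For a single-surfactant monolayer this reduces to
closed forms: the tail slab contains only hydrophobic tails, so
$A_s = E_{\rm tail}/(\rho_1 d_1)$; the head slab holds one head fragment
per molecule plus $N_W$ waters of 10 electrons each, so
$N_W = (\rho_2 d_2 A_s - E_{\rm head})/10$. Surface excesses convert as
$\Gamma = M/(N_A A_s)$ (mg/m²) through one centralized conversion.
Electron counts are sums of atomic numbers of the neutral fragments — no
dispersion corrections, and no deprotonation (oleic acid is treated as
protonated, appropriate near pH 6).

Built-in species: oleic acid (C₁₈H₃₄O₂, M = 282.46, 158 e⁻ split 135 tail
/ 23 carboxyl head), water (10 e⁻), and polysorbate 80 with the average
monooleate formula C₆₄H₁₂₄O₂₆ consistent with the nominal average
molecular weight 1310 g/mol — 716 electrons (sum of atomic numbers),
split 135 (oleate tail) / 581 (sorbitan + polyoxyethylene head).

For mixed films the system is solved with a configurable **fragment
partition** across slabs. The default for polysorbate 80 places the tails
plus 25% of the head electrons in the air-proximal layer and the remaining
ethoxylate in the hydrated layer(s): the compact interfacial conformation
of ethoxylated sorbitan surfactants buries a significant portion of the
headgroup near the tails, but no measured fraction exists, so a quarter is
adopted as the documented default and exposed as configuration. Square
systems solve exactly; a negative solution triggers a
non-negativity-constrained refit with a warning rather than silent
clipping.

The **molar-volume balance** $A\,d_i = \sum_s$ (fragment volumes in slab
$i$) is implemented as a reported residual (`volume_balance_residual()`),
not a constraint: the electron balances alone determine the composition,
and the volume check flags physically overfilled or underfilled slabs.

# Tension isotherms

Equilibrium tension vs bulk concentration follows the Szyszkowski
equation, the equation of state conjugate to the Langmuir isotherm:

$$\gamma(c) = \gamma_0 - RT\,\Gamma_\infty \ln(1 + c/a),$$

with $\Gamma_\infty$ the maximum coverage (mol/m²) and $a$ the adsorption
constant (mol/L). Defaults: $\gamma_0 = 72.5$ mN/m (clean water) and
$T = 296.15$ K, both overridable. $\gamma_0$ is held fixed by default —
the clean-interface tension is measured independently to better precision
than the fit could give — with `fit_gamma0 = TRUE` available.

The cmc is located as the breakpoint of a continuous two-segment
piecewise-linear fit of $\gamma$ vs $\ln c$: a descending line meeting a
flat plateau (grid search plus local refinement of the breakpoint). This
makes the visual criterion "tension becomes independent of bulk
concentration" reproducible under noise. Two caveats are deliberate:

* a kink is only accepted as a plateau when the descending slope exceeds
  0.5 mN/m per e-fold (a genuine branch falls by $RT\Gamma_\infty$, several
  mN/m), so flat-only data report `cmc = NA` rather than a spurious
  breakpoint;
* because the sub-cmc branch is mildly curved in $\ln c$, the linear
  chord biases the noiseless breakpoint by about 1–2% — negligible
  against the noise-driven scatter, but the reason the estimator is
  tested at percent-level rather than machine tolerance.

$(\Gamma_\infty, a)$ are then fitted by weighted least squares of the
Szyszkowski law to the sub-cmc points, in log-parameters to keep both
positive. With fewer than five sub-plateau points the fit refuses rather
than returning an ill-determined pair; a practical isotherm design for
this estimator therefore needs a denser concentration ladder than the
five-point series typical of tensiometry campaigns — the recovery
studies in the test suite use 25 log-spaced concentrations over the same
0.0012–0.12 mM span.

Equilibrium tension from a pendant-drop relaxation trace is taken as the
mean of the final 10% of the time span (window configurable). The
synthetic relaxation trace is an acknowledged empirical stand-in
($\gamma_{\rm eq} + (\gamma_0-\gamma_{\rm eq})/(1+(t/\tau)^p)$) used only
to exercise that rule; no kinetic (Ward–Tordai) model is implied.

# The synthetic-data generator

`make_reflectivity()` emulates Fresnel-normalized beamline curves: the
exact forward model on 200 log-spaced points over
$0.016 \le Q_z \le 0.6$ Å⁻¹, with **multiplicative** Gaussian noise
(default 2% relative) and $dR = {\rm sd}\cdot R$. Multiplicative noise is
chosen over Poisson counts because normalized curves carry no count
scale; constant relative error is what remains after footprint and
background corrections. `make_isotherm_data()` applies additive Gaussian
noise (0.3 mN/m, typical pendant-drop scatter between repeat
measurements) to the Szyszkowski-plus-plateau model; its default
concentrations are the measured five-point ladder (0.0012, 0.012, 0.024,
0.06, 0.12 mM).

`make_scenario()` returns reference stacks with documented truth: the two
fitted oleic acid monolayer depositions (45.4 and 34.9 Å²/molecule), a
two-layer polysorbate 80 film at the cmc, and a three-slab mixed OA/PS80
film constructed *forward* from target surface excesses through the same
electron balances the solver inverts — so composition recovery is exact by
construction and any end-to-end error is attributable to the reflectivity
fit.

What the generator does **not** emulate: footprint and background
imperfections, resolution smearing, point-to-point correlated errors,
sample damage drifts, or subphase scattering. Passing recovery tests
therefore demonstrate the estimators are correct and calibrated under the
assumed noise model, not that real beamline systematics are harmless.

# Numerical choices

* Slicing: 0.25 Å slices, profile truncated at $6\sigma$ beyond the outer
  interfaces (erf tails $< 10^{-8}$ there). Finer slicing changes
  $R$ at $Q_z = 0.6$ Å⁻¹ by under 0.1% at 0.1 Å.
* $\sigma = 0$ is an exact sharp step (midpoint value at the interface
  itself), never a division by zero.
* The recursion is compiled (Rcpp); one two-slab forward model on 200
  points costs ~0.2 ms (damping path) / ~2.5 ms (sliced path).
* Problem sizes in the test suite are chosen for a laptop-scale run:
  20 replicate fits with 600-step chains for the coverage study, 100
  replicate isotherm refits, 50 random stacks for the engine
  cross-validation, 100-case composition fuzzing.
* Seeds: every stochastic routine takes an explicit seed and restores the
  caller's RNG state.

# Known limitations

* No absorption, no off-specular/diffuse scattering, no polarization, no
  multilayer Bragg optics: thin organic films on water only.
* The independence assumption in the propagated uncertainties
  (see above) understates errors of correlated parameter combinations.
* Electron-balance composition needs an assumed fragment partition for
  mixed films; the 25% head-electron default is a documented convention,
  not a measurement.
* The cmc breakpoint estimator assumes a single kink; strongly premicellar
  aggregation or impurity minima in $\gamma(\ln c)$ would mislead it.
* Slab number selection is the analyst's: the package fits a given stack
  and does not automate model comparison.
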