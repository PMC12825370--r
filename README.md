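# monofilm

Slab-model analysis of specular X-ray reflectivity (XRR) from surfactant
films at the air–water interface, with conversion of fitted electron-density
profiles into monolayer composition, and Langmuir/Szyszkowski analysis of
equilibrium surface tension. The package is aimed at interfacial
biophysicists and formulation scientists who fit reflectivity curves from
liquid-surface beamlines and want the downstream composition numbers — area
per molecule, surface excesses, hydration — with honest uncertainties.

## What it computes

**Electron-density profile.** The interface is modeled as N slabs between
air (ρ_N) and the aqueous subphase (ρ_0), each with thickness d_i, electron
density ρ_i, and interfacial roughness σ. The laterally averaged profile is
a sum of error functions,

    ρ(z) = ½ Σ_i erf((z − z_i)/(√2 σ_i)) (ρ_i − ρ_{i+1}) + (ρ_0 + ρ_N)/2,

which runs from ρ_N in air to ρ_0 deep in the water.

**Reflectivity.** R(Q_z) is computed by the Parratt recursion over the slab
stack with Névot–Croce roughness damping, falling back to fine slicing of
the smoothed profile when the roughness is large compared to the thinnest
slab. Q_z = (4π/λ) sin α; curves are normalized to the Fresnel reflectivity
R_F of the ideal sharp interface, with critical wave vector
q_c = 4√(π r_e Δρ) (≈ 0.0217 Å⁻¹ for water).

**Fitting.** Bounded least squares in log-reflectivity space, followed by
affine-invariant ensemble MCMC. Parameter uncertainties are the 84%
credible interval of the posterior: the (16th, 84th) percentiles about the
median, reporting the larger of the two asymmetric bounds.

**Composition.** Per-slab electron balances ρ_i·d_i = Σ_s n_s·E_{s,i}
convert fitted slabs into molecules per area n_s: area per molecule
A_s = n_tail-electrons/(ρd) from the tail slab, waters per headgroup
N_W = (ρdA_s − n_head)/10 from the hydrated slab, and surface excesses
Γ = M/(N_A A_s) in mg/m². A molar-volume balance is reported as a
consistency residual. Mixed films (e.g. oleic acid + polysorbate 80) are
solved as a linear system given a fragment partition across slabs.

**Tension isotherms.** Equilibrium tension vs bulk concentration is fitted
to the Szyszkowski equation γ = γ₀ − RTΓ_∞ ln(1 + c/a), conjugate to the
Langmuir isotherm; the critical micelle concentration (cmc) is located as
the breakpoint of a two-segment piecewise-linear fit of γ vs ln c.

A synthetic-data module generates reflectivity curves, tension isotherms,
and relaxation traces with known ground truth so every stage is testable
without beamline data.

## Worked example

The fitted two-slab model of an oleic acid monolayer deposited at
45.4 Å²/molecule (tail slab d = 10.63 Å, ρ = 0.312 e⁻/Å³; hydrated head
slab d = 5.025 Å, ρ = 0.350 e⁻/Å³; shared σ = 3.594 Å):

```r
library(monofilm)

m <- interface_model(list(slab(10.63, 0.312), slab(5.025, 0.350)),
                     shared_sigma = 3.594)
sp <- list(OA = builtin_species("OA"), water = builtin_species("water"))
partition <- rbind(OA = c(135, 23), water = c(0, 10))
mixed_layer_composition(m, sp, partition)
#> monolayer composition:
#>   Gamma_OA     =    1.152 mg/m^2  (n = 0.02457 /A^2)
#>   Gamma_water  =   0.3571 mg/m^2  (n = 0.1194 /A^2)
#>   A_s(OA) = 40.7 A^2/molecule, N_W = 4.859 waters/headgroup
#>   per-slab balance residuals: 0, 0
```

Each oleic acid molecule occupies 40.7 Å² (1.15 mg/m² surface excess) and
carries about 4.9 waters per carboxyl headgroup (0.36 mg/m² of interfacial
water). Fitting a synthetic curve from this model and sampling the
posterior:

```r
curve <- make_reflectivity(m, synthetic_spec(seed = 1, noise = 0.02))
spec  <- fit_spec(m, noise_rel = 0.02, seed = 1)
fit   <- fit_least_squares(curve, spec)
post  <- sample_posterior(curve, spec, fit)
post$summary   # median, err_lo, err_hi, err per parameter
```

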