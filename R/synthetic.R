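# Synthetic inputs with the statistical structure the analysis assumes:
# multiplicative Gaussian noise on reflectivity (normalized data carry no
# count scale), additive Gaussian noise on tension, everything seeded.

#' Specification for synthetic data generation
#'
#' @param seed Integer seed; every generator is deterministic given it.
#' @param qz Wave-vector grid in Å⁻¹. Default 200 log-spaced points across
#'   the measured range 0.016–0.6 Å⁻¹.
#' @param noise Relative (reflectivity) or absolute (tension, mN/m) Gaussian
#'   noise scale. Default 0.02.
#' @return Object of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(seed = 1L,
                           qz = 10^seq(log10(0.016), log10(0.6),
                                       length.out = 200),
                           noise = 0.02) {
  stopifnot(is.numeric(seed), length(seed) == 1, noise >= 0)
  if (any(qz <= 0) || any(diff(qz) <= 0))
    stop("qz grid must be positive and strictly increasing")
  structure(list(seed = as.integer(seed), qz = qz, noise = noise),
            class = "synthetic_spec")
}

#' Simulate a measured reflectivity curve
#'
#' Forward-models the stack with [parratt_reflectivity()] and applies
#' multiplicative Gaussian noise: `r = R(qz) * (1 + eps)`,
#' `eps ~ N(0, noise^2)`, with the uncertainty column `dr = noise * r`.
#' Deterministic per seed.
#'
#' @param model An [interface_model()].
#' @param spec A [synthetic_spec()].
#' @return An unnormalized [reflectivity_curve()] with `dr`.
#' @export
make_reflectivity <- function(model, spec = synthetic_spec()) {
  stopifnot(inherits(model, "interface_model"),
            inherits(spec, "synthetic_spec"))
  r0 <- parratt_reflectivity(model, spec$qz)$r
  r <- if (spec$noise > 0) {
    with_seed(spec$seed, r0 * (1 + rnorm(length(r0), 0, spec$noise)))
  } else r0
  r <- pmax(r, .Machine$double.xmin)  # noise cannot push R below zero
  reflectivity_curve(spec$qz, r, dr = spec$noise * r, normalized = FALSE)
}

#' Reference scenarios with documented ground truth
#'
#' Returns an interface model together with the composition that generated
#' it, enabling end-to-end recovery tests:
#'
#' * `"OA-monolayer"` — the two-slab oleic acid monolayer at 45.4
#'   Å²/molecule deposition: tail slab d = 10.63 Å, rho = 0.312 e⁻/Å³ over
#'   head slab d = 5.025 Å, rho = 0.350 e⁻/Å³, shared roughness 3.594 Å.
#' * `"OA-compressed"` — the same film compressed to 34.9 Å²/molecule:
#'   d = 11.64/6 Å, rho = 0.303/0.357 e⁻/Å³, roughness 3.758 Å.
#' * `"PS80-layer"` — two-layer polysorbate 80 adsorption layer at the cmc
#'   built from surface excesses Gamma_PS80 = 1.79, Gamma_W = 1.63 mg/m²:
#'   tails plus a quarter of the head electrons in the first layer, the
#'   remaining ethoxylate head in the hydrated second layer.
#' * `"mixed-3-slab"` — three-slab mixed OA/PS80 film built from
#'   Gamma_OA = 1.34, Gamma_PS80 = 1.09, Gamma_W = 1.51 mg/m²: OA tails
#'   (plus PS80 tails) on top, hydrated OA heads plus part of the PS80
#'   ethoxylate in the middle, the rest of the PS80 headgroup below.
#'
#' For the composition-built scenarios the slab densities follow from the
#' electron balances (the same equations [mixed_layer_composition()]
#' inverts), so composition recovery is exact by construction.
#'
#' @param tag Scenario name.
#' @return List with `model` ([interface_model()]), `truth` (named list of
#'   generating values), `species`, and `partition` (electrons species x
#'   slabs) where applicable.
#' @export
make_scenario <- function(tag = c("OA-monolayer", "OA-compressed",
                                  "PS80-layer", "mixed-3-slab")) {
  if (!is.character(tag) || length(tag) != 1 ||
      !tag %in% c("OA-monolayer", "OA-compressed", "PS80-layer",
                  "mixed-3-slab"))
    stop("unknown scenario tag; available: OA-monolayer, OA-compressed, ",
         "PS80-layer, mixed-3-slab")
  oa <- builtin_species("OA"); wa <- builtin_species("water")
  ps <- builtin_species("PS80")
  if (tag %in% c("OA-monolayer", "OA-compressed")) {
    p <- if (tag == "OA-monolayer")
      list(d1 = 10.63, rho1 = 0.312, d2 = 5.025, rho2 = 0.350, sigma = 3.594)
    else
      list(d1 = 11.64, rho1 = 0.303, d2 = 6, rho2 = 0.357, sigma = 3.758)
    model <- interface_model(list(slab(p$d1, p$rho1), slab(p$d2, p$rho2)),
                             shared_sigma = p$sigma)
    species <- list(OA = oa, water = wa)
    partition <- rbind(OA = c(oa$tail_electrons, oa$head_electrons),
                       water = c(0, wa$electrons))
    comp <- mixed_layer_composition(model, species, partition)
    return(list(model = model, truth = c(p, list(composition = comp)),
                species = species, partition = partition))
  }
  if (tag == "PS80-layer") {
    gamma <- c(PS80 = 1.79, water = 1.63)
    n <- c(gamma_to_number_density(gamma[["PS80"]], ps$molar_mass),
           gamma_to_number_density(gamma[["water"]], wa$molar_mass))
    # tails + 25% of head electrons in layer 1; water split as the head
    head_frac1 <- 0.25
    partition <- rbind(
      PS80 = c(ps$tail_electrons + head_frac1 * ps$head_electrons,
               (1 - head_frac1) * ps$head_electrons),
      water = c(head_frac1 * wa$electrons, (1 - head_frac1) * wa$electrons))
    d <- c(12, 22)
  } else {  # mixed-3-slab
    gamma <- c(OA = 1.34, PS80 = 1.09, water = 1.51)
    n <- c(gamma_to_number_density(gamma[["OA"]], oa$molar_mass),
           gamma_to_number_density(gamma[["PS80"]], ps$molar_mass),
           gamma_to_number_density(gamma[["water"]], wa$molar_mass))
    # OA tails + PS80 tails on top; OA heads + 25% PS80 head + water in the
    # middle; remaining PS80 head + water below
    partition <- rbind(
      OA = c(oa$tail_electrons, oa$head_electrons, 0),
      PS80 = c(ps$tail_electrons, 0.25 * ps$head_electrons,
               0.75 * ps$head_electrons),
      water = c(0, 0.3 * wa$electrons, 0.7 * wa$electrons))
    d <- c(14, 8, 17)
  }
  species <- switch(tag,
    "PS80-layer" = list(PS80 = ps, water = wa),
    "mixed-3-slab" = list(OA = oa, PS80 = ps, water = wa))
  names(n) <- names(species)
  # densities from the forward electron balances
  rho <- as.numeric(t(partition) %*% n) / d
  model <- interface_model(
    mapply(function(di, ri) slab(di, ri), d, rho, SIMPLIFY = FALSE),
    shared_sigma = 3.6)
  list(model = model,
       truth = list(gamma = gamma, n = n, d = d, rho = rho),
       species = species, partition = partition)
}

#' Simulate an equilibrium tension isotherm
#'
#' Tension follows [szyszkowski_tension()] below the cmc and stays flat at
#' the cmc value above it; additive Gaussian noise (default 0.3 mN/m) is
#' applied per point. The default concentration ladder is the measured one
#' (0.0012, 0.012, 0.024, 0.06, 0.12 mM); recovery simulations use a denser
#' log-spaced grid over the same span.
#'
#' @param truth List with `Gamma_inf` (mol/m²), `a` (mol/L), `cmc` (mM),
#'   and optionally `gamma0` (default 72.5) and `temperature` (default
#'   296.15 K). Defaults are the fitted polysorbate 80 values:
#'   `Gamma_inf = 1.94e-6` mol/m² (2.54 mg/m²), `a = 1.058e-7` mol/L,
#'   `cmc = 0.024` mM.
#' @param spec A [synthetic_spec()]; `spec$noise` is the tension noise in
#'   mN/m (use 0.3 for realistic pendant-drop scatter).
#' @param concentration Concentrations in mM. Default the measured ladder.
#' @return A [tension_isotherm()].
#' @export
make_isotherm_data <- function(truth = list(Gamma_inf = 1.94e-6,
                                            a = 1.058e-7, cmc = 0.024),
                               spec = synthetic_spec(noise = 0.3),
                               concentration = c(0.0012, 0.012, 0.024,
                                                 0.06, 0.12)) {
  stopifnot(is.list(truth), inherits(spec, "synthetic_spec"))
  gamma0 <- truth$gamma0 %||% 72.5
  temperature <- truth$temperature %||% 296.15
  stopifnot(truth$Gamma_inf > 0, truth$a > 0, truth$cmc > 0)
  c_eff <- pmin(concentration, truth$cmc) * 1e-3   # mM -> mol/L, clamped
  g <- szyszkowski_tension(c_eff, gamma0, truth$Gamma_inf, truth$a,
                           temperature)
  if (spec$noise > 0)
    g <- with_seed(spec$seed, g + rnorm(length(g), 0, spec$noise))
  tension_isotherm(concentration, g, sd = rep(max(spec$noise, 1e-6),
                                              length(g)),
                   gamma0 = gamma0, temperature = temperature)
}

#' Simulate a pendant-drop tension relaxation trace
#'
#' Empirical monotone relaxation
#' `gamma(t) = gamma_eq + (gamma0 - gamma_eq) / (1 + (t/tau)^p)` plus
#' additive noise — a stand-in used only to exercise the long-time plateau
#' extraction rule; no kinetic model is implied.
#'
#' @param gamma_eq Equilibrium tension in mN/m, `< gamma0`.
#' @param gamma0 Initial (clean-interface) tension in mN/m.
#' @param timescale Relaxation timescale tau in s.
#' @param spec A [synthetic_spec()]; `spec$noise` in mN/m.
#' @param t Times in s. Default 400 points over 1–10000 s (log-spaced).
#' @param p Shape exponent. Default 1.
#' @return Data frame with columns `t`, `gamma`.
#' @export
make_relaxation_trace <- function(gamma_eq, gamma0 = 72.5, timescale = 100,
                                  spec = synthetic_spec(noise = 0.1),
                                  t = 10^seq(0, 4, length.out = 400), p = 1) {
  stopifnot(gamma_eq < gamma0, timescale > 0, p > 0)
  g <- gamma_eq + (gamma0 - gamma_eq) / (1 + (t / timescale)^p)
  if (spec$noise > 0)
    g <- with_seed(spec$seed, g + rnorm(length(g), 0, spec$noise))
  data.frame(t = t, gamma = g)
}
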