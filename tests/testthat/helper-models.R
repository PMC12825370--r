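# Shared fixtures: the fitted two-slab oleic acid monolayer stacks and the
# polysorbate 80 isotherm parameters used across the suite.

oa_model <- function() {
  interface_model(list(slab(10.63, 0.312), slab(5.025, 0.350)),
                  shared_sigma = 3.594)
}

oa_truth <- c(d1 = 10.63, rho1 = 0.312, d2 = 5.025, rho2 = 0.350,
              sigma = 3.594)

oa_compressed_model <- function() {
  interface_model(list(slab(11.64, 0.303), slab(6, 0.357)),
                  shared_sigma = 3.758)
}

ps80_isotherm_truth <- list(Gamma_inf = 1.94e-6, a = 1.058e-7, cmc = 0.024)

# dense log-spaced concentration grid over the measured span (mM)
isotherm_grid <- function(n = 25) {
  10^seq(log10(0.0012), log10(0.12), length.out = n)
}

# random slab stack in the smooth-roughness regime where the damping-factor
# and slicing renderings of roughness agree closely
random_stack <- function(sigma_max = 2) {
  n <- sample(1:3, 1)
  d <- runif(n, 8, 30)
  rho <- runif(n, 0.20, 0.45)
  sig <- runif(1, 0.5, sigma_max)
  interface_model(mapply(slab, d, rho, SIMPLIFY = FALSE), shared_sigma = sig)
}

first_fringe_minimum <- function(model, qz = seq(0.05, 0.6, by = 5e-4)) {
  rr <- normalize_to_fresnel(parratt_reflectivity(model, qz), model)$r
  i <- which(diff(sign(diff(rr))) > 0) + 1   # local minima
  qz[i[1]]
}
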