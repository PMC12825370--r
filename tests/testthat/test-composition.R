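oa <- builtin_species("OA")
wa <- builtin_species("water")
ps <- builtin_species("PS80")

test_that("built-in species carry consistent electron bookkeeping", {
  expect_equal(oa$electrons, 158)                    # C18H34O2
  expect_equal(oa$tail_electrons + oa$head_electrons, oa$electrons)
  expect_equal(wa$electrons, 10)
  expect_equal(ps$electrons, 716)                    # C64H124O26
  expect_error(species_fragments("x", 100, 0, 0), "electrons")
})

test_that("tail-slab electron balance gives the printed areas per molecule", {
  expect_equal(area_per_molecule(slab(10.63, 0.312), 135), 40.70,
               tolerance = 0.01)
  expect_equal(area_per_molecule(slab(11.64, 0.303), 135), 38.19,
               tolerance = 0.01)
  # round trip: rho back from the area
  A <- area_per_molecule(slab(10.63, 0.312), 135)
  expect_equal(135 / (A * 10.63), 0.312, tolerance = 1e-12)
})

test_that("head-slab balance gives the printed hydration numbers", {
  A1 <- area_per_molecule(slab(10.63, 0.312), 135)
  expect_equal(waters_per_headgroup(slab(5.025, 0.350), A1, 23), 4.8,
               tolerance = 0.02)
  A2 <- area_per_molecule(slab(11.64, 0.303), 135)
  expect_equal(waters_per_headgroup(slab(6, 0.357), A2, 23), 5.8,
               tolerance = 0.02)
  # anhydrous head: electrons exactly account for the head fragment
  d <- 5; A <- 40
  rho <- 23 / (d * A)
  expect_equal(waters_per_headgroup(slab(d, rho), A, 23), 0)
  expect_error(waters_per_headgroup(slab(5, 0.01), 40, 23), "negative water")
})

test_that("surface excess conversion reproduces the printed Gamma values", {
  expect_equal(surface_excess(282.46, 40.70), 1.15, tolerance = 0.01)
  expect_equal(surface_excess(282.46, 40.70) * 2,
               surface_excess(282.46, 40.70 / 2), tolerance = 1e-12)
  # water excess from the hydration number
  A <- 40.70
  gw <- 4.8 * surface_excess(18.015, A)
  expect_equal(gw, 0.35, tolerance = 0.03)
})

test_that("excess-ratio identities reproduce the printed derived columns", {
  expect_equal(waters_from_excesses(1.63, 1.79, 1310), 66.20,
               tolerance = 0.005)
  expect_equal(waters_from_excesses(0, 1.5, 1310), 0)
  expect_equal(molar_surface_ratio(1.34, 1.09), 5.69, tolerance = 0.005)
  expect_equal(molar_surface_ratio(1.12, 1.20), 4.30, tolerance = 0.01)
  expect_equal(molar_surface_ratio(0, 1.2), 0)
  expect_error(molar_surface_ratio(1, 0), "gamma_2")
  # round trip through surface_excess
  A <- 52.3
  nw <- waters_from_excesses(3 * surface_excess(18.015, A),
                             surface_excess(282.46, A), 282.46)
  expect_equal(nw, 3, tolerance = 1e-12)
})

test_that("two-slab single-species solve reduces to the simple balances", {
  m <- oa_model()
  part <- rbind(OA = c(135, 23), water = c(0, 10))
  comp <- mixed_layer_composition(m, list(OA = oa, water = wa), part)
  expect_equal(comp$A_s, area_per_molecule(m$slabs[[1]], 135),
               tolerance = 1e-12)
  expect_equal(comp$N_W,
               waters_per_headgroup(m$slabs[[2]], comp$A_s, 23),
               tolerance = 1e-12)
  expect_equal(unname(comp$gamma["OA"]), surface_excess(282.46, comp$A_s),
               tolerance = 1e-12)
  # internal consistency of the returned composition
  expect_equal(comp$N_W,
               waters_from_excesses(comp$gamma[["water"]],
                                    comp$gamma[["OA"]], 282.46),
               tolerance = 1e-9)
})

test_that("forward-constructed mixed stack inverts exactly", {
  sc <- make_scenario("mixed-3-slab")
  comp <- mixed_layer_composition(sc$model, sc$species, sc$partition)
  expect_equal(unname(comp$gamma[c("OA", "PS80", "water")]),
               unname(sc$truth$gamma[c("OA", "PS80", "water")]),
               tolerance = 1e-6)
  expect_true(all(comp$residuals < 1e-9))
})

test_that("solver conditioning: 1 percent density perturbation moves total Gamma by under 3 percent", {
  sc <- make_scenario("mixed-3-slab")
  comp0 <- mixed_layer_composition(sc$model, sc$species, sc$partition)
  m <- sc$model
  m$slabs[[1]]$rho <- m$slabs[[1]]$rho * 1.01
  comp1 <- suppressWarnings(
    mixed_layer_composition(m, sc$species, sc$partition, tol = 1))
  rel <- abs(sum(comp1$gamma) - sum(comp0$gamma)) / sum(comp0$gamma)
  expect_lt(rel, 0.03)
})

test_that("degenerate partitions are rejected with informative errors", {
  m <- oa_model()
  bad <- rbind(OA = c(100, 23), water = c(0, 10))   # row sum wrong
  expect_error(mixed_layer_composition(m, list(OA = oa, water = wa), bad),
               "sum to the species")
  three <- rbind(OA = c(135, 23), PS80 = c(135, 581), water = c(0, 10))
  expect_error(
    mixed_layer_composition(m, list(OA = oa, PS80 = ps, water = wa), three),
    "underdetermined")
})

test_that("composition round trip survives seeded fuzzing", {
  withr::with_seed(2024, {
    for (i in 1:100) {
      n_true <- c(OA = runif(1, 0.01, 0.04), water = runif(1, 0.05, 0.6))
      part <- rbind(OA = c(135, 23), water = c(0, 10))
      d <- runif(2, 4, 16)
      rho <- as.numeric(t(part) %*% n_true) / d
      m <- interface_model(list(slab(d[1], rho[1]), slab(d[2], rho[2])),
                           shared_sigma = 3)
      comp <- mixed_layer_composition(m, list(OA = oa, water = wa), part)
      expect_equal(unname(comp$n), unname(n_true), tolerance = 1e-6)
    }
  })
})

test_that("unit identity Gamma * A_s * N_A = M on the chosen scales", {
  # Gamma [mg/m^2] * A_s [A^2] * N_A * 1e-23 = M [g/mol]
  A <- 40.70
  g <- surface_excess(282.46, A)
  expect_equal(g * A * 6.02214e23 * 1e-23, 282.46, tolerance = 1e-9)
})

test_that("hydration number increases with head-slab density", {
  A <- 40.7
  nw <- vapply(seq(0.33, 0.4, by = 0.01), function(r)
    waters_per_headgroup(slab(5.025, r), A, 23), numeric(1))
  expect_true(all(diff(nw) > 0))
})

test_that("volume balance residual is zero when volumes match and linear in thickness error", {
  sc <- make_scenario("mixed-3-slab")
  comp <- mixed_layer_composition(sc$model, sc$species, sc$partition)
  # construct volumes that exactly fill each slab
  n <- comp$n
  d <- vapply(sc$model$slabs, `[[`, numeric(1), "d")
  # distribute each slab volume over species proportionally to electron content
  vol <- sc$partition * 0
  for (i in seq_along(d)) {
    e_i <- sc$partition[, i] * n
    vol[, i] <- if (sum(e_i) > 0) e_i / sum(e_i) * d[i] / n else 0
    vol[n == 0, i] <- 0
  }
  res0 <- volume_balance_residual(comp, vol)
  expect_true(all(res0 < 1e-9))
  # perturb one thickness by epsilon: residual = epsilon to first order
  eps <- 0.02
  m2 <- sc$model; m2$slabs[[2]]$d <- m2$slabs[[2]]$d * (1 + eps)
  comp2 <- comp; comp2$model <- m2
  res2 <- volume_balance_residual(comp2, vol)
  expect_equal(res2[2], eps / (1 + eps), tolerance = 1e-6)
  expect_error(volume_balance_residual(comp, NULL), "volumes")
})

test_that("tail-only slab satisfies the volume balance by construction", {
  # tail volume per molecule = 135 e- / rho fills the tail slab exactly
  m <- oa_model()
  part <- rbind(OA = c(135, 23), water = c(0, 10))
  comp <- mixed_layer_composition(m, list(OA = oa, water = wa), part)
  v_tail <- 135 / 0.312
  vol <- rbind(OA = c(v_tail, 0), water = c(0, 0))
  res <- volume_balance_residual(comp, vol)
  expect_lt(res[1], 1e-9)
})

test_that("simple monolayer wrapper propagates slab uncertainties", {
  m <- oa_model()
  out <- monolayer_composition(m, errors = c(d1 = 0.0407, rho1 = 6.1e-5,
                                             d2 = 0.0519, rho2 = 3.3e-4))
  expect_equal(out$A_s$value, 40.70, tolerance = 0.01)
  expect_equal(out$gamma$value, 1.15, tolerance = 0.01)
  expect_equal(out$N_W$value, 4.8, tolerance = 0.02)
  expect_true(all(c(out$A_s$sd, out$gamma$sd, out$gamma_w$sd, out$N_W$sd) > 0))
})
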