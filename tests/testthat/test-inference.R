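test_that("fit_spec validates bounds, initial values and walker counts", {
  m <- oa_model()
  expect_error(fit_spec(m, free = "banana"), "unknown parameter")
  expect_error(fit_spec(m, lower = c(d1 = 20), upper = c(d1 = 10)),
               "lower < upper")
  expect_error(fit_spec(m, init = c(d1 = 1e4)), "within bounds")
  expect_error(fit_spec(m, n_walkers = 3), "walkers")
})

test_that("noiseless self-consistent fit recovers the generating parameters", {
  m <- oa_model()
  curve <- make_reflectivity(m, synthetic_spec(seed = 3, noise = 0))
  fit <- fit_least_squares(curve, fit_spec(m, seed = 3))
  expect_equal(unname(fit$par), unname(oa_truth), tolerance = 1e-6)
  expect_lt(fit$chisq, 1e-10)
})

test_that("fit recovers truth from initial values perturbed by 20 percent", {
  m <- oa_model()
  curve <- make_reflectivity(m, synthetic_spec(seed = 3, noise = 0))
  init <- oa_truth * c(1.2, 0.8, 0.8, 1.2, 0.8)
  fit <- fit_least_squares(curve, fit_spec(m, seed = 3, init = init))
  expect_lt(max(abs(fit$par - oa_truth) / oa_truth), 5e-3)
})

test_that("reduced chi-squared is near one under the generating noise model", {
  m <- oa_model()
  curve <- make_reflectivity(m, synthetic_spec(seed = 11, noise = 0.01))
  fit <- fit_least_squares(curve, fit_spec(m, noise_rel = 0.01))
  expect_gt(fit$chisq_red, 0.5)
  expect_lt(fit$chisq_red, 2)
})

test_that("insufficient data per parameter is rejected", {
  m <- oa_model()
  curve <- make_reflectivity(
    m, synthetic_spec(seed = 1, noise = 0,
                      qz = 10^seq(log10(0.016), log10(0.6), length.out = 10)))
  expect_error(fit_least_squares(curve, fit_spec(m)), "3 data points")
})

test_that("posterior sampling is seed-deterministic and summarizes the 84% interval", {
  m <- oa_model()
  curve <- make_reflectivity(m, synthetic_spec(seed = 21, noise = 0.02))
  spec <- fit_spec(m, noise_rel = 0.02, seed = 9, n_steps = 150)
  fit <- fit_least_squares(curve, spec)
  p1 <- sample_posterior(curve, spec, fit)
  p2 <- sample_posterior(curve, spec, fit)
  expect_identical(p1$chain, p2$chain)             # bit-identical given seed
  s <- p1$summary
  expect_equal(s$err, pmax(s$err_lo, s$err_hi))    # conservative bound
  expect_true(all(s$err_lo >= 0 & s$err_hi >= 0))
  expect_gt(p1$acceptance_fraction, 0.1)
  expect_lt(p1$acceptance_fraction, 0.7)
  # truth should sit within a few reported errors of the median
  expect_true(all(abs(s$median - oa_truth[s$parameter]) < 5 * s$err))
})

test_that("posterior interval width shrinks with the noise scale", {
  m <- oa_model()
  widths <- vapply(c(0.04, 0.005), function(ns) {
    curve <- make_reflectivity(m, synthetic_spec(seed = 33, noise = ns))
    spec <- fit_spec(m, noise_rel = ns, seed = 4, n_steps = 150)
    fit <- fit_least_squares(curve, spec)
    p <- sample_posterior(curve, spec, fit)
    p$summary$err[p$summary$parameter == "d1"]
  }, numeric(1))
  expect_lt(widths[2], widths[1])
})

test_that("error propagation handles degenerate and linear cases exactly", {
  expect_equal(propagate_independent(function(x) x[1]^2 + x[2], c(3, 4),
                                     c(0, 0))$sd, 0)
  expect_equal(propagate_independent(function(x) 3 * x[1], 5, 2)$sd, 6,
               tolerance = 1e-6)
})

test_that("error propagation matches a Monte-Carlo oracle for the area formula", {
  f <- function(x) 135 / (x[2] * x[1])    # A_s(d, rho)
  vals <- c(10.63, 0.312); sds <- c(0.0407, 6.1e-5)
  p <- propagate_independent(f, vals, sds)
  mc <- withr::with_seed(77, {
    draws <- cbind(rnorm(1e5, vals[1], sds[1]), rnorm(1e5, vals[2], sds[2]))
    sd(135 / (draws[, 2] * draws[, 1]))
  })
  expect_equal(p$sd, mc, tolerance = 0.02)
})

test_that("fit report round-trips through JSON", {
  m <- oa_model()
  curve <- make_reflectivity(m, synthetic_spec(seed = 3, noise = 0.02))
  spec <- fit_spec(m, seed = 2, n_steps = 60)
  fit <- fit_least_squares(curve, spec)
  path <- withr::local_tempfile(fileext = ".json")
  write_fit_report(fit, sample_posterior(curve, spec, fit), path)
  rep <- jsonlite::read_json(path)
  expect_equal(rep$parameters$d1, unname(fit$par["d1"]), tolerance = 1e-12)
  expect_equal(rep$seed, 2)
  expect_length(rep$posterior, 5)
})
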