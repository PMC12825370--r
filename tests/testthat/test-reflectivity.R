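test_that("qz-angle conversion matches the specular geometry and round-trips", {
  expect_equal(qz_from_alpha(0, 1.28), 0)
  expect_equal(qz_from_alpha(pi / 2, 1.28), 4 * pi / 1.28)
  a <- alpha_from_qz(0.6, 1.28)
  expect_equal(qz_from_alpha(a, 1.28), 0.6, tolerance = 1e-12)
  expect_error(qz_from_alpha(-0.1), "alpha")
  expect_error(alpha_from_qz(-0.1), "qz")
})

test_that("Fresnel reflectivity: total reflection, critical qz, asymptotic decay", {
  qc <- critical_qz(0.334, 0)
  expect_equal(qc, 4 * sqrt(pi * 2.8179403e-5 * 0.334), tolerance = 1e-12)
  expect_equal(qc, 0.02175, tolerance = 1e-3)
  expect_equal(fresnel_reflectivity(0.5 * qc), 1.0)
  q <- 20 * qc
  expect_equal(fresnel_reflectivity(q), (qc / (2 * q))^4, tolerance = 0.01)
})

test_that("empty stack reproduces the Fresnel curve exactly", {
  bare <- interface_model(shared_sigma = 0)
  qz <- seq(0.016, 0.6, length.out = 200)
  expect_equal(parratt_reflectivity(bare, qz)$r, fresnel_reflectivity(qz),
               tolerance = 1e-12)
})

test_that("a zero-contrast film is invisible", {
  qz <- seq(0.016, 0.6, length.out = 150)
  m <- interface_model(list(slab(10, 0.334, 0)), shared_sigma = 0)
  expect_equal(parratt_reflectivity(m, qz)$r, fresnel_reflectivity(qz),
               tolerance = 1e-9)
})

test_that("reflectivity respects the energy bound and total reflection below qc", {
  qz <- 10^seq(log10(0.005), log10(0.6), length.out = 300)
  withr::with_seed(101, {
    for (i in 1:10) {
      m <- random_stack(sigma_max = 3.5)
      r <- parratt_reflectivity(m, qz)$r
      expect_true(all(r >= 0 & r <= 1 + 1e-9))
    }
  })
  bare <- interface_model(shared_sigma = 0)
  qlow <- seq(0.002, 0.95 * critical_qz(), length.out = 50)
  expect_equal(parratt_reflectivity(bare, qlow)$r, rep(1, 50),
               tolerance = 1e-9)
})

test_that("Parratt recursion agrees with the transfer-matrix oracle", {
  qz <- 10^seq(log10(0.016), log10(0.6), length.out = 120)
  # identical slicing: the two algebraic routes must coincide to rounding
  m <- oa_model()
  r_rec <- parratt_reflectivity(m, qz, method = "slice", slice_dz = 0.2)$r
  r_mat <- matrix_reflectivity(m, qz, dz = 0.2)$r
  expect_equal(r_rec, r_mat, tolerance = 1e-12)
  # damping-factor rendering vs independently sliced profile, smooth regime
  withr::with_seed(42, {
    for (i in 1:10) {
      mi <- random_stack(sigma_max = 2)
      r1 <- parratt_reflectivity(mi, qz, method = "nevot-croce")$r
      r2 <- matrix_reflectivity(mi, qz, dz = 0.1)$r
      expect_lt(max(abs(r1 - r2) / pmax(r2, 1e-300)), 5e-3)
    }
  })
})

test_that("rough thin slabs trigger the slicing fallback", {
  # sigma = 3.594 exceeds half the 5.025 A head slab: auto must slice
  m <- oa_model()
  qz <- 10^seq(log10(0.016), log10(0.6), length.out = 80)
  r_auto <- parratt_reflectivity(m, qz)$r
  r_slice <- parratt_reflectivity(m, qz, method = "slice")$r
  r_nc <- parratt_reflectivity(m, qz, method = "nevot-croce")$r
  expect_equal(r_auto, r_slice, tolerance = 1e-14)
  expect_gt(max(abs(r_auto - r_nc) / r_auto), 1e-3)
})

test_that("Fresnel normalization is reciprocal and flattens the bare interface", {
  qz <- seq(0.016, 0.6, length.out = 150)
  bare <- interface_model(shared_sigma = 0)
  flat <- normalize_to_fresnel(parratt_reflectivity(bare, qz), bare)
  expect_equal(flat$r, rep(1, length(qz)), tolerance = 1e-9)
  m <- oa_model()
  rc <- parratt_reflectivity(m, qz)
  back <- denormalize_from_fresnel(normalize_to_fresnel(rc, m), m)
  expect_equal(back$r, rc$r, tolerance = 1e-12)
  expect_error(normalize_to_fresnel(normalize_to_fresnel(rc, m), m),
               "already")
  expect_error(denormalize_from_fresnel(rc, m), "not")
})

test_that("fringe spacing tracks total film thickness", {
  # at the full fitted roughness the damping envelope swallows the weak
  # minima of this low-contrast film, so probe the fringe geometry at a
  # moderate roughness where the minima are resolved
  mk <- function(d1) interface_model(list(slab(d1, 0.312),
                                          slab(5.025, 0.350)),
                                     shared_sigma = 1.5)
  q1 <- first_fringe_minimum(mk(10.63))
  # first Kiessig minimum sits near 2*pi/(d1+d2) = 0.401 1/A
  expect_lt(abs(q1 - 2 * pi / 15.655) / (2 * pi / 15.655), 0.25)
  # thicker films push the first minimum to smaller qz, strictly
  qmins <- vapply(c(10.63, 12.5, 14.5),
                  function(d1) first_fringe_minimum(mk(d1)), numeric(1))
  expect_true(all(diff(qmins) < 0))
})

test_that("resolution smearing leaves the curve close to unsmeared at small dq/q", {
  m <- oa_model()
  qz <- seq(0.05, 0.5, length.out = 60)
  r0 <- parratt_reflectivity(m, qz)$r
  r1 <- parratt_reflectivity(m, qz, dq_q = 0.001)$r
  r2 <- parratt_reflectivity(m, qz, dq_q = 0.05)$r
  expect_equal(r1, r0, tolerance = 1e-3)
  expect_gt(max(abs(r2 - r0) / r0), 0.01)  # visible at beamline-scale widths
})
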