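#' Wave-vector transfer from incidence angle
#'
#' Specular geometry: `Qz = (4*pi/lambda) * sin(alpha)`.
#'
#' @param alpha Incidence angle in radians, in `[0, pi/2]`.
#' @param wavelength X-ray wavelength in Å (1.28 Å for the beamline setup
#'   emulated here).
#' @return Wave-vector transfer in Å⁻¹.
#' @seealso [alpha_from_qz()] for the inverse.
#' @export
qz_from_alpha <- function(alpha, wavelength = 1.28) {
  stopifnot(is.numeric(alpha), is.numeric(wavelength))
  if (any(alpha < 0) || any(alpha > pi / 2))
    stop("alpha must lie in [0, pi/2] radians")
  if (wavelength <= 0) stop("wavelength must be > 0")
  (4 * pi / wavelength) * sin(alpha)
}

#' Incidence angle from wave-vector transfer
#'
#' @param qz Wave-vector transfer in Å⁻¹, `>= 0`.
#' @param wavelength X-ray wavelength in Å.
#' @return Incidence angle in radians.
#' @export
alpha_from_qz <- function(qz, wavelength = 1.28) {
  stopifnot(is.numeric(qz), is.numeric(wavelength))
  if (any(qz < 0)) stop("qz must be >= 0")
  if (wavelength <= 0) stop("wavelength must be > 0")
  x <- qz * wavelength / (4 * pi)
  if (any(x > 1)) stop("qz exceeds the back-reflection limit 4*pi/lambda")
  asin(x)
}

#' Critical wave vector of an interface
#'
#' `q_c = 4 * sqrt(pi * r_e * (rho_subphase - rho_air))`; total external
#' reflection occurs below it. For water against air (contrast 0.334 e⁻/Å³)
#' this is about 0.0217 Å⁻¹.
#'
#' @param rho_subphase,rho_air Electron densities in e⁻/Å³.
#' @return Critical wave vector in Å⁻¹.
#' @export
critical_qz <- function(rho_subphase = xrr_constants$rho_water, rho_air = 0) {
  if (rho_subphase <= rho_air) stop("rho_subphase must exceed rho_air")
  4 * sqrt(pi * xrr_constants$r_e * (rho_subphase - rho_air))
}

#' Fresnel reflectivity of the ideal sharp interface
#'
#' \deqn{R_F = \left|\frac{q - \sqrt{q^2 - q_c^2}}{q + \sqrt{q^2 -
#'   q_c^2}}\right|^2} with the evanescent branch below `q_c` giving total
#' external reflection, `R_F = 1`. Dividing a measured curve by `R_F`
#' removes the steep `q^-4` decay and highlights the film structure.
#'
#' @param qz Wave-vector transfer(s) in Å⁻¹, `> 0`.
#' @param rho_subphase,rho_air Electron densities in e⁻/Å³.
#' @return Reflectivity values in `[0, 1]`.
#' @examples
#' fresnel_reflectivity(0.01)   # below q_c: total reflection
#' fresnel_reflectivity(0.3)    # high-q tail ~ (q_c/2q)^4
#' @export
fresnel_reflectivity <- function(qz, rho_subphase = xrr_constants$rho_water,
                                 rho_air = 0) {
  stopifnot(is.numeric(qz))
  if (any(qz <= 0)) stop("qz must be > 0")
  qc <- critical_qz(rho_subphase, rho_air)
  kz <- qz / 2
  kt <- sqrt(as.complex(kz^2 - (qc / 2)^2))
  Mod((kz - kt) / (kz + kt))^2
}

# complex vertical wavevectors in every medium, matrix [length(qz) x nmedia]
layer_kz <- function(qz, rho_levels, rho_air) {
  fourpire <- 4 * pi * xrr_constants$r_e
  kz0sq <- (qz / 2)^2
  vapply(rho_levels, function(rho) {
    sqrt(as.complex(kz0sq - fourpire * (rho - rho_air)))
  }, complex(length(qz)))
}

#' Specular reflectivity of a slab stack (Parratt recursion)
#'
#' Computes `|r(qz)|^2` by the recursive Fresnel-coefficient (Parratt)
#' scheme for the stack of homogeneous slabs, with interfacial roughness
#' applied as Nevot-Croce damping of each interface coefficient. Absorption
#' is neglected (imaginary scattering density zero), appropriate for organic
#' films and water at hard-X-ray wavelengths.
#'
#' When the largest roughness exceeds half the thinnest slab the damping
#'-factor picture breaks down; `method = "auto"` (the default) then renders
#' the smoothed density profile of [build_edp()] into fine slices
#' (`slice_dz` Å) and runs the same recursion with sharp interfaces.
#'
#' @param model An [interface_model()].
#' @param qz Strictly positive wave-vector transfers in Å⁻¹.
#' @param method `"auto"`, `"nevot-croce"`, or `"slice"`.
#' @param slice_dz Slice thickness in Å for `"slice"` rendering.
#' @param nc_threshold Roughness/thickness ratio above which `"auto"` falls
#'   back to slicing: fallback when `max(sigma) > nc_threshold * min(d)`.
#' @param dq_q Optional relative Gaussian resolution width; `0` (default)
#'   applies no instrumental smearing. When positive, the curve is
#'   convolved with a Gaussian of sigma `dq_q * qz` by 7-point
#'   Gauss-Hermite quadrature.
#' @return A [reflectivity_curve()] (unnormalized).
#' @examples
#' m <- interface_model(list(slab(10.63, 0.312), slab(5.025, 0.350)),
#'                      shared_sigma = 3.594)
#' rc <- parratt_reflectivity(m, seq(0.016, 0.6, length.out = 100))
#' max(rc$r)  # <= 1: total external reflection plateau
#' @export
parratt_reflectivity <- function(model, qz,
                                 method = c("auto", "nevot-croce", "slice"),
                                 slice_dz = 0.25, nc_threshold = 0.5,
                                 dq_q = 0) {
  stopifnot(inherits(model, "interface_model"), is.numeric(qz))
  if (any(qz <= 0)) stop("qz must be > 0")
  if (dq_q < 0) stop("dq_q must be >= 0")
  method <- match.arg(method)
  if (method == "auto") {
    sig <- interface_sigmas(model)
    dmin <- if (length(model$slabs))
      min(vapply(model$slabs, `[[`, numeric(1), "d")) else Inf
    method <- if (max(sig) > nc_threshold * dmin) "slice" else "nevot-croce"
  }
  eval_r <- if (method == "slice" && length(model$slabs) > 0) {
    sliced <- slice_model(model, dz = slice_dz)
    function(q) parratt_recursion(sliced$d, sliced$rho,
                                  numeric(length(sliced$rho) + 1),
                                  model$rho_air, model$rho_subphase, q)
  } else {
    d <- vapply(model$slabs, `[[`, numeric(1), "d")
    rho <- vapply(model$slabs, `[[`, numeric(1), "rho")
    sig <- interface_sigmas(model)
    function(q) parratt_recursion(d, rho, sig, model$rho_air,
                                  model$rho_subphase, q)
  }
  r <- if (dq_q > 0) {
    # Gauss-Hermite nodes/weights, n = 7 (weights sum to sqrt(pi))
    gh_x <- c(-2.651961356835233, -1.673551628767471, -0.816287882858965,
              0, 0.816287882858965, 1.673551628767471, 2.651961356835233)
    gh_w <- c(0.0009717812450995, 0.05451558281913, 0.4256072526101,
              0.8102646175568, 0.4256072526101, 0.05451558281913,
              0.0009717812450995)
    acc <- 0
    for (i in seq_along(gh_x)) {
      qi <- pmax(qz * (1 + sqrt(2) * dq_q * gh_x[i]), 1e-8)
      acc <- acc + gh_w[i] * eval_r(qi)
    }
    acc / sqrt(pi)
  } else {
    eval_r(qz)
  }
  reflectivity_curve(qz, r, normalized = FALSE)
}

# Core recursion (compiled). d, rho: per-slab vectors (possibly empty);
# sigma: one per interface, air-side first (length length(d) + 1).
parratt_recursion <- function(d, rho, sigma, rho_air, rho_subphase, qz) {
  parratt_recursion_cpp(as.numeric(d), as.numeric(rho), as.numeric(sigma),
                        rho_air, rho_subphase, as.numeric(qz))
}

# Render the smoothed EDP into thin sharp slices (density evaluated at the
# slice midpoints) for the slicing fallback and the transfer-matrix oracle.
slice_model <- function(model, dz = 0.25, pad_sigma = 6) {
  zi <- interface_positions(model)
  sig <- interface_sigmas(model)
  span <- pad_sigma * max(sig, dz)
  edges <- seq(min(zi) - span, max(zi) + span, by = dz)
  zc <- edges[-length(edges)] + dz / 2
  rho_levels <- layer_densities(model)
  rho <- rep(model$rho_air, length(zc))
  for (j in seq_along(zi)) {
    drho <- rho_levels[j + 1] - rho_levels[j]
    step <- if (sig[j] > 0) {
      0.5 * (1 + erf((zc - zi[j]) / (sqrt(2) * sig[j])))
    } else {
      0.5 * (1 + sign(zc - zi[j]))
    }
    rho <- rho + drho * step
  }
  list(d = rep(dz, length(zc)), rho = rho)
}

#' Transfer-matrix (Abeles) reflectivity of a slab stack
#'
#' Independent route to the same physics as [parratt_reflectivity()]: the
#' smoothed density profile is rendered into fine sharp slices and the
#' reflected amplitude is obtained from the product of 2x2 characteristic
#' matrices rather than the Parratt ratio recursion. Used as a
#' cross-validation oracle in the test suite.
#'
#' @param model An [interface_model()].
#' @param qz Wave-vector transfers in Å⁻¹.
#' @param dz Slice thickness in Å.
#' @return A [reflectivity_curve()] (unnormalized).
#' @export
matrix_reflectivity <- function(model, qz, dz = 0.2) {
  stopifnot(inherits(model, "interface_model"), is.numeric(qz))
  if (any(qz <= 0)) stop("qz must be > 0")
  sliced <- slice_model(model, dz = dz)
  rho_levels <- c(model$rho_air, sliced$rho, model$rho_subphase)
  k <- layer_kz(qz, rho_levels, model$rho_air)
  nq <- length(qz)
  n_media <- length(rho_levels)
  # M = product over internal media of interface + propagation matrices,
  # amplitude formalism: at each interface j|j+1,
  #   I_j = (1/t) [[1, r], [r, 1]],  P_j = diag(e^{-i k d}, e^{i k d})
  m11 <- rep(complex(real = 1), nq); m12 <- complex(nq)
  m21 <- complex(nq);                m22 <- rep(complex(real = 1), nq)
  for (j in 1:(n_media - 1)) {
    kj <- k[, j]; kj1 <- k[, j + 1]
    r <- (kj - kj1) / (kj + kj1)
    t <- 2 * kj / (kj + kj1)
    i11 <- 1 / t; i12 <- r / t; i21 <- r / t; i22 <- 1 / t
    a11 <- m11 * i11 + m12 * i21; a12 <- m11 * i12 + m12 * i22
    a21 <- m21 * i11 + m22 * i21; a22 <- m21 * i12 + m22 * i22
    if (j < n_media - 1) {
      ph <- exp(1i * kj1 * sliced$d[j])
      a11 <- a11 / ph; a12 <- a12 * ph
      a21 <- a21 / ph; a22 <- a22 * ph
    }
    m11 <- a11; m12 <- a12; m21 <- a21; m22 <- a22
  }
  reflectivity_curve(qz, Mod(m21 / m11)^2, normalized = FALSE)
}

#' Construct a reflectivity curve
#'
#' @param qz Strictly increasing wave-vector transfers in Å⁻¹, `> 0`.
#' @param r Reflectivity values, `>= 0`.
#' @param dr Optional 1-sigma uncertainties, `>= 0`.
#' @param normalized Logical: is `r` already divided by the Fresnel
#'   reflectivity?
#' @return An object of class `"reflectivity_curve"`.
#' @export
reflectivity_curve <- function(qz, r, dr = NULL, normalized = FALSE) {
  stopifnot(is.numeric(qz), is.numeric(r), length(qz) == length(r))
  if (any(qz <= 0)) stop("qz must be > 0")
  if (any(diff(qz) <= 0)) stop("qz must be strictly increasing")
  if (any(r < 0)) stop("reflectivity must be >= 0")
  if (!is.null(dr)) {
    stopifnot(length(dr) == length(r))
    if (any(dr < 0)) stop("dr must be >= 0")
  }
  structure(list(qz = qz, r = r, dr = dr, normalized = isTRUE(normalized)),
            class = "reflectivity_curve")
}

#' @export
print.reflectivity_curve <- function(x, ...) {
  cat(sprintf("reflectivity curve: %d points, qz in [%.4g, %.4g] 1/A%s%s\n",
              length(x$qz), min(x$qz), max(x$qz),
              if (x$normalized) ", Fresnel-normalized (R/RF)" else "",
              if (!is.null(x$dr)) ", with uncertainties" else ""))
  invisible(x)
}

#' Normalize a reflectivity curve to the Fresnel reflectivity
#'
#' Divides `r` (and `dr`) pointwise by `R_F(qz)` of the bare
#' air/subphase interface of `model`, flagging the curve as normalized.
#' A bare-interface curve becomes flat 1 at all `qz`; film structure shows
#' as Kiessig fringes about 1.
#'
#' @param curve An unnormalized [reflectivity_curve()].
#' @param model The [interface_model()] supplying the ambient densities.
#' @return A normalized `"reflectivity_curve"`.
#' @export
normalize_to_fresnel <- function(curve, model) {
  stopifnot(inherits(curve, "reflectivity_curve"),
            inherits(model, "interface_model"))
  if (curve$normalized) stop("curve is already Fresnel-normalized")
  rf <- fresnel_reflectivity(curve$qz, model$rho_subphase, model$rho_air)
  reflectivity_curve(curve$qz, curve$r / rf,
                     dr = if (!is.null(curve$dr)) curve$dr / rf,
                     normalized = TRUE)
}

#' Undo Fresnel normalization
#'
#' Inverse of [normalize_to_fresnel()]; restores the unnormalized curve.
#'
#' @inheritParams normalize_to_fresnel
#' @return An unnormalized `"reflectivity_curve"`.
#' @export
denormalize_from_fresnel <- function(curve, model) {
  stopifnot(inherits(curve, "reflectivity_curve"),
            inherits(model, "interface_model"))
  if (!curve$normalized) stop("curve is not Fresnel-normalized")
  rf <- fresnel_reflectivity(curve$qz, model$rho_subphase, model$rho_air)
  reflectivity_curve(curve$qz, curve$r * rf,
                     dr = if (!is.null(curve$dr)) curve$dr * rf,
                     normalized = FALSE)
}
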