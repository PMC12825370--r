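# Langmuir/Szyszkowski analysis of equilibrium surface tension vs bulk
# concentration, and cmc location as the plateau breakpoint in gamma vs ln c.

#' Szyszkowski surface tension law
#'
#' The equation of state conjugate to the Langmuir adsorption isotherm:
#' \deqn{\gamma(c) = \gamma_0 - R T \Gamma_\infty \ln(1 + c/a),}
#' with `Gamma_inf` the maximum surface coverage (mol/m²) and `a` the
#' adsorption constant (mol/L). At `c >> a` the tension falls by
#' `R*T*Gamma_inf` per e-fold of concentration (the Gibbs-isotherm slope).
#'
#' @param c Bulk concentration in mol/L (may be a vector), `>= 0`.
#' @param gamma0 Clean-interface tension in mN/m (72.5 for water at room
#'   temperature).
#' @param Gamma_inf Maximum surface coverage in mol/m².
#' @param a Adsorption constant in mol/L.
#' @param temperature Temperature in K. Default 296.15 (23 °C).
#' @return Surface tension in mN/m.
#' @examples
#' szyszkowski_tension(1.058e-7, 72.5, 1.94e-6, 1.058e-7)  # gamma0 - RT*G*ln 2
#' @export
szyszkowski_tension <- function(c, gamma0 = 72.5, Gamma_inf, a,
                                temperature = 296.15) {
  stopifnot(is.numeric(c), gamma0 > 0, Gamma_inf > 0, a > 0, temperature > 0)
  if (any(c < 0)) stop("concentration must be >= 0")
  # R*T*Gamma_inf: J/m^2 = N/m -> mN/m
  gamma0 - 1e3 * xrr_constants$R_gas * temperature * Gamma_inf * log1p(c / a)
}

#' Langmuir fractional coverage
#'
#' `theta = c / (a + c)`.
#'
#' @inheritParams szyszkowski_tension
#' @return Coverage in `[0, 1)`.
#' @export
langmuir_coverage <- function(c, a) {
  stopifnot(a > 0)
  if (any(c < 0)) stop("concentration must be >= 0")
  c / (a + c)
}

#' Surface pressure
#'
#' `Pi = gamma0 - gamma`, the tension reduction relative to the clean
#' interface.
#'
#' @param gamma Measured tension in mN/m.
#' @param gamma0 Clean-interface tension in mN/m.
#' @return Surface pressure in mN/m.
#' @export
surface_pressure <- function(gamma, gamma0 = 72.5) {
  gamma0 - gamma
}

#' Construct a tension isotherm
#'
#' @param concentration Bulk concentrations in mM, `> 0`.
#' @param gamma Equilibrium tensions in mN/m.
#' @param sd Optional 1-sigma uncertainties in mN/m.
#' @param gamma0 Clean-interface tension in mN/m. Default 72.5.
#' @param temperature Temperature in K. Default 296.15.
#' @return Object of class `"tension_isotherm"`.
#' @export
tension_isotherm <- function(concentration, gamma, sd = NULL, gamma0 = 72.5,
                             temperature = 296.15) {
  stopifnot(is.numeric(concentration), is.numeric(gamma),
            length(concentration) == length(gamma))
  if (any(concentration <= 0)) stop("concentrations must be > 0")
  if (is.null(sd)) sd <- rep(0.3, length(gamma))
  stopifnot(length(sd) == length(gamma), all(sd >= 0))
  if (any(gamma > gamma0 + 3 * pmax(sd, 0.1)))
    stop("tension above the clean-interface baseline gamma0")
  o <- order(concentration)
  structure(list(concentration = concentration[o], gamma = gamma[o],
                 sd = sd[o], gamma0 = gamma0, temperature = temperature),
            class = "tension_isotherm")
}

#' @export
print.tension_isotherm <- function(x, ...) {
  cat(sprintf("tension isotherm: %d points, c in [%.4g, %.4g] mM, gamma in [%.4g, %.4g] mN/m\n",
              length(x$concentration), min(x$concentration),
              max(x$concentration), min(x$gamma), max(x$gamma)))
  invisible(x)
}

# Two-segment continuous piecewise-linear fit of gamma vs ln c:
# descending line for x < xb meeting a flat plateau for x >= xb.
# Returns breakpoint (ln c), plateau level, slope, and SSE.
breakpoint_fit <- function(x, y, w = NULL) {
  if (is.null(w)) w <- rep(1, length(y))
  sse_at <- function(xb) {
    z <- pmin(x - xb, 0)
    fit <- lm.wfit(cbind(1, z), y, w)
    sum(w * fit$residuals^2)
  }
  # coarse grid between interior points, then local refinement
  grid <- seq(min(x), max(x), length.out = 201)
  sses <- vapply(grid, sse_at, numeric(1))
  i <- which.min(sses)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- optimize(sse_at, c(lo, hi), tol = 1e-10)
  xb <- opt$minimum
  z <- pmin(x - xb, 0)
  fit <- lm.wfit(cbind(1, z), y, w)
  list(breakpoint = xb, plateau = fit$coefficients[1],
       slope = fit$coefficients[2], sse = opt$objective)
}

#' Fit a tension isotherm to the Langmuir/Szyszkowski model
#'
#' Two-stage analysis of equilibrium tension vs bulk concentration:
#'
#' 1. The cmc is located as the breakpoint of a continuous two-segment
#'    piecewise-linear fit of `gamma` vs `ln c` — a descending line meeting
#'    a flat plateau. This makes the visual criterion "tension becomes
#'    independent of bulk concentration" reproducible under noise.
#' 2. `(Gamma_inf, a)` are fitted by weighted least squares of the
#'    Szyszkowski law to the sub-cmc points (concentrations at or below the
#'    breakpoint).
#'
#' If no plateau is detected (the plateau would hold fewer than 2 points,
#' or the fitted descending slope is not negative), the cmc is reported as
#' `NA` and the Szyszkowski fit uses all points.
#'
#' @param iso A [tension_isotherm()].
#' @param fit_gamma0 Logical: treat the clean-interface tension as a third
#'   free parameter? Default `FALSE` (fixed at `iso$gamma0`).
#' @return Object of class `"isotherm_fit"`: `Gamma_inf` (mol/m²),
#'   `Gamma_inf_mg` (mg/m², using `molar_mass`), `a` (mol/L), `cmc` (mM or
#'   `NA`), each with `sd` where available, plus the plateau level and
#'   per-parameter standard errors from the weighted fit.
#' @param molar_mass Molar mass (g/mol) used to express the coverage in
#'   mg/m². Default 1310 (polysorbate 80).
#' @examples
#' truth <- list(Gamma_inf = 1.94e-6, a = 1.058e-7, cmc = 0.024)
#' iso <- make_isotherm_data(truth, synthetic_spec(seed = 7, noise = 0),
#'                           concentration = 10^seq(log10(0.0012), log10(0.12),
#'                                                  length.out = 25))
#' fit_isotherm(iso)
#' @export
fit_isotherm <- function(iso, fit_gamma0 = FALSE, molar_mass = 1310) {
  stopifnot(inherits(iso, "tension_isotherm"))
  x <- log(iso$concentration)   # ln(c/mM); shift-invariant for the breakpoint
  y <- iso$gamma
  w <- if (all(iso$sd > 0)) 1 / iso$sd^2 else rep(1, length(y))
  bp <- breakpoint_fit(x, y, w)
  n_plateau <- sum(x >= bp$breakpoint - 1e-12)
  cmc <- exp(bp$breakpoint)
  # a genuine descending branch falls by ~RT*Gamma_inf per e-fold (several
  # mN/m); require at least 0.5 mN/m per e-fold to call the kink a plateau
  plateau_ok <- n_plateau >= 2 && is.finite(bp$slope) && bp$slope < -0.5 &&
    cmc <= max(iso$concentration) && cmc >= min(iso$concentration)
  if (!plateau_ok) cmc <- NA_real_
  sub <- if (plateau_ok) iso$concentration <= cmc * (1 + 1e-9) else
    rep(TRUE, length(x))
  if (sum(sub) < 5)
    stop("need at least 5 points below the plateau to fit the isotherm")
  c_mol <- iso$concentration[sub] * 1e-3   # mM -> mol/L
  ysub <- y[sub]; wsub <- w[sub]
  RT <- 1e3 * xrr_constants$R_gas * iso$temperature
  # start values: slope of gamma vs ln c gives RT*Gamma_inf; a from intercept
  slope0 <- abs(coef(lm(ysub ~ log(c_mol), weights = wsub))[2])
  G0 <- max(slope0 / RT, 1e-8)
  a0 <- max(min(c_mol) / 10, 1e-10)
  par0 <- c(log(G0), log(a0))
  if (fit_gamma0) par0 <- c(par0, iso$gamma0)
  resid_fun <- function(p) {
    g0 <- if (fit_gamma0) p[3] else iso$gamma0
    # log-parameterization keeps positivity; clamp against over/underflow
    G <- exp(min(max(p[1], -46), 5))
    a <- exp(min(max(p[2], -46), 5))
    model <- szyszkowski_tension(c_mol, g0, G, a, iso$temperature)
    sqrt(wsub) * (model - ysub)
  }
  ls <- minpack.lm::nls.lm(par0, fn = resid_fun,
                           control = minpack.lm::nls.lm.control(maxiter = 500))
  Gamma_inf <- exp(min(max(ls$par[1], -46), 5))
  a <- exp(min(max(ls$par[2], -46), 5))
  gamma0_fit <- if (fit_gamma0) ls$par[3] else iso$gamma0
  # standard errors in log-parameters -> delta method
  vc <- tryCatch(vcov_from_nlslm(ls), error = function(e) NULL)
  sd_G <- sd_a <- NA_real_
  if (!is.null(vc)) {
    sd_G <- Gamma_inf * sqrt(vc[1, 1])
    sd_a <- a * sqrt(vc[2, 2])
  }
  structure(list(
    Gamma_inf = Gamma_inf, Gamma_inf_sd = sd_G,
    Gamma_inf_mg = Gamma_inf * molar_mass * 1e3,
    a = a, a_sd = sd_a,
    cmc = cmc, plateau = unname(bp$plateau), gamma0 = gamma0_fit,
    temperature = iso$temperature, n_sub_cmc = sum(sub),
    chisq = sum(resid_fun(ls$par)^2), converged = ls$info %in% 1:4
  ), class = "isotherm_fit")
}

vcov_from_nlslm <- function(ls) {
  # covariance of the log-parameters from the Jacobian at the optimum
  h <- ls$hessian
  if (is.null(h)) stop("no hessian")
  n <- length(ls$fvec); p <- length(ls$par)
  s2 <- sum(ls$fvec^2) / max(n - p, 1)
  solve(h) * 2 * s2
}

#' @export
print.isotherm_fit <- function(x, ...) {
  cat(sprintf("Langmuir/Szyszkowski fit (T = %.4g K, gamma0 = %.4g mN/m):\n",
              x$temperature, x$gamma0))
  cat(sprintf("  Gamma_inf = %.4g mol/m^2 (%.3g mg/m^2)\n",
              x$Gamma_inf, x$Gamma_inf_mg))
  cat(sprintf("  a         = %.4g mol/L\n", x$a))
  if (is.na(x$cmc)) cat("  cmc       : not determined (no plateau)\n")
  else cat(sprintf("  cmc       = %.4g mM (plateau %.4g mN/m)\n",
                   x$cmc, x$plateau))
  invisible(x)
}

#' Equilibrium tension from a relaxation trace
#'
#' The equilibrium tension of a pendant-drop relaxation experiment is taken
#' as the mean of the final fraction of the trace (the long-time plateau).
#'
#' @param t Times in s (increasing).
#' @param gamma Tensions in mN/m.
#' @param window Final fraction of the time span to average. Default 0.1.
#' @return Equilibrium tension in mN/m.
#' @export
equilibrium_tension <- function(t, gamma, window = 0.1) {
  stopifnot(is.numeric(t), is.numeric(gamma), length(t) == length(gamma),
            window > 0, window <= 1)
  if (any(diff(t) <= 0)) stop("t must be strictly increasing")
  cutoff <- max(t) - window * (max(t) - min(t))
  mean(gamma[t >= cutoff])
}
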