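# Parameter vectors are mapped onto an interface model by name:
# "d1","rho1","sigma1",... plus optionally "rho_subphase". With a shared
# roughness the single name "sigma" is used for every interface.

#' Specify a reflectivity fit
#'
#' Names, bounds, and initial values of the free parameters of an
#' [interface_model()], plus the noise model and sampler settings. Parameter
#' names follow `d<i>`, `rho<i>` for slab `i` (air side first), `sigma` for
#' a roughness shared by every interface (the default, one roughness per
#' sample), `sigma<i>` for per-interface roughness, and optionally
#' `rho_subphase`.
#'
#' @param model Template [interface_model()] supplying fixed values and the
#'   stack geometry.
#' @param free Character vector of free parameter names.
#' @param lower,upper Named numeric vectors of bounds (finite, lower <
#'   upper). Defaults: d in (0.5, 60) Å, rho in (0, 0.7) e⁻/Å³, sigma in
#'   (0, 10) Å.
#' @param init Named numeric vector of initial values; defaults to the
#'   template model's values.
#' @param noise_rel Relative Gaussian noise scale used when the curve
#'   carries no `dr` column. Default 0.02.
#' @param seed Integer seed for the sampler.
#' @param n_walkers Ensemble walkers; default `4 *` number of free
#'   parameters.
#' @param n_steps Sampler steps per walker. Default 600.
#' @param burn_frac Fraction of each chain discarded as burn-in. Default
#'   0.25.
#' @return An object of class `"fit_spec"`.
#' @export
fit_spec <- function(model, free = NULL, lower = NULL, upper = NULL,
                     init = NULL, noise_rel = 0.02, seed = 1L,
                     n_walkers = NULL, n_steps = 600L, burn_frac = 0.25) {
  stopifnot(inherits(model, "interface_model"))
  nsl <- length(model$slabs)
  if (is.null(free)) {
    free <- c(rbind(paste0("d", seq_len(nsl)), paste0("rho", seq_len(nsl))))
    free <- c(free, "sigma")
  }
  defaults <- model_param_values(model)
  bad <- setdiff(free, names(defaults))
  if (length(bad)) stop("unknown parameter name(s): ", paste(bad, collapse = ", "))
  lo <- default_lower(free); hi <- default_upper(free)
  if (!is.null(lower)) lo[names(lower)] <- lower
  if (!is.null(upper)) hi[names(upper)] <- upper
  ini <- defaults[free]
  if (!is.null(init)) ini[names(init)] <- init
  if (any(!is.finite(lo)) || any(!is.finite(hi)) || any(lo >= hi))
    stop("bounds must be finite with lower < upper")
  if (any(ini < lo) || any(ini > hi))
    stop("initial values must lie within bounds")
  if (is.null(n_walkers)) n_walkers <- 4L * length(free)
  if (n_walkers < 2L * length(free))
    stop("need at least 2 walkers per free parameter")
  if (n_steps < 4L) stop("n_steps too small")
  structure(list(model = model, free = free, lower = lo, upper = hi,
                 init = ini, noise_rel = noise_rel, seed = as.integer(seed),
                 n_walkers = as.integer(n_walkers),
                 n_steps = as.integer(n_steps), burn_frac = burn_frac),
            class = "fit_spec")
}

model_param_values <- function(model) {
  nsl <- length(model$slabs)
  v <- c()
  for (i in seq_len(nsl)) {
    s <- model$slabs[[i]]
    v[paste0("d", i)] <- s$d
    v[paste0("rho", i)] <- s$rho
    v[paste0("sigma", i)] <- s$sigma
  }
  v["sigma"] <- if (!is.null(model$shared_sigma)) model$shared_sigma
                else if (nsl) model$slabs[[1]]$sigma else model$sigma_air
  v["rho_subphase"] <- model$rho_subphase
  v
}

default_lower <- function(free) {
  lo <- numeric(length(free)); names(lo) <- free
  lo[grepl("^d[0-9]+$", free)] <- 0.5
  lo[grepl("^rho", free)] <- 1e-6
  lo[grepl("^sigma", free)] <- 1e-3
  lo
}

default_upper <- function(free) {
  hi <- numeric(length(free)); names(hi) <- free
  hi[grepl("^d[0-9]+$", free)] <- 60
  hi[grepl("^rho", free)] <- 0.7
  hi[grepl("^sigma", free)] <- 10
  hi
}

# Apply a named parameter vector to the template model.
apply_params <- function(model, par) {
  nm <- names(par)
  for (i in seq_along(model$slabs)) {
    di <- paste0("d", i); ri <- paste0("rho", i); si <- paste0("sigma", i)
    if (di %in% nm) model$slabs[[i]]$d <- unname(par[di])
    if (ri %in% nm) model$slabs[[i]]$rho <- unname(par[ri])
    if (si %in% nm) model$slabs[[i]]$sigma <- unname(par[si])
  }
  if ("sigma" %in% nm) {
    model$shared_sigma <- unname(par["sigma"])
    model$slabs <- lapply(model$slabs, function(s) {
      s$sigma <- unname(par["sigma"]); s
    })
    model$sigma_air <- unname(par["sigma"])
  }
  if ("rho_subphase" %in% nm) model$rho_subphase <- unname(par["rho_subphase"])
  model
}

# Residuals in log-reflectivity space; sigma_log = dr/r (or the relative
# noise scale), so multiplicative noise has unit-variance residuals.
log_residuals <- function(par, curve, spec) {
  if (is.null(names(par))) names(par) <- spec$free
  m <- apply_params(spec$model, par)
  rm <- parratt_reflectivity(m, curve$qz)$r
  sig <- if (!is.null(curve$dr)) curve$dr / curve$r
         else rep(spec$noise_rel, length(curve$r))
  sig[!is.finite(sig) | sig <= 0] <- max(spec$noise_rel, 1e-12)
  (log(rm) - log(curve$r)) / sig
}

#' Bounded least-squares fit of a slab model to a reflectivity curve
#'
#' Minimizes the sum of squared residuals in log-reflectivity space,
#' `sum(((log R_model - log R_data)/sigma_log)^2)`, by
#' Levenberg-Marquardt with box bounds ([minpack.lm::nls.lm]). The
#' log-space likelihood weights the eight-decade dynamic range of a
#' reflectivity curve evenly across fringes.
#'
#' @param curve An unnormalized [reflectivity_curve()] with at least three
#'   points per free parameter.
#' @param spec A [fit_spec()].
#' @return A list of class `"xrr_fit"`: `model` (fitted
#'   [interface_model()]), `par` (named vector), `chisq`, `dof`,
#'   `chisq_red`, `converged`, `at_bounds` (names of parameters within
#'   1e-6 of a bound), and `message`.
#' @export
fit_least_squares <- function(curve, spec) {
  stopifnot(inherits(curve, "reflectivity_curve"), inherits(spec, "fit_spec"))
  if (curve$normalized)
    stop("fit operates on unnormalized reflectivity; denormalize first")
  npar <- length(spec$free)
  if (length(curve$qz) < 3 * npar)
    stop("need at least 3 data points per free parameter")
  # box-constrained quasi-Newton first (robust to distant starts), then
  # Levenberg-Marquardt polish to the precision of the optimum
  pre <- optim(spec$init,
               function(p) sum(log_residuals(p, curve, spec)^2),
               method = "L-BFGS-B", lower = spec$lower, upper = spec$upper,
               control = list(maxit = 500))
  res <- minpack.lm::nls.lm(
    par = pre$par, lower = spec$lower, upper = spec$upper,
    fn = function(p) log_residuals(p, curve, spec),
    control = minpack.lm::nls.lm.control(maxiter = 500)
  )
  par <- unlist(res$par)
  names(par) <- spec$free
  chisq <- sum(log_residuals(par, curve, spec)^2)
  dof <- length(curve$qz) - npar
  converged <- res$info %in% 1:4
  span <- spec$upper - spec$lower
  at_bounds <- spec$free[par - spec$lower < 1e-6 * span |
                         spec$upper - par < 1e-6 * span]
  if (!converged)
    warning("least-squares fit did not converge: ", res$message)
  if (length(at_bounds))
    warning("parameter(s) at bounds: ", paste(at_bounds, collapse = ", "))
  # Laplace (Gauss-Newton) parameter scales at the optimum; used to
  # initialize the posterior sampler's walker ensemble
  par_scale <- tryCatch(sqrt(diag(solve(res$hessian))),
                        error = function(e) rep(NA_real_, npar))
  structure(list(model = apply_params(spec$model, par), par = par,
                 chisq = chisq, dof = dof, chisq_red = chisq / dof,
                 converged = converged, at_bounds = at_bounds,
                 par_scale = setNames(par_scale, spec$free),
                 message = res$message, spec = spec),
            class = "xrr_fit")
}

#' @export
print.xrr_fit <- function(x, ...) {
  cat(sprintf("slab-model fit: chi^2 = %.4g (reduced %.3g), %s\n",
              x$chisq, x$chisq_red,
              if (x$converged) "converged" else "NOT converged"))
  print(round(x$par, 5))
  invisible(x)
}

# log-posterior: flat priors inside the box, Gaussian likelihood in log R
log_posterior <- function(par, curve, spec) {
  if (any(par < spec$lower) || any(par > spec$upper)) return(-Inf)
  -0.5 * sum(log_residuals(par, curve, spec)^2)
}

#' Sample the posterior of a slab-model fit by ensemble MCMC
#'
#' Affine-invariant stretch-move ensemble sampler (Goodman & Weare) over the
#' same log-reflectivity Gaussian likelihood as [fit_least_squares()], with
#' flat priors inside the parameter box. Uncertainties are reported from the
#' 84% credible interval of the posterior: the (16th, 84th) percentiles
#' about the median, with the conservative reported error taken as the
#' larger of the two asymmetric bounds.
#'
#' @param curve An unnormalized [reflectivity_curve()].
#' @param spec A [fit_spec()] (supplies seed, walkers, steps, burn-in).
#' @param start An `"xrr_fit"` from [fit_least_squares()] (or a named
#'   vector of start values).
#' @param stretch_a Stretch-move scale parameter. Default 2.
#' @return A list of class `"posterior_summary"`: `summary` (data frame
#'   with median, `err_lo`, `err_hi`, `err` = max of the two, per
#'   parameter), `chain` (post-burn-in samples, iterations x walkers x
#'   parameters flattened to a matrix), `acceptance_fraction`, `seed`, and
#'   `diagnostics` (warnings raised).
#' @export
sample_posterior <- function(curve, spec, start, stretch_a = 2) {
  stopifnot(inherits(curve, "reflectivity_curve"), inherits(spec, "fit_spec"))
  p0 <- if (inherits(start, "xrr_fit")) start$par else start
  p0 <- p0[spec$free]
  if (any(is.na(p0))) stop("start must supply every free parameter")
  npar <- length(p0); nw <- spec$n_walkers; ns <- spec$n_steps
  lp_fun <- function(p) log_posterior(p, curve, spec)
  span <- spec$upper - spec$lower
  # walker dispersion: mildly overdispersed Laplace scales when available,
  # so the ensemble starts near the stationary distribution
  init_sd <- 1e-4 * span
  if (inherits(start, "xrr_fit") && !is.null(start$par_scale)) {
    ok <- is.finite(start$par_scale) & start$par_scale > 0
    init_sd[ok] <- pmin(0.5 * start$par_scale[ok], 0.05 * span[ok])
  }
  with_seed(spec$seed, {
    walkers <- matrix(rep(p0, each = nw), nrow = nw)
    walkers <- walkers + matrix(rnorm(nw * npar), nw, npar) *
      rep(init_sd, each = nw)
    walkers <- pmin(pmax(walkers, rep(spec$lower + 1e-12 * span, each = nw)),
                    rep(spec$upper - 1e-12 * span, each = nw))
    lp <- apply(walkers, 1, lp_fun)
    chain <- array(NA_real_, c(ns, nw, npar))
    n_acc <- 0
    for (step in seq_len(ns)) {
      for (w in seq_len(nw)) {
        other <- sample(seq_len(nw)[-w], 1)
        zz <- (1 / stretch_a) * (1 + (stretch_a - 1) * runif(1))^2
        prop <- walkers[other, ] + zz * (walkers[w, ] - walkers[other, ])
        lp_prop <- lp_fun(prop)
        log_ratio <- (npar - 1) * log(zz) + lp_prop - lp[w]
        if (is.finite(lp_prop) && log(runif(1)) < log_ratio) {
          walkers[w, ] <- prop
          lp[w] <- lp_prop
          n_acc <- n_acc + 1
        }
      }
      chain[step, , ] <- walkers
    }
    acc <- n_acc / (ns * nw)
    burn <- max(1L, floor(spec$burn_frac * ns))
    post <- chain[(burn + 1):ns, , , drop = FALSE]
    flat <- matrix(post, ncol = npar)
    colnames(flat) <- spec$free
    qs <- apply(flat, 2, quantile, probs = c(0.16, 0.5, 0.84), names = FALSE)
    summary <- data.frame(
      parameter = spec$free,
      median = qs[2, ],
      err_lo = qs[2, ] - qs[1, ],
      err_hi = qs[3, ] - qs[2, ],
      row.names = NULL
    )
    summary$err <- pmax(summary$err_lo, summary$err_hi)
    diagnostics <- character()
    if (acc < 0.1 || acc > 0.7) {
      msg <- sprintf("acceptance fraction %.3f outside [0.1, 0.7]", acc)
      warning(msg)
      diagnostics <- c(diagnostics, msg)
    }
    structure(list(summary = summary, chain = flat,
                   acceptance_fraction = acc, seed = spec$seed,
                   diagnostics = diagnostics),
              class = "posterior_summary")
  })
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat(sprintf("posterior summary (acceptance %.2f, seed %d):\n",
              x$acceptance_fraction, x$seed))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-12s %10.5g  +%.3g / -%.3g  (reported +/- %.3g)\n",
                s$parameter[i], s$median[i], s$err_hi[i], s$err_lo[i],
                s$err[i]))
  invisible(x)
}

#' First-order error propagation for independent variables
#'
#' Standard analytical propagation `sd_f^2 = sum((df/dx_i)^2 sd_i^2)` for a
#' scalar function of independently uncertain inputs, with the partial
#' derivatives taken by central finite differences (step `1e-6` times the
#' scale of each input; absolute step `1e-6` for zero-valued inputs).
#'
#' @param f Function taking a numeric vector.
#' @param values Numeric vector of input values.
#' @param sds Numeric vector of 1-sigma uncertainties, `>= 0`.
#' @return List with `value = f(values)` and `sd`.
#' @examples
#' propagate_independent(function(x) 3 * x[1], 5, 2)$sd  # 6
#' @export
propagate_independent <- function(f, values, sds) {
  stopifnot(is.function(f), is.numeric(values), is.numeric(sds),
            length(values) == length(sds))
  if (any(sds < 0)) stop("sds must be >= 0")
  g <- numeric(length(values))
  for (i in seq_along(values)) {
    h <- 1e-6 * max(abs(values[i]), 0)
    if (h == 0) h <- 1e-6
    up <- values; up[i] <- up[i] + h
    dn <- values; dn[i] <- dn[i] - h
    g[i] <- (f(up) - f(dn)) / (2 * h)
  }
  list(value = f(values), sd = sqrt(sum(g^2 * sds^2)))
}

#' Write a fit report as JSON
#'
#' Records per-parameter medians with conservative errors, the chi-squared
#' of the point fit, the seed and the chain settings — everything needed to
#' reproduce the fit.
#'
#' @param fit An `"xrr_fit"` from [fit_least_squares()].
#' @param posterior Optional `"posterior_summary"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, posterior = NULL, path) {
  stopifnot(inherits(fit, "xrr_fit"))
  rep <- list(
    parameters = as.list(fit$par),
    chisq = fit$chisq, dof = fit$dof, chisq_red = fit$chisq_red,
    converged = fit$converged, at_bounds = fit$at_bounds
  )
  if (!is.null(posterior)) {
    stopifnot(inherits(posterior, "posterior_summary"))
    s <- posterior$summary
    rep$posterior <- lapply(seq_len(nrow(s)), function(i)
      list(parameter = s$parameter[i], median = s$median[i],
           err_lo = s$err_lo[i], err_hi = s$err_hi[i], err = s$err[i]))
    rep$acceptance_fraction <- posterior$acceptance_fraction
    rep$seed <- posterior$seed
  }
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
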