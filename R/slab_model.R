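#' Construct a single slab of an interfacial film
#'
#' A slab is one homogeneous layer of the film model: thickness `d` (Å),
#' electron density `rho` (e⁻/Å³) and roughness `sigma` (Å) of the interface
#' *below* the slab, i.e. toward the subphase.
#'
#' @param d Thickness in Å, `> 0`.
#' @param rho Electron density in e⁻/Å³, `>= 0`.
#' @param sigma Interfacial roughness in Å, `>= 0`.
#' @return An object of class `"slab"`.
#' @examples
#' slab(10.63, 0.312, 3.594)
#' @export
slab <- function(d, rho, sigma = 0) {
  stopifnot(is.numeric(d), length(d) == 1, is.finite(d),
            is.numeric(rho), length(rho) == 1, is.finite(rho),
            is.numeric(sigma), length(sigma) == 1, is.finite(sigma))
  if (d <= 0) stop("slab thickness d must be > 0, got ", d)
  if (rho < 0) stop("slab electron density rho must be >= 0, got ", rho)
  if (sigma < 0) stop("slab roughness sigma must be >= 0, got ", sigma)
  structure(list(d = d, rho = rho, sigma = sigma), class = "slab")
}

#' @export
print.slab <- function(x, ...) {
  cat(sprintf("slab: d = %.4g A, rho = %.4g e-/A^3, sigma = %.4g A\n",
              x$d, x$rho, x$sigma))
  invisible(x)
}

#' Construct an interface model (slab stack between air and subphase)
#'
#' Slabs are listed from the air side to the subphase side, matching the
#' convention that slab number 1 sits in the air phase above the surface.
#' `z = 0` is placed at the air-side first interface and `z` increases into
#' the subphase, so interface positions are the partial sums of the slab
#' thicknesses.
#'
#' @param slabs List of [slab()] objects, air side first. May be empty for
#'   the bare interface.
#' @param rho_air Electron density of the air phase (e⁻/Å³). Default 0.
#' @param rho_subphase Electron density of the aqueous subphase (e⁻/Å³).
#'   Default 0.334, pure water at room temperature (10 electrons per
#'   molecule and the bulk mass density).
#' @param shared_sigma If non-`NULL`, one roughness (Å) applied to every
#'   interface, overriding the per-slab values. This is the default fitting
#'   mode: one roughness per sample.
#' @param sigma_air Roughness of the topmost (air-side) interface when
#'   `shared_sigma` is not used. Defaults to the first slab's `sigma`, or 0
#'   for the bare interface.
#' @return An object of class `"interface_model"` with fields `slabs`,
#'   `rho_air`, `rho_subphase`, `shared_sigma` and `sigma_air`.
#' @examples
#' # two-slab oleic acid monolayer: tail slab above a hydrated headgroup slab
#' oa <- interface_model(
#'   slabs = list(slab(10.63, 0.312), slab(5.025, 0.350)),
#'   shared_sigma = 3.594
#' )
#' interface_positions(oa)
#' @export
interface_model <- function(slabs = list(), rho_air = 0,
                            rho_subphase = xrr_constants$rho_water,
                            shared_sigma = NULL, sigma_air = NULL) {
  stopifnot(is.list(slabs))
  slabs <- lapply(slabs, function(s) {
    if (!inherits(s, "slab")) s <- do.call(slab, as.list(s))
    s
  })
  if (rho_air < 0) stop("rho_air must be >= 0")
  if (rho_subphase <= rho_air)
    stop("rho_subphase must exceed rho_air (reflection from the denser side)")
  if (!is.null(shared_sigma)) {
    if (shared_sigma < 0) stop("shared_sigma must be >= 0")
    slabs <- lapply(slabs, function(s) { s$sigma <- shared_sigma; s })
  }
  if (is.null(sigma_air)) {
    sigma_air <- if (!is.null(shared_sigma)) shared_sigma
                 else if (length(slabs)) slabs[[1]]$sigma else 0
  }
  if (sigma_air < 0) stop("sigma_air must be >= 0")
  structure(list(slabs = slabs, rho_air = rho_air,
                 rho_subphase = rho_subphase,
                 shared_sigma = shared_sigma, sigma_air = sigma_air),
            class = "interface_model")
}

#' @export
print.interface_model <- function(x, ...) {
  cat(sprintf("interface model: %d slab(s), rho_air = %.4g, rho_subphase = %.4g e-/A^3\n",
              length(x$slabs), x$rho_air, x$rho_subphase))
  for (i in seq_along(x$slabs)) {
    s <- x$slabs[[i]]
    cat(sprintf("  %d: d = %8.4g A  rho = %7.4g e-/A^3  sigma = %6.4g A\n",
                i, s$d, s$rho, s$sigma))
  }
  invisible(x)
}

#' Interface positions of a slab stack
#'
#' @param model An [interface_model()].
#' @return Numeric vector of interface depths `z_i` in Å (strictly
#'   increasing), starting at 0 for the air-side interface; length is the
#'   number of slabs plus one.
#' @export
interface_positions <- function(model) {
  stopifnot(inherits(model, "interface_model"))
  cumsum(c(0, vapply(model$slabs, `[[`, numeric(1), "d")))
}

# densities of the successive media: air, slabs..., subphase
layer_densities <- function(model) {
  c(model$rho_air, vapply(model$slabs, `[[`, numeric(1), "rho"),
    model$rho_subphase)
}

# roughness of each interface, air-side first
interface_sigmas <- function(model) {
  c(model$sigma_air, vapply(model$slabs, `[[`, numeric(1), "sigma"))
}

#' Evaluate the error-function-smoothed electron density profile
#'
#' The laterally averaged electron density is modeled as a sum of error
#' functions, one per interface: each interface at depth `z_i` with
#' roughness `sigma_i` contributes a smoothed step between the densities of
#' the adjacent media,
#' \deqn{\rho(z) = \rho_{air} + \sum_i \tfrac12\left[1 +
#'   \mathrm{erf}\!\left(\frac{z - z_i}{\sqrt2\,\sigma_i}\right)\right]
#'   (\rho_{i+1} - \rho_i),}
#' which runs from `rho_air` on the air side to `rho_subphase` deep in the
#' water. `sigma = 0` is handled as an exact sharp step.
#'
#' @param model An [interface_model()].
#' @param z_grid Strictly increasing depths in Å. Must extend at least
#'   `5 * max(sigma)` beyond the outermost interfaces on both sides.
#' @return An object of class `"edp"`: list with `z`, `rho` and the model.
#' @examples
#' m <- interface_model(list(slab(10.63, 0.312), slab(5.025, 0.350)),
#'                      shared_sigma = 3.594)
#' p <- build_edp(m, seq(-40, 60, by = 0.1))
#' range(p$rho)
#' @export
build_edp <- function(model, z_grid) {
  stopifnot(inherits(model, "interface_model"), is.numeric(z_grid))
  if (any(diff(z_grid) <= 0)) stop("z_grid must be strictly increasing")
  zi <- interface_positions(model)
  sig <- interface_sigmas(model)
  pad <- 5 * max(sig, 0)
  if (min(z_grid) > min(zi) - pad || max(z_grid) < max(zi) + pad)
    stop("z_grid must span all interfaces by at least 5*max(sigma) on each side")
  rho_levels <- layer_densities(model)
  rho <- rep(model$rho_air, length(z_grid))
  for (j in seq_along(zi)) {
    drho <- rho_levels[j + 1] - rho_levels[j]
    step <- if (sig[j] > 0) {
      0.5 * (1 + erf((z_grid - zi[j]) / (sqrt(2) * sig[j])))
    } else {
      # sharp step; erf(0) = 0 midpoint convention at the interface itself
      0.5 * (1 + sign(z_grid - zi[j]))
    }
    rho <- rho + drho * step
  }
  structure(list(z = z_grid, rho = rho, model = model), class = "edp")
}

#' @export
print.edp <- function(x, ...) {
  cat(sprintf("electron density profile: %d points, z in [%.3g, %.3g] A, rho in [%.4g, %.4g] e-/A^3\n",
              length(x$z), min(x$z), max(x$z), min(x$rho), max(x$rho)))
  invisible(x)
}

#' Areal excess electron density of the film
#'
#' Integrates the profile against the bare sharp air/subphase step placed at
#' the air-side interface (`z = 0`):
#' \deqn{\int \left[\rho(z) - \rho_{step}(z)\right] dz = \sum_i d_i
#'   (\rho_i - \rho_0),}
#' with \eqn{\rho_0} the subphase density. The error-function smoothing
#' conserves this integral, so the result is independent of the roughness —
#' a useful consistency check between fitted stacks of different sigma.
#'
#' @param profile An `"edp"` from [build_edp()].
#' @param model The [interface_model()] the profile was built from.
#' @return Areal excess in e⁻/Å².
#' @export
film_excess_integral <- function(profile, model) {
  stopifnot(inherits(profile, "edp"), inherits(model, "interface_model"))
  if (!identical(profile$model[c("slabs", "rho_air", "rho_subphase")],
                 model[c("slabs", "rho_air", "rho_subphase")]))
    stop("profile was not built from this model")
  z <- profile$z
  # reference: rho_air above z = 0, rho_subphase below; integrate analytically
  ref_integral <- model$rho_air * (0 - min(z)) +
    model$rho_subphase * (max(z) - 0)
  trapz(z, profile$rho) - ref_integral
}

#' Analytic areal excess of a slab stack
#'
#' Closed form `sum(d_i * (rho_i - rho_subphase))` that
#' [film_excess_integral()] must reproduce by quadrature for any roughness.
#'
#' @param model An [interface_model()].
#' @return Areal excess in e⁻/Å².
#' @export
slab_excess <- function(model) {
  stopifnot(inherits(model, "interface_model"))
  if (!length(model$slabs)) return(0)
  d <- vapply(model$slabs, `[[`, numeric(1), "d")
  rho <- vapply(model$slabs, `[[`, numeric(1), "rho")
  sum(d * (rho - model$rho_subphase))
}

#' Default evaluation grid for a model's electron density profile
#'
#' @param model An [interface_model()].
#' @param dz Grid spacing in Å.
#' @param pad Extra span beyond `5 * max(sigma)` on each side, in Å.
#' @return Strictly increasing numeric vector of depths.
#' @export
edp_grid <- function(model, dz = 0.05, pad = 5) {
  zi <- interface_positions(model)
  span <- 5 * max(interface_sigmas(model), 1) + pad
  seq(min(zi) - span, max(zi) + span, by = dz)
}
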