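# Electron-balance conversion of fitted slabs into monolayer composition.
# Per-slab balance: rho_i * d_i (e-/A^2) = sum over species of
# (molecules/A^2) * (electrons of that species' fragment in slab i).

#' Per-molecule electron and volume bookkeeping for a surfactant species
#'
#' Splits a molecule's electrons into the fragment assigned to the
#' air-proximal tail slab and the fragment assigned to the hydrated
#' headgroup slab(s). Electron counts are sums of atomic numbers of the
#' neutral fragments (no dispersion corrections).
#'
#' @param name Species name.
#' @param molar_mass Molar mass in g/mol.
#' @param tail_electrons,head_electrons Electrons in the tail and head
#'   fragments; both `> 0`.
#' @param tail_volume,head_volume Optional fragment molecular volumes in Å³
#'   for the molar-volume consistency check.
#' @return An object of class `"species_fragments"` with an additional
#'   `electrons = tail_electrons + head_electrons` field.
#' @seealso [builtin_species()] for oleic acid, water and polysorbate 80.
#' @export
species_fragments <- function(name, molar_mass, tail_electrons,
                              head_electrons, tail_volume = NULL,
                              head_volume = NULL) {
  stopifnot(is.character(name), molar_mass > 0,
            tail_electrons >= 0, head_electrons >= 0)
  if (tail_electrons + head_electrons <= 0)
    stop("species must carry electrons")
  structure(list(name = name, molar_mass = molar_mass,
                 tail_electrons = tail_electrons,
                 head_electrons = head_electrons,
                 electrons = tail_electrons + head_electrons,
                 tail_volume = tail_volume, head_volume = head_volume),
            class = "species_fragments")
}

#' Built-in species definitions
#'
#' * `"OA"` — oleic acid C18H34O2, M = 282.46 g/mol, 158 electrons split as
#'   tail C17H33 (135 e⁻) + carboxyl head CO2H (23 e⁻).
#' * `"water"` — H2O, M = 18.015 g/mol, 10 electrons (all "head").
#' * `"PS80"` — polysorbate 80, average monooleate formula C64H124O26
#'   consistent with the nominal average molecular weight 1310 g/mol;
#'   716 electrons split as oleate tail C17H33 (135 e⁻) + sorbitan/POE
#'   headgroup (581 e⁻).
#'
#' @param name One of `"OA"`, `"water"`, `"PS80"`.
#' @return A [species_fragments()] object.
#' @examples
#' builtin_species("OA")$tail_electrons  # 135
#' @export
builtin_species <- function(name = c("OA", "water", "PS80")) {
  name <- match.arg(name)
  switch(name,
    OA = species_fragments("OA", molar_mass = 282.46,
                           tail_electrons = 135, head_electrons = 23),
    water = species_fragments("water", molar_mass = xrr_constants$M_water,
                              tail_electrons = 0, head_electrons = 10),
    PS80 = species_fragments("PS80", molar_mass = 1310,
                             tail_electrons = 135, head_electrons = 581)
  )
}

# centralized unit conversions ------------------------------------------------

# molecules per A^2  ->  surface excess in mg/m^2
number_density_to_gamma <- function(n_per_A2, molar_mass) {
  # n [1/A^2] * 1e20 [A^2/m^2] * M/N_A [g] * 1e3 [mg/g]
  n_per_A2 * 1e23 * molar_mass / xrr_constants$N_A
}

# surface excess in mg/m^2  ->  molecules per A^2
gamma_to_number_density <- function(gamma, molar_mass) {
  gamma * xrr_constants$N_A / (1e23 * molar_mass)
}

#' Area per molecule from the tail-slab electron balance
#'
#' The air-proximal slab contains only the hydrophobic tails, so its areal
#' electron density `rho * d` (e⁻/Å²) counts one tail fragment per
#' molecule: `A_s = tail_electrons / (rho * d)`.
#'
#' @param tail_slab A [slab()] (only `d` and `rho` are used).
#' @param tail_electrons Electrons of the tail fragment (135 for the oleic
#'   acid tail C17H33).
#' @return Area per molecule in Å².
#' @examples
#' area_per_molecule(slab(10.63, 0.312), 135)  # ~40.7 A^2
#' @export
area_per_molecule <- function(tail_slab, tail_electrons) {
  stopifnot(inherits(tail_slab, "slab"), tail_electrons > 0)
  if (tail_slab$rho <= 0 || tail_slab$d <= 0)
    stop("tail slab must have positive rho and d")
  tail_electrons / (tail_slab$rho * tail_slab$d)
}

#' Waters per headgroup from the head-slab electron balance
#'
#' The hydrated slab holds one head fragment per molecule plus `N_W` water
#' molecules: `rho * d * A_s = head_electrons + 10 * N_W`, so
#' `N_W = (rho * d * A_s - head_electrons) / 10`.
#'
#' @param head_slab A [slab()].
#' @param A_s Area per molecule in Å² (from [area_per_molecule()]).
#' @param head_electrons Electrons of the head fragment (23 for CO2H).
#' @return Waters per headgroup (dimensionless).
#' @export
waters_per_headgroup <- function(head_slab, A_s, head_electrons) {
  stopifnot(inherits(head_slab, "slab"), A_s > 0, head_electrons >= 0)
  total <- head_slab$rho * head_slab$d * A_s
  if (total < head_electrons)
    stop(sprintf(
      "head slab (d = %.4g, rho = %.4g) holds %.4g electrons per molecule, fewer than the %.4g of the head fragment: negative water content",
      head_slab$d, head_slab$rho, total, head_electrons))
  (total - head_electrons) / xrr_constants$e_water
}

#' Surface excess from area per molecule
#'
#' `Gamma = M / (N_A * A_s)` converted to mg/m²; monotone decreasing in
#' `A_s`.
#'
#' @param molar_mass Molar mass in g/mol.
#' @param A_s Area per molecule in Å².
#' @return Surface excess in mg/m².
#' @examples
#' surface_excess(282.46, 40.70)  # ~1.15 mg/m^2
#' @export
surface_excess <- function(molar_mass, A_s) {
  stopifnot(molar_mass > 0)
  if (A_s <= 0) stop("A_s must be > 0")
  number_density_to_gamma(1 / A_s, molar_mass)
}

#' Waters per headgroup from two surface excesses
#'
#' Consistency identity `N_W = (Gamma_W / M_W) / (Gamma_s / M_s)`: the
#' molar ratio of interfacial water to the surfactant.
#'
#' @param gamma_w Water surface excess in mg/m².
#' @param gamma_s Surfactant surface excess in mg/m², `> 0`.
#' @param molar_mass_s Surfactant molar mass in g/mol.
#' @return Waters per headgroup.
#' @export
waters_from_excesses <- function(gamma_w, gamma_s, molar_mass_s) {
  if (gamma_s <= 0) stop("gamma_s must be > 0")
  stopifnot(gamma_w >= 0, molar_mass_s > 0)
  (gamma_w / xrr_constants$M_water) / (gamma_s / molar_mass_s)
}

#' Surface molar ratio of two species from their surface excesses
#'
#' `(Gamma_1/M_1) / (Gamma_2/M_2)`, e.g. the OA/PS80 molar ratio at the
#' interface.
#'
#' @param gamma_1,gamma_2 Surface excesses in mg/m²; `gamma_2 > 0`.
#' @param molar_mass_1,molar_mass_2 Molar masses in g/mol; defaults are
#'   oleic acid (282.46) and polysorbate 80 (1310).
#' @return Dimensionless molar ratio.
#' @export
molar_surface_ratio <- function(gamma_1, gamma_2, molar_mass_1 = 282.46,
                                molar_mass_2 = 1310) {
  if (gamma_2 <= 0) stop("gamma_2 must be > 0")
  stopifnot(gamma_1 >= 0, molar_mass_1 > 0, molar_mass_2 > 0)
  (gamma_1 / molar_mass_1) / (gamma_2 / molar_mass_2)
}

#' Solve the per-slab electron balances of a mixed interfacial layer
#'
#' Given a fitted stack and a partition of each species' electrons across
#' the slabs, solves the linear system
#' `rho_i * d_i = sum_s n_s * E_{s,i}` for the number densities `n_s`
#' (molecules/Å²), where `E_{s,i}` is the electron count of species `s`
#' assigned to slab `i`. One equation per slab; the system must be square
#' (as many species, including water, as slabs) or overdetermined, and is
#' solved by least squares with the per-slab balance residuals reported.
#' A negative solution triggers a non-negativity-constrained refit with a
#' warning.
#'
#' @param model An [interface_model()] whose slabs carry the fitted `d`,
#'   `rho`.
#' @param species Named list of [species_fragments()] (include water).
#' @param partition Numeric matrix, species x slabs: electrons of each
#'   species per molecule assigned to each slab. Rows must sum to each
#'   species' total electron count. Row names must match `names(species)`.
#' @param reference Species whose headgroup count normalizes `A_s` and
#'   `N_W`. Default: first non-water species.
#' @param tol Relative tolerance on the per-slab balance residuals before
#'   an infeasibility error is raised. Default 1e-6 (square systems solve
#'   exactly).
#' @return Object of class `"monolayer_composition"`: `n` (molecules/Å² per
#'   species), `gamma` (mg/m² per species), `A_s` (Å² per reference
#'   molecule), `N_W` (waters per reference headgroup), `residuals`
#'   (per-slab relative electron-balance residuals), `partition`.
#' @examples
#' # oleic acid monolayer: tail slab + hydrated head slab
#' m <- interface_model(list(slab(10.63, 0.312), slab(5.025, 0.350)),
#'                      shared_sigma = 3.594)
#' sp <- list(OA = builtin_species("OA"), water = builtin_species("water"))
#' part <- rbind(OA = c(135, 23), water = c(0, 10))
#' mixed_layer_composition(m, sp, part)
#' @export
mixed_layer_composition <- function(model, species, partition,
                                    reference = NULL, tol = 1e-6) {
  stopifnot(inherits(model, "interface_model"), is.list(species),
            is.matrix(partition))
  nsl <- length(model$slabs)
  nsp <- length(species)
  if (nrow(partition) != nsp || ncol(partition) != nsl)
    stop("partition must be a species x slabs matrix")
  if (is.null(rownames(partition)) || !setequal(rownames(partition), names(species)))
    stop("partition row names must match species names")
  partition <- partition[names(species), , drop = FALSE]
  tot <- vapply(species, `[[`, numeric(1), "electrons")
  if (any(abs(rowSums(partition) - tot) > 1e-9 * pmax(tot, 1)))
    stop("each partition row must sum to the species' total electron count")
  if (nsl < nsp)
    stop("underdetermined: fewer slabs (balances) than species")
  b <- vapply(model$slabs, function(s) s$rho * s$d, numeric(1))
  A <- t(partition)                       # slabs x species
  n <- qr.solve(A, b)                     # least squares if overdetermined
  if (any(n < -1e-12)) {
    warning("unconstrained electron balance gave negative number densities; refitting with non-negativity")
    obj <- function(x) sum((A %*% x - b)^2)
    opt <- optim(pmax(n, 1e-8), obj, method = "L-BFGS-B",
                 lower = rep(0, nsp))
    n <- opt$par
  }
  n <- pmax(n, 0)
  resid <- as.numeric(abs(A %*% n - b) / b)
  if (any(resid > tol) && nsl == nsp)
    stop("electron balances unsolvable within tolerance; per-slab relative residuals: ",
         paste(signif(resid, 3), collapse = ", "))
  names(n) <- names(species)
  mm <- vapply(species, `[[`, numeric(1), "molar_mass")
  gamma <- number_density_to_gamma(n, mm)
  is_water <- names(species) == "water" |
    vapply(species, `[[`, character(1), "name") == "water"
  if (is.null(reference)) reference <- names(species)[!is_water][1]
  n_ref <- n[[reference]]
  A_s <- if (n_ref > 0) 1 / n_ref else NA_real_
  n_w <- if (any(is_water)) sum(n[is_water]) else 0
  N_W <- if (n_ref > 0) n_w / n_ref else NA_real_
  structure(list(n = n, gamma = gamma, A_s = A_s, N_W = N_W,
                 reference = reference, residuals = resid,
                 partition = partition, model = model, species = species),
            class = "monolayer_composition")
}

#' @export
print.monolayer_composition <- function(x, ...) {
  cat("monolayer composition:\n")
  for (s in names(x$gamma))
    cat(sprintf("  Gamma_%-6s = %8.4g mg/m^2  (n = %.4g /A^2)\n",
                s, x$gamma[[s]], x$n[[s]]))
  cat(sprintf("  A_s(%s) = %.4g A^2/molecule, N_W = %.4g waters/headgroup\n",
              x$reference, x$A_s, x$N_W))
  cat(sprintf("  per-slab balance residuals: %s\n",
              paste(signif(x$residuals, 3), collapse = ", ")))
  invisible(x)
}

#' Molar-volume balance residual per slab
#'
#' Compares each slab's geometric volume per unit area (`d_i`, Å³/Å²)
#' with the volume of the molecular fragments the composition assigns to
#' it: `residual_i = |d_i - sum_s n_s V_{s,i}| / d_i`. Reported as a
#' consistency diagnostic, not enforced — the electron balances alone
#' determine the composition.
#'
#' @param composition A `"monolayer_composition"` from
#'   [mixed_layer_composition()].
#' @param volumes Numeric matrix, species x slabs: fragment molecular
#'   volumes in Å³ assigned to each slab. Row names must match the species.
#' @return Numeric vector of relative residuals, one per slab.
#' @export
volume_balance_residual <- function(composition, volumes) {
  stopifnot(inherits(composition, "monolayer_composition"))
  if (missing(volumes) || is.null(volumes))
    stop("fragment volumes are required for the molar-volume balance")
  n <- composition$n
  model <- composition$model
  nsl <- length(model$slabs)
  if (!is.matrix(volumes) || ncol(volumes) != nsl ||
      !setequal(rownames(volumes), names(n)))
    stop("volumes must be a species x slabs matrix with rows matching the species")
  volumes <- volumes[names(n), , drop = FALSE]
  d <- vapply(model$slabs, `[[`, numeric(1), "d")
  filled <- as.numeric(t(volumes) %*% n)
  abs(d - filled) / d
}

#' Composition of a simple surfactant monolayer (tail slab + head slab)
#'
#' Convenience wrapper for the single-species two-slab case: area per
#' molecule from the tail slab, hydration from the head slab, surface
#' excesses for surfactant and water, with uncertainties propagated from
#' the slab-parameter errors treating them as independent.
#'
#' @param model Two-slab [interface_model()], tail slab first.
#' @param species A [species_fragments()]; default oleic acid.
#' @param errors Optional named numeric vector of 1-sigma errors on
#'   `d1`, `rho1`, `d2`, `rho2` (missing entries are 0).
#' @return A list with `A_s`, `gamma`, `gamma_w`, `N_W`, each a
#'   `(value, sd)` pair.
#' @examples
#' m <- interface_model(list(slab(10.63, 0.312), slab(5.025, 0.350)),
#'                      shared_sigma = 3.594)
#' monolayer_composition(m)
#' @export
monolayer_composition <- function(model, species = builtin_species("OA"),
                                  errors = NULL) {
  stopifnot(inherits(model, "interface_model"), length(model$slabs) == 2,
            inherits(species, "species_fragments"))
  err <- c(d1 = 0, rho1 = 0, d2 = 0, rho2 = 0)
  if (!is.null(errors)) err[names(errors)] <- errors
  s1 <- model$slabs[[1]]; s2 <- model$slabs[[2]]
  x0 <- c(s1$d, s1$rho, s2$d, s2$rho)
  sds <- unname(err[c("d1", "rho1", "d2", "rho2")])
  f_As <- function(x) species$tail_electrons / (x[2] * x[1])
  f_g  <- function(x) surface_excess(species$molar_mass, f_As(x))
  f_nw <- function(x) (x[4] * x[3] * f_As(x) - species$head_electrons) /
    xrr_constants$e_water
  f_gw <- function(x) f_nw(x) * xrr_constants$M_water /
    (species$molar_mass) * f_g(x)
  list(A_s = propagate_independent(f_As, x0, sds),
       gamma = propagate_independent(f_g, x0, sds),
       gamma_w = propagate_independent(f_gw, x0, sds),
       N_W = propagate_independent(f_nw, x0, sds))
}
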