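# Physical constants used throughout. Units: lengths in Angstrom, electron
# densities in e-/A^3, surface excesses in mg/m^2, tension in mN/m.

#' Physical constants
#'
#' Constants used by the reflectivity and composition calculations:
#' classical electron radius `r_e` (Å), Avogadro's number `N_A` (1/mol),
#' molar gas constant `R_gas` (J/mol/K), molar mass of water `M_water`
#' (g/mol), electrons per water molecule `e_water`, and the electron density
#' of pure water at room temperature `rho_water` (e⁻/Å³).
#'
#' @format A named list.
#' @export
xrr_constants <- list(
  r_e       = 2.8179403e-5,  # classical electron radius, Angstrom
  N_A       = 6.02214e23,    # Avogadro
  R_gas     = 8.314462618,   # J / mol / K
  M_water   = 18.015,        # g / mol
  e_water   = 10,            # electrons per H2O
  rho_water = 0.334          # e-/A^3, pure water at room temperature
)

# error function in terms of the normal CDF
erf <- function(x) 2 * stats::pnorm(sqrt(2) * x) - 1

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

`%||%` <- function(a, b) if (is.null(a)) b else a
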