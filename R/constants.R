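#' Physical constants used throughout the package
#'
#' CODATA 2018 values. Energies are handled internally in kcal/mol; the
#' Boltzmann and Planck constants are kept in SI for rate prefactors and
#' diffusion coefficients.
#'
#' @return A named list with components:
#'   \item{kB}{Boltzmann constant, J/K}
#'   \item{h}{Planck constant, J s}
#'   \item{N_A}{Avogadro number, 1/mol}
#'   \item{R_kcal}{molar gas constant, kcal/(mol K)}
#'   \item{R_J}{molar gas constant, J/(mol K)}
#'   \item{c_cm}{speed of light, cm/s (for wavenumber conversions)}
#'   \item{hartree_kcal}{1 hartree in kcal/mol}
#'   \item{T_ref}{default temperature, 298.15 K (1 M standard state)}
#'
#' @examples
#' pc <- phys_constants()
#' pc$kB * pc$N_A / pc$R_J  # == 1
#' @export
phys_constants <- function() {
  kB <- 1.380649e-23
  NA_ <- 6.02214076e23
  list(
    kB = kB,
    h = 6.62607015e-34,
    N_A = NA_,
    R_J = kB * NA_,
    R_kcal = kB * NA_ / 4184,
    c_cm = 2.99792458e10,
    hartree_kcal = 627.5095,
    T_ref = 298.15
  )
}

.energy_units <- c("hartree", "kcal_per_mol", "kJ_per_mol")

# factors to kcal/mol
.to_kcal <- c(hartree = 627.5095, kcal_per_mol = 1, kJ_per_mol = 1 / 4.184)

#' Convert molar energies between hartree, kcal/mol and kJ/mol
#'
#' @param x numeric vector of energies.
#' @param from,to units, one of `"hartree"`, `"kcal_per_mol"`, `"kJ_per_mol"`.
#' @return numeric vector in the target units. Round trips are exact to
#'   relative precision 1e-12.
#' @examples
#' convert_energy(1, "hartree", "kcal_per_mol")  # 627.5095
#' @export
convert_energy <- function(x, from, to) {
  from <- match.arg(from, .energy_units)
  to <- match.arg(to, .energy_units)
  x * .to_kcal[[from]] / .to_kcal[[to]]
}
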