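#' Physical constants used throughout the package
#'
#' All energies are in kcal/mol, lengths in angstrom, charges in elementary
#' charge units, temperatures in kelvin, electric fields in MV/cm.
#'
#' * `kB`: Boltzmann constant, kcal/(mol K).
#' * `hartree_to_kcal`: Hartree to kcal/mol.
#' * `hartree_to_eV`: Hartree to electronvolt.
#' * `coulomb_const`: Coulomb prefactor, kcal A / (mol e^2); two unit charges
#'   1 A apart repel with +332.0637 kcal/mol.
#' * `efield_const`: e / (4 pi eps0) in MV A^2 / (cm e); a unit point charge
#'   1 A away produces a field of 1439.964 MV/cm.
#'
#' @format A named list of scalars.
#' @export
#' @examples
#' md_constants$kB * 300   # thermal energy at 300 K, kcal/mol
md_constants <- list(
  kB             = 0.0019872041,
  hartree_to_kcal = 627.5095,
  hartree_to_eV  = 27.2114,
  coulomb_const  = 332.0637,
  efield_const   = 1439.964
)
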