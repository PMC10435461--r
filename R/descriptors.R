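#' Conceptual-DFT reactivity descriptors from frontier-orbital energies
#'
#' Computes, per input record, the eight standard global reactivity indices
#' from the HOMO and LUMO energies (eV):
#' ionization potential IP = -E_HOMO, electron affinity EA = -E_LUMO,
#' band gap (magnitude reported, signed value retained), chemical hardness
#' eta = (E_LUMO - E_HOMO)/2, global softness S = 1/eta, chemical potential
#' mu = -(IP + EA)/2, electrophilicity index omega = mu^2/(2 eta), and
#' electronegativity chi = -mu. All intermediates are kept unrounded.
#' Open-shell species carrying a SOMO energy use (HOMO, LUMO) for the
#' descriptors; the SOMO is carried through as annotation only.
#'
#' @param orbitals A data frame with columns `label`, `e_homo` and `e_lumo`
#'   (eV) and optionally `e_somo` (eV) and `dipole` (debye).
#' @return A tibble with one row per input: `label`, `e_homo`, `e_lumo`,
#'   `ip`, `ea`, `e_g` (magnitude), `e_g_signed`, `eta`, `s`, `mu`, `omega`,
#'   `chi`, plus `e_somo`/`dipole` when supplied. All energies eV
#'   (softness eV^-1).
#' @export
#' @examples
#' compute_descriptors(data.frame(label = "1", e_homo = -4.24, e_lumo = -2.69))
compute_descriptors <- function(orbitals) {
  orbitals <- as_tibble(orbitals)
  stopifnot(all(c("e_homo", "e_lumo") %in% names(orbitals)))
  if (!"label" %in% names(orbitals))
    orbitals$label <- as.character(seq_len(nrow(orbitals)))
  if (any(!is.finite(orbitals$e_homo)) || any(!is.finite(orbitals$e_lumo)))
    abort("orbital energies must be finite")
  if (any(orbitals$e_homo > orbitals$e_lumo))
    abort("closed-shell ordering violated: e_homo must be <= e_lumo")
  if (any(orbitals$e_homo == orbitals$e_lumo))
    abort("degenerate gap (e_homo == e_lumo): hardness is zero and softness undefined")

  out <- orbitals |>
    mutate(
      ip = -.data$e_homo,
      ea = -.data$e_lumo,
      e_g_signed = .data$e_homo - .data$e_lumo,
      e_g = abs(.data$e_g_signed),
      eta = (.data$e_lumo - .data$e_homo) / 2,
      s = 1 / .data$eta,
      mu = -(.data$ip + .data$ea) / 2,
      omega = .data$mu^2 / (2 * .data$eta),
      chi = -.data$mu
    )
  keep <- c("label", "e_homo", "e_lumo",
            intersect(c("e_somo", "dipole"), names(out)),
            "ip", "ea", "e_g", "e_g_signed", "eta", "s", "mu", "omega", "chi")
  out[, keep]
}

#' Read frontier-orbital records from JSON
#'
#' Accepts an array of objects with fields `label`, `e_homo_eV`, `e_lumo_eV`
#' and optionally `e_somo_eV`, `dipole_D`.
#'
#' @param path JSON file path.
#' @return A tibble suitable for [compute_descriptors()].
#' @export
read_orbital_energies <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  rec <- as_tibble(rec)
  out <- tibble(label = as.character(rec$label),
                e_homo = rec$e_homo_eV, e_lumo = rec$e_lumo_eV)
  if (!is.null(rec$e_somo_eV)) out$e_somo <- rec$e_somo_eV
  if (!is.null(rec$dipole_D)) out$dipole <- rec$dipole_D
  out
}

#' Second-order (E2) donor-acceptor stabilization energies
#'
#' Second-order perturbative estimate of the energy lowering when a filled
#' donor natural bond orbital mixes with an empty acceptor orbital:
#' E(2) = q_i |F_ij|^2 / (eps_acceptor - eps_donor), reported as a positive
#' magnitude in kcal/mol (inputs in hartree; conversion 627.5095).
#'
#' @param interactions A data frame with columns `q_i` (orbital occupancy,
#'   electrons, in (0, 2]), `f_ij` (off-diagonal Fock element, hartree),
#'   `eps_donor` and `eps_acceptor` (orbital energies, hartree), and
#'   optionally `donor_label`/`acceptor_label`.
#' @return The input tibble with an `e2` column (kcal/mol, >= 0).
#' @export
#' @examples
#' nbo_e2(data.frame(q_i = 2, f_ij = 0.05, eps_donor = 0, eps_acceptor = 0.5))
nbo_e2 <- function(interactions) {
  x <- as_tibble(interactions)
  stopifnot(all(c("q_i", "f_ij", "eps_donor", "eps_acceptor") %in% names(x)))
  if (any(x$q_i <= 0 | x$q_i > 2))
    abort("orbital occupancy q_i must lie in (0, 2]")
  if (any(x$eps_acceptor == x$eps_donor))
    abort("degenerate donor/acceptor energies: E(2) undefined (division by zero)")
  x$e2 <- abs(-x$q_i * abs(x$f_ij)^2 / (x$eps_acceptor - x$eps_donor)) *
    md_constants$hartree_to_kcal
  x
}
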