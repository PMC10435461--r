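#' Electric field of point charges at a point
#'
#' \eqn{\vec E = K \sum_i q_i (p - r_i)/|p - r_i|^3} with
#' K = 1439.964 MV A^2 / (cm e): a unit positive charge one angstrom from
#' the evaluation point produces a field of 1439.964 MV/cm directed away
#' from the charge. No distance cutoff is applied (fields decay as 1/r^2
#' and the full sum is cheap at desk scale).
#'
#' @param coords n x 3 coordinate matrix (angstrom).
#' @param charges Per-atom charges (e).
#' @param point Length-3 evaluation point.
#' @param exclusions Atom indices omitted from the sum.
#' @return Length-3 field vector in MV/cm.
#' @export
#' @examples
#' field_at_point(rbind(c(1, 0, 0)), 1, c(0, 0, 0))  # c(-1439.964, 0, 0)
field_at_point <- function(coords, charges, point, exclusions = integer(0)) {
  coords <- as.matrix(coords)
  if (any(!is.finite(point))) abort("evaluation point must be finite")
  keep <- setdiff(seq_len(nrow(coords)), exclusions)
  if (length(keep) == 0) return(c(0, 0, 0))
  dvec <- sweep(-coords[keep, , drop = FALSE], 2, point, "+")
  r <- sqrt(rowSums(dvec^2))
  if (any(r < 0.05)) {
    i <- keep[which(r < 0.05)[1]]
    abort(sprintf("source atom %d is %.3f A from the evaluation point (singularity)",
                  i, min(r)))
  }
  colSums(md_constants$efield_const * charges[keep] * dvec / r^3)
}

#' Project a field vector onto a bond axis
#'
#' Signed scalar projection \eqn{\vec E \cdot \vec r / |\vec r|}; positive
#' values point from the first bond atom towards the second.
#'
#' @param field Length-3 field vector (MV/cm).
#' @param bond Length-3 bond vector (from atom i to atom j).
#' @return Scalar projection in MV/cm.
#' @export
project_field <- function(field, bond) {
  nb <- sqrt(sum(bond^2))
  if (nb == 0) abort("zero-length bond vector")
  sum(field * bond) / nb
}

#' Define a probe bond for field projection
#'
#' @param atom_i,atom_j Distinct atom indices into the topology; the
#'   positive field direction runs from i to j.
#' @param at Evaluation point rule: `"midpoint"` (default), `"atom_i"` or
#'   `"atom_j"`.
#' @return An object of class `bond_probe`.
#' @export
bond_probe <- function(atom_i, atom_j, at = c("midpoint", "atom_i", "atom_j")) {
  if (atom_i == atom_j) abort("probe atoms must be distinct")
  structure(list(atom_i = as.integer(atom_i), atom_j = as.integer(atom_j),
                 at = match.arg(at)), class = "bond_probe")
}

#' Read a probe definition from YAML
#'
#' Expects two selectors `atom_i` and `atom_j`, each with `resid` and
#' `name` fields, plus an optional `at` rule.
#'
#' @param path YAML file path.
#' @param topology The `md_topology` the selectors resolve against.
#' @return A [bond_probe()].
#' @export
read_probe_yaml <- function(path, topology) {
  y <- yaml::read_yaml(path)
  pick <- function(sel) {
    i <- which(topology$resid == sel$resid & topology$name == sel$name)
    if (length(i) != 1)
      abort(sprintf("probe selector resid %s name %s matches %d atoms",
                    sel$resid, sel$name, length(i)))
    i
  }
  bond_probe(pick(y$atom_i), pick(y$atom_j), at = y$at %||% "midpoint")
}

#' Per-residue electric field projected onto a probe bond
#'
#' For every frame: the evaluation point follows the probe rule (bond
#' midpoint by default) and the bond vector runs atom_i to atom_j; for
#' every residue, the field generated by that residue's atoms alone is
#' projected onto the bond. The profile reports the per-residue mean and
#' standard deviation over frames. By default the two probe atoms and all
#' ligand atoms are excluded from the field sources (the quantity of
#' interest is the protein environment's action on the probed interaction);
#' the decomposition is exactly additive over residues. Frames where the
#' probe atoms coincide are skipped with a warning and counted.
#'
#' @param trajectory An `md_trajectory`.
#' @param topology An `md_topology` with charges.
#' @param probe A [bond_probe()].
#' @param exclusions Atom indices excluded from the sources; defaults to
#'   the probe atoms plus all ligand atoms.
#' @param keep_matrix Retain the residue x frame projection matrix as an
#'   attribute.
#' @return A tibble of class `ef_profile`: `resid`, `mean`, `sd` (MV/cm);
#'   attributes `skipped_frames`, and `projections` if requested.
#' @export
per_residue_efield <- function(trajectory, topology, probe,
                               exclusions = NULL, keep_matrix = FALSE) {
  stopifnot(inherits(trajectory, "md_trajectory"),
            inherits(topology, "md_topology"),
            inherits(probe, "bond_probe"))
  if (is.null(exclusions))
    exclusions <- union(c(probe$atom_i, probe$atom_j),
                        which(topology$is_ligand))
  residues <- sort(unique(topology$resid[!seq_len(nrow(topology)) %in%
                                           exclusions]))
  res_atoms <- lapply(residues, function(r)
    setdiff(which(topology$resid == r), exclusions))
  keep <- lengths(res_atoms) > 0
  residues <- residues[keep]; res_atoms <- res_atoms[keep]
  proj <- matrix(NA_real_, length(residues), trajectory$n_frames)
  skipped <- 0L
  for (f in seq_len(trajectory$n_frames)) {
    x <- frame_coords(trajectory, f)
    ri <- x[probe$atom_i, ]; rj <- x[probe$atom_j, ]
    bond <- rj - ri
    if (sum(bond^2) == 0) {
      skipped <- skipped + 1L
      warn(sprintf("frame %d: probe atoms coincide; frame skipped", f))
      next
    }
    point <- switch(probe$at, midpoint = (ri + rj) / 2, atom_i = ri,
                    atom_j = rj)
    for (k in seq_along(residues)) {
      incl <- setdiff(seq_len(nrow(x)), res_atoms[[k]])
      ef <- field_at_point(x, topology$charge, point, exclusions = incl)
      proj[k, f] <- project_field(ef, bond)
    }
  }
  ok <- colSums(is.na(proj)) == 0
  out <- tibble(resid = residues,
                mean = rowMeans(proj[, ok, drop = FALSE]),
                sd = apply(proj[, ok, drop = FALSE], 1,
                           function(v) if (length(v) > 1) sd(v) else 0))
  attr(out, "skipped_frames") <- skipped
  if (keep_matrix) attr(out, "projections") <- proj
  class(out) <- c("ef_profile", class(out))
  out
}

#' Rank residues by projected electric field magnitude
#'
#' Residues whose mean projected field magnitude meets the significance
#' threshold (default 7.5 MV/cm), sorted by descending |mean|; the total
#' summed field across the retained residues is reported as an attribute.
#'
#' @param profile An `ef_profile` (or tibble with `resid`, `mean`, `sd`).
#' @param threshold Significance threshold in MV/cm.
#' @return A tibble: `resid`, `mean`, `sd`, sorted by |mean| descending;
#'   attribute `total_ef` (sum of retained means, MV/cm).
#' @export
rank_residues <- function(profile, threshold = 7.5) {
  out <- profile |>
    filter(abs(.data$mean) >= threshold) |>
    arrange(desc(abs(.data$mean)))
  out <- as_tibble(out)
  attr(out, "total_ef") <- sum(out$mean)
  attr(out, "threshold") <- threshold
  out
}
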