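#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Least-squares optimal rotation and translation mapping `mobile` onto
#' `reference`, via singular value decomposition of the cross-covariance
#' with the usual determinant correction so the rotation is proper
#' (det = +1). The returned `rmsd_after` is minimal over all rigid motions.
#'
#' @param mobile,reference n x 3 coordinate matrices (angstrom).
#' @param selection Optional indices of the points used to fit (and over
#'   which `rmsd_after` is evaluated); defaults to all points.
#' @return A list of class `superposition`: `rotation` (3 x 3, proper
#'   orthogonal), `translation` (length 3, applied after rotation),
#'   `rmsd_after` (angstrom), and `transform(x)` applying the fit.
#' @export
kabsch_superpose <- function(mobile, reference, selection = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (is.null(selection)) selection <- seq_len(nrow(mobile))
  m <- mobile[selection, , drop = FALSE]
  r <- reference[selection, , drop = FALSE]
  if (nrow(m) != nrow(r)) abort("selections must have equal length")
  if (nrow(m) < 3) abort("at least 3 points are required for superposition")
  mc <- colMeans(m); rc <- colMeans(r)
  m0 <- sweep(m, 2, mc); r0 <- sweep(r, 2, rc)
  if (min(svd(m0)$d) < 1e-10 * max(svd(m0)$d, 1))
    abort("selection points are collinear; rotation is underdetermined")
  s <- svd(crossprod(m0, r0))
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  trans <- rc - as.numeric(rot %*% mc)
  transform <- function(x) sweep(as.matrix(x) %*% t(rot), 2, trans, "+")
  fitted <- transform(m)
  rmsd <- sqrt(mean(rowSums((fitted - r)^2)))
  structure(list(rotation = rot, translation = trans,
                 rmsd_after = rmsd, transform = transform),
            class = "superposition")
}

# resolve a selection argument to atom indices
resolve_selection <- function(selection, topology, n_atoms) {
  if (is.null(selection)) return(seq_len(n_atoms))
  if (is.character(selection) && length(selection) == 1) {
    if (is.null(topology)) abort("a topology is required for named selections")
    idx <- switch(selection,
      backbone = which(topology$name %in% c("N", "CA", "C")),
      ligand = which(topology$is_ligand),
      ligand_heavy = which(topology$is_ligand &
                             !grepl("^H", topology$name)),
      protein = which(!topology$is_ligand),
      abort(paste("unknown selection keyword:", selection)))
    if (length(idx) == 0) abort(paste("selection is empty:", selection))
    return(idx)
  }
  as.integer(selection)
}

#' Per-frame coordinate RMSD after optimal superposition (cRMSD)
#'
#' For every frame, the selected atoms are superposed onto the reference
#' selection (Kabsch) and the root-mean-square deviation over the selection
#' is reported. The conventional protein choice is the backbone N, CA, C
#' atoms, which the `"backbone"` keyword selects from a topology.
#'
#' @param trajectory An `md_trajectory`.
#' @param reference n x 3 reference coordinates (same atom count).
#' @param topology Optional `md_topology` (needed for keyword selections).
#' @param selection Atom indices or one of `"backbone"`, `"ligand"`,
#'   `"ligand_heavy"`, `"protein"`.
#' @return A tibble: `frame`, `rmsd` (angstrom).
#' @export
c_rmsd <- function(trajectory, reference, topology = NULL,
                   selection = "backbone") {
  stopifnot(inherits(trajectory, "md_trajectory"))
  sel <- resolve_selection(selection, topology, trajectory$n_atoms)
  if (length(sel) == 0) abort("empty selection")
  ref <- as.matrix(reference)[sel, , drop = FALSE]
  vals <- vapply(seq_len(trajectory$n_frames), function(f) {
    kabsch_superpose(frame_coords(trajectory, f)[sel, , drop = FALSE],
                     ref)$rmsd_after
  }, numeric(1))
  tibble(frame = seq_len(trajectory$n_frames), rmsd = vals)
}

#' Per-frame distance RMSD (dRMSD), superposition-free
#'
#' RMS over all unique intra-selection pair distances of the difference
#' between the frame and the reference: a rigid-motion-invariant deviation
#' measure, conventionally applied to the ligand heavy atoms.
#'
#' @inheritParams c_rmsd
#' @param selection Defaults to `"ligand_heavy"`.
#' @return A tibble: `frame`, `drmsd` (angstrom).
#' @export
d_rmsd <- function(trajectory, reference, topology = NULL,
                   selection = "ligand_heavy") {
  stopifnot(inherits(trajectory, "md_trajectory"))
  sel <- resolve_selection(selection, topology, trajectory$n_atoms)
  if (length(sel) < 2)
    abort("dRMSD needs at least 2 atoms in the selection")
  dref <- dist(as.matrix(reference)[sel, , drop = FALSE])
  vals <- vapply(seq_len(trajectory$n_frames), function(f) {
    dfr <- dist(frame_coords(trajectory, f)[sel, , drop = FALSE])
    sqrt(mean((dfr - dref)^2))
  }, numeric(1))
  tibble(frame = seq_len(trajectory$n_frames), drmsd = vals)
}

#' Per-residue root-mean-square fluctuation (RMSF)
#'
#' Each frame is superposed (on the selection) to the time-average
#' structure, the per-atom RMS deviation from its mean position is taken,
#' and atoms are averaged within residues. The grand mean and standard
#' deviation across residues summarise overall mobility.
#'
#' @inheritParams c_rmsd
#' @param selection Atom indices or keyword; defaults to all atoms.
#' @param align Superpose frames to the average structure first (default);
#'   set `FALSE` to measure raw fluctuations in the lab frame.
#' @return A tibble `resid`, `rmsf` (angstrom) with attributes
#'   `atom_rmsf` (per-atom tibble), `grand_mean` and `grand_sd`.
#' @export
rmsf <- function(trajectory, topology = NULL, selection = NULL,
                 align = TRUE) {
  stopifnot(inherits(trajectory, "md_trajectory"))
  if (trajectory$n_frames < 2)
    abort("RMSF needs at least 2 frames")
  sel <- resolve_selection(selection, topology, trajectory$n_atoms)
  nf <- trajectory$n_frames
  frames <- lapply(seq_len(nf), function(f)
    frame_coords(trajectory, f)[sel, , drop = FALSE])
  if (align) {
    # two-pass: align to frame 1, form the mean, re-align to the mean
    ref <- frames[[1]]
    aligned <- lapply(frames, function(x) kabsch_superpose(x, ref)$transform(x))
    mean1 <- Reduce(`+`, aligned) / nf
    aligned <- lapply(frames, function(x) kabsch_superpose(x, mean1)$transform(x))
    frames <- aligned
  }
  mcoord <- Reduce(`+`, frames) / nf
  sq <- Reduce(`+`, lapply(frames, function(x) rowSums((x - mcoord)^2))) / nf
  atom_tbl <- tibble(atom = sel, rmsf = sqrt(sq))
  if (!is.null(topology)) {
    atom_tbl$resid <- topology$resid[sel]
  } else {
    atom_tbl$resid <- sel
  }
  res <- atom_tbl |>
    group_by(.data$resid) |>
    summarise(rmsf = mean(.data$rmsf), .groups = "drop")
  attr(res, "atom_rmsf") <- atom_tbl
  attr(res, "grand_mean") <- mean(res$rmsf)
  attr(res, "grand_sd") <- sd(res$rmsf)
  res
}

#' Interdomain centre-of-mass distance features
#'
#' For exactly four named regions, the mass-weighted centre-of-mass distance
#' of each of the six unordered region pairs is computed per frame. Column
#' order is fixed: pairs in the order given by `utils::combn` over the
#' region order supplied, named `"A|B"`.
#'
#' @param trajectory An `md_trajectory`.
#' @param topology An `md_topology` supplying masses and residue indices.
#' @param regions Named list of residue ranges; defaults to the topology's
#'   `regions` attribute. Exactly 4 non-empty regions are required.
#' @return A tibble with `frame` plus six distance columns (angstrom).
#' @export
interdomain_features <- function(trajectory, topology, regions = NULL) {
  stopifnot(inherits(trajectory, "md_trajectory"),
            inherits(topology, "md_topology"))
  regions <- regions %||% attr(topology, "regions")
  if (length(regions) != 4)
    abort(sprintf("exactly 4 regions are required (got %d)", length(regions)))
  idx <- lapply(regions, region_atoms, topology = topology)
  empty <- names(regions)[lengths(idx) == 0]
  if (length(empty) > 0)
    abort(paste("empty region(s):", paste(empty, collapse = ", ")))
  mass <- topology$mass
  if (is.null(mass) || all(mass == 0)) mass <- rep(1, nrow(topology))
  pairs <- utils::combn(names(regions), 2)
  out <- matrix(NA_real_, trajectory$n_frames, ncol(pairs))
  colnames(out) <- paste(pairs[1, ], pairs[2, ], sep = "|")
  for (f in seq_len(trajectory$n_frames)) {
    x <- frame_coords(trajectory, f)
    com <- vapply(idx, function(i)
      colSums(x[i, , drop = FALSE] * mass[i]) / sum(mass[i]), numeric(3))
    for (p in seq_len(ncol(pairs))) {
      out[f, p] <- sqrt(sum((com[, pairs[1, p]] - com[, pairs[2, p]])^2))
    }
  }
  bind_cols(tibble(frame = seq_len(trajectory$n_frames)), as_tibble(out))
}

#' Per-state summary of interdomain distances
#'
#' For each conformational state, the mean and standard deviation of three
#' selected distance pairs over the member frames, plus a "total average"
#' row per state: the mean of the three pair means (the usual table
#' convention), with its spread taken as the sample standard deviation of
#' those three means. States with no member frames are omitted with a
#' warning.
#'
#' @param features Output of [interdomain_features()] (or any tibble with a
#'   `frame` column and distance columns).
#' @param labels Integer state label per frame (NA = unassigned), or a
#'   tibble with columns `frame` and `label`/`state`.
#' @param pairs Character vector of exactly 3 distance column names.
#' @return A tibble: `state`, `pair`, `mean`, `sd`, including a
#'   `"total_average"` pair row per state.
#' @export
summarize_interdomain_by_state <- function(features, labels, pairs) {
  stopifnot(length(pairs) == 3, all(pairs %in% names(features)))
  if (is.data.frame(labels)) {
    lab_col <- intersect(c("label", "state"), names(labels))[1]
    labels <- labels[[lab_col]][match(features$frame, labels$frame)]
  }
  if (length(labels) != nrow(features))
    abort("labels must align with the feature frames")
  states <- sort(unique(labels[!is.na(labels)]))
  if (is.factor(labels)) states <- levels(labels)
  rows <- list()
  for (s in states) {
    m <- features[which(labels == s), pairs, drop = FALSE]
    if (nrow(m) == 0) {
      warn(sprintf("state %s has no member frames; omitted", s))
      next
    }
    mus <- unname(vapply(m, mean, numeric(1)))
    sds <- unname(vapply(m, function(v) if (length(v) > 1) sd(v) else 0,
                         numeric(1)))
    rows[[length(rows) + 1]] <- tibble(
      state = s, pair = c(pairs, "total_average"),
      mean = c(mus, mean(mus)),
      sd = c(sds, if (length(mus) > 1) sd(mus) else 0))
  }
  if (length(states) == 0)
    warn("no labelled frames; returning an empty summary")
  bind_rows(rows)
}
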