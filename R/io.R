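#' Topology and trajectory containers
#'
#' An `md_topology` is a tibble of per-atom records (serial, name, resid,
#' resname, charge, lj_sigma, lj_epsilon, mass, is_ligand) carrying a
#' `regions` attribute: a named list of inclusive 1-based residue-index
#' ranges. An `md_trajectory` wraps a frames x atoms x 3 coordinate array
#' in angstrom.
#'
#' @param atoms A data frame of per-atom records.
#' @param regions Named list; each element a length-2 inclusive residue range
#'   or a matrix of such ranges (rows).
#' @return `new_md_topology()` returns an `md_topology`;
#'   `new_md_trajectory()` an `md_trajectory`.
#' @export
new_md_topology <- function(atoms, regions = list()) {
  atoms <- as_tibble(atoms)
  req <- c("serial", "name", "resid", "resname")
  if (!all(req %in% names(atoms)))
    abort(paste("topology needs columns:", paste(req, collapse = ", ")))
  if (is.unsorted(atoms$resid))
    abort("residue indices must be non-decreasing")
  rng <- range(atoms$resid)
  for (nm in names(regions)) {
    r <- matrix(unlist(regions[[nm]]), ncol = 2, byrow = TRUE)
    if (any(r[, 1] > r[, 2]) || any(r < rng[1]) || any(r > rng[2]))
      abort(sprintf("region '%s' is outside residue bounds %d..%d",
                    nm, rng[1], rng[2]))
  }
  structure(atoms, regions = regions,
            class = c("md_topology", class(atoms)))
}

#' @param coords A frames x atoms x 3 numeric array (angstrom), or a single
#'   atoms x 3 matrix for a one-frame trajectory.
#' @param time Optional per-frame times (ps).
#' @rdname new_md_topology
#' @export
new_md_trajectory <- function(coords, time = NULL) {
  if (is.matrix(coords)) coords <- array(coords, c(1, dim(coords)))
  stopifnot(length(dim(coords)) == 3, dim(coords)[3] == 3)
  if (any(!is.finite(coords))) abort("trajectory coordinates must be finite")
  structure(list(coords = coords, time = time,
                 n_frames = dim(coords)[1], n_atoms = dim(coords)[2]),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("<md_trajectory: %d frames x %d atoms>\n", x$n_frames, x$n_atoms))
  invisible(x)
}

#' Extract one frame of a trajectory as an atoms x 3 matrix
#' @param trajectory An `md_trajectory`.
#' @param i Frame index.
#' @export
frame_coords <- function(trajectory, i) {
  stopifnot(inherits(trajectory, "md_trajectory"),
            i >= 1, i <= trajectory$n_frames)
  matrix(trajectory$coords[i, , ], ncol = 3)
}

#' Read a structure file into a topology and reference coordinates
#'
#' PDB files are parsed with bio3d; a JSON sidecar (same path with extension
#' `.json`) supplies charges and Lennard-Jones parameters when present.
#' Atoms are kept in file order and 1-based residue indexing is preserved
#' from the source.
#'
#' @param path Path to a PDB file.
#' @param sidecar Optional path to the charge/LJ sidecar JSON; defaults to
#'   `<path>.json` if that file exists.
#' @param regions Named list of residue-index ranges to attach.
#' @return A list with `topology` and `reference` (n x 3 matrix, A).
#' @export
read_structure <- function(path, sidecar = NULL, regions = list()) {
  if (!file.exists(path)) abort(paste("file not found:", path))
  if (file.size(path) == 0) abort(paste("empty structure file:", path))
  pdb <- tryCatch(bio3d::read.pdb(path),
                  error = function(e) abort(paste0("cannot parse ", path, ": ",
                                                   conditionMessage(e))))
  at <- pdb$atom
  topo <- tibble(
    serial = at$eleno, name = at$elety,
    resid = at$resno, resname = at$resid,
    charge = 0, lj_sigma = 0, lj_epsilon = 0, mass = 1,
    is_ligand = at$resid %in% c("LIG", "HET")
  )
  if (is.null(sidecar)) {
    cand <- paste0(path, ".json")
    if (file.exists(cand)) sidecar <- cand
  }
  if (!is.null(sidecar)) {
    sc <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    for (fld in c("charge", "lj_sigma", "lj_epsilon", "mass", "is_ligand")) {
      if (!is.null(sc[[fld]])) {
        if (length(sc[[fld]]) != nrow(topo))
          abort(sprintf("sidecar field '%s' has %d values for %d atoms",
                        fld, length(sc[[fld]]), nrow(topo)))
        topo[[fld]] <- sc[[fld]]
      }
    }
    if (!is.null(sc$regions) && length(regions) == 0)
      regions <- lapply(sc$regions, function(r) matrix(unlist(r), ncol = 2,
                                                       byrow = TRUE))
  }
  coords <- unname(cbind(at$x, at$y, at$z))
  list(topology = new_md_topology(topo, regions = regions),
       reference = coords)
}

#' Write a topology + reference structure as PDB with a JSON sidecar
#'
#' @param topology An `md_topology`.
#' @param reference n x 3 coordinate matrix (angstrom).
#' @param path Output PDB path; `<path>.json` receives charges, LJ
#'   parameters, masses, the ligand flag and the region definitions.
#' @return `path`, invisibly.
#' @export
write_structure <- function(topology, reference, path) {
  stopifnot(inherits(topology, "md_topology"),
            nrow(reference) == nrow(topology))
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(reference)),
                   resno = topology$resid,
                   resid = topology$resname,
                   eleno = topology$serial,
                   elety = topology$name)
  side <- list(charge = topology$charge, lj_sigma = topology$lj_sigma,
               lj_epsilon = topology$lj_epsilon, mass = topology$mass,
               is_ligand = topology$is_ligand,
               regions = attr(topology, "regions"),
               seed = attr(topology, "seed"))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read and write multi-frame XYZ trajectories
#'
#' Plain XYZ blocks: atom count line, comment line, then `name x y z` rows,
#' repeated per frame; coordinates in angstrom.
#'
#' @param path File path.
#' @return `read_xyz_trajectory()` returns an `md_trajectory`.
#' @export
read_xyz_trajectory <- function(path) {
  if (!file.exists(path)) abort(paste("file not found:", path))
  lines <- readLines(path)
  if (length(lines) == 0) abort(paste("empty trajectory file:", path))
  frames <- list()
  i <- 1
  while (i <= length(lines)) {
    if (!grepl("^\\s*\\d+\\s*$", lines[i]))
      abort(sprintf("malformed XYZ at line %d: expected atom count", i))
    nat <- as.integer(lines[i])
    if (i + 1 + nat > length(lines))
      abort(sprintf("truncated XYZ frame starting at line %d", i))
    block <- lines[(i + 2):(i + 1 + nat)]
    parts <- strsplit(trimws(block), "\\s+")
    if (any(lengths(parts) < 4))
      abort(sprintf("malformed XYZ atom record near line %d", i + 2))
    xyz <- suppressWarnings(
      t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3))))
    if (any(is.na(xyz)))
      abort(sprintf("non-numeric coordinates in frame starting at line %d", i))
    frames[[length(frames) + 1]] <- xyz
    i <- i + 2 + nat
  }
  nat <- nrow(frames[[1]])
  if (!all(vapply(frames, nrow, 1L) == nat))
    abort("inconsistent atom count across XYZ frames")
  coords <- array(NA_real_, c(length(frames), nat, 3))
  for (f in seq_along(frames)) coords[f, , ] <- frames[[f]]
  new_md_trajectory(coords)
}

#' @param trajectory An `md_trajectory`.
#' @param names Optional atom names (defaults to "C").
#' @rdname read_xyz_trajectory
#' @export
write_xyz_trajectory <- function(trajectory, path, names = NULL) {
  stopifnot(inherits(trajectory, "md_trajectory"))
  if (is.null(names)) names <- rep("C", trajectory$n_atoms)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(trajectory$n_frames)) {
    xyz <- frame_coords(trajectory, f)
    writeLines(c(as.character(trajectory$n_atoms),
                 sprintf("frame %d", f),
                 sprintf("%s %.6f %.6f %.6f", names, xyz[, 1], xyz[, 2],
                         xyz[, 3])), con)
  }
  invisible(path)
}

#' Read a DCD trajectory (X-PLOR/CHARMM dialect)
#'
#' Thin wrapper over [bio3d::read.dcd()]; big-endian or otherwise
#' non-conforming files surface as a parse error.
#'
#' @param path File path.
#' @return An `md_trajectory`.
#' @export
read_dcd_trajectory <- function(path) {
  if (!file.exists(path)) abort(paste("file not found:", path))
  m <- tryCatch(bio3d::read.dcd(path, verbose = FALSE),
                error = function(e)
                  abort(paste0("cannot read DCD (expected little-endian ",
                               "X-PLOR/CHARMM layout): ", conditionMessage(e))))
  nat <- ncol(m) / 3
  coords <- array(NA_real_, c(nrow(m), nat, 3))
  for (f in seq_len(nrow(m))) coords[f, , ] <- matrix(m[f, ], ncol = 3,
                                                      byrow = TRUE)
  new_md_trajectory(coords)
}

#' Read region definitions from YAML
#'
#' Expected layout: `name: [[start, end], ...]` with 1-based inclusive
#' residue ranges.
#'
#' @param path YAML file path.
#' @return Named list of range matrices.
#' @export
read_regions_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  lapply(y, function(r) matrix(unlist(r), ncol = 2, byrow = TRUE))
}

# residue-region -> atom indices
region_atoms <- function(topology, region) {
  r <- matrix(unlist(region), ncol = 2, byrow = TRUE)
  keep <- rep(FALSE, nrow(topology))
  for (i in seq_len(nrow(r)))
    keep <- keep | (topology$resid >= r[i, 1] & topology$resid <= r[i, 2])
  which(keep)
}
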