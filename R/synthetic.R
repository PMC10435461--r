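#' Specify a multi-well 2-D potential
#'
#' Defines the collective-variable energy surface used by the Brownian
#' sampler as a smooth blend (soft minimum) of parabolic basins,
#' \eqn{U(x) = -\epsilon \log \sum_i \exp(-V_i(x)/\epsilon)} with
#' \eqn{V_i(x) = -d_i + k_i |x - c_i|^2 / 2}, where \eqn{d_i} is the well
#' depth (kcal/mol), \eqn{k_i = d_i / w_i^2} the basin stiffness implied by
#' the width \eqn{w_i}, and \eqn{\epsilon} = 0.2 kcal/mol a fixed seam
#' smoothing. Each basin is exactly harmonic away from the seams, the
#' landscape grows quadratically far from all wells (global confinement),
#' and for equal-stiffness wells the basin free-energy gap equals the depth
#' gap.
#'
#' @param wells A data frame with columns `cx`, `cy` (well centre, CV units),
#'   `depth` (kcal/mol, > 0) and `width` (CV units, > 0); one row per well.
#' @param temperature Simulation temperature in kelvin.
#' @return An object of class `potential_spec`.
#' @export
#' @examples
#' potential_spec(data.frame(cx = 0, cy = 0, depth = 20, width = 1))
potential_spec <- function(wells, temperature = 300) {
  wells <- as_tibble(wells)
  stopifnot(all(c("cx", "cy", "depth", "width") %in% names(wells)))
  if (nrow(wells) < 1) abort("at least one well is required")
  if (any(wells$depth <= 0)) abort("well depths must be positive")
  if (any(wells$width <= 0)) abort("well widths must be positive")
  if (temperature < 0) abort("temperature must be non-negative")
  structure(list(wells = wells, temperature = temperature),
            class = "potential_spec")
}

#' Parameters for the overdamped Langevin (Brownian) integrator
#'
#' @param dt Time step in reduced units (> 0).
#' @param friction Friction coefficient, 1/time (> 0).
#' @param n_steps Number of steps to integrate (>= 1).
#' @param seed Integer seed; identical seeds give bit-identical trajectories.
#' @return An object of class `langevin_params`.
#' @export
langevin_params <- function(dt = 1e-3, friction = 1, n_steps = 10000,
                            seed = 20230817) {
  if (dt <= 0) abort("dt must be positive")
  if (friction <= 0) abort("friction must be positive")
  if (n_steps < 1) abort("n_steps must be >= 1")
  structure(list(dt = dt, friction = friction,
                 n_steps = as.integer(n_steps), seed = as.integer(seed)),
            class = "langevin_params")
}

# potential energy and gradient of the soft-min parabolic-well surface
# x: n x 2 matrix -> list(U = n vector, grad = n x 2)
well_potential <- function(potential, x, eps = 0.2) {
  w <- potential$wells
  n <- nrow(x)
  nw <- nrow(w)
  V <- matrix(NA_real_, n, nw)
  for (i in seq_len(nw)) {
    k <- w$depth[i] / w$width[i]^2
    V[, i] <- -w$depth[i] +
      0.5 * k * ((x[, 1] - w$cx[i])^2 + (x[, 2] - w$cy[i])^2)
  }
  vmin <- do.call(pmin, as.data.frame(V))
  ex <- exp(-(V - vmin) / eps)
  Z <- rowSums(ex)
  U <- vmin - eps * log(Z)
  lam <- ex / Z                       # softmax basin weights
  gx <- numeric(n); gy <- numeric(n)
  for (i in seq_len(nw)) {
    k <- w$depth[i] / w$width[i]^2
    gx <- gx + lam[, i] * k * (x[, 1] - w$cx[i])
    gy <- gy + lam[, i] * k * (x[, 2] - w$cy[i])
  }
  list(U = U, grad = cbind(gx, gy))
}

#' Sample a 2-D potential with overdamped Langevin dynamics
#'
#' Euler--Maruyama integration of Brownian dynamics,
#' \eqn{x_{t+1} = x_t - (\Delta t/\gamma)\nabla U + \sqrt{2 k_B T \Delta t/\gamma}\,\xi},
#' whose long-run histogram converges to the Boltzmann distribution of the
#' well system at the spec temperature. Used as ground-truth sampling for
#' free-energy landscape recovery.
#'
#' @param potential A [potential_spec()].
#' @param params A [langevin_params()].
#' @param x0 Optional starting point (length-2 numeric); defaults to the
#'   centre of the deepest well.
#' @return A tibble with columns `step`, `x`, `y`.
#' @export
#' @examples
#' pot <- potential_spec(data.frame(cx = 0, cy = 0, depth = 20, width = 1))
#' head(simulate_langevin_2d(pot, langevin_params(n_steps = 100, seed = 1)))
simulate_langevin_2d <- function(potential, params, x0 = NULL) {
  stopifnot(inherits(potential, "potential_spec"),
            inherits(params, "langevin_params"))
  if (is.null(x0)) {
    i <- which.max(potential$wells$depth)
    x0 <- c(potential$wells$cx[i], potential$wells$cy[i])
  }
  n <- params$n_steps
  kT <- md_constants$kB * potential$temperature
  step_len <- params$dt / params$friction
  noise_sd <- sqrt(2 * kT * step_len)
  out <- matrix(NA_real_, n, 2)
  withr::with_seed(params$seed, {
    noise <- matrix(rnorm(2L * n, sd = noise_sd), n, 2)
    x <- matrix(x0, 1, 2)
    for (t in seq_len(n)) {
      g <- well_potential(potential, x)$grad
      if (any(!is.finite(g))) {
        abort(sprintf("non-finite force at step %d (position %.3g, %.3g)",
                      t, x[1], x[2]))
      }
      x <- x - step_len * g + noise[t, , drop = FALSE]
      out[t, ] <- x
    }
  })
  tibble(step = seq_len(n), x = out[, 1], y = out[, 2])
}

#' Specify a toy charged bead complex
#'
#' Describes a coarse bead "protein" (a compact random-walk chain of
#' residues, several beads each) plus a planar 4-coordinate metal--ligand
#' mimic: one metal bead, four donor beads at 90 degrees in a plane, and a
#' ring of peripheral beads, echoing a distorted square-planar
#' bis-chelate complex at bead resolution.
#'
#' @param n_residues Number of protein residues.
#' @param atoms_per_residue Beads per residue.
#' @param charge_scale Charge magnitude scale in e; 0 gives a neutral system.
#' @param lj_sigma_range Length-2 range of Lennard-Jones sigma, angstrom.
#' @param lj_epsilon_range Length-2 range of Lennard-Jones epsilon, kcal/mol.
#' @param ligand_spec List with `donor_distance` (A, metal-donor bond),
#'   `n_ring_beads` (peripheral beads) and `ring_radius` (A).
#' @param seed Integer seed; regeneration with the same seed is bit-identical.
#' @return An object of class `toy_complex_spec`.
#' @export
toy_complex_spec <- function(n_residues = 20, atoms_per_residue = 3,
                             charge_scale = 0.4,
                             lj_sigma_range = c(2.5, 3.5),
                             lj_epsilon_range = c(0.05, 0.2),
                             ligand_spec = list(donor_distance = 2.2,
                                                n_ring_beads = 8,
                                                ring_radius = 3.5),
                             seed = 20230817) {
  stopifnot(n_residues >= 1, atoms_per_residue >= 1,
            charge_scale >= 0, length(lj_sigma_range) == 2,
            length(lj_epsilon_range) == 2)
  structure(list(n_residues = as.integer(n_residues),
                 atoms_per_residue = as.integer(atoms_per_residue),
                 charge_scale = charge_scale,
                 lj_sigma_range = lj_sigma_range,
                 lj_epsilon_range = lj_epsilon_range,
                 ligand_spec = ligand_spec,
                 seed = as.integer(seed)),
            class = "toy_complex_spec")
}

#' Build a toy bead complex topology and reference structure
#'
#' Generates per-atom charges, Lennard-Jones parameters, masses and residue
#' assignments for the bead protein and the planar metal--ligand mimic of a
#' [toy_complex_spec()]. Beads closer than 0.5 angstrom are rejected and the
#' placement resampled (error after 100 attempts). Deterministic under the
#' spec seed; the total system charge is reported as an attribute.
#'
#' @param spec A [toy_complex_spec()].
#' @return A list with `topology` (an `md_topology` tibble: serial, name,
#'   resid, resname, charge, lj_sigma, lj_epsilon, mass, is_ligand, with a
#'   `regions` attribute) and `reference` (n x 3 coordinate matrix, A).
#' @export
#' @examples
#' sys <- build_toy_complex(toy_complex_spec(n_residues = 5, seed = 1))
#' nrow(sys$topology)
build_toy_complex <- function(spec) {
  stopifnot(inherits(spec, "toy_complex_spec"))
  withr::with_seed(spec$seed, {
    n_prot <- spec$n_residues * spec$atoms_per_residue
    for (try in seq_len(100)) {
      # compact residue backbone: random walk with 3.8 A steps
      steps <- matrix(rnorm(3L * spec$n_residues), ncol = 3)
      steps <- steps / sqrt(rowSums(steps^2)) * 3.8
      centers <- apply(steps, 2, cumsum)
      if (spec$n_residues == 1) centers <- matrix(steps, 1, 3)
      # gentle pull towards the centroid keeps the chain globular
      centers <- sweep(centers, 2, colMeans(centers))
      centers <- centers * 0.8
      atoms <- centers[rep(seq_len(spec$n_residues),
                           each = spec$atoms_per_residue), , drop = FALSE] +
        matrix(rnorm(3L * n_prot, sd = 0.8), ncol = 3)
      if (n_prot < 2 || min(dist(atoms)) >= 0.5) break
      if (try == 100) abort("could not place beads without overlap in 100 tries")
    }
    # planar metal-ligand mimic, offset from the protein surface
    lig_origin <- c(max(atoms[, 1]) + 6, 0, 0)
    dd <- spec$ligand_spec$donor_distance
    donors <- rbind(c(dd, 0, 0), c(0, dd, 0), c(-dd, 0, 0), c(0, -dd, 0))
    nr <- spec$ligand_spec$n_ring_beads
    ang <- 2 * pi * (seq_len(nr) - 1) / nr
    ring <- cbind(spec$ligand_spec$ring_radius * cos(ang),
                  spec$ligand_spec$ring_radius * sin(ang), 0)
    lig <- sweep(rbind(c(0, 0, 0), donors, ring), 2, lig_origin, "+")
    coords <- rbind(atoms, lig)
    n_lig <- nrow(lig)
    n_all <- n_prot + n_lig

    charge <- c(runif(n_prot, -1, 1) * spec$charge_scale,
                # metal positive, donors negative, ring mildly charged
                2 * spec$charge_scale,
                rep(-0.6 * spec$charge_scale, 4),
                runif(nr, -0.2, 0.2) * spec$charge_scale)
    lj_sigma <- c(runif(n_prot, spec$lj_sigma_range[1], spec$lj_sigma_range[2]),
                  2.0, rep(3.0, 4),
                  runif(nr, spec$lj_sigma_range[1], spec$lj_sigma_range[2]))
    lj_eps <- c(runif(n_prot, spec$lj_epsilon_range[1], spec$lj_epsilon_range[2]),
                0.1, rep(0.2, 4),
                runif(nr, spec$lj_epsilon_range[1], spec$lj_epsilon_range[2]))
  })

  topology <- tibble(
    serial = seq_len(n_prot + n_lig),
    name = c(rep(c("CA", paste0("B", seq_len(max(spec$atoms_per_residue - 1, 0))))[
      seq_len(spec$atoms_per_residue)], spec$n_residues),
      "M", paste0("D", 1:4), paste0("R", seq_len(n_lig - 5))),
    resid = c(rep(seq_len(spec$n_residues), each = spec$atoms_per_residue),
              rep(spec$n_residues + 1L, n_lig)),
    resname = c(rep("BEA", n_prot), rep("LIG", n_lig)),
    charge = charge,
    lj_sigma = lj_sigma,
    lj_epsilon = lj_eps,
    mass = c(rep(12, n_prot), 58.7, rep(32.1, 4), rep(12, n_lig - 5)),
    is_ligand = c(rep(FALSE, n_prot), rep(TRUE, n_lig))
  )
  q <- spec$n_residues
  regions <- list(core = c(1L, max(1L, q %/% 4L)),
                  phe_cluster = c(q %/% 4L + 1L, max(q %/% 2L, q %/% 4L + 1L)),
                  beta_domain = c(q %/% 2L + 1L, max(3L * q %/% 4L, q %/% 2L + 1L)),
                  bb_loop = c(3L * q %/% 4L + 1L, q))
  topo <- new_md_topology(topology, regions = regions)
  attr(topo, "total_charge") <- sum(charge)
  attr(topo, "seed") <- spec$seed
  list(topology = topo, reference = unname(coords))
}

#' Simulate a metastable toy trajectory with known state structure
#'
#' Frames fluctuate harmonically (Gaussian displacements at the equilibrium
#' amplitude) about a set of anchor structures, while the active anchor
#' switches by a discrete Markov jump process whose stationary distribution
#' equals `weights`. True per-frame state labels are returned alongside, so
#' downstream clustering can be scored against exact ground truth.
#'
#' @param topology An `md_topology` (atom count must match the anchors).
#' @param anchors List of n x 3 coordinate matrices, one per metastable state.
#' @param weights Stationary state probabilities; must sum to 1.
#' @param params A [langevin_params()]; `n_steps` frames are generated and
#'   `seed` fixes the realisation.
#' @param noise_sd Isotropic per-atom fluctuation amplitude, angstrom.
#' @param switch_prob Per-frame probability of redrawing the state from
#'   `weights` (jump-process mixing rate).
#' @return A list with `trajectory` (an `md_trajectory`) and `labels`
#'   (tibble: frame, label).
#' @export
simulate_toy_trajectory <- function(topology, anchors, weights, params,
                                    noise_sd = 0.3, switch_prob = 0.05) {
  stopifnot(inherits(params, "langevin_params"), length(anchors) >= 1)
  if (abs(sum(weights) - 1) > 1e-8) abort("weights must sum to 1")
  if (length(weights) != length(anchors))
    abort("one weight per anchor is required")
  n_atoms <- nrow(anchors[[1]])
  if (!all(vapply(anchors, nrow, 1L) == n_atoms))
    abort("all anchors must share an atom count")
  if (!is.null(topology) && nrow(topology) != n_atoms)
    abort(sprintf("topology has %d atoms but anchors have %d",
                  nrow(topology), n_atoms))
  n <- params$n_steps
  withr::with_seed(params$seed, {
    labels <- integer(n)
    labels[1] <- sample.int(length(weights), 1, prob = weights)
    if (n > 1) {
      jump <- runif(n - 1) < switch_prob
      draws <- sample.int(length(weights), n - 1, replace = TRUE, prob = weights)
      for (t in 2:n) labels[t] <- if (jump[t - 1]) draws[t - 1] else labels[t - 1]
    }
    coords <- array(NA_real_, c(n, n_atoms, 3))
    for (t in seq_len(n)) {
      coords[t, , ] <- anchors[[labels[t]]] +
        if (noise_sd > 0) matrix(rnorm(3L * n_atoms, sd = noise_sd),
                                 n_atoms, 3) else 0
    }
  })
  list(trajectory = new_md_trajectory(coords),
       labels = tibble(frame = seq_len(n), label = labels))
}
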