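# shared fixture builders and independent oracles

kT300 <- 0.0019872041 * 300

euler_rotation <- function(a, b, c) {
  rz <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3,
               byrow = TRUE)
  ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3, 3,
               byrow = TRUE)
  rx <- matrix(c(1, 0, 0, 0, cos(c), -sin(c), 0, sin(c), cos(c)), 3, 3,
               byrow = TRUE)
  rz %*% ry %*% rx
}

random_rotation <- function() {
  euler_rotation(runif(1, 0, 2 * pi), runif(1, 0, pi), runif(1, 0, 2 * pi))
}

# independent oracle: minimum RMSD over rotations by multi-start optimisation
# of an Euler-angle parameterisation (centroids matched analytically)
brute_force_rmsd <- function(mobile, reference) {
  m0 <- sweep(mobile, 2, colMeans(mobile))
  r0 <- sweep(reference, 2, colMeans(reference))
  f <- function(ang) {
    R <- euler_rotation(ang[1], ang[2], ang[3])
    sqrt(mean(rowSums((m0 %*% t(R) - r0)^2)))
  }
  best <- Inf
  for (s in seq_len(24)) {
    st <- runif(3, 0, 2 * pi)
    o <- optim(st, f, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-14))
    o <- optim(o$par, f, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
    best <- min(best, o$value)
  }
  best
}

# small topology: n residues x m beads, unit masses, no ligand
tiny_topology <- function(n_res = 4, per_res = 2, regions = list()) {
  n <- n_res * per_res
  new_md_topology(tibble::tibble(
    serial = seq_len(n), name = rep(c("CA", "CB")[seq_len(per_res)], n_res),
    resid = rep(seq_len(n_res), each = per_res),
    resname = "ALA", charge = 0, lj_sigma = 3, lj_epsilon = 0.1,
    mass = 1, is_ligand = FALSE), regions = regions)
}

# direct all-pairs reference implementations (no cutoff)
oracle_coulomb <- function(coords, charges, ga, gb) {
  e <- 0
  for (i in ga) for (j in gb) {
    r <- sqrt(sum((coords[i, ] - coords[j, ])^2))
    e <- e + 332.0637 * charges[i] * charges[j] / r
  }
  e
}

oracle_lj <- function(coords, sig, eps, ga, gb) {
  e <- 0
  for (i in ga) for (j in gb) {
    r <- sqrt(sum((coords[i, ] - coords[j, ])^2))
    s <- (sig[i] + sig[j]) / 2
    ee <- sqrt(eps[i] * eps[j])
    e <- e + 4 * ee * ((s / r)^12 - (s / r)^6)
  }
  e
}

oracle_field <- function(coords, charges, point, excl = integer(0)) {
  f <- c(0, 0, 0)
  for (i in setdiff(seq_len(nrow(coords)), excl)) {
    d <- point - coords[i, ]
    r <- sqrt(sum(d^2))
    f <- f + 1439.964 * charges[i] * d / r^3
  }
  f
}
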