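test_that("a unit point charge at 1 A produces the reference field", {
  f <- field_at_point(rbind(c(1, 0, 0)), 1, c(0, 0, 0))
  expect_equal(f, c(-1439.964, 0, 0))     # points away from the charge
  expect_equal(sqrt(sum(f^2)), 1439.964)
})

test_that("fields superpose and vanish by symmetry", {
  sym <- rbind(c(1, 0, 0), c(-1, 0, 0))
  expect_equal(field_at_point(sym, c(1, 1), c(0, 0, 0)), c(0, 0, 0),
               tolerance = 1e-12)
  set.seed(50)
  a <- matrix(runif(30, -5, 5), 10, 3)
  b <- matrix(runif(15, -5, 5), 5, 3)
  qa <- runif(10, -1, 1); qb <- runif(5, -1, 1)
  expect_equal(field_at_point(rbind(a, b), c(qa, qb), c(0.3, 0.1, -0.2)),
               field_at_point(a, qa, c(0.3, 0.1, -0.2)) +
                 field_at_point(b, qb, c(0.3, 0.1, -0.2)),
               tolerance = 1e-9)
})

test_that("field evaluation matches the brute-force oracle on large systems", {
  set.seed(51)
  coords <- matrix(runif(300, -8, 8), 100, 3)
  q <- runif(100, -1, 1)
  p <- c(0.5, -0.3, 0.2)
  excl <- c(3L, 40L)
  expect_equal(field_at_point(coords, q, p, exclusions = excl),
               oracle_field(coords, q, p, excl), tolerance = 1e-9)
  # linearity: doubling the charges doubles the field
  expect_equal(field_at_point(coords, 2 * q, p),
               2 * field_at_point(coords, q, p), tolerance = 1e-9)
})

test_that("near-singular evaluation points are rejected", {
  expect_error(field_at_point(rbind(c(0.01, 0, 0)), 1, c(0, 0, 0)),
               "singularity")
  expect_error(field_at_point(rbind(c(1, 0, 0)), 1, c(NA, 0, 0)), "finite")
})

test_that("projection onto the bond axis is a signed dot product", {
  expect_identical(project_field(c(0, 5, 0), c(1, 0, 0)), 0)
  expect_identical(project_field(c(10, 0, 0), c(2, 0, 0)), 10)
  expect_identical(project_field(c(3, 4, 0), c(1, 0, 0)), 3)
  expect_error(project_field(c(1, 1, 1), c(0, 0, 0)), "zero-length")
})

test_that("per-residue decomposition is exact and handles the static case", {
  # one protein residue with a +1 e atom 1 A beyond atom j along the bond
  topo <- new_md_topology(tibble::tibble(
    serial = 1:3, name = c("S", "M", "Q"), resid = c(1L, 2L, 3L),
    resname = c("CYS", "LIG", "ARG"), charge = c(0, 0, 1),
    lj_sigma = 3, lj_epsilon = 0.1, mass = 1,
    is_ligand = c(FALSE, TRUE, FALSE)))
  coords <- rbind(c(-1, 0, 0), c(1, 0, 0), c(1, 0, 0) + c(1, 0, 0))
  # probe midpoint is the origin; source at distance 2 gives K/4 projected
  tr <- new_md_trajectory(array(rep(coords, each = 3), c(3, 3, 3)))
  prof <- per_residue_efield(tr, topo, bond_probe(1, 2))
  expect_identical(nrow(prof), 1L)      # probe atoms and ligand excluded
  expect_equal(prof$mean, -1439.964 / 4)
  expect_identical(prof$sd, 0)
})

test_that("residue contributions sum to the total included field each frame", {
  sys <- build_toy_complex(toy_complex_spec(n_residues = 6, seed = 52))
  tr <- simulate_toy_trajectory(sys$topology,
                                list(sys$reference, sys$reference + 1),
                                c(0.6, 0.4),
                                langevin_params(n_steps = 4, seed = 53),
                                noise_sd = 0.2)
  metal <- which(sys$topology$name == "M")
  donor <- which(sys$topology$name == "D1")
  probe <- bond_probe(donor, metal)
  prof <- per_residue_efield(tr$trajectory, sys$topology, probe,
                             keep_matrix = TRUE)
  proj <- attr(prof, "projections")
  excl <- union(c(donor, metal), which(sys$topology$is_ligand))
  for (f in 1:4) {
    x <- frame_coords(tr$trajectory, f)
    point <- (x[donor, ] + x[metal, ]) / 2
    total <- field_at_point(x, sys$topology$charge, point, exclusions = excl)
    expect_equal(sum(proj[, f]),
                 project_field(total, x[metal, ] - x[donor, ]),
                 tolerance = 1e-9)
  }
  # doubling the charges doubles every projection
  topo2 <- sys$topology
  topo2$charge <- 2 * topo2$charge
  prof2 <- per_residue_efield(tr$trajectory, topo2, probe)
  expect_equal(prof2$mean, 2 * prof$mean, tolerance = 1e-9)
})

test_that("projected fields are invariant under a global rotation", {
  sys <- build_toy_complex(toy_complex_spec(n_residues = 5, seed = 54))
  metal <- which(sys$topology$name == "M")
  donor <- which(sys$topology$name == "D1")
  tr1 <- new_md_trajectory(sys$reference)
  set.seed(55)
  R <- random_rotation()
  tr2 <- new_md_trajectory(sys$reference %*% t(R) + 3)
  p1 <- per_residue_efield(tr1, sys$topology, bond_probe(donor, metal))
  p2 <- per_residue_efield(tr2, sys$topology, bond_probe(donor, metal))
  expect_equal(p1$mean, p2$mean, tolerance = 1e-9)
})

test_that("all-zero charges give a null profile", {
  sys <- build_toy_complex(toy_complex_spec(n_residues = 4, charge_scale = 0,
                                            seed = 56))
  metal <- which(sys$topology$name == "M")
  donor <- which(sys$topology$name == "D1")
  prof <- per_residue_efield(new_md_trajectory(sys$reference), sys$topology,
                             bond_probe(donor, metal))
  expect_true(all(prof$mean == 0))
  expect_true(all(prof$sd == 0))
})

test_that("residue ranking filters, sorts and totals significant fields", {
  prof <- tibble::tibble(resid = 1:3, mean = c(13, 9.5, 3), sd = 0)
  r <- rank_residues(prof, threshold = 7.5)
  expect_identical(r$mean, c(13, 9.5))
  expect_equal(attr(r, "total_ef"), 22.5)
  low <- rank_residues(tibble::tibble(resid = 1:2, mean = c(1, 2), sd = 0),
                       threshold = 7.5)
  expect_identical(nrow(low), 0L)
  all_in <- rank_residues(prof, threshold = 0)
  expect_identical(nrow(all_in), 3L)
  expect_equal(attr(all_in, "total_ef"), sum(prof$mean))
})
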