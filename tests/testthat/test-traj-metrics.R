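test_that("Kabsch superposition recovers rigid motions exactly", {
  set.seed(10)
  ref <- matrix(rnorm(15), 5, 3)
  sp0 <- kabsch_superpose(ref, ref)
  expect_equal(sp0$rotation, diag(3), tolerance = 1e-12)
  expect_equal(sp0$translation, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(sp0$rmsd_after, 0, tolerance = 1e-12)
  R <- euler_rotation(pi / 2, 0, 0)
  mob <- ref %*% t(R) + matrix(c(3, -1, 7), 5, 3, byrow = TRUE)
  sp <- kabsch_superpose(mob, ref)
  expect_lt(sp$rmsd_after, 1e-10)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-9)
})

test_that("Kabsch matches a rotational-search oracle on small noisy sets", {
  set.seed(11)
  for (case in 1:3) {
    n <- sample(4:6, 1)
    ref <- matrix(rnorm(3 * n, sd = 2), n, 3)
    mob <- ref %*% t(random_rotation()) +
      matrix(rnorm(3 * n, sd = 0.3), n, 3) + 1.5
    expect_equal(kabsch_superpose(mob, ref)$rmsd_after,
                 brute_force_rmsd(mob, ref), tolerance = 1e-6)
  }
})

test_that("degenerate superposition inputs are rejected", {
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line + 1), "collinear")
  expect_error(kabsch_superpose(line[1:2, ], line[1:2, ]), "3 points")
})

test_that("cRMSD is zero for copies and rigid motions of the reference", {
  set.seed(12)
  ref <- matrix(rnorm(30), 10, 3)
  frames <- array(NA_real_, c(3, 10, 3))
  frames[1, , ] <- ref
  frames[2, , ] <- ref + 1          # uniform displacement
  frames[3, , ] <- ref %*% t(random_rotation()) - 2
  tr <- new_md_trajectory(frames)
  r <- c_rmsd(tr, ref, selection = 1:10)
  expect_equal(r$rmsd, c(0, 0, 0), tolerance = 1e-9)
})

test_that("cRMSD equals the brute-force minimum for a perturbed frame", {
  ref <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0), c(0, 0, 2))
  frame <- ref + rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(0.5, -0.5, 0))
  tr <- new_md_trajectory(frame)
  got <- c_rmsd(tr, ref, selection = 1:4)$rmsd
  set.seed(13)
  expect_equal(got, brute_force_rmsd(frame, ref), tolerance = 1e-6)
})

test_that("cRMSD and RMSF are invariant to a rigid transform of all frames", {
  set.seed(14)
  base <- array(rnorm(5 * 8 * 3), c(5, 8, 3))
  ref <- matrix(base[1, , ], ncol = 3)
  tr1 <- new_md_trajectory(base)
  R <- random_rotation()
  moved <- base
  for (f in 1:5) moved[f, , ] <- matrix(base[f, , ], ncol = 3) %*% t(R) + 4
  tr2 <- new_md_trajectory(moved)
  expect_equal(c_rmsd(tr1, ref, selection = 1:8)$rmsd,
               c_rmsd(tr2, ref %*% t(R) + 4, selection = 1:8)$rmsd,
               tolerance = 1e-9)
  expect_equal(rmsf(tr1, selection = 1:8)$rmsf,
               rmsf(tr2, selection = 1:8)$rmsf, tolerance = 1e-9)
})

test_that("dRMSD is invariant to per-frame rigid motions and scales with dilation", {
  set.seed(15)
  ref <- matrix(rnorm(18), 6, 3)
  frames <- array(NA_real_, c(2, 6, 3))
  frames[1, , ] <- ref %*% t(random_rotation()) + 3
  frames[2, , ] <- ref %*% t(random_rotation()) - 1
  r <- d_rmsd(new_md_trajectory(frames), ref, selection = 1:6)
  expect_equal(r$drmsd, c(0, 0), tolerance = 1e-9)
  # doubling a unit equilateral triangle grows every pair distance by 1 A
  tri <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0))
  r2 <- d_rmsd(new_md_trajectory(2 * tri), tri, selection = 1:3)
  expect_equal(r2$drmsd, 1)
  expect_error(d_rmsd(new_md_trajectory(tri), tri, selection = 1),
               "at least 2")
})

test_that("RMSF matches its definition and summarises consistently", {
  # static trajectory: all zeros
  ref <- matrix(rnorm(12), 4, 3)
  static <- new_md_trajectory(array(rep(ref, each = 3), c(3, 4, 3)))
  expect_equal(rmsf(static, selection = 1:4)$rmsf, rep(0, 4),
               tolerance = 1e-12)
  # one atom oscillating +/- 1 A along x, alignment off
  frames <- array(0, c(2, 4, 3))
  frames[, 2, ] <- 5                    # anchor atoms elsewhere
  frames[, 3, 2] <- c(0, 9)
  frames[1, 1, 1] <- -1
  frames[2, 1, 1] <- 1
  r <- rmsf(new_md_trajectory(frames), align = FALSE)
  expect_equal(r$rmsf[1], 1)
  expect_equal(attr(r, "grand_mean"), mean(r$rmsf))
  expect_error(rmsf(new_md_trajectory(ref)), "2 frames")
})

test_that("interdomain distances are mass-weighted COM separations", {
  topo <- tiny_topology(n_res = 4, per_res = 2,
                        regions = list(a = c(1, 1), b = c(2, 2),
                                       c = c(3, 3), d = c(4, 4)))
  coords <- matrix(0, 8, 3)
  coords[3:4, 1] <- 5                   # region b at x = 5
  coords[5:6, 2] <- 3
  coords[7:8, 3] <- 4
  tr <- new_md_trajectory(coords)
  f <- interdomain_features(tr, topo)
  expect_identical(ncol(f), 7L)         # frame + 6 pairs
  expect_equal(f[["a|b"]], 5)
  expect_equal(f[["a|c"]], 3)
  expect_equal(f[["b|c"]], sqrt(25 + 9))
  # duplicated region -> zero distance
  topo2 <- tiny_topology(n_res = 4, per_res = 2,
                         regions = list(a = c(1, 1), a2 = c(1, 1),
                                        c = c(3, 3), d = c(4, 4)))
  expect_equal(interdomain_features(tr, topo2)[["a|a2"]], 0)
  # unequal masses shift the COM
  topo3 <- tiny_topology(n_res = 4, per_res = 2,
                         regions = list(a = c(1, 1), b = c(2, 2),
                                        c = c(3, 3), d = c(4, 4)))
  topo3$mass <- c(3, 1, 1, 1, 1, 1, 1, 1)
  coords2 <- coords
  coords2[1, 1] <- -4                   # heavy atom pulls region a
  com_a <- (3 * -4 + 1 * 0) / 4
  expect_equal(interdomain_features(new_md_trajectory(coords2),
                                    topo3)[["a|b"]], 5 - com_a)
})

test_that("region bookkeeping rejects bad definitions", {
  expect_error(tiny_topology(regions = list(a = c(1, 9))), "outside")
  topo <- tiny_topology(n_res = 4, per_res = 2,
                        regions = list(a = c(1, 1), b = c(2, 2),
                                       c = c(3, 3)))
  tr <- new_md_trajectory(matrix(0, 8, 3))
  expect_error(interdomain_features(tr, topo), "exactly 4")
})

test_that("per-state interdomain summary follows the total-average convention", {
  # two states with constant distances: sd 0, totals = mean of pair means
  f <- tibble::tibble(frame = 1:4,
                      p1 = c(17.2, 17.2, 20.4, 20.4),
                      p2 = c(19.7, 19.7, 20.2, 20.2),
                      p3 = c(24.5, 24.5, 26.7, 26.7))
  s <- summarize_interdomain_by_state(f, c(1L, 1L, 2L, 2L),
                                      c("p1", "p2", "p3"))
  tot <- s[s$pair == "total_average", ]
  expect_equal(round(tot$mean, 1), c(20.5, 22.4))
  expect_equal(s$sd[s$pair != "total_average"], rep(0, 6))
  expect_warning(
    summarize_interdomain_by_state(f, factor(c(1, 1, 2, 2),
                                             levels = c(1, 2, 3)),
                                   c("p1", "p2", "p3")),
    "no member frames")
})

test_that("structures round-trip through PDB with sidecar metadata", {
  sys <- build_toy_complex(toy_complex_spec(n_residues = 20,
                                            atoms_per_residue = 3, seed = 9))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(sys$topology, sys$reference, path)
  back <- read_structure(path)
  expect_equal(back$reference, sys$reference, tolerance = 2e-3)
  expect_identical(nrow(back$topology), nrow(sys$topology))
  expect_identical(length(unique(back$topology$resid)), 21L)
  expect_equal(back$topology$charge, sys$topology$charge)
  expect_identical(back$topology$is_ligand, sys$topology$is_ligand)
  expect_identical(length(attr(back$topology, "regions")), 4L)
})

test_that("trajectories round-trip through multi-frame XYZ", {
  set.seed(16)
  tr <- new_md_trajectory(array(rnorm(2 * 5 * 3), c(2, 5, 3)))
  path <- withr::local_tempfile(fileext = ".xyz")
  write_xyz_trajectory(tr, path)
  back <- read_xyz_trajectory(path)
  expect_identical(back$n_frames, 2L)
  expect_equal(back$coords, tr$coords, tolerance = 1e-6)
})

test_that("malformed structure and trajectory files raise parse errors", {
  empty <- withr::local_tempfile(fileext = ".pdb")
  file.create(empty)
  expect_error(read_structure(empty), "empty")
  expect_error(read_structure("does/not/exist.pdb"), "not found")
  bad <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("3", "comment", "C 0 0 0"), bad)
  expect_error(read_xyz_trajectory(bad), "truncated")
  bad2 <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("1", "comment", "C a b c"), bad2)
  expect_error(read_xyz_trajectory(bad2), "line")
})
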