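test_that("EM fitting is deterministic and recovers a single Gaussian", {
  set.seed(30)
  pts <- matrix(rnorm(600, mean = 2, sd = 0.5), ncol = 2)
  f1 <- gmm_fit(pts, k_range = 1:2, restarts = 2, seed = 5)
  f2 <- gmm_fit(pts, k_range = 1:2, restarts = 2, seed = 5)
  expect_identical(f1, f2)
  expect_identical(f1$k, 1L)
  se <- 0.5 / sqrt(300)
  expect_lt(max(abs(f1$means[1, ] - 2)), 3 * se)
})

test_that("EM recovers weights and means of a separated two-component mixture", {
  set.seed(31)
  pts <- rbind(matrix(rnorm(2 * 3500, 0, 1), ncol = 2),
               matrix(rnorm(2 * 1500, 6, 1), ncol = 2))
  fit <- gmm_fit(pts, k_range = 2, restarts = 3, seed = 6)
  ord <- order(fit$weights, decreasing = TRUE)
  expect_equal(fit$weights[ord], c(0.7, 0.3), tolerance = 0.05 / 0.7)
  expect_lt(max(abs(fit$means[ord[1], ] - 0)), 0.1)
  expect_lt(max(abs(fit$means[ord[2], ] - 6)), 0.1)
  # BIC prefers 2 components over 1 and 3 here
  fit_sel <- gmm_fit(pts, k_range = 1:3, restarts = 2, seed = 6)
  expect_identical(fit_sel$k, 2L)
  # cross-check against an independent mixture implementation
  withr::local_package("mclust")
  ref <- mclust::Mclust(pts, G = 2, modelNames = "VVV", verbose = FALSE)
  expect_equal(sort(fit$weights), sort(ref$parameters$pro), tolerance = 0.02)
  expect_equal(fit$means[order(fit$means[, 1]), ],
               unname(t(ref$parameters$mean))[
                 order(ref$parameters$mean[1, ]), ],
               tolerance = 0.05)
  expect_equal(fit$loglik, ref$loglik, tolerance = 1e-3)
})

test_that("the mixture density integrates to one", {
  set.seed(32)
  pts <- rbind(matrix(rnorm(400, -1, 0.7), ncol = 2),
               matrix(rnorm(400, 2, 0.7), ncol = 2))
  fit <- gmm_fit(pts, k_range = 2, restarts = 2, seed = 7)
  g <- seq(-8, 9, by = 0.05)
  grid <- expand.grid(x = g, y = g)
  mass <- sum(gmm_density(fit, grid)) * 0.05^2
  expect_equal(mass, 1, tolerance = 0.01)
})

test_that("the free-energy surface is a shifted negative log density", {
  set.seed(33)
  pts <- matrix(rnorm(1000), ncol = 2)
  fit <- gmm_fit(pts, k_range = 1, restarts = 1, seed = 8)
  s <- free_energy_surface(fit, temperature = 300, points = pts)
  expect_equal(min(s$G), 0)
  # monotone: higher density <=> lower free energy
  d <- gmm_density(fit, s[, c("x", "y")])
  fin <- is.finite(s$G)
  expect_equal(order(d[fin]), order(-s$G[fin]))
  # argmin within one grid cell of the mode
  i <- which.min(s$G)
  cell <- diff(sort(unique(s$x)))[1]
  expect_lt(max(abs(c(s$x[i], s$y[i]) - fit$means[1, ])), 1.5 * cell)
  expect_error(free_energy_surface(fit, grid = list(100 + 0:2, 100 + 0:2)),
               "grid misplaced")
})

test_that("a symmetric equal mixture gives two equal minima", {
  fit <- structure(list(
    weights = c(0.5, 0.5), means = rbind(c(-2, 0), c(2, 0)),
    covariances = list(diag(2) * 0.25, diag(2) * 0.25),
    loglik = 0, bic = 0, k = 2L, d = 2L, n = 100L,
    fit_meta = list()), class = "gmm_model")
  s <- free_energy_surface(fit, grid = list(seq(-4, 4, 0.1),
                                            seq(-2, 2, 0.1)))
  gl <- s$G[abs(s$x + 2) < 1e-9 & abs(s$y) < 1e-9]
  gr <- s$G[abs(s$x - 2) < 1e-9 & abs(s$y) < 1e-9]
  expect_equal(gl, gr, tolerance = 1e-9)
  expect_equal(gl, 0, tolerance = 1e-9)
})

test_that("core extraction keeps the chi-square mass of an isolated Gaussian", {
  set.seed(34)
  pts <- matrix(rnorm(10000), ncol = 2)
  fit <- gmm_fit(pts, k_range = 1, restarts = 2, seed = 9)
  a <- extract_core_states(fit, pts)
  # mass inside the unit Mahalanobis radius in 2-D: 1 - exp(-1/2)
  expect_equal(mean(!is.na(a$label)), 1 - exp(-0.5), tolerance = 0.025)
  expect_true(all(a$density[!is.na(a$label)] >=
                    attr(a, "thresholds")[a$label[!is.na(a$label)]]))
})

test_that("far-separated components are never cross-assigned", {
  set.seed(35)
  truth <- rep(1:2, c(600, 400))
  pts <- rbind(matrix(rnorm(1200, 0, 0.5), ncol = 2),
               matrix(rnorm(800, 10, 0.5), ncol = 2))
  fit <- gmm_fit(pts, k_range = 2, restarts = 2, seed = 10)
  a <- extract_core_states(fit, pts)
  # map fitted components to true ones by their means
  comp_of_truth <- order(fit$means[, 1])
  assigned <- !is.na(a$label)
  expect_true(all(a$label[assigned] ==
                    comp_of_truth[truth[assigned]]))
  # core populations are strictly smaller than hard-assignment ones
  hard <- tabulate(max.col(gmm_posterior(fit, pts)), 2) / nrow(pts)
  core <- state_populations(a, n_states = 2)$percent / 100
  expect_true(all(core < hard))
})

test_that("state populations total the per-state percentages", {
  # published-style percentage rows pass through unchanged
  apo <- state_populations(c(4.9, 1.9, 1.2, 16.7, 10))
  expect_identical(attr(apo, "total_percent"), 34.7)
  bound <- state_populations(c(5.7, 6.3, 9.5, 7.3, 0.4, 8.3))
  expect_identical(attr(bound, "total_percent"), 37.5)
  # label vectors are tabulated over all frames
  lab <- c(1L, 1L, 2L, NA, NA, NA, NA, NA, NA, NA)
  p <- state_populations(lab)
  expect_equal(p$percent, c(20, 10))
  expect_equal(attr(p, "total_percent"), 30)
  none <- state_populations(rep(NA_integer_, 5), n_states = 3)
  expect_equal(none$percent, c(0, 0, 0))
  expect_equal(attr(none, "total_percent"), 0)
})

test_that("states are ordered by mode free energy with documented tie-breaks", {
  fit <- structure(list(
    weights = c(0.3, 0.5, 0.2), means = rbind(c(0, 0), c(8, 0), c(0, 8)),
    covariances = replicate(3, diag(2), simplify = FALSE),
    loglik = 0, bic = 0, k = 3L, d = 2L, n = 100L,
    fit_meta = list()), class = "gmm_model")
  ord <- order_states_by_energy(fit)
  expect_identical(ord$state, c(2L, 1L, 3L))    # density follows weight
  expect_equal(ord$g_mode[1], 0)
  expect_true(all(diff(ord$g_mode) >= 0))
  # exact ties (equilateral means, equal weights) fall back to population,
  # then index
  fit$weights <- c(1, 1, 1) / 3
  fit$means <- rbind(c(0, 0), c(8, 0), c(4, 4 * sqrt(3)))
  pops <- state_populations(c(10.2, 30.4, 20.3))
  ord2 <- order_states_by_energy(fit, pops)
  expect_identical(ord2$state, c(2L, 3L, 1L))
  # equal populations too: index order decides
  ord3 <- order_states_by_energy(fit, state_populations(c(10.5, 10.5, 10.5)))
  expect_identical(ord3$state, 1:3)
})

test_that("tidiers expose mixture parameters and fit metadata", {
  set.seed(36)
  fit <- gmm_fit(matrix(rnorm(400), ncol = 2), k_range = 1:2, restarts = 2,
                 seed = 11)
  td <- tidy(fit)
  expect_identical(nrow(td), fit$k)
  expect_equal(sum(td$weight), 1)
  gl <- glance(fit)
  expect_identical(gl$k, fit$k)
  expect_identical(gl$seed, 11L)
})

test_that("undersized samples are rejected before fitting", {
  expect_error(gmm_fit(matrix(rnorm(60), ncol = 2), k_range = 2:8),
               "at least")
})
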