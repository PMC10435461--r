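# log density of N(mu, Sigma) at rows of x, via Cholesky
log_dmvnorm <- function(x, mu, sigma) {
  d <- ncol(x)
  ch <- chol(sigma)
  z <- backsolve(ch, t(sweep(x, 2, mu)), transpose = TRUE)
  -0.5 * colSums(z^2) - sum(log(diag(ch))) - 0.5 * d * log(2 * pi)
}

# k-means++ style seeding: spread initial centres by squared distance
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  if (k > 1) {
    d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
    for (j in 2:k) {
      p <- d2 / sum(d2)
      centers[j, ] <- x[sample.int(n, 1, prob = p), ]
      d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j, ])^2))
    }
  }
  centers
}

# one EM run; returns NULL on irrecoverable collapse
em_gmm_once <- function(x, k, tol = 1e-6, max_iter = 500, floor = 1e-6) {
  n <- nrow(x); d <- ncol(x)
  centers <- kmeanspp_centers(x, k)
  if (k == 1) {
    cluster <- rep(1L, n)
    means <- matrix(colMeans(x), 1, d)
  } else {
    km <- tryCatch(
      suppressWarnings(stats::kmeans(x, centers = centers, iter.max = 20)),
      error = function(e) NULL)
    if (is.null(km)) {
      # degenerate seeding: hard-assign to the nearest seeded centre
      d2 <- vapply(seq_len(k), function(j)
        rowSums(sweep(x, 2, centers[j, ])^2), numeric(n))
      cluster <- max.col(-d2)
      means <- centers
    } else {
      cluster <- km$cluster
      means <- km$centers
    }
  }
  weights <- pmax(tabulate(cluster, k), 1) / n
  weights <- weights / sum(weights)
  base_cov <- cov(x) + diag(floor, d)
  covs <- replicate(k, base_cov, simplify = FALSE)
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    logp <- matrix(NA_real_, n, k)
    for (j in seq_len(k)) {
      lp <- tryCatch(log_dmvnorm(x, means[j, ], covs[[j]]),
                     error = function(e) NULL)
      if (is.null(lp)) return(NULL)
      logp[, j] <- log(weights[j]) + lp
    }
    m <- apply(logp, 1, max)
    lse <- m + log(rowSums(exp(logp - m)))
    ll <- sum(lse)
    resp <- exp(logp - lse)
    nk <- colSums(resp)
    if (any(nk < d + 1)) return(NULL)  # collapsing component
    weights <- nk / n
    for (j in seq_len(k)) {
      means[j, ] <- colSums(resp[, j] * x) / nk[j]
      xc <- sweep(x, 2, means[j, ])
      covs[[j]] <- crossprod(xc * sqrt(resp[, j])) / nk[j] + diag(floor, d)
    }
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  list(weights = weights, means = unname(means), covariances = covs,
       loglik = ll, iterations = iter)
}

#' Fit a Gaussian mixture model by expectation-maximisation
#'
#' Full-covariance EM with k-means++-style initialisation, several random
#' restarts per candidate component count, and model selection by minimum
#' BIC over `k_range`. Convergence when the log-likelihood change drops
#' below `tol` (or 500 iterations). A small diagonal floor keeps the
#' covariances positive definite; a restart whose EM collapses (singular
#' covariance or emptied component) is discarded, and an error is raised
#' only if every restart for every k fails. Deterministic under `seed`.
#'
#' @param points A data frame or matrix of frame coordinates in collective
#'   -variable space (rows = frames).
#' @param k_range Candidate numbers of components.
#' @param restarts EM restarts per k.
#' @param seed Integer seed fixing initialisation.
#' @param tol Log-likelihood convergence tolerance.
#' @param floor Diagonal covariance floor.
#' @return An object of class `gmm_model`: `weights`, `means` (k x d),
#'   `covariances` (list of d x d SPD matrices), `loglik`, `bic`, `k`,
#'   `d`, `n`, and `fit_meta` (per-k BIC table, restarts, seed).
#' @export
#' @examples
#' pts <- rbind(matrix(rnorm(200), ncol = 2),
#'              matrix(rnorm(200, mean = 5), ncol = 2))
#' fit <- gmm_fit(pts, k_range = 1:3, restarts = 2, seed = 1)
#' fit$k
gmm_fit <- function(points, k_range = 2:8, restarts = 5, seed = 20230817,
                    tol = 1e-6, floor = 1e-6) {
  x <- as.matrix(as.data.frame(points)[,
    setdiff(colnames(as.data.frame(points)), "frame"), drop = FALSE])
  storage.mode(x) <- "double"
  if (any(!is.finite(x))) abort("points must be finite")
  n <- nrow(x)
  if (n < 10 * max(k_range))
    abort(sprintf("need at least %d frames for k up to %d (got %d)",
                  10 * max(k_range), max(k_range), n))
  d <- ncol(x)
  fits <- list()
  score <- tibble(k = integer(), bic = numeric(), loglik = numeric())
  withr::with_seed(as.integer(seed), {
    for (k in k_range) {
      best <- NULL
      for (r in seq_len(restarts)) {
        f <- em_gmm_once(x, k, tol = tol, floor = floor)
        if (!is.null(f) && (is.null(best) || f$loglik > best$loglik))
          best <- f
      }
      if (is.null(best)) next
      p <- (k - 1) + k * d + k * d * (d + 1) / 2
      best$bic <- -2 * best$loglik + p * log(n)
      fits[[as.character(k)]] <- best
      score <- bind_rows(score, tibble(k = k, bic = best$bic,
                                       loglik = best$loglik))
    }
  })
  if (nrow(score) == 0)
    abort("EM failed for every candidate k after all restarts")
  kbest <- score$k[which.min(score$bic)]
  f <- fits[[as.character(kbest)]]
  structure(list(weights = f$weights, means = f$means,
                 covariances = f$covariances,
                 loglik = f$loglik, bic = f$bic,
                 k = kbest, d = d, n = n,
                 fit_meta = list(selection = score, restarts = restarts,
                                 seed = as.integer(seed))),
            class = "gmm_model")
}

#' Mixture density and posterior responsibilities of a fitted GMM
#'
#' @param model A `gmm_model`.
#' @param points Data frame or matrix of coordinates.
#' @return `gmm_density()` returns the mixture density per row;
#'   `gmm_posterior()` an n x k matrix of component posteriors.
#' @export
gmm_density <- function(model, points) {
  x <- as.matrix(as.data.frame(points)[,
    setdiff(colnames(as.data.frame(points)), "frame"), drop = FALSE])
  dens <- matrix(0, nrow(x), model$k)
  for (j in seq_len(model$k))
    dens[, j] <- model$weights[j] *
      exp(log_dmvnorm(x, model$means[j, ], model$covariances[[j]]))
  rowSums(dens)
}

#' @rdname gmm_density
#' @export
gmm_posterior <- function(model, points) {
  x <- as.matrix(as.data.frame(points)[,
    setdiff(colnames(as.data.frame(points)), "frame"), drop = FALSE])
  logp <- matrix(NA_real_, nrow(x), model$k)
  for (j in seq_len(model$k))
    logp[, j] <- log(model$weights[j]) +
      log_dmvnorm(x, model$means[j, ], model$covariances[[j]])
  m <- apply(logp, 1, max)
  p <- exp(logp - m)
  p / rowSums(p)
}

#' @export
print.gmm_model <- function(x, ...) {
  cat(sprintf("<gmm_model: k = %d components in %d dims, n = %d, BIC = %.1f>\n",
              x$k, x$d, x$n, x$bic))
  invisible(x)
}

#' Tidy a fitted Gaussian mixture model
#'
#' `tidy()` returns one row per mixture component (weight, means, largest
#' covariance eigenvalue); `glance()` a one-row model summary.
#'
#' @param x A `gmm_model`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.gmm_model <- function(x, ...) {
  mtab <- as_tibble(as.data.frame(x$means))
  names(mtab) <- paste0("mean_", seq_len(x$d))
  bind_cols(tibble(component = seq_len(x$k), weight = x$weights), mtab) |>
    mutate(max_cov_eigen = vapply(x$covariances,
                                  function(s) max(eigen(s)$values),
                                  numeric(1)))
}

#' @rdname tidy.gmm_model
#' @export
glance.gmm_model <- function(x, ...) {
  tibble(k = x$k, d = x$d, n = x$n, loglik = x$loglik, bic = x$bic,
         restarts = x$fit_meta$restarts, seed = x$fit_meta$seed)
}
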