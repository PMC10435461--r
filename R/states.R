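#' Free-energy surface of a Gaussian mixture density
#'
#' Evaluates \eqn{G(x) = -k_B T \log \rho(x)} on a regular grid, where
#' \eqn{\rho} is the fitted mixture density, and shifts the surface so the
#' global minimum is 0. Cells whose density falls below `floor` are flagged
#' not-sampled (`G = Inf`) rather than given a huge finite energy.
#'
#' @param model A `gmm_model` (any dimension; 1-D and 2-D are typical).
#' @param grid Optional list of coordinate vectors, one per dimension. By
#'   default a 100-point axis per dimension spanning the component means
#'   +/- 10% of their spread plus 3 standard deviations.
#' @param temperature Temperature in kelvin (default 300).
#' @param floor Density floor below which cells are flagged not-sampled.
#' @param points Optional data used only to size the default grid.
#' @return A tibble of class `fel_surface` with one coordinate column per
#'   dimension (`x`, `y`, ...) and `G` (kcal/mol); attributes `temperature`,
#'   `grid`, `floor`.
#' @export
free_energy_surface <- function(model, grid = NULL, temperature = 300,
                                floor = 1e-12, points = NULL) {
  stopifnot(inherits(model, "gmm_model"))
  d <- model$d
  if (is.null(grid)) {
    grid <- lapply(seq_len(d), function(j) {
      sdj <- sqrt(max(vapply(model$covariances, function(s) s[j, j],
                             numeric(1))))
      if (!is.null(points)) {
        p <- as.matrix(as.data.frame(points))[, j]
        lo <- min(p); hi <- max(p)
        pad <- 0.1 * (hi - lo)
      } else {
        lo <- min(model$means[, j]) - 3 * sdj
        hi <- max(model$means[, j]) + 3 * sdj
        pad <- 0.1 * (hi - lo)
      }
      seq(lo - pad, hi + pad, length.out = 100)
    })
  }
  stopifnot(length(grid) == d)
  pts <- as.matrix(expand.grid(grid))
  rho <- gmm_density(model, pts)
  if (all(rho < floor))
    abort("density is below the floor everywhere on the grid; grid misplaced")
  kT <- md_constants$kB * temperature
  G <- ifelse(rho >= floor, -kT * log(rho), Inf)
  G <- G - min(G)
  out <- as_tibble(as.data.frame(pts))
  names(out) <- c("x", "y", "z", paste0("v", 4:10))[seq_len(d)]
  out$G <- G
  structure(out, temperature = temperature, grid = grid, floor = floor,
            class = c("fel_surface", class(out)))
}

# direction set on the unit sphere in d dims (deterministic)
unit_directions <- function(d, n_dir = 64) {
  if (d == 1) return(matrix(c(1, -1), ncol = 1))
  if (d == 2) {
    a <- 2 * pi * (seq_len(n_dir) - 1) / n_dir
    return(cbind(cos(a), sin(a)))
  }
  u <- withr::with_seed(1L, matrix(rnorm(n_dir * d), n_dir, d))
  u / sqrt(rowSums(u^2))
}

#' Extract inflection-delimited core states from a fitted mixture
#'
#' For each mixture component the density profile along the Mahalanobis
#' radius from the component mean (mixture density averaged over a fixed
#' fan of directions) is scanned for the first sign change of its second
#' derivative; the mixture density at that inflection radius becomes the
#' component's core threshold. A frame is assigned to component c iff its
#' posterior for c exceeds 0.5 AND the mixture density at the frame is at
#' least threshold(c); all other frames stay unassigned, which is why core
#' populations sum to well under 100%. For an isolated Gaussian the
#' inflection sits at Mahalanobis radius 1, so the core captures the
#' classical 39.35% of that component's mass in 2-D. If no inflection is
#' found (degenerate profile) the threshold falls back to the 60th density
#' percentile of the component's members, with a message.
#'
#' @param model A `gmm_model`.
#' @param points The frame coordinates to label (data frame or matrix).
#' @param r_max,dr Radius scan range and step (Mahalanobis units).
#' @param n_dir Number of scan directions.
#' @return A tibble of class `state_assignment`: `frame`, `label` (integer
#'   or NA), `density`; attribute `thresholds` (per-state core density) and
#'   `posterior_cut` (0.5).
#' @export
extract_core_states <- function(model, points, r_max = 5, dr = 0.02,
                                n_dir = 64) {
  stopifnot(inherits(model, "gmm_model"))
  x <- as.matrix(as.data.frame(points)[,
    setdiff(colnames(as.data.frame(points)), "frame"), drop = FALSE])
  dens <- gmm_density(model, x)
  post <- gmm_posterior(model, x)
  dirs <- unit_directions(model$d, n_dir)
  radii <- seq(0, r_max, by = dr)
  thresholds <- numeric(model$k)
  for (c in seq_len(model$k)) {
    L <- t(chol(model$covariances[[c]]))   # Sigma = L L'
    # profile: mixture density averaged over the direction fan
    prof <- vapply(radii, function(r) {
      pts <- sweep(r * dirs %*% t(L), 2, model$means[c, ], "+")
      mean(gmm_density(model, pts))
    }, numeric(1))
    d2 <- diff(prof, differences = 2)
    flip <- which(d2 >= 0)[1]
    if (is.na(flip) || flip <= 1) {
      members <- which(max.col(post) == c)
      if (length(members) == 0) members <- seq_len(nrow(x))
      thresholds[c] <- quantile(dens[members], 0.6, names = FALSE)
      inform(sprintf(
        "component %d: no density inflection found; falling back to the 60th density percentile", c))
    } else {
      thresholds[c] <- prof[flip + 1]
    }
  }
  best <- max.col(post)
  pbest <- post[cbind(seq_len(nrow(x)), best)]
  label <- ifelse(pbest > 0.5 & dens >= thresholds[best], best, NA_integer_)
  out <- tibble(frame = seq_len(nrow(x)), label = as.integer(label),
                density = dens)
  structure(out, thresholds = thresholds, posterior_cut = 0.5,
            class = c("state_assignment", class(out)))
}

#' State populations as percentages of all frames
#'
#' Given per-frame core-state labels, the percentage of frames assigned to
#' each state and the total sampled percentage (their sum, below 100% when
#' frames outside any core remain unassigned). Pre-computed per-state
#' percentages (a numeric vector, e.g. a published table row) are passed
#' through unchanged and totalled.
#'
#' @param assignment A `state_assignment` (or tibble with `label`), a label
#'   vector with NAs for unassigned frames, or a numeric vector of per-state
#'   percentages.
#' @param n_states Optional number of states (pads absent states with 0).
#' @return A tibble of class `state_populations`: `state`, `percent`, with
#'   attribute `total_percent`.
#' @export
#' @examples
#' state_populations(c(4.9, 1.9, 1.2, 16.7, 10))  # total 34.7
state_populations <- function(assignment, n_states = NULL) {
  if (!is.data.frame(assignment) && is.double(assignment) &&
      any(assignment %% 1 != 0, na.rm = TRUE)) {
    # a vector of per-state percentages, passed through
    pct <- as.numeric(assignment)
    out <- tibble(state = seq_along(pct), percent = pct)
    attr(out, "total_percent") <- sum(pct)
    class(out) <- c("state_populations", class(out))
    return(out)
  }
  labels <- if (is.data.frame(assignment)) assignment$label else assignment
  labels <- as.integer(labels)
  k <- n_states %||% if (all(is.na(labels))) 0L else max(labels, na.rm = TRUE)
  counts <- if (k > 0) tabulate(labels[!is.na(labels)], k) else integer(0)
  pct <- 100 * counts / length(labels)
  out <- tibble(state = seq_len(k), percent = pct)
  attr(out, "total_percent") <- sum(pct)
  class(out) <- c("state_populations", class(out))
  out
}

#' Order states along an energy pathway
#'
#' States are ordered by ascending free energy of their density modes,
#' i.e. descending mixture density at the component means; ties are broken
#' by descending population, then by state index. This energy ordering is
#' a ranking of metastable basins, not a kinetic pathway.
#'
#' @param model A `gmm_model`.
#' @param populations Optional `state_populations` used for tie-breaking.
#' @param temperature Temperature (K) for the reported mode free energies.
#' @return A tibble: `rank`, `state`, `mode_density`, `g_mode` (kcal/mol,
#'   minimum at 0), `percent` (if populations supplied).
#' @export
order_states_by_energy <- function(model, populations = NULL,
                                   temperature = 300) {
  stopifnot(inherits(model, "gmm_model"))
  dens <- gmm_density(model, model$means)
  kT <- md_constants$kB * temperature
  g <- -kT * log(dens)
  g <- g - min(g)
  pct <- if (!is.null(populations)) {
    populations$percent[match(seq_len(model$k), populations$state)]
  } else rep(0, model$k)
  ord <- order(-dens, -pct, seq_len(model$k))
  out <- tibble(rank = seq_len(model$k), state = ord,
                mode_density = dens[ord], g_mode = g[ord])
  if (!is.null(populations)) out$percent <- pct[ord]
  out
}
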