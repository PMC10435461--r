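#' Flatten superposed backbone coordinates into a feature matrix
#'
#' Each frame is superposed onto the reference over the selection and the
#' selected coordinates are unrolled into one row (x1, y1, z1, x2, ...),
#' the standard cRMSD-consistent input for coordinate PCA. The alternative
#' `mode = "deviations"` instead records the per-atom deviation magnitude
#' from the reference after superposition.
#'
#' @inheritParams c_rmsd
#' @param mode `"coordinates"` (default) or `"deviations"`.
#' @return A tibble, one row per frame.
#' @export
backbone_features <- function(trajectory, reference, topology = NULL,
                              selection = "backbone",
                              mode = c("coordinates", "deviations")) {
  mode <- match.arg(mode)
  sel <- resolve_selection(selection, topology, trajectory$n_atoms)
  ref <- as.matrix(reference)[sel, , drop = FALSE]
  rows <- lapply(seq_len(trajectory$n_frames), function(f) {
    x <- frame_coords(trajectory, f)[sel, , drop = FALSE]
    fit <- kabsch_superpose(x, ref)$transform(x)
    if (mode == "coordinates") as.numeric(t(fit))
    else sqrt(rowSums((fit - ref)^2))
  })
  m <- do.call(rbind, rows)
  colnames(m) <- if (mode == "coordinates") {
    paste0(rep(c("x", "y", "z"), length(sel)), rep(sel, each = 3))
  } else paste0("dev", sel)
  as_tibble(m)
}

# fix component signs: largest-magnitude loading positive
fix_signs <- function(basis, scores) {
  for (j in seq_len(ncol(basis))) {
    i <- which.max(abs(basis[, j]))
    if (basis[i, j] < 0) {
      basis[, j] <- -basis[, j]
      scores[, j] <- -scores[, j]
    }
  }
  list(basis = basis, scores = scores)
}

#' Principal component analysis of a frame feature matrix
#'
#' Mean-centred eigendecomposition of the covariance matrix (no scaling by
#' default, since coordinate features share units); projections onto the
#' top `k` components have variance equal to the eigenvalues. Component
#' signs are fixed by making each component's largest-magnitude loading
#' positive, so repeated runs are comparable.
#'
#' @param features A data frame of numeric columns, one row per frame
#'   (non-numeric columns named `frame` are carried through, not projected).
#' @param k Number of components to keep.
#' @param scale Standardise features to unit variance first (correlation
#'   PCA); default `FALSE`.
#' @return A list of class `projection_model` with elements `center`,
#'   `scale`, `basis` (features x k, orthonormal), `explained_variance`
#'   (all eigenvalues, non-increasing), `total_variance`, and `scores`: a
#'   tibble of the projected frames (`PC1`, `PC2`, ...).
#' @export
pca_fit_transform <- function(features, k = 2, scale = FALSE) {
  x <- as.matrix(features[, setdiff(names(features), "frame"), drop = FALSE])
  if (any(is.na(x))) abort("features contain missing values")
  if (nrow(x) <= k)
    abort(sprintf("need more than k = %d frames (got %d)", k, nrow(x)))
  p <- prcomp(x, center = TRUE, scale. = scale)
  eig <- p$sdev^2
  rank <- sum(eig > max(eig) * 1e-12)
  if (rank < k)
    abort(sprintf("feature matrix has rank %d < k = %d", rank, k))
  basis <- p$rotation[, seq_len(k), drop = FALSE]
  scores <- p$x[, seq_len(k), drop = FALSE]
  fs <- fix_signs(basis, scores)
  colnames(fs$scores) <- paste0("PC", seq_len(k))
  scores <- as_tibble(fs$scores)
  structure(list(center = p$center,
                 scale = if (scale) p$scale else NULL,
                 basis = fs$basis,
                 explained_variance = eig,
                 total_variance = sum(eig),
                 scores = scores),
            class = "projection_model")
}

#' Linear discriminant projection of labelled frame features
#'
#' Directions maximising between-class over within-class scatter, obtained
#' by whitening with the within-class covariance (Cholesky; ridge
#' regularised with a logged epsilon if singular) and taking the singular
#' value decomposition of the whitened, weight-scaled class-mean matrix.
#' At most `n_classes - 1` informative components exist.
#'
#' @param features A data frame of numeric columns, one row per frame.
#' @param labels Class label per frame (>= 2 classes, each with >= 2 rows).
#' @param k Number of discriminants to keep.
#' @param scale Standardise features first; default `FALSE` (the usual
#'   interdomain distances already share units).
#' @return A `projection_model` (as in [pca_fit_transform()]) whose
#'   `explained_variance` holds the discriminant eigenvalues
#'   (between/within scatter ratios) and whose `scores` tibble has columns
#'   `LD1`, `LD2`, ... plus the labels.
#' @export
lda_fit_transform <- function(features, labels, k = 2, scale = FALSE) {
  x <- as.matrix(features[, setdiff(names(features), "frame"), drop = FALSE])
  if (any(is.na(x))) abort("features contain missing values")
  labels <- as.vector(labels)
  if (length(labels) != nrow(x)) abort("one label per frame is required")
  cls <- sort(unique(labels))
  if (length(cls) < 2) abort("at least 2 classes are required")
  if (any(table(labels) < 2)) abort("every class needs at least 2 frames")
  ctr <- colMeans(x)
  scl <- if (scale) apply(x, 2, sd) else rep(1, ncol(x))
  if (any(scl == 0)) abort("constant feature cannot be standardised")
  x <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  d <- ncol(x)
  # within-class scatter (pooled covariance)
  Sw <- matrix(0, d, d)
  means <- matrix(0, length(cls), d)
  prop <- numeric(length(cls))
  for (i in seq_along(cls)) {
    xi <- x[labels == cls[i], , drop = FALSE]
    means[i, ] <- colMeans(xi)
    Sw <- Sw + crossprod(sweep(xi, 2, means[i, ]))
    prop[i] <- nrow(xi) / nrow(x)
  }
  Sw <- Sw / (nrow(x) - length(cls))
  ch <- tryCatch(chol(Sw), error = function(e) NULL)
  if (is.null(ch)) {
    eps <- 1e-8 * mean(diag(Sw))
    inform(sprintf("within-class scatter singular; ridge epsilon %.3g added",
                   eps))
    ch <- chol(Sw + diag(eps, d))
  }
  # whiten the weighted class means and take their SVD
  M <- sweep(means, 2, colSums(means * prop))
  Mw <- t(backsolve(ch, t(M), transpose = TRUE)) * sqrt(prop)
  sv <- svd(Mw)
  k_eff <- min(k, length(cls) - 1, d)
  # discriminant directions back in feature space
  W <- backsolve(ch, sv$v[, seq_len(k_eff), drop = FALSE])
  W <- apply(W, 2, function(v) v / sqrt(sum(v^2)))
  W <- matrix(W, nrow = d)
  scores <- x %*% W
  fs <- fix_signs(W, scores)
  colnames(fs$scores) <- paste0("LD", seq_len(k_eff))
  scores <- as_tibble(fs$scores)
  scores$label <- labels
  structure(list(center = ctr, scale = if (scale) scl else NULL,
                 basis = fs$basis,
                 explained_variance = sv$d[seq_len(k_eff)]^2,
                 total_variance = sum(sv$d^2),
                 scores = scores),
            class = "projection_model")
}

#' Apply a fitted projection model to new feature rows
#'
#' @param model A `projection_model`.
#' @param features A data frame with the same feature columns used to fit.
#' @return A tibble of projected coordinates.
#' @export
project_features <- function(model, features) {
  x <- as.matrix(features[, setdiff(names(features), "frame"), drop = FALSE])
  x <- sweep(x, 2, model$center)
  if (!is.null(model$scale)) x <- sweep(x, 2, model$scale, "/")
  s <- x %*% model$basis
  colnames(s) <- names(model$scores)[seq_len(ncol(s))]
  as_tibble(s)
}

#' @export
print.projection_model <- function(x, ...) {
  cat(sprintf("<projection_model: %d features -> %d components>\n",
              nrow(x$basis), ncol(x$basis)))
  ev <- x$explained_variance[seq_len(min(5, length(x$explained_variance)))]
  cat("  leading variances:", paste(signif(ev, 4), collapse = ", "), "\n")
  invisible(x)
}
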