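# Feature reduction: ordinary-PCA dimension estimate plus Gaussian kernel
# PCA with out-of-sample (Nystrom-style) projection, so that new drugs can
# be embedded in the feature space fitted on the training drugs.

#' Estimate a reduced feature dimension with ordinary PCA
#'
#' Counts the leading principal components whose covariance eigenvalue is
#' at least `epsilon` times the largest one — i.e. the components that have
#' not yet decayed to (near) zero.
#'
#' @param F n x p feature matrix, n >= 2.
#' @param epsilon relative eigenvalue cutoff in (0, 1].
#' @return positive integer, the retained dimension.
#' @export
estimate_dimension <- function(F, epsilon = 1e-6) {
  stop_if_not_matrix(F)
  if (nrow(F) < 2) stop("need at least 2 rows")
  if (!is.numeric(epsilon) || epsilon <= 0) stop("`epsilon` must be > 0")
  ev <- stats::prcomp(F, center = TRUE, scale. = FALSE)$sdev^2
  if (max(ev) <= 0) stop("zero-variance feature matrix")
  sum(ev >= epsilon * max(ev))
}

gauss_kernel <- function(X, Y, bandwidth) {
  # exp(-||x - y||^2 / (2 * bandwidth)); bandwidth is the variance sigma^2
  d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
  exp(-pmax(d2, 0) / (2 * bandwidth))
}

#' Fit Gaussian kernel PCA and embed the training points
#'
#' Builds the Gaussian kernel matrix `k(x, y) = exp(-||x - y||^2 /
#' (2 * bandwidth))`, double-centers it in feature space, and
#' eigendecomposes it. Embedded coordinates are the centered-kernel
#' eigenvectors scaled by the square roots of their eigenvalues, ordered by
#' descending eigenvalue.
#'
#' @param F n x p feature matrix.
#' @param n_components number of coordinates to keep, `<= n`. Components
#'   whose eigenvalue is numerically zero are dropped with a warning.
#' @param bandwidth kernel variance sigma^2 (> 0).
#' @return list with `map` (a `kpca_map` usable with [kpca_transform()])
#'   and `coordinates` (n x n_components matrix).
#' @export
kpca_fit_transform <- function(F, n_components, bandwidth) {
  stop_if_not_matrix(F)
  if (!is.numeric(bandwidth) || bandwidth <= 0) {
    stop("`bandwidth` must be a positive real")
  }
  n <- nrow(F)
  if (n_components < 1 || n_components > n) {
    stop("`n_components` must be in [1, nrow(F)]")
  }
  K <- gauss_kernel(F, F, bandwidth)
  col_means <- colMeans(K)
  grand_mean <- mean(K)
  Kc <- K - matrix(col_means, n, n, byrow = TRUE) -
    matrix(col_means, n, n) + grand_mean
  eig <- eigen(Kc, symmetric = TRUE)
  lambda <- eig$values
  keep <- seq_len(n_components)
  pos <- lambda[keep] > max(lambda[1], 0) * 1e-12
  if (!all(pos)) {
    warning(sprintf(
      "only %d component(s) have non-degenerate eigenvalues; dropping %d",
      sum(pos), n_components - sum(pos)))
    keep <- keep[pos]
  }
  if (length(keep) == 0) stop("kernel matrix has no non-degenerate component")
  lambda <- lambda[keep]
  V <- eig$vectors[, keep, drop = FALSE]
  coords <- V %*% diag(sqrt(lambda), nrow = length(lambda))
  rownames(coords) <- rownames(F)
  map <- structure(
    list(training_points = F,
         kernel_bandwidth = bandwidth,
         n_components = length(keep),
         eigenvalues = lambda,
         eigenvectors = V,
         kernel_col_means = col_means,
         kernel_grand_mean = grand_mean),
    class = "kpca_map")
  list(map = map, coordinates = coords)
}

#' @export
print.kpca_map <- function(x, ...) {
  cat(sprintf("<kpca_map> %d training points, %d components, bandwidth=%g\n",
              nrow(x$training_points), x$n_components, x$kernel_bandwidth))
  invisible(x)
}

#' Embed new points with a fitted kernel PCA map
#'
#' Projects new rows into the training embedding: the new-point kernel rows
#' are centered with the training kernel statistics and projected on the
#' stored eigenvectors scaled by inverse eigenvalue roots. Transforming the
#' training matrix itself reproduces the fit-time coordinates.
#'
#' @param map a `kpca_map` from [kpca_fit_transform()].
#' @param F_new matrix of new rows with the training column count.
#' @return matrix of embedded coordinates, `nrow(F_new) x n_components`.
#' @export
kpca_transform <- function(map, F_new) {
  if (is.vector(F_new)) F_new <- matrix(F_new, ncol = length(F_new))
  stop_if_not_matrix(F_new)
  if (ncol(F_new) != ncol(map$training_points)) {
    stop(sprintf("F_new has %d columns; map expects %d",
                 ncol(F_new), ncol(map$training_points)))
  }
  n <- nrow(map$training_points)
  Knew <- gauss_kernel(F_new, map$training_points, map$kernel_bandwidth)
  Kc <- Knew -
    matrix(map$kernel_col_means, nrow(F_new), n, byrow = TRUE) -
    rowMeans(Knew) + map$kernel_grand_mean
  coords <- Kc %*% map$eigenvectors %*%
    diag(1 / sqrt(map$eigenvalues), nrow = map$n_components)
  rownames(coords) <- rownames(F_new)
  coords
}
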