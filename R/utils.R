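# Internal numerical helpers shared across modules.

#' Moore-Penrose pseudo-inverse via singular value decomposition
#'
#' Singular values below `tol * max(sv)` are treated as zero.
#' @param X numeric matrix.
#' @param tol relative tolerance for rank truncation.
#' @return the pseudo-inverse of `X` (ncol(X) x nrow(X)).
#' @keywords internal
#' @noRd
pinv <- function(X, tol = sqrt(.Machine$double.eps)) {
  s <- svd(X)
  keep <- s$d > tol * max(s$d, 0)
  if (!any(keep)) {
    return(matrix(0, ncol(X), nrow(X)))
  }
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' Numerical rank of a matrix
#'
#' Counts singular values above `max(dim(X)) * eps * sigma_max`, the
#' LAPACK-style default rank tolerance.
#' @keywords internal
#' @noRd
numerical_rank <- function(X) {
  d <- svd(X, nu = 0, nv = 0)$d
  if (max(d) == 0) {
    return(0L)
  }
  sum(d > max(dim(X)) * .Machine$double.eps * max(d))
}

#' Squared Frobenius norm of X - W %*% H
#' @keywords internal
#' @noRd
frob2_residual <- function(X, W, H) {
  sum((X - W %*% H)^2)
}

stop_if_not_matrix <- function(X, arg = deparse(substitute(X))) {
  if (!is.matrix(X) || !is.numeric(X)) {
    stop(sprintf("`%s` must be a numeric matrix", arg), call. = FALSE)
  }
  if (anyNA(X) || any(!is.finite(X))) {
    stop(sprintf("`%s` contains missing or non-finite values", arg),
         call. = FALSE)
  }
  invisible(X)
}
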