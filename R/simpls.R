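# Multivariate partial least squares regression by the SIMPLS algorithm
# (de Jong 1993): successive deflation of the cross-product matrix
# S = Xc' Yc rather than of the data, which makes the extracted weights
# apply directly to the centered predictors.
#
# PLSR is used here because drug descriptor columns (fingerprint bits) and
# latent encoding columns are strongly collinear, where ordinary least
# squares is unstable; with k equal to the rank of the centered predictors
# SIMPLS reproduces the least-squares fit.

#' Fit a SIMPLS partial least squares regression
#'
#' Regresses a multivariate response `Y` (n x r) on predictors `F` (n x p)
#' with `k` latent factors. Both blocks are mean-centered; no variance
#' scaling is applied (binary fingerprint features have a meaningful
#' scale). The model is `Y ~ (F - mean) B + intercept`.
#'
#' @param F predictor matrix, n x p.
#' @param Y response matrix, n x r (a vector is treated as one column).
#' @param k number of latent factors, `1 <= k <= min(p, n - 1)`.
#' @return object of class `plsr_model` with `B` (p x r coefficients),
#'   `intercept` (length r), `k` (requested), `k_used` (extracted; smaller
#'   only if the predictor rank is exhausted), `feature_means`,
#'   `response_means`.
#' @export
simpls_fit <- function(F, Y, k) {
  if (is.vector(F)) F <- matrix(F, ncol = 1)
  if (is.vector(Y)) Y <- matrix(Y, ncol = 1)
  stop_if_not_matrix(F); stop_if_not_matrix(Y)
  n <- nrow(F); p <- ncol(F); r <- ncol(Y)
  if (nrow(Y) != n) stop("F and Y must have the same number of rows")
  if (n < 2) stop("need at least 2 training rows")
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k != floor(k) ||
      k > min(p, n - 1)) {
    stop(sprintf("`k` must be an integer in [1, min(p, n - 1)] = [1, %d]",
                 min(p, n - 1)))
  }
  k <- as.integer(k)

  fmeans <- colMeans(F)
  ymeans <- colMeans(Y)
  Xc <- sweep(F, 2, fmeans)
  Yc <- sweep(Y, 2, ymeans)
  if (all(abs(Xc) < 1e-12)) stop("predictors are constant after centering")

  S <- crossprod(Xc, Yc)                      # p x r
  R <- matrix(0, p, k); Q <- matrix(0, r, k)
  V <- matrix(0, p, k)
  k_used <- 0L
  for (a in seq_len(k)) {
    # dominant right singular vector of the deflated cross-product
    if (r == 1L) {
      q <- 1
    } else {
      q <- eigen(crossprod(S), symmetric = TRUE)$vectors[, 1]
    }
    w <- S %*% q                              # predictor weights, p x 1
    t_sc <- Xc %*% w
    normt <- sqrt(sum(t_sc^2))
    if (normt < 1e-12 * sqrt(n)) break        # predictor rank exhausted
    t_sc <- t_sc / normt
    w <- w / normt
    p_load <- crossprod(Xc, t_sc)             # p x 1
    q_load <- crossprod(Yc, t_sc)             # r x 1
    v <- p_load
    if (a > 1) {
      Vp <- V[, seq_len(a - 1), drop = FALSE]
      v <- v - Vp %*% crossprod(Vp, p_load)
    }
    nv <- sqrt(sum(v^2))
    if (nv < 1e-12) break
    v <- v / nv
    S <- S - v %*% crossprod(v, S)
    R[, a] <- w; Q[, a] <- q_load; V[, a] <- v
    k_used <- a
  }
  if (k_used == 0L) stop("no usable latent factor could be extracted")
  R <- R[, seq_len(k_used), drop = FALSE]
  Q <- Q[, seq_len(k_used), drop = FALSE]
  B <- R %*% t(Q)                             # p x r
  structure(
    list(B = B,
         intercept = as.numeric(ymeans - crossprod(fmeans, B)),
         k = k, k_used = k_used,
         feature_means = fmeans, response_means = ymeans),
    class = "plsr_model")
}

#' @export
print.plsr_model <- function(x, ...) {
  cat(sprintf("<plsr_model> p=%d features -> r=%d responses, k=%d latent factors\n",
              nrow(x$B), ncol(x$B), x$k_used))
  invisible(x)
}

#' Predict from a SIMPLS model
#'
#' @param model a `plsr_model` from [simpls_fit()].
#' @param F_new matrix of new predictor rows (n x p).
#' @return n x r matrix of predictions
#'   `(F_new - feature_means) B + response_means`, equivalently
#'   `F_new B + intercept`.
#' @export
plsr_predict <- function(model, F_new) {
  if (is.vector(F_new)) F_new <- matrix(F_new, ncol = length(F_new))
  stop_if_not_matrix(F_new)
  if (ncol(F_new) != nrow(model$B)) {
    stop(sprintf("F_new has %d columns; model expects %d",
                 ncol(F_new), nrow(model$B)))
  }
  F_new %*% model$B + rep(model$intercept, each = nrow(F_new))
}

#' Serialize a PLSR model
#'
#' Writes `B.csv` and `plsr.json` (intercept, means, k) under `dir`.
#' @param model a `plsr_model`.
#' @param dir output directory.
#' @export
write_plsr_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(model$B, file.path(dir, "B.csv"), row.names = FALSE)
  meta <- list(intercept = model$intercept, k = model$k,
               k_used = model$k_used,
               feature_means = as.numeric(model$feature_means),
               response_means = as.numeric(model$response_means))
  jsonlite::write_json(meta, file.path(dir, "plsr.json"), digits = NA)
  invisible(dir)
}
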