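# Nonnegative matrix factorization (NMF) and semi-nonnegative matrix
# factorization (semi-NMF) by multiplicative updates.
#
# NMF:      X (>= 0)  ~  W (>= 0) %*% H (>= 0)
# semi-NMF: X (mixed) ~  W (mixed) %*% H (>= 0)
#
# Both minimise ||X - W H||_F^2. On a network adjacency matrix the columns
# of W act as latent communities and the columns of H as soft community
# memberships of the nodes, which is what makes the factors interpretable
# for DDI networks.

EPS_DIV <- 1e-9   # denominator safeguard in multiplicative updates

new_factor_pair <- function(W, H, r, mode, objective_trace, converged,
                            iterations, h_min, w_min) {
  structure(
    list(W = W, H = H, r = r, mode = mode,
         objective_trace = objective_trace, converged = converged,
         iterations = iterations,
         h_min = h_min,   # smallest H entry seen over all iterations
         w_min = w_min),  # smallest W entry seen (NMF only; NA for semi-NMF)
    class = "factor_pair")
}

#' @export
print.factor_pair <- function(x, ...) {
  cat(sprintf(
    "<factor_pair> mode=%s r=%d iterations=%d converged=%s final ||X-WH||_F^2=%.6g\n",
    x$mode, x$r, x$iterations, x$converged,
    x$objective_trace[length(x$objective_trace)]))
  invisible(x)
}

check_rank_arg <- function(r, dims) {
  if (!is.numeric(r) || length(r) != 1 || r < 1 || r != floor(r)) {
    stop("`r` must be a positive integer")
  }
  if (r >= min(dims)) {
    stop(sprintf("`r` must satisfy 1 <= r < min(dim(X)) = %d", min(dims)))
  }
  as.integer(r)
}

#' Nonnegative matrix factorization by multiplicative updates
#'
#' Factorizes a nonnegative matrix `X` as `W %*% H` with `W >= 0`,
#' `H >= 0`, minimising the squared Frobenius residual with the classical
#' Lee-Seung multiplicative updates:
#' `W <- W * (X H') / (W H H')`, `H <- H * (W' X) / (W' W H)`.
#' Every denominator is safeguarded with a small epsilon. Iteration stops
#' when the relative objective change drops below `tol` or after
#' `max_iter` updates; the objective trace is non-increasing.
#'
#' @param X nonnegative numeric matrix.
#' @param r latent dimension, `1 <= r < min(dim(X))`.
#' @param max_iter maximum number of update sweeps.
#' @param tol relative objective-change stopping threshold.
#' @param seed integer seed for the random initialization
#'   (`W`, `H` ~ Uniform(0,1) scaled by `sqrt(mean(X)/r)`).
#' @return a `factor_pair` with components `W` (m x r), `H` (r x n), `r`,
#'   `objective_trace` (squared Frobenius residual after each sweep,
#'   starting with the initial value), `converged`, `iterations`.
#' @export
nmf_decompose <- function(X, r, max_iter = 500, tol = 1e-6, seed = 1L) {
  stop_if_not_matrix(X)
  if (any(X < 0)) stop("NMF requires a nonnegative input matrix")
  r <- check_rank_arg(r, dim(X))
  m <- nrow(X); n <- ncol(X)

  set.seed(as.integer(seed))
  scale <- sqrt(max(mean(X), EPS_DIV) / r)
  W <- matrix(stats::runif(m * r), m, r) * scale
  H <- matrix(stats::runif(r * n), r, n) * scale

  obj <- frob2_residual(X, W, H)
  trace <- numeric(max_iter + 1)
  trace[1] <- obj
  h_min <- min(H); w_min <- min(W)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    W <- W * (X %*% t(H)) / (W %*% (H %*% t(H)) + EPS_DIV)
    H <- H * (t(W) %*% X) / ((t(W) %*% W) %*% H + EPS_DIV)
    h_min <- min(h_min, H); w_min <- min(w_min, W)
    obj_new <- frob2_residual(X, W, H)
    trace[it + 1] <- obj_new
    if (abs(obj - obj_new) / max(obj, EPS_DIV) < tol) {
      converged <- TRUE
      obj <- obj_new
      break
    }
    obj <- obj_new
  }
  new_factor_pair(W, H, r, "nmf", trace[seq_len(it + 1)], converged, it,
                  h_min, w_min)
}

#' Semi-nonnegative matrix factorization
#'
#' Factorizes a mixed-sign matrix `X` as `W %*% H` with `H >= 0` and `W`
#' unconstrained in sign, minimising `||X - W H||_F^2` with the Ding et al.
#' alternating updates: `W <- X %*% pinv(H)` (exact least-squares step via
#' the Moore-Penrose pseudo-inverse) followed by the elementwise
#' multiplicative update
#' `H <- H * sqrt( ((W'X)^pos + (W'W)^neg H) / ((W'X)^neg + (W'W)^pos H) )`,
#' where `M^pos`/`M^neg` are the nonnegative positive/negative parts of `M`
#' (see [split_signs()]).
#'
#' @inheritParams nmf_decompose
#' @param X real matrix, mixed signs allowed; must not be all zero.
#' @param init `"kmeans"` (default) clusters the columns of `X` into `r`
#'   groups and starts `H` at the 0/1 indicator plus 0.2, `W = X pinv(H)`;
#'   `"random"` starts `H` at `|N(0,1)|`.
#' @return a `factor_pair` (see [nmf_decompose()]); `mode = "seminmf"`.
#' @export
semi_nmf_decompose <- function(X, r, max_iter = 500, tol = 1e-6, seed = 1L,
                               init = c("kmeans", "random")) {
  stop_if_not_matrix(X)
  init <- match.arg(init)
  r <- check_rank_arg(r, dim(X))
  if (all(X == 0)) stop("all-zero input: semi-NMF is degenerate")
  n <- ncol(X)

  set.seed(as.integer(seed))
  H <- NULL
  if (init == "kmeans") {
    km <- tryCatch(
      suppressWarnings(stats::kmeans(t(X), centers = r, nstart = 3,
                                     iter.max = 100)),
      error = function(e) NULL)
    if (!is.null(km)) {
      H <- matrix(0.2, r, n)
      H[cbind(km$cluster, seq_len(n))] <- 1.2
    }
  }
  if (is.null(H)) {
    H <- abs(matrix(stats::rnorm(r * n), r, n))
  }
  W <- X %*% pinv(H)

  obj <- frob2_residual(X, W, H)
  trace <- numeric(max_iter + 1)
  trace[1] <- obj
  h_min <- min(H)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    W <- X %*% pinv(H)
    WtX <- split_signs(t(W) %*% X)
    WtW <- split_signs(t(W) %*% W)
    H <- H * sqrt((WtX$pos + WtW$neg %*% H) /
                    (WtX$neg + WtW$pos %*% H + EPS_DIV))
    h_min <- min(h_min, H)
    obj_new <- frob2_residual(X, W, H)
    trace[it + 1] <- obj_new
    if (abs(obj - obj_new) / max(obj, EPS_DIV) < tol) {
      converged <- TRUE
      obj <- obj_new
      break
    }
    obj <- obj_new
  }
  new_factor_pair(W, H, r, "seminmf", trace[seq_len(it + 1)], converged, it,
                  h_min, NA_real_)
}

#' Frobenius reconstruction error of a factorization
#'
#' Returns `||X - W H||_F` (unsquared Frobenius norm; the squared objective
#' is available per iteration in `fp$objective_trace`).
#'
#' @param X the factorized matrix.
#' @param fp a `factor_pair`.
#' @return nonnegative scalar.
#' @export
reconstruction_error <- function(X, fp) {
  stop_if_not_matrix(X)
  if (nrow(X) != nrow(fp$W) || ncol(X) != ncol(fp$H)) {
    stop("shape mismatch between X and the factor pair")
  }
  sqrt(frob2_residual(X, fp$W, fp$H))
}

#' Serialize a factor pair to CSV + JSON sidecar
#'
#' Writes `W.csv` (drugs x components), `H.csv` (drugs x components, i.e.
#' the transpose of H) and `factorization.json` (r, mode, iterations,
#' final objective) under `dir`.
#' @param fp a `factor_pair`.
#' @param dir output directory (created if missing).
#' @param drug_ids optional row labels.
#' @export
write_factor_pair <- function(fp, dir, drug_ids = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  W <- fp$W; Ht <- t(fp$H)
  if (!is.null(drug_ids)) {
    rownames(W) <- drug_ids
    rownames(Ht) <- drug_ids
  }
  utils::write.csv(W, file.path(dir, "W.csv"),
                   row.names = !is.null(drug_ids))
  utils::write.csv(Ht, file.path(dir, "H.csv"),
                   row.names = !is.null(drug_ids))
  meta <- list(r = fp$r, mode = fp$mode, iterations = fp$iterations,
               converged = fp$converged,
               final_objective = fp$objective_trace[length(fp$objective_trace)])
  jsonlite::write_json(meta, file.path(dir, "factorization.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
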