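# The two-phase DDINMF pipeline.
#
# Training: factorize the DDI adjacency matrix A ~ W H (NMF on the binary
# network, semi-NMF on the signed network), then regress the drug feature
# matrix F onto the transposed encoding matrix, H' = F B, with SIMPLS.
#
# Prediction (cold start): new drugs have no known interactions, so their
# feature rows F_x are mapped into the latent space, H_x' = F_x B, and
# interaction scores against the known drugs are reconstructed as
# A_x = (W H_x)'. In binary mode a larger score means a more likely
# interaction; in comprehensive mode the sign of the score carries
# enhancive (+) versus degressive (-).

#' Train a DDINMF model
#'
#' @param A a [signed_adjacency()] over the training (known) drugs.
#' @param F feature matrix with rownames matching `drug_ids(A)` in the
#'   same order (rows = drugs, columns = binary descriptors).
#' @param mode `"comprehensive"` factorizes the signed matrix with
#'   semi-NMF; `"binary"` first turns every -1 entry into +1 and uses NMF.
#' @param r latent dimension, or `"auto"` for `floor(numerical rank / 2)`
#'   of the factorized matrix.
#' @param k number of SIMPLS latent factors.
#' @param reduce `NULL` for no feature reduction, or a list with elements
#'   `bandwidth` (kernel variance), `n_components` (integer or `"auto"`,
#'   which applies [estimate_dimension()]) and optionally `epsilon`.
#' @param factor_opts list of options passed to the factorization
#'   (`max_iter`, `tol`, `init`).
#' @param seed integer seed controlling factorization initialization.
#' @return object of class `ddinmf_model`.
#' @export
ddinmf_train <- function(A, F, mode = c("comprehensive", "binary"),
                         r = "auto", k = 20, reduce = NULL,
                         factor_opts = list(), seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(rownames(F)) || !identical(rownames(F), drug_ids(A))) {
    stop("rownames(F) must match drug_ids(A) exactly (same drugs, same order)")
  }
  X <- if (mode == "binary") {
    B <- binarize(A)
    matrix(as.numeric(B), nrow(B), dimnames = dimnames(B))
  } else {
    matrix(as.numeric(A), nrow(A), dimnames = dimnames(A))
  }
  if (identical(r, "auto")) {
    r <- max(1L, numerical_rank(X) %/% 2L)
  }

  fo <- utils::modifyList(list(max_iter = 500, tol = 1e-6, init = "kmeans"),
                          factor_opts)
  fp <- if (mode == "binary") {
    nmf_decompose(X, r = r, max_iter = fo$max_iter, tol = fo$tol, seed = seed)
  } else {
    semi_nmf_decompose(X, r = r, max_iter = fo$max_iter, tol = fo$tol,
                       seed = seed, init = fo$init)
  }

  kpca <- NULL
  F_eff <- F
  if (!is.null(reduce)) {
    if (is.null(reduce$bandwidth)) stop("reduce$bandwidth is required")
    nc <- reduce$n_components
    if (is.null(nc) || identical(nc, "auto")) {
      nc <- min(estimate_dimension(F, reduce$epsilon %||% 1e-6), nrow(F) - 1L)
    }
    kp <- kpca_fit_transform(F, n_components = nc,
                             bandwidth = reduce$bandwidth)
    kpca <- kp$map
    F_eff <- kp$coordinates
  }

  plsr <- simpls_fit(F_eff, t(fp$H), k = k)

  structure(
    list(mode = mode, factor_pair = fp, plsr = plsr, kpca = kpca,
         training_drug_ids = drug_ids(A), r = fp$r, k = k,
         n_features = ncol(F), seed = as.integer(seed)),
    class = "ddinmf_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ddinmf_model <- function(x, ...) {
  cat(sprintf(
    "<ddinmf_model> mode=%s, %d training drugs, r=%d latent communities, k=%d PLS factors%s\n",
    x$mode, length(x$training_drug_ids), x$r, x$k,
    if (is.null(x$kpca)) "" else
      sprintf(", kernel-PCA reduced to %d dims", x$kpca$n_components)))
  invisible(x)
}

#' Predict interaction scores for new drugs
#'
#' Maps new-drug feature rows into the latent space with the trained
#' regression, `H_x' = F_x B`, then reconstructs scores against the known
#' drugs, `A_x = (W H_x)'`.
#'
#' @param model a `ddinmf_model`.
#' @param F_x feature matrix of new drugs (raw feature dimension; the
#'   model's kernel-PCA map, if any, is applied internally). Rownames are
#'   used as new-drug ids.
#' @return n x m score matrix (new drugs x known drugs) with drug ids as
#'   dimnames. `n = 0` gives an empty 0 x m matrix.
#' @export
ddinmf_predict <- function(model, F_x) {
  if (!is.matrix(F_x)) stop("`F_x` must be a matrix")
  if (ncol(F_x) != model$n_features) {
    stop(sprintf("F_x has %d columns; model was trained on %d features",
                 ncol(F_x), model$n_features))
  }
  m <- length(model$training_drug_ids)
  if (nrow(F_x) == 0) {
    return(matrix(numeric(0), 0, m,
                  dimnames = list(character(0), model$training_drug_ids)))
  }
  if (!is.null(rownames(F_x)) &&
      any(rownames(F_x) %in% model$training_drug_ids)) {
    warning("some new-drug ids overlap the training drugs")
  }
  F_eff <- if (is.null(model$kpca)) F_x else kpca_transform(model$kpca, F_x)
  Hx_t <- plsr_predict(model$plsr, F_eff)        # n x r
  scores <- Hx_t %*% t(model$factor_pair$W)      # (W H_x)' = H_x' W'
  dimnames(scores) <- list(rownames(F_x), model$training_drug_ids)
  scores
}

#' Threshold scores into hard interaction labels
#'
#' Comprehensive mode: `+1` if score > tau, `-1` if score < -tau, else 0
#' (with the default `tau = 0` the sign of the score decides enhancive
#' versus degressive). Binary mode: 1 if score > tau else 0.
#'
#' @param scores numeric matrix (or vector) of predicted scores.
#' @param mode `"comprehensive"` or `"binary"`.
#' @param tau nonnegative decision threshold.
#' @return integer label matrix of the same shape.
#' @export
classify_scores <- function(scores, mode = c("comprehensive", "binary"),
                            tau = 0) {
  mode <- match.arg(mode)
  if (!is.numeric(tau) || length(tau) != 1 || tau < 0) {
    stop("`tau` must be a nonnegative scalar")
  }
  labels <- if (mode == "comprehensive") {
    (scores > tau) - (scores < -tau)
  } else {
    (scores > tau) * 1
  }
  storage.mode(labels) <- "integer"
  labels
}

#' Serialize a trained DDINMF model to a directory
#'
#' Writes the factor pair, the PLSR model and a `model.json` manifest.
#' The kernel-PCA map (if any) has its training points stored as CSV.
#' @param model a `ddinmf_model`.
#' @param dir output directory.
#' @export
write_ddinmf_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_factor_pair(model$factor_pair, file.path(dir, "factors"),
                    drug_ids = model$training_drug_ids)
  write_plsr_model(model$plsr, file.path(dir, "plsr"))
  jsonlite::write_json(
    list(mode = model$mode, r = model$r, k = model$k,
         n_features = model$n_features, seed = model$seed,
         training_drug_ids = model$training_drug_ids,
         kpca = !is.null(model$kpca)),
    file.path(dir, "model.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
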