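# Signed-network structure: triangle census under balance theory,
# latent-space embeddings of the factor matrices, and degree-embedding
# correlations.
#
# Balance theory classifies a triangle by its number of negative edges:
# 0 or 2 negatives = balanced ("the friend of my friend is my friend" /
# "the enemy of my enemy is my friend"), 1 negative = unbalanced,
# 3 negatives = weakly balanced.

#' Census of signed triangles
#'
#' Counts every unordered node triple whose three pairwise entries are all
#' nonzero, classified by the multiset of edge signs:
#' `n_ppp` = all positive, `n_pnn` = two negatives, `n_npp` = exactly one
#' negative, `n_nnn` = all negative. Counting uses traces of products of
#' the positive-part and negative-part adjacency matrices (an O(m^3)
#' matrix-multiplication pass).
#'
#' @param A a [signed_adjacency()].
#' @return object of class `triangle_census`: list with the four pattern
#'   counts plus `n_balanced` (= n_ppp + n_pnn), `n_unbalanced` (= n_npp),
#'   `n_weak` (= n_nnn) and `n_total`.
#' @export
triangle_census <- function(A) {
  P <- (unclass(A) == 1L) * 1
  N <- (unclass(A) == -1L) * 1
  PP <- P %*% P
  NN <- N %*% N
  tr <- function(M) sum(diag(M))
  # a triangle with j negative edges yields 2 directed closed walks for
  # each distinct cyclic type pattern, 6 in total
  n_ppp <- round(tr(PP %*% P) / 6)
  n_npp <- round(tr(PP %*% N) / 2)
  n_pnn <- round(tr(NN %*% P) / 2)
  n_nnn <- round(tr(NN %*% N) / 6)
  structure(
    list(n_ppp = n_ppp, n_pnn = n_pnn, n_npp = n_npp, n_nnn = n_nnn,
         n_balanced = n_ppp + n_pnn, n_unbalanced = n_npp, n_weak = n_nnn,
         n_total = n_ppp + n_pnn + n_npp + n_nnn),
    class = "triangle_census")
}

#' @export
print.triangle_census <- function(x, ...) {
  cat(sprintf(
    "Signed triangle census (%d triangles):\n  (+,+,+) %d  (+,-,-) %d  [balanced %d]\n  (-,+,+) %d  [unbalanced]\n  (-,-,-) %d  [weakly balanced]\n",
    x$n_total, x$n_ppp, x$n_pnn, x$n_balanced, x$n_unbalanced, x$n_weak))
  invisible(x)
}

#' Fraction of balanced triangles
#'
#' @param census a `triangle_census`.
#' @param include_weak count weakly balanced (all-negative) triangles as
#'   balanced too.
#' @return value in [0, 1]; error when the census has no triangles.
#' @export
balance_fraction <- function(census, include_weak = FALSE) {
  if (census$n_total == 0) stop("network has no triangles")
  bal <- census$n_balanced + if (include_weak) census$n_weak else 0
  bal / census$n_total
}

#' Kernel-PCA embedding of factorization features
#'
#' Embeds per-drug latent features derived from a factorization — rows of
#' the community matrix W (`source = "community"`, how each drug
#' contributes to the latent communities) or columns of the encoding
#' matrix H (`source = "encoding"`, how strongly each drug belongs to
#' them) — into `c` coordinates with Gaussian kernel PCA.
#'
#' @param fp a `factor_pair`.
#' @param source `"community"` or `"encoding"`.
#' @param c number of embedded coordinates (default 3, for 3-D
#'   visualisation).
#' @param bandwidth kernel variance (see [kpca_fit_transform()]).
#' @return object of class `latent_embedding`: list with `coordinates`
#'   (m x c, columns ordered by descending eigenvalue), `source`,
#'   `eigenvalues`.
#' @export
latent_embedding <- function(fp, source = c("community", "encoding"),
                             c = 3, bandwidth = 4) {
  source <- match.arg(source)
  M <- if (source == "community") fp$W else t(fp$H)
  if (source == "encoding" && min(fp$H) < 0) {
    stop("encoding matrix H must be nonnegative")
  }
  if (c > nrow(M)) stop("`c` cannot exceed the number of drugs")
  kp <- kpca_fit_transform(M, n_components = c, bandwidth = bandwidth)
  structure(
    list(coordinates = kp$coordinates, source = source,
         eigenvalues = kp$map$eigenvalues),
    class = "latent_embedding")
}

#' Spearman correlation between degrees and an embedded component
#'
#' @param emb a `latent_embedding`.
#' @param profile a [degree_profile()] over the same drugs in the same
#'   order.
#' @param which `"degree"` (total degree) or `"diff"` (positive minus
#'   negative degree).
#' @param component index of the embedded coordinate to correlate with.
#' @return Spearman rho in [-1, 1]; constant inputs are an error.
#' @export
degree_embedding_correlation <- function(emb, profile,
                                         which = c("degree", "diff"),
                                         component = 1) {
  which <- match.arg(which)
  x <- profile[[which]]
  if (component < 1 || component > ncol(emb$coordinates)) {
    stop("`component` out of range")
  }
  y <- emb$coordinates[, component]
  if (length(x) != length(y)) stop("profile and embedding sizes differ")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for constant input")
  }
  stats::cor(x, y, method = "spearman")
}
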