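# Shared fixture builders: all fixtures are generated in code.

# random symmetric signed adjacency over m drugs
random_signed_adjacency <- function(m, p_edge = 0.3, p_neg = 0.3, seed = 1) {
  set.seed(seed)
  A <- matrix(0L, m, m)
  up <- which(upper.tri(A), arr.ind = TRUE)
  s <- ifelse(stats::runif(nrow(up)) < p_edge,
              ifelse(stats::runif(nrow(up)) < p_neg, -1L, 1L), 0L)
  A[up] <- s
  A[up[, c(2, 1)]] <- s
  signed_adjacency(A, sprintf("d%03d", seq_len(m)))
}

# exhaustive O(m^3) triangle census, independent of the package path
brute_triangle_census <- function(A) {
  m <- nrow(A)
  counts <- c(n_ppp = 0, n_pnn = 0, n_npp = 0, n_nnn = 0)
  if (m >= 3) {
    for (i in 1:(m - 2)) for (j in (i + 1):(m - 1)) for (k in (j + 1):m) {
      e <- c(A[i, j], A[i, k], A[j, k])
      if (all(e != 0)) {
        nn <- sum(e == -1)
        counts[c("n_ppp", "n_npp", "n_pnn", "n_nnn")[nn + 1]] <-
          counts[c("n_ppp", "n_npp", "n_pnn", "n_nnn")[nn + 1]] + 1
      }
    }
  }
  as.list(counts)
}

# O(n^2) Mann-Whitney AUROC oracle with tie credit 1/2
brute_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# tiny exact signed factorization fixture: X = W0 H0, H0 >= 0
exact_semi_case <- function(seed = 1, m = 8, n = 10, r = 2) {
  set.seed(seed)
  W0 <- matrix(stats::rnorm(m * r), m, r)
  H0 <- matrix(stats::runif(r * n), r, n)
  list(X = W0 %*% H0, W0 = W0, H0 = H0, r = r)
}

expect_trace_nonincreasing <- function(fp, tol = 1e-10) {
  d <- diff(fp$objective_trace)
  expect_true(all(d <= tol),
              label = sprintf("objective trace non-increasing (max step %.3g)",
                              max(d)))
}
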