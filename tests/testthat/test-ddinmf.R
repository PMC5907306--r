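make_aligned_features <- function(A, p = 12, seed = 1) {
  set.seed(seed)
  F <- matrix(rbinom(nrow(A) * p, 1, 0.3), nrow(A), p)
  storage.mode(F) <- "double"
  rownames(F) <- drug_ids(A)
  F
}

test_that("training smoke contract on a tiny 7-drug network", {
  A <- random_signed_adjacency(7, p_edge = 0.5, seed = 2)
  F <- make_aligned_features(A)
  m <- ddinmf_train(A, F, mode = "comprehensive", r = 2, k = 2, seed = 1)
  expect_s3_class(m, "ddinmf_model")
  expect_equal(m$r, 2)
  X <- matrix(as.numeric(A), nrow(A))
  expect_true(is.finite(reconstruction_error(X, m$factor_pair)))
  expect_gte(min(m$factor_pair$H), 0)
})

test_that("planted exact structure is recovered by self-prediction", {
  # A entries generated from a signed rank-2 model, features = H0'
  set.seed(8)
  m_drugs <- 24
  W0 <- matrix(rnorm(m_drugs * 2), m_drugs, 2)
  H0 <- matrix(runif(2 * m_drugs), 2, m_drugs)
  S <- W0 %*% H0
  S <- (S + t(S)) / 2
  A_raw <- matrix(0L, m_drugs, m_drugs)
  A_raw[abs(S) > stats::quantile(abs(S), 0.5)] <- 1L
  A_raw <- A_raw * sign(S)
  diag(A_raw) <- 0L
  A_raw[lower.tri(A_raw)] <- t(A_raw)[lower.tri(A_raw)]
  A <- signed_adjacency(A_raw, sprintf("d%02d", seq_len(m_drugs)))
  F <- t(H0); rownames(F) <- drug_ids(A)
  model <- ddinmf_train(A, F, mode = "comprehensive", r = 2, k = 2, seed = 3)
  # self-prediction on the training drugs deliberately overlaps ids
  self_scores <- suppressWarnings(ddinmf_predict(model, F))
  rho <- suppressWarnings(
    cor(as.vector(self_scores), as.numeric(A), method = "spearman"))
  # discretizing the planted rank-2 scores into {-1,0,1} caps the
  # attainable correlation; observed 0.53-0.69 across seeds
  expect_gt(rho, 0.5)
})

test_that("binary mode equals training on the binarized network", {
  A <- random_signed_adjacency(15, seed = 5)
  F <- make_aligned_features(A, seed = 5)
  m1 <- ddinmf_train(A, F, mode = "binary", r = 3, k = 2, seed = 9)
  B <- binarize(A)
  m2 <- ddinmf_train(signed_adjacency(unclass(B)[, ], drug_ids(A)), F,
                     mode = "binary", r = 3, k = 2, seed = 9)
  expect_equal(m1$factor_pair$W, m2$factor_pair$W)
  expect_equal(m1$plsr$B, m2$plsr$B)
})

test_that("prediction contracts hold", {
  A <- random_signed_adjacency(20, seed = 6)
  F <- make_aligned_features(A, p = 10, seed = 6)
  model <- ddinmf_train(A, F, mode = "comprehensive", r = 4, k = 3, seed = 2)

  # duplicate of a training drug scores close to its reconstructed row
  d <- 7
  F_new <- F[d, , drop = FALSE]
  rownames(F_new) <- "new1"
  s <- ddinmf_predict(model, F_new)
  recon <- (model$factor_pair$W %*% model$factor_pair$H)[, d]
  train_fit <- plsr_predict(model$plsr, F)
  plsr_resid <- max(abs(train_fit - t(model$factor_pair$H)))
  bound <- ncol(model$factor_pair$W) * max(abs(model$factor_pair$W)) *
    plsr_resid + 1e-8
  expect_lt(max(abs(as.numeric(s) - recon)), bound)

  # all-mean feature row maps to the mean latent profile through W
  F_mean <- matrix(colMeans(F), 1, dimnames = list("new2", NULL))
  s2 <- ddinmf_predict(model, F_mean)
  expect_equal(as.numeric(s2),
               as.numeric(model$factor_pair$W %*% model$plsr$response_means),
               tolerance = 1e-10)

  # zero new drugs give an empty 0 x m matrix
  s0 <- ddinmf_predict(model, F[0, , drop = FALSE])
  expect_equal(dim(s0), c(0L, 20L))

  expect_error(ddinmf_predict(model, F[, 1:5]), "columns")
  expect_warning(ddinmf_predict(model, F[1:2, ]), "overlap")
})

test_that("kernel-PCA reduction integrates into the pipeline", {
  A <- random_signed_adjacency(25, seed = 9)
  F <- make_aligned_features(A, p = 15, seed = 9)
  m <- ddinmf_train(A, F, mode = "comprehensive", r = 3, k = 3,
                    reduce = list(bandwidth = 4, n_components = 8), seed = 1)
  expect_equal(m$kpca$n_components, 8)
  s <- ddinmf_predict(m, matrix(rbinom(15, 1, 0.3), 1, 15,
                                dimnames = list("x", NULL)))
  expect_true(all(is.finite(s)))
})

test_that("classify_scores thresholds as documented", {
  sc <- matrix(c(0.5, -0.5, 0.0), 1)
  expect_identical(as.integer(classify_scores(sc, "comprehensive", 0.1)),
                   c(1L, -1L, 0L))
  expect_identical(as.integer(classify_scores(sc, "binary", 0.1)),
                   c(1L, 0L, 0L))
  # huge tau suppresses every call
  expect_true(all(classify_scores(sc, "comprehensive", 1e9) == 0L))
  # brute-force elementwise agreement
  set.seed(1)
  sc <- matrix(rnorm(60), 6, 10)
  lab <- classify_scores(sc, "comprehensive", 0.3)
  for (i in seq_len(6)) for (j in seq_len(10)) {
    expect_identical(lab[i, j],
                     if (sc[i, j] > 0.3) 1L else if (sc[i, j] < -0.3) -1L
                     else 0L)
  }
  expect_error(classify_scores(sc, "binary", -1), "nonnegative")
})

test_that("end-to-end run is deterministic under a fixed seed", {
  A <- random_signed_adjacency(18, seed = 12)
  F <- make_aligned_features(A, seed = 12)
  F_new <- matrix(rbinom(24, 1, 0.3), 2, 12,
                  dimnames = list(c("x1", "x2"), NULL))
  s1 <- ddinmf_predict(ddinmf_train(A, F, "comprehensive", r = 3, k = 2,
                                    seed = 7), F_new)
  s2 <- ddinmf_predict(ddinmf_train(A, F, "comprehensive", r = 3, k = 2,
                                    seed = 7), F_new)
  expect_identical(s1, s2)
})

test_that("train validates drug alignment and r = auto", {
  A <- random_signed_adjacency(10, seed = 1)
  F <- make_aligned_features(A)
  rownames(F)[1] <- "zzz"
  expect_error(ddinmf_train(A, F), "rownames")

  F <- make_aligned_features(A)
  m <- ddinmf_train(A, F, mode = "binary", r = "auto", k = 2, seed = 1)
  X <- matrix(as.numeric(binarize(A)), 10)
  expect_equal(m$r, max(1L, qr(X)$rank %/% 2L))
})
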