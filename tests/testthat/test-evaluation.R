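test_that("cold-start folds partition the drugs evenly and reproducibly", {
  ids <- sprintf("d%02d", 1:10)
  sch <- make_cv_folds(ids, K = 5, seed = 3)
  expect_length(sch$folds, 5)
  expect_true(all(lengths(sch$folds) == 2))
  expect_setequal(unlist(sch$folds), ids)
  expect_equal(anyDuplicated(unlist(sch$folds)), 0)

  # uneven division: sizes differ by at most one
  sch2 <- make_cv_folds(sprintf("d%02d", 1:13), K = 4, seed = 1)
  expect_lte(diff(range(lengths(sch2$folds))), 1)

  expect_identical(make_cv_folds(ids, 5, seed = 3), sch)
  expect_false(identical(make_cv_folds(ids, 5, seed = 4)$folds, sch$folds))
  expect_error(make_cv_folds(ids, K = 11), "exceed")
  expect_error(make_cv_folds(ids, K = 1), "at least 2")
})

test_that("test pairs are test x train only (set-arithmetic oracle)", {
  ids <- sprintf("d%02d", 1:12)
  sch <- make_cv_folds(ids, K = 3, seed = 9)
  for (f in sch$folds) {
    train <- setdiff(ids, f)
    test_pairs <- expand.grid(a = f, b = train, stringsAsFactors = FALSE)
    expect_equal(nrow(test_pairs), length(f) * length(train))
    expect_false(any(test_pairs$b %in% f))       # no test x test
    expect_false(any(test_pairs$a %in% train))   # no train leakage
  }
})

test_that("signed evaluation transforms scores as documented", {
  # all enhancive/none reduces to the untransformed binary case
  sc <- c(2, -1, 0.5, 0)
  tr <- c(1, 0, 1, 0)
  se <- signed_eval_scores(sc, tr)
  expect_equal(se$scores, sc)
  expect_equal(se$labels, as.integer(tr))

  # degressive scores are negated and labelled positive
  se <- signed_eval_scores(-3, -1)
  expect_equal(se$scores, 3)
  expect_equal(se$labels, 1L)

  # string labels accepted
  se <- signed_eval_scores(c(1, -2, 0.1), c("enhancive", "degressive", "none"))
  expect_equal(se$scores, c(1, 2, 0.1))
  expect_equal(se$labels, c(1L, 1L, 0L))
  expect_error(signed_eval_scores(1, "maybe"), "unknown truth")

  # a perfectly signed predictor yields AUROC 1 downstream
  truth <- c(rep(1, 5), rep(-1, 5), rep(0, 10))
  scores <- ifelse(truth == 1, 1, ifelse(truth == -1, -1, 0))
  se <- signed_eval_scores(scores, truth)
  expect_equal(auroc(se$scores, se$labels), 1.0)
  expect_equal(aupr(se$scores, se$labels), 1.0)

  # "abs" option folds non-interaction scores
  se <- signed_eval_scores(c(-2, 1), c(0, 1), noninteraction = "abs")
  expect_equal(se$scores, c(2, 1))
})

test_that("auroc equals the pairwise Mann-Whitney oracle", {
  expect_equal(auroc(c(3, 2, 1), c(1, 1, 0)), 1.0)
  expect_equal(auroc(c(1, 1), c(1, 0)), 0.5)  # tie midrank
  for (seed in 1:5) {
    set.seed(seed)
    n <- 200
    scores <- sample(round(rnorm(n), 1))  # rounding forces ties
    labels <- rbinom(n, 1, 0.3)
    if (length(unique(labels)) < 2) next
    expect_equal(auroc(scores, labels), brute_auroc(scores, labels),
                 tolerance = 1e-12)
  }
  expect_error(auroc(c(1, 2), c(1, 1)), "both classes")
})

test_that("auroc is invariant under strictly monotone score transforms", {
  set.seed(10)
  scores <- rnorm(100)
  labels <- rbinom(100, 1, 0.4)
  a0 <- auroc(scores, labels)
  expect_equal(auroc(exp(scores), labels), a0)
  expect_equal(auroc(2 * scores + 5, labels), a0)
  expect_equal(auroc(rank(scores), labels), a0)
})

test_that("aupr behaves at the boundaries and under ties", {
  expect_equal(aupr(c(3, 2, 1), c(1, 1, 0)), 1.0)
  expect_equal(aupr(c(1, 2, 3), c(1, 1, 0)), mean(c(1 / 2, 2 / 3)))
  # all scores tied: precision everywhere equals the prevalence
  expect_equal(aupr(rep(1, 10), c(rep(1, 4), rep(0, 6))), 0.4)
  # order of tied entries must not matter
  sc <- c(2, 1, 1, 1, 0); lab1 <- c(1, 1, 0, 0, 0); lab2 <- c(1, 0, 0, 1, 0)
  expect_equal(aupr(sc, lab1), aupr(sc, lab2))
})

test_that("shuffled labels give chance-level metrics", {
  set.seed(77)
  aucs <- replicate(10, {
    scores <- rnorm(400)
    labels <- sample(c(rep(1, 100), rep(0, 300)))
    auroc(scores, labels)
  })
  expect_gt(mean(aucs), 0.45)
  expect_lt(mean(aucs), 0.55)
})

test_that("hitting ratio counts confirmed top-k pairs", {
  cand <- sprintf("p%02d", 1:20)
  sc <- 20:1
  expect_equal(unname(hitting_ratio(cand, sc, cand[1:5], k_list = 5)), 1.0)
  expect_equal(unname(hitting_ratio(cand, sc, character(0), c(5, 10))),
               c(0, 0))
  # hypergeometric expectation: random scores, 10% truth density
  set.seed(3)
  ratios <- replicate(300, {
    truth <- sample(cand, 2)
    unname(hitting_ratio(cand, sample(20), truth, 10))
  })
  expect_lt(abs(mean(ratios) - 0.1), 0.03)
  expect_error(hitting_ratio(character(0), numeric(0), cand, 1), "empty")
  expect_error(hitting_ratio(cand, sc, cand, 21), "number of candidates")
})

test_that("run_cv is deterministic and aggregates per-fold results", {
  b <- generate_benchmark("small", seed = 2)
  cfg <- list(mode = "binary", K = 4, k = 5, repeats = 2, seed = 11,
              factor_opts = list(max_iter = 60))
  r1 <- run_cv(b$adjacency, b$features, cfg)
  r2 <- run_cv(b$adjacency, b$features, cfg)
  expect_equal(r1$per_fold, r2$per_fold)
  expect_equal(nrow(r1$per_fold), 8)
  expect_equal(r1$auroc, mean(tapply(r1$per_fold$auroc, r1$per_fold$rep,
                                     mean)))
  expect_gte(r1$auroc_sd, 0)
  expect_gt(r1$auroc, 0.5)  # planted structure is learnable above chance
})

test_that("run_cv signed mode reduces to binary labels correctly", {
  b <- generate_benchmark("small", seed = 4)
  res <- run_cv(b$adjacency, b$features,
                list(mode = "comprehensive", K = 3, k = 5, seed = 5,
                     factor_opts = list(max_iter = 60)))
  expect_true(all(res$per_fold$auroc >= 0 & res$per_fold$auroc <= 1))
  expect_true(all(res$per_fold$aupr >= 0 & res$per_fold$aupr <= 1))
})
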