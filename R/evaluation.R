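# Cold-start cross-validation and ranking metrics.
#
# The evaluation scenario matches screening for newly developed drugs: in
# each fold 1/K of the drugs are removed and treated as "new" (all their
# interactions hidden). The model trains on pairs among the remaining
# drugs only and is scored on new x known pairs only — never on
# new x new pairs, which would require two cold-start drugs at once.

#' Random drug folds for cold-start cross-validation
#'
#' @param drug_ids character vector of drug identifiers.
#' @param K number of folds (>= 2, <= number of drugs).
#' @param seed integer seed; the same seed reproduces the same partition.
#' @return object of class `cv_scheme`: list with `K`, `folds` (list of K
#'   disjoint id vectors whose sizes differ by at most one), `seed`.
#' @export
make_cv_folds <- function(drug_ids, K = 10, seed = 1L) {
  n <- length(drug_ids)
  if (K < 2) stop("`K` must be at least 2")
  if (K > n) stop("`K` cannot exceed the number of drugs")
  set.seed(as.integer(seed))
  perm <- sample(drug_ids)
  fold_of <- rep(seq_len(K), length.out = n)
  folds <- split(perm, fold_of)
  names(folds) <- NULL
  structure(list(K = as.integer(K), folds = folds, seed = as.integer(seed)),
            class = "cv_scheme")
}

#' Transform signed predictions for AUROC/AUPR computation
#'
#' In comprehensive (signed) prediction, enhancive interactions tend to
#' score above zero and degressive interactions below zero. To reuse the
#' binary ranking metrics, both interaction types are labelled positive and
#' degressive scores are negated, so a well-signed prediction ranks every
#' true interaction above the non-interactions.
#'
#' @param scores numeric vector of predicted pair scores.
#' @param truth vector of pair labels: `+1`/`"enhancive"`,
#'   `-1`/`"degressive"`, `0`/`"none"`.
#' @param noninteraction how non-interaction scores enter the comparison:
#'   `"raw"` (default, scores unchanged) or `"abs"` (absolute value, which
#'   treats a strongly negative score on a non-pair as a confident —
#'   wrong — degressive call).
#' @return list with `scores` (transformed) and `labels` (1 = interaction,
#'   0 = none).
#' @export
signed_eval_scores <- function(scores, truth,
                               noninteraction = c("raw", "abs")) {
  noninteraction <- match.arg(noninteraction)
  if (length(scores) != length(truth)) {
    stop("`scores` and `truth` must have the same length")
  }
  tr <- as.character(truth)
  tr[tr == "enhancive"] <- "1"
  tr[tr == "degressive"] <- "-1"
  tr[tr == "none"] <- "0"
  if (!all(tr %in% c("-1", "0", "1"))) {
    stop("unknown truth label(s): ",
         paste(unique(truth[!tr %in% c("-1", "0", "1")]), collapse = ", "))
  }
  tr <- as.integer(tr)
  out <- ifelse(tr == -1L, -scores, scores)
  if (noninteraction == "abs") {
    out[tr == 0L] <- abs(scores[tr == 0L])
  }
  list(scores = as.numeric(out), labels = as.integer(tr != 0L))
}

check_two_classes <- function(labels) {
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  if (length(unique(labels)) < 2) {
    stop("both classes must be present to compute a ranking metric")
  }
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney probability with midrank tie handling:
#' `AUROC = (sum of positive-score midranks - n1 (n1 + 1) / 2) / (n1 n0)`.
#'
#' @param scores numeric vector of scores (larger = more positive).
#' @param labels 0/1 vector; both classes must be present.
#' @return AUROC in [0, 1].
#' @export
auroc <- function(scores, labels) {
  check_two_classes(labels)
  r <- rank(scores, ties.method = "average")
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Step-summation form (average precision): scores are sorted in
#' decreasing order and precision is accumulated at each recall step, i.e.
#' at each true positive. Tied scores are processed as a block so the
#' result does not depend on their internal order.
#'
#' @inheritParams auroc
#' @return AUPR in (0, 1].
#' @export
aupr <- function(scores, labels) {
  check_two_classes(labels)
  o <- order(scores, decreasing = TRUE)
  lab <- labels[o]
  sc <- scores[o]
  # within a tie block, use the block-end cumulative counts for precision
  tp <- cumsum(lab)
  n_seen <- seq_along(lab)
  block_end <- rev(!duplicated(rev(sc)))   # TRUE at the last index of a block
  blk_id <- cumsum(c(TRUE, sc[-1] != sc[-length(sc)]))
  tp_blk <- tp[block_end][blk_id]
  n_blk <- n_seen[block_end][blk_id]
  sum((tp_blk / n_blk)[lab == 1]) / sum(lab)
}

#' Fraction of top-k predictions confirmed in a reference set
#'
#' Candidates are ranked by decreasing score; for each `k` the hitting
#' ratio is the fraction of the first `k` candidates present in `truth`.
#'
#' @param candidates character vector of candidate pair identifiers.
#' @param scores numeric scores aligned with `candidates`.
#' @param truth character vector of confirmed pair identifiers (may be
#'   empty).
#' @param k_list integer vector of cutoffs, each `<= length(candidates)`.
#' @return named numeric vector of hitting ratios, one per cutoff.
#' @export
hitting_ratio <- function(candidates, scores, truth, k_list) {
  if (length(candidates) == 0) stop("empty candidate list")
  if (length(scores) != length(candidates)) {
    stop("`scores` must align with `candidates`")
  }
  if (any(k_list < 1) || any(k_list > length(candidates))) {
    stop("each k must be in [1, number of candidates]")
  }
  ranked <- candidates[order(scores, decreasing = TRUE)]
  out <- vapply(k_list, function(k) mean(ranked[seq_len(k)] %in% truth),
                numeric(1))
  names(out) <- paste0("top", k_list)
  out
}

#' Cold-start K-fold cross-validation of DDINMF
#'
#' For each fold: drugs in the fold are held out as new drugs, the model is
#' trained on the remaining drugs' pairs, and test x train pairs are scored
#' and evaluated with AUROC/AUPR (binary mode) or their signed extension
#' (comprehensive mode, via [signed_eval_scores()]). Kernel-PCA feature
#' reduction, when enabled, is refitted inside each training fold by
#' default so held-out drugs never influence the feature map.
#'
#' @param A a [signed_adjacency()].
#' @param F feature matrix aligned with `A`.
#' @param config list of options: `mode` ("binary"/"comprehensive"),
#'   `r`, `k`, `K`, `repeats`, `seed`, `reduce`, `factor_opts`,
#'   `noninteraction` ("raw"/"abs").
#' @return object of class `cv_result`: list with `auroc`, `aupr` (grand
#'   means), `auroc_sd`, `aupr_sd` (across repeats of the per-repeat fold
#'   means), `per_fold` (data.frame: repeat, fold, auroc, aupr),
#'   `n_repeats`, `config`.
#' @export
run_cv <- function(A, F, config = list()) {
  cfg <- utils::modifyList(
    list(mode = "comprehensive", r = "auto", k = 20, K = 10, repeats = 1,
         seed = 1L, reduce = NULL, factor_opts = list(),
         noninteraction = "raw"),
    config)
  if (is.null(rownames(F)) || !identical(rownames(F), drug_ids(A))) {
    stop("rownames(F) must match drug_ids(A)")
  }
  ids <- drug_ids(A)
  rows <- list()
  for (rep_i in seq_len(cfg$repeats)) {
    rep_seed <- cfg$seed + (rep_i - 1L)
    scheme <- make_cv_folds(ids, K = cfg$K, seed = rep_seed)
    for (fold_i in seq_len(cfg$K)) {
      test_ids <- scheme$folds[[fold_i]]
      train_ids <- setdiff(ids, test_ids)
      A_tr <- signed_adjacency(unclass(A)[train_ids, train_ids],
                               train_ids)
      if (all(A_tr == 0L)) stop("fold with an empty training network")
      model <- ddinmf_train(A_tr, F[train_ids, , drop = FALSE],
                            mode = cfg$mode, r = cfg$r, k = cfg$k,
                            reduce = cfg$reduce,
                            factor_opts = cfg$factor_opts,
                            seed = rep_seed * 1000L + fold_i)
      scores <- ddinmf_predict(model, F[test_ids, , drop = FALSE])
      truth <- as.vector(unclass(A)[test_ids, train_ids])
      sc <- as.vector(scores)
      if (cfg$mode == "binary") {
        lab <- as.integer(truth != 0L)
      } else {
        se <- signed_eval_scores(sc, truth,
                                 noninteraction = cfg$noninteraction)
        sc <- se$scores
        lab <- se$labels
      }
      rows[[length(rows) + 1L]] <- data.frame(
        rep = rep_i, fold = fold_i,
        auroc = auroc(sc, lab), aupr = aupr(sc, lab))
    }
  }
  per_fold <- do.call(rbind, rows)
  rep_means <- stats::aggregate(per_fold[c("auroc", "aupr")],
                                by = list(rep = per_fold$rep), mean)
  structure(
    list(auroc = mean(rep_means$auroc), aupr = mean(rep_means$aupr),
         auroc_sd = stats::sd(rep_means$auroc),
         aupr_sd = stats::sd(rep_means$aupr),
         per_fold = per_fold, n_repeats = cfg$repeats, config = cfg),
    class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  sd_txt <- function(s) if (is.na(s)) "" else sprintf(" ± %.3f", s)
  cat(sprintf("Cold-start %d-fold CV (%s mode, %d repeat(s)):\n",
              x$config$K, x$config$mode, x$n_repeats))
  cat(sprintf("  AUROC = %.3f%s\n", x$auroc, sd_txt(x$auroc_sd)))
  cat(sprintf("  AUPR  = %.3f%s\n", x$aupr, sd_txt(x$aupr_sd)))
  invisible(x)
}
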