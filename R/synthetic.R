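# Synthetic signed DDI networks with planted community structure,
# controllable structural balance, and binary feature matrices coupled to
# community membership — so that factorization, regression, evaluation and
# balance analysis are all testable offline against a known ground truth.
#
# Sign model: each community carries a polarity in {+1, -1}; the base sign
# of an edge is the product of its endpoint polarities. Product signs make
# every triangle's negative-edge count even (0 or 2), so with zero sign
# noise the network is perfectly structurally balanced; `sign_noise`
# interpolates toward random signs.

#' Specification of a synthetic signed DDI benchmark
#'
#' @param m number of drugs.
#' @param c number of planted communities.
#' @param p_in,p_out within/between-community edge probabilities.
#' @param polarity_fraction target fraction of drugs with negative
#'   polarity; realised by giving `round(c * polarity_fraction)`
#'   communities negative polarity (community sizes are near-equal, so the
#'   drug-level fraction tracks the target). A community-level polarity
#'   keeps the sign learnable from community-coupled features.
#' @param sign_noise probability of flipping each edge sign.
#' @param p_features total feature dimension (binary descriptors,
#'   fingerprint-like).
#' @param feature_signal number of characteristic feature columns owned by
#'   each community.
#' @param feature_flip probability of flipping each signal bit.
#' @param noise_density activation probability of the non-signal noise
#'   columns (sparse, fingerprint-like background).
#' @param seed integer seed.
#' @return validated list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(m = 200, c = 4, p_in = 0.3, p_out = 0.02,
                           polarity_fraction = 0.25, sign_noise = 0.05,
                           p_features = 300, feature_signal = 40,
                           feature_flip = 0.05, noise_density = 0.1,
                           seed = 1L) {
  probs <- c(p_in = p_in, p_out = p_out,
             polarity_fraction = polarity_fraction,
             sign_noise = sign_noise, feature_flip = feature_flip,
             noise_density = noise_density)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]: ",
         paste(names(probs)[probs < 0 | probs > 1], collapse = ", "))
  }
  if (m < c || c < 1) stop("need m >= c >= 1")
  if (p_features < c * feature_signal) {
    stop("p_features must be at least c * feature_signal")
  }
  structure(
    list(m = as.integer(m), c = as.integer(c), p_in = p_in, p_out = p_out,
         polarity_fraction = polarity_fraction, sign_noise = sign_noise,
         p_features = as.integer(p_features),
         feature_signal = as.integer(feature_signal),
         feature_flip = feature_flip, noise_density = noise_density,
         seed = as.integer(seed)),
    class = "synthetic_spec")
}

#' Generate a planted-community signed network
#'
#' Drugs are assigned to `c` near-equal communities; undirected edges are
#' drawn independently with probability `p_in` (same community) or `p_out`
#' (different communities). The base sign of edge (i, j) is
#' `polarity(i) * polarity(j)`; each sign is then flipped independently
#' with probability `sign_noise`.
#'
#' @param spec a [synthetic_spec()].
#' @return object of class `synthetic_truth`: list with `adjacency`
#'   (a [signed_adjacency()]), `community` (integer per drug), `polarity`
#'   (+1/-1 per drug), `spec`.
#' @export
generate_signed_network <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) stop("`spec` must be a synthetic_spec")
  set.seed(spec$seed)
  m <- spec$m; cc <- spec$c
  ids <- sprintf("D%04d", seq_len(m))
  community <- sort(rep(seq_len(cc), length.out = m))
  n_neg_comm <- round(cc * spec$polarity_fraction)
  neg_comms <- if (n_neg_comm > 0) {
    sample(seq_len(cc), n_neg_comm)
  } else {
    integer(0)
  }
  polarity <- ifelse(community %in% neg_comms, -1L, 1L)

  A <- matrix(0L, m, m, dimnames = list(ids, ids))
  up <- which(upper.tri(A), arr.ind = TRUE)
  same <- community[up[, 1]] == community[up[, 2]]
  p_edge <- ifelse(same, spec$p_in, spec$p_out)
  has_edge <- stats::runif(nrow(up)) < p_edge
  base_sign <- polarity[up[, 1]] * polarity[up[, 2]]
  flip <- stats::runif(nrow(up)) < spec$sign_noise
  sign <- ifelse(flip, -base_sign, base_sign)
  vals <- ifelse(has_edge, sign, 0L)
  A[up] <- as.integer(vals)
  A[up[, c(2, 1)]] <- as.integer(vals)

  structure(
    list(adjacency = signed_adjacency(A, ids),
         community = stats::setNames(community, ids),
         polarity = stats::setNames(polarity, ids),
         spec = spec),
    class = "synthetic_truth")
}

#' Generate community-coupled binary drug features
#'
#' Community `g` owns columns `((g - 1) * feature_signal + 1) :
#' (g * feature_signal)`; a drug's signal bits are 1 on its own
#' community's columns and 0 on the other communities' columns, each then
#' flipped with probability `feature_flip`. The remaining columns are pure
#' noise bits with activation probability `noise_density`.
#'
#' @param truth a `synthetic_truth` from [generate_signed_network()].
#' @param spec the matching [synthetic_spec()] (defaults to `truth$spec`).
#' @return binary feature matrix, `m x p_features`, drug ids as rownames.
#' @export
generate_features <- function(truth, spec = truth$spec) {
  set.seed(spec$seed + 104729L)   # decoupled stream from the network draw
  m <- spec$m
  ids <- names(truth$community)
  n_signal <- spec$c * spec$feature_signal
  base <- matrix(0L, m, n_signal)
  for (g in seq_len(spec$c)) {
    cols <- ((g - 1L) * spec$feature_signal + 1L):(g * spec$feature_signal)
    base[truth$community == g, cols] <- 1L
  }
  flip <- matrix(stats::runif(m * n_signal) < spec$feature_flip, m, n_signal)
  signal <- abs(base - flip * 1L)
  n_noise <- spec$p_features - n_signal
  noise <- matrix(
    as.integer(stats::runif(m * n_noise) < spec$noise_density), m, n_noise)
  F <- cbind(signal, noise)
  storage.mode(F) <- "double"
  rownames(F) <- ids
  colnames(F) <- sprintf("f%03d", seq_len(ncol(F)))
  F
}

#' Ready-made synthetic benchmarks
#'
#' `"default"`: m = 200 drugs in 4 communities, p_in = 0.3, p_out = 0.02,
#' polarity_fraction = 0.25, sign_noise = 0.05, 300 features with 40
#' signal columns per community and 5% bit-flip noise. `"small"`: m = 60,
#' c = 3, otherwise identical.
#'
#' @param preset `"default"` or `"small"`.
#' @param seed integer seed; the same seed reproduces identical outputs.
#' @return list with `adjacency`, `features`, `truth`.
#' @export
generate_benchmark <- function(preset = c("default", "small"), seed = 1L) {
  preset <- match.arg(preset)
  spec <- switch(preset,
    default = synthetic_spec(m = 200, c = 4, seed = seed),
    small = synthetic_spec(m = 60, c = 3, seed = seed))
  truth <- generate_signed_network(spec)
  F <- generate_features(truth)
  list(adjacency = truth$adjacency, features = F, truth = truth)
}

#' Write a synthetic benchmark to disk
#'
#' Writes `edges.tsv`, `features.csv` and `truth.json` under `dir`.
#' @param bench output of [generate_benchmark()].
#' @param dir output directory.
#' @export
write_benchmark <- function(bench, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_signed_edge_list(bench$adjacency, file.path(dir, "edges.tsv"))
  write_feature_table(bench$features, file.path(dir, "features.csv"))
  jsonlite::write_json(
    list(community = as.list(bench$truth$community),
         polarity = as.list(bench$truth$polarity),
         spec = unclass(bench$truth$spec)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
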