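# Signed / binary DDI network data model, sign decomposition, degree
# statistics, and edge-list / feature-table input-output.
#
# A drug-drug interaction (DDI) set is modelled as a signed network: an
# m x m symmetric adjacency matrix A with a_ij = +1 for an enhancive
# interaction (the drugs increase each other's pharmaceutical behaviour,
# e.g. serum concentration), -1 for a degressive interaction, and 0 for
# no known interaction. Collapsing signs gives the conventional binary
# DDI matrix.

#' Construct a signed adjacency matrix
#'
#' Wraps and validates an integer matrix with entries in \{-1, 0, +1\}
#' representing a signed (comprehensive) DDI network. Rows and columns are
#' labelled by drug identifier; the matrix must be symmetric with a zero
#' diagonal.
#'
#' @param matrix numeric matrix with entries in \{-1, 0, +1\}.
#' @param drug_ids character vector of unique drug identifiers, one per row.
#'   Defaults to the rownames of `matrix`.
#' @return an object of class `signed_adjacency`: the matrix with
#'   `dimnames` set to the drug ids.
#' @examples
#' A <- signed_adjacency(rbind(c(0, 1), c(1, 0)), c("a", "b"))
#' @export
signed_adjacency <- function(matrix, drug_ids = rownames(matrix)) {
  stop_if_not_matrix(matrix)
  if (is.null(drug_ids)) {
    stop("`drug_ids` must be supplied or present as rownames")
  }
  drug_ids <- as.character(drug_ids)
  m <- nrow(matrix)
  if (ncol(matrix) != m) stop("adjacency matrix must be square")
  if (length(drug_ids) != m) stop("length(drug_ids) must equal nrow(matrix)")
  if (anyDuplicated(drug_ids)) stop("drug ids must be unique")
  if (!all(matrix %in% c(-1, 0, 1))) {
    stop("signed adjacency entries must be -1, 0 or +1")
  }
  if (!isSymmetric(unname(matrix))) stop("adjacency matrix must be symmetric")
  if (any(diag(matrix) != 0)) stop("adjacency diagonal must be zero")
  storage.mode(matrix) <- "integer"
  dimnames(matrix) <- list(drug_ids, drug_ids)
  class(matrix) <- c("signed_adjacency", class(matrix))
  matrix
}

#' @export
print.signed_adjacency <- function(x, ...) {
  m <- nrow(x)
  n_pos <- sum(x == 1L) / 2
  n_neg <- sum(x == -1L) / 2
  cat(sprintf(
    "Signed DDI network: %d drugs, %d interactions (%d enhancive, %d degressive)\n",
    m, n_pos + n_neg, n_pos, n_neg))
  invisible(x)
}

#' Drug identifiers of a network or feature matrix
#' @param x a `signed_adjacency`, `binary_adjacency` or matrix with rownames.
#' @return character vector of drug ids.
#' @export
drug_ids <- function(x) rownames(x)

#' Read a signed edge list
#'
#' Reads a tab-separated file with header `drug_a<TAB>drug_b<TAB>sign`, one
#' undirected edge per row. Signs may be the integers `+1`/`-1` or the
#' literals `"E"` (enhancive) / `"D"` (degressive). Drugs are ordered
#' lexicographically in the returned matrix; duplicate rows for the same
#' unordered pair are collapsed.
#'
#' @param path path to the TSV file.
#' @param strict if `TRUE`, duplicate rows for the same pair with
#'   conflicting signs are an error; otherwise the first occurrence wins
#'   with a warning.
#' @return a [signed_adjacency()].
#' @export
read_signed_edge_list <- function(path, strict = FALSE) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  if (ncol(df) < 3) stop("edge list needs columns drug_a, drug_b, sign")
  names(df)[1:3] <- c("drug_a", "drug_b", "sign")
  sign_raw <- trimws(df$sign)
  sign <- ifelse(sign_raw %in% c("E", "+1", "1"), 1L,
                 ifelse(sign_raw %in% c("D", "-1"), -1L, NA_integer_))
  if (anyNA(sign)) {
    stop("malformed sign value(s): ",
         paste(unique(sign_raw[is.na(sign)]), collapse = ", "))
  }
  if (any(df$drug_a == df$drug_b)) {
    stop("self-loop rows are not allowed")
  }
  ids <- sort(unique(c(df$drug_a, df$drug_b)))
  m <- length(ids)
  A <- matrix(0L, m, m, dimnames = list(ids, ids))
  # canonical unordered pair key
  lo <- pmin(df$drug_a, df$drug_b)
  hi <- pmax(df$drug_a, df$drug_b)
  key <- paste(lo, hi, sep = "\r")
  first <- !duplicated(key)
  conflict <- tapply(sign, key, function(s) length(unique(s)) > 1)
  if (any(conflict)) {
    bad <- sub("\r", " / ", names(conflict)[conflict])
    msg <- paste0("conflicting duplicate edges for pair(s): ",
                  paste(bad, collapse = "; "))
    if (strict) stop(msg)
    warning(msg, "; keeping first occurrence")
  }
  A[cbind(lo[first], hi[first])] <- sign[first]
  A[cbind(hi[first], lo[first])] <- sign[first]
  signed_adjacency(A, ids)
}

#' Write a signed edge list
#'
#' Inverse of [read_signed_edge_list()]: one row per undirected interaction,
#' signs written as `1` / `-1`.
#' @param A a [signed_adjacency()].
#' @param path output path.
#' @export
write_signed_edge_list <- function(A, path) {
  idx <- which(upper.tri(A) & A != 0, arr.ind = TRUE)
  df <- data.frame(drug_a = rownames(A)[idx[, 1]],
                   drug_b = colnames(A)[idx[, 2]],
                   sign = A[idx])
  df <- df[order(df$drug_a, df$drug_b), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Collapse a signed network to its binary form
#'
#' Returns the conventional binary DDI matrix: entry `|a_ij|`, i.e. 1
#' wherever any interaction (enhancive or degressive) is present.
#'
#' @param A a [signed_adjacency()] (a \{0,1\} matrix is accepted and
#'   returned unchanged, making the operation idempotent).
#' @return a matrix of class `binary_adjacency` with the same drug ids.
#' @export
binarize <- function(A) {
  B <- abs(unclass(A))
  storage.mode(B) <- "integer"
  class(B) <- c("binary_adjacency", class(B))
  B
}

#' Split a matrix into its positive and negative parts
#'
#' Decomposes any real matrix X into nonnegative matrices
#' `pos = (|X| + X) / 2` and `neg = (|X| - X) / 2`, so that
#' `X = pos - neg`, `|X| = pos + neg`, and `pos * neg = 0` elementwise.
#' This is the sign decomposition used inside the semi-NMF multiplicative
#' update.
#'
#' @param X numeric matrix.
#' @return list with nonnegative components `pos` and `neg`.
#' @examples
#' split_signs(rbind(c(1, -2), c(0, 3)))
#' @export
split_signs <- function(X) {
  stop_if_not_matrix(X)
  list(pos = (abs(X) + X) / 2, neg = (abs(X) - X) / 2)
}

#' Per-drug signed degree statistics
#'
#' For each drug: `pos_degree` = number of enhancive interactions,
#' `neg_degree` = number of degressive interactions, `degree` = their sum,
#' and `diff = pos_degree - neg_degree`.
#'
#' @param A a [signed_adjacency()].
#' @return data.frame with columns `drug_id`, `degree`, `pos_degree`,
#'   `neg_degree`, `diff`.
#' @export
degree_profile <- function(A) {
  pos <- rowSums(A == 1L)
  neg <- rowSums(A == -1L)
  data.frame(drug_id = rownames(A),
             degree = as.integer(pos + neg),
             pos_degree = as.integer(pos),
             neg_degree = as.integer(neg),
             diff = as.integer(pos - neg),
             row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Write a degree profile as TSV
#' @param profile output of [degree_profile()].
#' @param path output path.
#' @export
write_degree_profile <- function(profile, path) {
  utils::write.table(profile, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a drug feature table
#'
#' First column = drug id, remaining columns numeric features, header row of
#' feature names. Separator is inferred from the extension (`.csv` = comma,
#' otherwise tab) unless given.
#'
#' @param path path to the CSV/TSV file.
#' @param sep field separator; `NULL` to infer from the extension.
#' @return numeric matrix, drugs in rows (rownames = ids), features in
#'   columns.
#' @export
read_feature_table <- function(path, sep = NULL) {
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  F <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(F) <- "double"
  if (anyNA(F)) stop("feature table contains missing values")
  rownames(F) <- ids
  F
}

#' Write a drug feature table
#' @param F numeric matrix with drug ids as rownames.
#' @param path output path; `.csv` writes comma-separated, otherwise tab.
#' @export
write_feature_table <- function(F, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(drug_id = rownames(F), F, check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
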