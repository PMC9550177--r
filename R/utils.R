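# Internal numeric helpers shared across modules.

#' Pairwise squared Euclidean distances between row sets
#'
#' @param A n x d matrix.
#' @param B m x d matrix.
#' @return n x m matrix of squared distances (clamped at 0).
#' @keywords internal
pairwise_sqdist <- function(A, B) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  D <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  pmax(D, 0)
}

#' Deterministic k-nearest-neighbour indices
#'
#' Brute-force neighbour search with ties broken by row index: for each
#' row of `X` (or of `query` against `X`), the indices of the `k` nearest
#' other rows in increasing distance order. Self matches are excluded
#' when `query` is missing.
#'
#' @param X reference matrix (rows = points).
#' @param k neighbour count.
#' @param query optional query matrix; when given, neighbours of each
#'   query row among the rows of `X` (self not excluded).
#' @return integer matrix (`nrow(query)` or `nrow(X)`) x `k`.
#' @keywords internal
knn_index <- function(X, k, query = NULL) {
  self <- is.null(query)
  if (self) query <- X
  D <- pairwise_sqdist(query, X)
  if (self) D[cbind(seq_len(nrow(X)), seq_len(nrow(X)))] <- Inf
  idx <- apply(D, 1, function(d) order(d, seq_along(d))[seq_len(k)])
  if (k == 1) matrix(idx, ncol = 1) else t(idx)
}

# row-wise cosine similarity between two matrices of matched shape;
# rows with a zero vector on either side give NA
rowwise_cosine <- function(A, B) {
  num <- rowSums(A * B)
  den <- sqrt(rowSums(A^2)) * sqrt(rowSums(B^2))
  ifelse(den > 0, num / den, NA_real_)
}

# scale a matrix by one global factor so that its total variance is 1
variance_normalise <- function(X) {
  v <- sum(apply(X, 2, stats::var))
  if (v == 0) return(X)
  X / sqrt(v)
}

#' Compare two velocity/arrow fields
#'
#' Per-cell cosine similarity and signed norm difference between a
#' reference field and a recovered field. Both matrices are first
#' variance-normalised by a single global factor each (total variance 1)
#' so that norms are comparable; cosines are unaffected. Cells with a
#' zero vector on either side get `NA` cosine.
#'
#' @param recovered,truth matched matrices (cells x dims).
#' @return data.frame with columns `cosine` and `norm_diff`
#'   (`||truth|| - ||recovered||` after normalisation).
#' @export
evaluate_velocities <- function(recovered, truth) {
  stopifnot(identical(dim(recovered), dim(truth)))
  R <- variance_normalise(recovered)
  T_ <- variance_normalise(truth)
  data.frame(cosine = rowwise_cosine(T_, R),
             norm_diff = sqrt(rowSums(T_^2)) - sqrt(rowSums(R^2)))
}
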