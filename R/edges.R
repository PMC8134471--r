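# Canonical edge indexing: the feature space of CPM is the vector of unique
# off-diagonal entries of a symmetric K x K connectome, ordered row-major over
# the upper triangle -- pairs (i, j) with i < j, i ascending then j ascending.
# All edge masks, saved models and localization summaries use this ordering.

#' Canonical edge ordering for a K-node connectome
#'
#' Returns the node pairs defining the edge feature space: all pairs
#' \eqn{(i, j)} with \eqn{i < j}, in row-major upper-triangle order
#' (\eqn{i} ascending, then \eqn{j} ascending).  A 268-node atlas yields
#' \eqn{268 \cdot 267 / 2 = 35778} edges.
#'
#' @param K Number of nodes (>= 2).
#' @return A list with integer vectors `i` and `j` (each of length
#'   `K * (K - 1) / 2`) and the edge count `n_edges`.
#' @export
#' @examples
#' edge_pairs(4)$n_edges  # 6
edge_pairs <- function(K) {
  K <- as.integer(K)
  if (is.na(K) || K < 2L) stop("edge_pairs: K must be an integer >= 2")
  i <- rep.int(seq_len(K - 1L), times = (K - 1L):1L)
  j <- sequence((K - 1L):1L, from = 2:K)
  list(i = i, j = j, n_edges = (K * (K - 1L)) %/% 2L)
}

#' Number of unique edges for K nodes
#' @param K Number of nodes.
#' @return `K * (K - 1) / 2`.
#' @export
n_edges <- function(K) (as.integer(K) * (as.integer(K) - 1L)) %/% 2L

#' Flatten a symmetric connectivity matrix to its canonical edge vector
#'
#' @param M Symmetric numeric K x K matrix (diagonal ignored; stored as 0
#'   by convention).
#' @param tol Maximum tolerated absolute asymmetry `|M - t(M)|`.
#' @return Numeric vector of length `K * (K - 1) / 2` in canonical edge order.
#' @seealso [devectorize_edges()] for the inverse.
#' @export
vectorize_matrix <- function(M, tol = 1e-8) {
  if (!is.matrix(M) || nrow(M) != ncol(M)) {
    stop("vectorize_matrix: M must be a square matrix")
  }
  asym <- max(abs(M - t(M)))
  if (is.na(asym) || asym > tol) {
    stop(sprintf(
      "vectorize_matrix: matrix asymmetric (max |M - t(M)| = %g > tol = %g)",
      asym, tol
    ))
  }
  ep <- edge_pairs(nrow(M))
  M[cbind(ep$i, ep$j)]
}

#' Rebuild a symmetric zero-diagonal matrix from a canonical edge vector
#'
#' @param v Edge vector of length `K * (K - 1) / 2`.
#' @param K Number of nodes.
#' @return Symmetric K x K matrix with zero diagonal.
#' @export
devectorize_edges <- function(v, K) {
  ep <- edge_pairs(K)
  if (length(v) != ep$n_edges) {
    stop(sprintf(
      "devectorize_edges: expected %d edge values for K = %d, got %d",
      ep$n_edges, K, length(v)
    ))
  }
  M <- matrix(0, K, K)
  M[cbind(ep$i, ep$j)] <- v
  M[cbind(ep$j, ep$i)] <- v
  M
}

#' Stack per-subject connectivity matrices into a subjects x edges matrix
#'
#' @param matrices Named list of symmetric K x K matrices (one per subject).
#' @param tol Asymmetry tolerance passed to [vectorize_matrix()].
#' @return Numeric matrix, one row per subject (rownames from the list names),
#'   one column per canonical edge.
#' @export
edge_matrix <- function(matrices, tol = 1e-8) {
  if (!length(matrices)) stop("edge_matrix: empty matrix list")
  E <- t(vapply(matrices, vectorize_matrix,
                numeric(n_edges(nrow(matrices[[1L]]))), tol = tol))
  rownames(E) <- names(matrices)
  E
}
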