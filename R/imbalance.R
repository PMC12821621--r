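#' Pairwise Euclidean distance matrix
#'
#' Distance between instance rows: `d(i, j) = ||s_i - s_j||_2` over the
#' voxel (column) coordinates.
#'
#' @param states Numeric matrix, one instance per row, at least 2 rows.
#' @return A symmetric N x N matrix with zero diagonal.
#' @export
pairwise_distance <- function(states) {
  states <- as.matrix(states)
  if (nrow(states) < 2) stop_field("need at least 2 instances, got %d", nrow(states))
  if (!all(is.finite(states))) stop_field("non-finite values in states")
  d <- as.matrix(stats::dist(states, method = "euclidean"))
  dimnames(d) <- NULL
  d
}

#' Combine two distance spaces
#'
#' Entrywise `sqrt(w^2 * dX^2 + dY^2)` — the Euclidean distance in the
#' concatenated state space when `weight = 1` (the default, equal
#' weighting of the two spaces).  `weight = 0` recovers `dY` alone, so
#' the weight can be scanned to probe how much of X's geometry helps.
#'
#' @param dX,dY Distance matrices of equal size.
#' @param weight Relative weight applied to `dX` inside the quadrature
#'   sum; `1` reproduces plain concatenation.
#' @return A distance matrix.
#' @export
combined_distance <- function(dX, dY, weight = 1) {
  if (!all(dim(dX) == dim(dY)))
    stop_field("distance matrices differ in size (%d vs %d)", nrow(dX), nrow(dY))
  sqrt(weight^2 * dX^2 + dY^2)
}

# Rank (1-based, self excluded) of column j within row i of dB.
# Ties broken by ascending instance index; diagonal never counted.
rank_in_rows <- function(dB, j) {
  N <- nrow(dB)
  target <- dB[cbind(seq_len(N), j)]
  dBx <- dB
  diag(dBx) <- Inf
  cols <- col(dBx)
  1L + rowSums(dBx < target) + rowSums(dBx == target & cols < j)
}

# First (lowest-index) minimum per row, self excluded.
nearest_neighbours <- function(dA, k = 1L) {
  N <- nrow(dA)
  dAx <- dA
  diag(dAx) <- Inf
  if (k == 1L) return(matrix(max.col(-dAx, ties.method = "first"), ncol = 1L))
  t(apply(dAx, 1, function(r) order(r)[seq_len(k)]))
}

#' Information imbalance between two distance spaces
#'
#' Measures how well nearest-neighbour structure in space A predicts
#' neighbourhoods in space B:
#' \deqn{\Delta(A \to B) = \frac{2}{N} \,\langle r_B(i, nn_A(i)) \rangle_i}
#' where `nn_A(i)` is instance i's nearest neighbour under `dA` (self
#' excluded) and `r_B` is that neighbour's distance rank in i's row of
#' `dB` (nearest = 1).  `Delta = 2/N` means A predicts B perfectly;
#' values near 1 mean no shared structure.  With `k > 1` the rank is
#' averaged over the k nearest A-neighbours.  Rank ties are broken by
#' ascending instance index.
#'
#' @param dA,dB Distance matrices over the same N >= 3 instances.
#' @param k Number of nearest neighbours in space A to average over.
#' @return A list of class `imbalance_result` with elements `delta`,
#'   `n_instances`, `k_neighbours`.
#' @export
information_imbalance <- function(dA, dB, k = 1L) {
  N <- nrow(dA)
  if (N < 3) stop_field("information imbalance needs N >= 3 instances, got %d", N)
  if (!all(dim(dA) == dim(dB)))
    stop_field("distance matrices differ in size (%d vs %d)", N, nrow(dB))
  k <- as.integer(k)
  if (k < 1 || k > N - 1) stop_field("k must be in [1, N-1]")
  nn <- nearest_neighbours(dA, k)
  ranks <- matrix(0, N, k)
  for (kk in seq_len(k)) ranks[, kk] <- rank_in_rows(dB, nn[, kk])
  structure(list(delta = 2 / N * mean(ranks), n_instances = N, k_neighbours = k),
            class = "imbalance_result")
}

#' @export
print.imbalance_result <- function(x, ...) {
  cat(sprintf("Information imbalance: Delta = %.4f (N = %d, k = %d)\n",
              x$delta, x$n_instances, x$k_neighbours))
  invisible(x)
}
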