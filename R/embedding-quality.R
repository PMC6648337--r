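#' Trustworthiness and continuity of a low-dimensional embedding
#'
#' Rank-based quality metrics for dimensionality reduction, analogous to
#' precision and recall. Trustworthiness penalizes *spurious* neighbors:
#' points inside the k-nearest-neighborhood of a sample in the embedding
#' that are not among its k nearest in the original space, weighted by how
#' far down the original-space ranking they sit. Continuity is the symmetric
#' counterpart, penalizing original-space neighbors *missing* from the
#' embedding neighborhood, weighted by embedding-space rank:
#'
#' \deqn{T(k) = 1 - \frac{2}{nk(2n-3k-1)} \sum_i \sum_{j \in U_k(i)} (r(i,j) - k)}
#'
#' Both are 1 for a perfect embedding. Note that a map can score high on both
#' while grouping samples by study rather than biology — these metrics see
#' geometry only, which is why the NMI metrics exist alongside them.
#'
#' @param high Genes x samples matrix (the original space).
#' @param low n x 2 (or n x d) embedding coordinates, samples in rows, in the
#'   column order of `high`.
#' @param k Neighborhood size; `1 <= k < (n - 1) / 2`. Default 12.
#' @return A single value in `[0, 1]`.
#' @export
trustworthiness <- function(high, low, k = 12L) {
  rk <- neighbor_ranks(high, low, k)
  # spurious: in embedding k-NN, not in original k-NN; penalty = original rank - k
  pen <- rk$rank_high[rk$rank_low <= k & rk$rank_high > k] - k
  1 - 2 / (rk$n * k * (2 * rk$n - 3 * k - 1)) * sum(pen)
}

#' @rdname trustworthiness
#' @export
continuity <- function(high, low, k = 12L) {
  rk <- neighbor_ranks(high, low, k)
  pen <- rk$rank_low[rk$rank_high <= k & rk$rank_low > k] - k
  1 - 2 / (rk$n * k * (2 * rk$n - 3 * k - 1)) * sum(pen)
}

neighbor_ranks <- function(high, low, k) {
  if (!is.matrix(low)) low <- as.matrix(low)
  n <- nrow(low)
  if (ncol(high) != n) {
    abort("`high` must have one column per embedding row")
  }
  k <- as.integer(k)
  if (k < 1L || k >= (n - 1) / 2) {
    abort(sprintf("`k` must satisfy 1 <= k < (n - 1)/2 = %.1f", (n - 1) / 2))
  }
  dh <- as.matrix(dist(t(high)))
  dl <- as.matrix(dist(low))
  list(n = n,
       rank_high = pairwise_ranks(dh),
       rank_low = pairwise_ranks(dl))
}

# rank[i, j] = neighbor rank of j with respect to i (1 = nearest), self = 0;
# ties broken by index for determinism
pairwise_ranks <- function(d) {
  n <- nrow(d)
  out <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    ord <- order(d[i, -i], seq_len(n - 1L))
    others <- seq_len(n)[-i]
    out[i, others[ord]] <- seq_len(n - 1L)
  }
  out
}
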