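#' Derive up/down gene sets for each map cluster
#'
#' For every cluster, each gene is correlated (Pearson) with the binary
#' indicator of cluster membership; p-values come from the t transform of r
#' with n - 2 degrees of freedom (two-sided). Among genes significant at
#' `p_threshold`, the `n_top` most positively correlated form the cluster's
#' `_UP` set and the `n_top` most negatively correlated its `_DN` set; when
#' fewer genes pass, the set is simply smaller.
#'
#' @param x Genes x samples matrix.
#' @param labels Cluster labels, one per sample (>= 2 clusters, each with
#'   >= 3 samples).
#' @param n_top Genes per directed set (default 20).
#' @param p_threshold Correlation significance cutoff (default 0.05).
#' @return A gene-set tibble (see [gene_sets()]) with sets named
#'   `cluster<k>_UP` / `cluster<k>_DN`.
#' @export
cluster_genesets <- function(x, labels, n_top = 20L, p_threshold = 0.05) {
  check_expression(x)
  if (length(labels) != ncol(x)) abort("one label per sample required")
  counts <- table(labels)
  if (length(counts) < 2L) abort("need at least 2 clusters")
  if (any(counts < 3L)) {
    abort(sprintf("cluster %s has fewer than 3 samples", names(counts)[counts < 3L][1L]))
  }
  n <- ncol(x)
  out_names <- character(0)
  out_genes <- list()
  out_dir <- character(0)
  for (c in sort(unique(labels))) {
    ind <- as.numeric(labels == c)
    r <- as.vector(cor(t(x), ind))
    r[is.na(r)] <- 0 # constant genes carry no signal
    tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tstat), df = n - 2)
    sig <- p < p_threshold
    up <- order(-r, rownames(x), method = "radix")
    up <- up[sig[up] & r[up] > 0]
    dn <- order(r, rownames(x), method = "radix")
    dn <- dn[sig[dn] & r[dn] < 0]
    for (side in list(list(sfx = "_UP", idx = head(up, n_top), dir = "up"),
                      list(sfx = "_DN", idx = head(dn, n_top), dir = "down"))) {
      if (length(side$idx) > 0L) {
        out_names <- c(out_names, paste0("cluster", c, side$sfx))
        out_genes <- c(out_genes, list(rownames(x)[side$idx]))
        out_dir <- c(out_dir, side$dir)
      }
    }
  }
  gene_sets(out_names, out_genes,
            description = "cluster-correlated genes", direction = out_dir)
}

#' Single-sample gene-set enrichment scores
#'
#' The gene-set variation scoring procedure: (1) for each gene, a kernel
#' estimate of the cumulative expression distribution across samples turns
#' raw values into a relative-expression statistic (Gaussian kernel with
#' bandwidth sd/4 for continuous log-scale data; Poisson kernel for integer
#' counts); (2) within each sample, genes are ranked by that statistic and
#' converted to the symmetric rank weight `|p/2 - rank|`; (3) a weighted
#' Kolmogorov-Smirnov-like random walk descends the ranked list, stepping up
#' by `weight^tau` (normalized) at in-set genes and down by `1/(p - |set|)`
#' otherwise; (4) with `mx_diff = FALSE` the score is the walk's deviation
#' of largest magnitude, sign retained — positive for coordinately increased
#' expression, negative for decreased.
#'
#' Sets are first intersected with the matrix genes; sets outside 5-500
#' surviving members are skipped with a warning.
#'
#' @param x Genes x samples matrix (log-scale values for `kcdf = "gaussian"`,
#'   integer counts for `kcdf = "poisson"`).
#' @param sets Gene-set tibble.
#' @param tau Rank-weight exponent (default 0.25).
#' @param mx_diff Score rule; this package implements the largest-deviation
#'   rule (`FALSE`), the setting used throughout.
#' @param kcdf Kernel for the expression statistic.
#' @return Samples x sets numeric score matrix.
#' @export
gsva_scores <- function(x, sets, tau = 0.25, mx_diff = FALSE,
                        kcdf = c("gaussian", "poisson")) {
  kcdf <- match.arg(kcdf)
  check_expression(x)
  if (isTRUE(mx_diff)) abort("only the largest-deviation rule (mx_diff = FALSE) is implemented")
  sets <- restrict_sets(sets, rownames(x))
  if (nrow(sets) == 0L) abort("no evaluable gene sets after size filtering")
  z <- kcdf_statistic(x, kcdf)
  walk_scores(z, sets, tau = tau)
}

# kernel estimate of each gene's cumulative expression distribution
kcdf_statistic <- function(x, kcdf) {
  n <- ncol(x)
  z <- x
  if (kcdf == "gaussian") {
    for (i in seq_len(nrow(x))) {
      h <- sd(x[i, ]) / 4
      if (h == 0) {
        z[i, ] <- 0.5
      } else {
        z[i, ] <- rowMeans(pnorm(outer(x[i, ], x[i, ], "-") / h))
      }
    }
  } else {
    if (any(x < 0) || any(x != round(x))) {
      abort("kcdf = 'poisson' expects non-negative integer counts")
    }
    for (i in seq_len(nrow(x))) {
      z[i, ] <- colMeans(matrix(
        ppois(rep(x[i, ], each = n), rep(x[i, ] + 0.5, times = n)),
        nrow = n))
    }
  }
  z
}

# the weighted KS-like walk, evaluated for all sets x samples
walk_scores <- function(z, sets, tau) {
  p <- nrow(z)
  n <- ncol(z)
  member <- matrix(FALSE, p, nrow(sets))
  for (k in seq_len(nrow(sets))) {
    member[match(sets$genes[[k]], rownames(z)), k] <- TRUE
  }
  set_size <- colSums(member)
  scores <- matrix(NA_real_, n, nrow(sets),
                   dimnames = list(colnames(z), sets$set))
  for (j in seq_len(n)) {
    ord <- order(-z[, j], rownames(z), method = "radix")
    w <- (abs(p / 2 - rank_in_order(ord)))^tau
    wo <- w[ord]
    mo <- member[ord, , drop = FALSE]
    inc <- mo * wo
    inc <- sweep(inc, 2L, colSums(inc), "/")
    dec <- (!mo) / rep(p - set_size, each = p)
    walk <- matrixStats::colCumsums(inc - dec)
    idx <- matrixStats::colMaxs(abs(walk))
    pick <- vapply(seq_len(ncol(walk)), function(k) {
      walk[which.max(abs(walk[, k])), k]
    }, numeric(1L))
    scores[j, ] <- pick
  }
  scores
}

# symmetric rank weight |p/2 - r| where r is the rank position in the
# descending order of the statistic
rank_in_order <- function(ord) {
  r <- integer(length(ord))
  r[ord] <- seq_along(ord)
  r
}

#' Size bins for the permutation null
#'
#' @return The gene-set sizes at which null score distributions are built:
#'   every size from 5 to 20, then 25, 30, 40, 50, 75, 100, 200, 300, 400,
#'   500. Sets of other sizes are evaluated against the nearest bin (ties
#'   toward the larger bin).
#' @export
default_size_bins <- function() c(5:20, 25L, 30L, 40L, 50L, 75L, 100L,
                                  200L, 300L, 400L, 500L)

nearest_bin <- function(size, bins) {
  d <- abs(bins - size)
  as.numeric(max(bins[d == min(d)]))
}

#' Empirical p-values for enrichment scores by gene permutation
#'
#' For every size bin needed, `n_permutations` random gene sets of that size
#' are drawn from the matrix genes and scored; each real set's score is then
#' compared per sample against its bin's null: the empirical p counts the
#' permuted scores at least as extreme in either direction (higher than
#' `|score|` or lower than `-|score|`), divided by the number of
#' permutations. Counting both tails keeps the p-value uniform under the
#' null whatever the skew of the null score distribution. A 0 count is
#' reported as 0 per that counting rule; the companion `p_pseudo` column
#' carries the (count + 1)/(n + 1) estimator for downstream stability.
#' Adjusted p-values are Benjamini-Hochberg across all (sample, set) pairs.
#'
#' @param x Genes x samples matrix the scores were computed from.
#' @param sets Gene-set tibble used for `scores`.
#' @param scores Samples x sets matrix from [gsva_scores()] (recomputed when
#'   `NULL`).
#' @param n_permutations Random sets per size bin (default 1000; < 100
#'   draws a warning).
#' @param size_bins Null bin sizes; see [default_size_bins()].
#' @param seed Integer seed for the permutation draws.
#' @param tau,kcdf Passed through to the scorer; must match `scores`.
#' @return Tibble: `sample_id`, `set`, `score`, `p_empirical`, `p_pseudo`,
#'   `p_adj`, `bin`.
#' @export
empirical_pvalues <- function(x, sets, scores = NULL, n_permutations = 1000L,
                              size_bins = default_size_bins(), seed = 1L,
                              tau = 0.25, kcdf = c("gaussian", "poisson")) {
  kcdf <- match.arg(kcdf)
  n_permutations <- as.integer(n_permutations)
  if (n_permutations <= 0L) abort("`n_permutations` must be positive")
  if (n_permutations < 100L) {
    warn(sprintf("%d permutations is few; empirical p-values will be coarse",
                 n_permutations))
  }
  sets <- restrict_sets(sets, rownames(x))
  if (is.null(scores)) scores <- gsva_scores(x, sets, tau = tau, kcdf = kcdf)
  scores <- scores[, sets$set, drop = FALSE]

  withr_seed(seed)
  z <- kcdf_statistic(x, kcdf)
  sizes <- lengths(sets$genes)
  bins_needed <- sort(unique(vapply(sizes, nearest_bin, numeric(1L), bins = size_bins)))
  genes <- rownames(x)
  null_scores <- list() # bin -> samples x n_permutations
  for (b in bins_needed) {
    rand <- gene_sets(sprintf("null%04d", seq_len(n_permutations)),
                      purrr::map(seq_len(n_permutations),
                                 ~ sample(genes, b)))
    null_scores[[as.character(b)]] <- walk_scores(z, rand, tau = tau)
  }

  grid <- tidyr::expand_grid(sample_id = rownames(scores), set = sets$set)
  grid$score <- scores[cbind(grid$sample_id, grid$set)]
  grid$bin <- vapply(sizes[match(grid$set, sets$set)], nearest_bin,
                     numeric(1L), bins = size_bins)
  cnt <- purrr::pmap_dbl(grid[c("sample_id", "score", "bin")],
                         function(sample_id, score, bin) {
                           nulls <- null_scores[[as.character(bin)]][sample_id, ]
                           sum(nulls >= abs(score)) + sum(nulls <= -abs(score))
                         })
  grid$p_empirical <- cnt / n_permutations
  grid$p_pseudo <- (cnt + 1) / (n_permutations + 1)
  grid$p_adj <- p.adjust(grid$p_empirical, method = "BH")
  grid
}

#' Hypergeometric enrichment of significant samples in clusters
#'
#' For each gene set and each cluster, tests whether samples scoring
#' significantly for the set pile up in the cluster: the upper-tail
#' hypergeometric probability of drawing at least the observed overlap when
#' `cluster_size` samples are drawn from `n_total` of which `n_significant`
#' are significant. BH adjustment is applied across the whole table.
#'
#' @param significant Samples x sets logical matrix.
#' @param clusters Cluster labels, one per sample (matrix row order).
#' @return Tibble: `set`, `cluster`, `n_total`, `n_significant`,
#'   `cluster_size`, `overlap`, `enrichment_fraction`, `p_value`, `p_adj`.
#' @export
cluster_enrichment <- function(significant, clusters) {
  if (!is.matrix(significant) || !is.logical(significant)) {
    abort("`significant` must be a logical samples x sets matrix")
  }
  if (length(clusters) != nrow(significant)) abort("one cluster label per sample required")
  N <- nrow(significant)
  out <- tidyr::expand_grid(set = colnames(significant),
                            cluster = sort(unique(clusters)))
  rows <- purrr::pmap(out, function(set, cluster) {
    in_c <- clusters == cluster
    m <- sum(significant[, set])
    q <- sum(significant[in_c, set])
    k <- sum(in_c)
    tibble(n_total = N, n_significant = m, cluster_size = k, overlap = q,
           enrichment_fraction = q / k,
           p_value = phyper(q - 1, m, N - m, k, lower.tail = FALSE))
  })
  out <- dplyr::bind_cols(out, dplyr::bind_rows(rows))
  out$p_adj <- p.adjust(out$p_value, method = "BH")
  out
}

#' Match clusters across independently built maps
#'
#' Scores the target dataset's samples with the source map's cluster gene
#' sets, derives per-sample significance from the permutation null (BH
#' adjusted, direction-consistent: `_UP` sets must score positive, `_DN`
#' negative), tests hypergeometric enrichment of significant samples in each
#' target cluster, and calls, per source cluster, the target cluster with
#' the smallest adjusted enrichment p-value below `alpha` its best match
#' (no match when none is below).
#'
#' @param source_sets Gene-set tibble from [cluster_genesets()] on map A.
#' @param target_x Genes x samples matrix of dataset B.
#' @param target_clusters Cluster labels of dataset B's own map.
#' @param alpha Adjusted-p threshold for both sample-level significance and
#'   the cluster-level match call (default 0.001).
#' @param n_permutations,seed,tau,kcdf Passed to [empirical_pvalues()].
#' @return A `cluster_match` object: `table` (per set x target cluster) and
#'   `best` (per source cluster: best-matching target cluster or `NA`).
#' @export
match_maps <- function(source_sets, target_x, target_clusters, alpha = 0.001,
                       n_permutations = 1000L, seed = 1L, tau = 0.25,
                       kcdf = c("gaussian", "poisson")) {
  kcdf <- match.arg(kcdf)
  sets <- restrict_sets(source_sets, rownames(target_x))
  if (nrow(sets) == 0L) abort("no source gene set keeps >= 5 genes in the target universe")
  scores <- gsva_scores(target_x, sets, tau = tau, kcdf = kcdf)
  pv <- empirical_pvalues(target_x, sets, scores = scores,
                          n_permutations = n_permutations, seed = seed,
                          tau = tau, kcdf = kcdf)
  pv <- dplyr::left_join(pv, sets[c("set", "direction")], by = "set")
  pv$significant <- pv$p_adj < alpha &
    dplyr::case_when(pv$direction == "up" ~ pv$score > 0,
                     pv$direction == "down" ~ pv$score < 0,
                     TRUE ~ TRUE)
  sig <- matrix(FALSE, nrow(scores), ncol(scores), dimnames = dimnames(scores))
  sig[cbind(pv$sample_id, pv$set)] <- pv$significant

  tab <- cluster_enrichment(sig, target_clusters)
  tab$source_cluster <- sub("^cluster(.*)_(UP|DN)$", "\\1", tab$set)

  best <- tab %>%
    dplyr::filter(.data$p_adj < alpha) %>%
    dplyr::group_by(.data$source_cluster) %>%
    dplyr::slice_min(.data$p_adj, n = 1L, with_ties = FALSE) %>%
    dplyr::ungroup() %>%
    dplyr::select("source_cluster", best_match = "cluster",
                  best_p_adj = "p_adj")
  all_src <- tibble(source_cluster = sort(unique(tab$source_cluster)))
  best <- dplyr::left_join(all_src, best, by = "source_cluster")

  tab <- dplyr::left_join(
    tab,
    dplyr::mutate(best, is_best = TRUE),
    by = "source_cluster") %>%
    dplyr::mutate(best_match_flag = !is.na(.data$best_match) &
                    .data$cluster == .data$best_match &
                    .data$p_adj == .data$best_p_adj) %>%
    dplyr::select(-"is_best", -"best_match", -"best_p_adj")

  structure(list(table = tab, best = best, alpha = alpha),
            class = "cluster_match")
}

#' @export
print.cluster_match <- function(x, ...) {
  matched <- sum(!is.na(x$best$best_match))
  cat(sprintf("<cluster_match> %d/%d source clusters matched at adj. p < %g\n",
              matched, nrow(x$best), x$alpha))
  invisible(x)
}

#' @method tidy cluster_match
#' @export
tidy.cluster_match <- function(x, ...) x$table

#' @method glance cluster_match
#' @export
glance.cluster_match <- function(x, ...) {
  tibble(n_source_clusters = nrow(x$best),
         n_matched = sum(!is.na(x$best$best_match)),
         alpha = x$alpha)
}

#' Correlate enrichment scores with cluster membership
#'
#' Pearson correlation of each gene set's per-sample scores with each
#' cluster's binary membership indicator, with t-distribution p-values and
#' BH adjustment across the table — the per-dataset summary consumed by
#' [consistent_enrichment()].
#'
#' @param scores Samples x sets score matrix.
#' @param clusters Cluster labels (matrix row order).
#' @return Tibble: `set`, `cluster`, `estimate`, `p_value`, `p_adj`.
#' @export
score_cluster_correlation <- function(scores, clusters) {
  if (length(clusters) != nrow(scores)) abort("one cluster label per sample required")
  n <- nrow(scores)
  out <- tidyr::expand_grid(set = colnames(scores),
                            cluster = sort(unique(clusters)))
  est <- purrr::pmap_dbl(out, function(set, cluster) {
    r <- suppressWarnings(cor(scores[, set], as.numeric(clusters == cluster)))
    if (is.na(r)) 0 else r
  })
  tstat <- est * sqrt((n - 2) / pmax(1 - est^2, .Machine$double.eps))
  out$estimate <- est
  out$p_value <- 2 * pt(-abs(tstat), df = n - 2)
  out$p_adj <- p.adjust(out$p_value, method = "BH")
  out
}

#' Cross-dataset consistency filter for enrichment results
#'
#' Keeps gene sets whose association with corresponding clusters replicates
#' across two datasets: the correlation sign must agree, the smaller
#' dataset's nominal p-value must be below `small_p`, and the larger
#' dataset's BH-adjusted p-value below `large_alpha`.
#'
#' @param results_small,results_large Tibbles from
#'   [score_cluster_correlation()] (or with columns `set`, `cluster`,
#'   `estimate`, `p_value`, `p_adj`), rows keyed by matched cluster ids.
#' @param small_p Nominal threshold for the smaller dataset (default 0.05).
#' @param large_alpha Adjusted threshold for the larger dataset (default
#'   0.001).
#' @return The consistent rows: `set`, `cluster`, estimates and p-values
#'   from both datasets.
#' @export
consistent_enrichment <- function(results_small, results_large,
                                  small_p = 0.05, large_alpha = 0.001) {
  joined <- dplyr::inner_join(results_small, results_large,
                              by = c("set", "cluster"),
                              suffix = c("_small", "_large"))
  shared_sets <- intersect(results_small$set, results_large$set)
  if (length(shared_sets) > 0L && nrow(joined) == 0L) {
    abort("cluster ids do not match between the two result tables")
  }
  dplyr::filter(joined,
                sign(.data$estimate_small) == sign(.data$estimate_large),
                .data$p_value_small < small_p,
                .data$p_adj_large < large_alpha)
}
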