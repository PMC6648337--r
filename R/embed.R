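#' Select the most variable genes
#'
#' Keeps the `ceiling(pct/100 * n_genes)` genes with the largest sample
#' variance (log-scale values, denominator n - 1), preserving the original
#' gene order among survivors. Variance ties are broken by gene id (stable),
#' so the selection is deterministic across platforms.
#'
#' @param x Genes x samples matrix.
#' @param pct Percentage of genes to keep, in `(0, 100]`. The map-building
#'   default elsewhere in the package is 15.
#' @return The row-subset matrix.
#' @export
select_variable_genes <- function(x, pct = 15) {
  check_expression(x)
  if (!is.numeric(pct) || pct <= 0 || pct > 100) {
    abort("`pct` must be in (0, 100]")
  }
  n_keep <- ceiling(pct / 100 * nrow(x))
  v <- matrixStats::rowVars(x)
  ord <- order(-v, rownames(x), method = "radix")
  keep <- sort(ord[seq_len(n_keep)])
  x[keep, , drop = FALSE]
}

#' Project samples onto top principal components
#'
#' Scores of the column-centered data on the leading principal components,
#' ordered by explained variance — the conventional pre-processing step that
#' t-SNE applies by default, and the comparator that the NMI parameter sweep
#' evaluates against variance-based gene selection.
#'
#' @param x Genes x samples matrix.
#' @param n_components Number of components, `< min(n_genes, n_samples)`.
#' @return A samples x components score matrix.
#' @export
pca_reduce <- function(x, n_components) {
  check_expression(x)
  n_components <- as.integer(n_components)
  if (n_components < 1L || n_components >= min(dim(x))) {
    abort(sprintf("`n_components` must be in [1, %d)", min(dim(x))))
  }
  p <- prcomp(t(x), center = TRUE, scale. = FALSE, rank. = n_components)
  scores <- p$x[, seq_len(n_components), drop = FALSE]
  rownames(scores) <- colnames(x)
  scores
}

#' Barnes-Hut t-SNE embedding
#'
#' Thin adapter over the Barnes-Hut t-SNE implementation in \pkg{Rtsne},
#' run single-threaded with a fixed seed so coordinates are reproducible.
#' Input is a features x samples matrix (genes, or PCA scores transposed);
#' internal PCA is disabled — feature selection is this package's explicit
#' pipeline step.
#'
#' @param x Features x samples numeric matrix.
#' @param perplexity t-SNE perplexity; must satisfy `perplexity < (n - 1)/3`.
#' @param theta Barnes-Hut accuracy trade-off; 0 is exact.
#' @param seed Integer seed.
#' @param max_iter Gradient-descent iterations.
#' @return An n x 2 coordinate matrix, samples in rows.
#' @export
tsne_embed <- function(x, perplexity = 30, theta = 0.5, seed = 1L, max_iter = 1000L) {
  if (!is.matrix(x) || !is.numeric(x)) abort("`x` must be a numeric matrix")
  n <- ncol(x)
  if (n < 4L) abort("need at least 4 samples to embed")
  if (perplexity >= (n - 1) / 3) {
    abort(sprintf("perplexity %.1f too large for %d samples (needs < %.1f)",
                  perplexity, n, (n - 1) / 3))
  }
  withr_seed(seed)
  fit <- Rtsne::Rtsne(t(x), dims = 2L, perplexity = perplexity, theta = theta,
                      pca = FALSE, max_iter = as.integer(max_iter),
                      check_duplicates = FALSE, num_threads = 1L, verbose = FALSE)
  coords <- fit$Y
  rownames(coords) <- colnames(x)
  colnames(coords) <- c("dim1", "dim2")
  coords
}

#' Gaussian mean-shift clustering of 2D map coordinates
#'
#' Every point ascends the kernel density estimate by iterating the
#' Gaussian-kernel mean shift until the move falls below `tol` (at most
#' `max_iter` iterations); converged modes closer than `merge_radius`
#' (default `bandwidth / 2`) are merged by connected components, and points
#' sharing a mode share a cluster. The number of clusters emerges from the
#' data. Labels are integers from 1 in order of first sample occurrence;
#' the centroid of a cluster is the mean coordinate of its members.
#'
#' @param coords n x 2 coordinate matrix.
#' @param bandwidth Gaussian kernel bandwidth (map units); 1.5 suits maps of
#'   a single disease entity, 2.5 full heterogeneous collections.
#' @param tol Convergence tolerance on the shift step.
#' @param max_iter Maximum mean-shift iterations per point.
#' @param merge_radius Mode-merge distance; defaults to `bandwidth / 2`.
#' @return A `mean_shift` list: `labels` (integer per sample), `modes`
#'   (n x 2 converged mode per sample), `centroids` (clusters x 2 matrix),
#'   `bandwidth`.
#' @export
mean_shift <- function(coords, bandwidth = 1.5, tol = 1e-4, max_iter = 300L,
                       merge_radius = bandwidth / 2) {
  if (!is.matrix(coords)) coords <- as.matrix(coords)
  if (!all(is.finite(coords))) abort("coordinates must be finite")
  if (bandwidth <= 0) abort("`bandwidth` must be > 0")
  n <- nrow(coords)

  modes <- coords
  h2 <- 2 * bandwidth^2
  for (i in seq_len(n)) {
    y <- coords[i, ]
    for (iter in seq_len(max_iter)) {
      d2 <- (coords[, 1L] - y[1L])^2 + (coords[, 2L] - y[2L])^2
      w <- exp(-d2 / h2)
      y_new <- c(sum(w * coords[, 1L]), sum(w * coords[, 2L])) / sum(w)
      if (sqrt(sum((y_new - y)^2)) < tol) {
        y <- y_new
        break
      }
      y <- y_new
    }
    modes[i, ] <- y
  }

  labels <- merge_modes(modes, merge_radius)
  centroids <- t(vapply(seq_len(max(labels)), function(c) {
    colMeans(coords[labels == c, , drop = FALSE])
  }, numeric(2L)))
  colnames(centroids) <- c("dim1", "dim2")
  rownames(centroids) <- as.character(seq_len(nrow(centroids)))

  structure(list(labels = labels, modes = modes, centroids = centroids,
                 bandwidth = bandwidth),
            class = "mean_shift")
}

# connected components of the "modes within radius" graph, labelled in order
# of first occurrence; union-find keeps the grouping order-invariant
merge_modes <- function(modes, radius) {
  n <- nrow(modes)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  d <- as.matrix(dist(modes))
  for (i in seq_len(n - 1L)) {
    near <- which(d[i, (i + 1L):n] <= radius) + i
    for (j in near) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1L))
  as.integer(factor(roots, levels = unique(roots)))
}
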