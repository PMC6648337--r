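#' Input affinities of a new sample to the reference samples
#'
#' Converts distances from one new sample to every reference sample into the
#' Gaussian input affinities used by the t-SNE objective: squared distances
#' enter a Gaussian kernel whose bandwidth is calibrated by binary search so
#' that the Shannon perplexity of the resulting distribution equals the
#' target. With `metric = "correlation"` the distance is one minus the
#' Pearson correlation between samples over the map features, which makes
#' affinities comparable across measurement platforms (log-CPM RNA-seq vs
#' log2 microarray intensities) without further normalization.
#'
#' @param new_values Named numeric vector of expression over the map's
#'   feature genes (order-matched to `reference`'s features).
#' @param reference A `reference_map`.
#' @param perplexity Target perplexity; default: the map's own.
#' @param metric `"euclidean"` or `"correlation"`.
#' @param tol Perplexity tolerance of the binary search.
#' @return Probability vector over reference samples (sums to 1).
#' @export
input_affinities <- function(new_values, reference,
                             perplexity = NULL,
                             metric = c("euclidean", "correlation"),
                             tol = 1e-6) {
  metric <- match.arg(metric)
  check_reference_map(reference)
  perplexity <- perplexity %||% reference$tsne_params$perplexity
  ref_expr <- reference$reference_expression[reference$feature_ids, , drop = FALSE]
  if (is.null(names(new_values))) {
    if (length(new_values) != length(reference$feature_ids)) {
      abort("unnamed `new_values` must match the feature count of the map")
    }
  } else {
    missing <- setdiff(reference$feature_ids, names(new_values))
    if (length(missing) > 0L) {
      abort(sprintf("new sample lacks %d map feature(s): %s", length(missing),
                    paste(head(missing, 5L), collapse = ", ")))
    }
    new_values <- new_values[reference$feature_ids]
  }
  d2 <- sample_distances(new_values, ref_expr, metric)^2
  calibrated_affinities(d2, perplexity, tol)
}

sample_distances <- function(v, ref_expr, metric) {
  if (metric == "euclidean") {
    sqrt(colSums((ref_expr - v)^2))
  } else {
    if (sd(v) == 0) {
      abort("zero-variance sample: correlation distance undefined")
    }
    1 - as.vector(cor(v, ref_expr))
  }
}

# Gaussian kernel on squared distances with precision beta found by binary
# search so that the Shannon perplexity matches the target
calibrated_affinities <- function(d2, perplexity, tol = 1e-6, max_iter = 200L) {
  n <- length(d2)
  if (perplexity >= n) abort("perplexity must be below the reference sample count")
  target <- log(perplexity)
  beta <- 1
  lo <- 0
  hi <- Inf
  for (iter in seq_len(max_iter)) {
    w <- exp(-d2 * beta)
    sw <- sum(w)
    if (sw == 0) { # bandwidth collapsed; relax
      hi <- beta
      beta <- (lo + hi) / 2
      next
    }
    p <- w / sw
    h <- -sum(p[p > 0] * log(p[p > 0])) # Shannon entropy = log(perplexity)
    if (abs(h - target) < tol) break
    if (h > target) { # too flat: increase precision
      lo <- beta
      beta <- if (is.finite(hi)) (lo + hi) / 2 else beta * 2
    } else {
      hi <- beta
      beta <- (lo + hi) / 2
    }
  }
  p
}

#' Place new samples onto a frozen reference map
#'
#' The locked-embedding variant of Barnes-Hut t-SNE: reference coordinates
#' are given and never move; each new sample independently minimizes the KL
#' divergence between its calibrated input affinities (see
#' [input_affinities()]) and the Student-t affinities between its embedding
#' point and the fixed reference points, by gradient descent on its own
#' coordinate only. Because each point optimizes alone against the locked
#' map, the result for a sample does not depend on which other samples are in
#' the batch, and the map itself is untouched.
#'
#' After embedding, samples are assigned to the nearest cluster centroid,
#' annotations are transferred by majority vote, and correlation diagnostics
#' flag samples the reference may not represent.
#'
#' @param reference A `reference_map`.
#' @param new_data Genes x samples matrix for the new samples. At least
#'   `min_feature_overlap` of the map's features must be present; under the
#'   correlation metric, missing features are mean-imputed from the
#'   reference.
#' @param metric `"euclidean"`, `"correlation"`, or `NULL` for the map's own.
#' @param theta Barnes-Hut accuracy parameter, kept with the result; the
#'   desk-scale optimizer evaluates exact gradients (theta recorded, default
#'   0.3).
#' @param seed Integer seed (consumed only by `init = "gaussian"`).
#' @param n_iter,learning_rate Optimizer settings: 500 gradient-descent
#'   iterations at rate 2, momentum 0.5 switching to 0.8 halfway. The rate is
#'   sized for the single-point objective (affinities sum to 1 over the
#'   reference, so gradients are O(1)); it reproduces the exact KL minimizer
#'   to numerical precision on well-separated maps.
#' @param init `"weighted"` (affinity-weighted mean of the top-10 reference
#'   points; deterministic) or `"gaussian"` (random, as in the unlocked
#'   algorithm).
#' @param perplexity Affinity perplexity; default: the map's.
#' @param min_feature_overlap Minimum fraction of map features the new data
#'   must provide (default 0.9).
#' @param max_r_warn,margin_warn Representativeness thresholds; see
#'   [remap_diagnostics()].
#' @return A `remap_result` with a per-sample tibble (coordinates, cluster,
#'   transferred annotation, diagnostics) and the run parameters.
#' @export
remap_samples <- function(reference, new_data, metric = NULL, theta = 0.3,
                          seed = 1L, n_iter = 500L, learning_rate = 2,
                          init = c("weighted", "gaussian"),
                          perplexity = NULL, min_feature_overlap = 0.9,
                          max_r_warn = 0.8, margin_warn = 0.05) {
  check_reference_map(reference)
  init <- match.arg(init)
  metric <- metric %||% reference$tsne_params$metric
  metric <- match.arg(metric, c("euclidean", "correlation"))
  perplexity <- perplexity %||% reference$tsne_params$perplexity
  if (!is.matrix(new_data) || ncol(new_data) == 0L) {
    abort("`new_data` must be a genes x samples matrix with >= 1 sample")
  }

  feats <- reference$feature_ids
  present <- intersect(feats, rownames(new_data))
  coverage <- length(present) / length(feats)
  if (coverage < min_feature_overlap) {
    abort(sprintf("new data covers only %.0f%% of map features (needs >= %.0f%%)",
                  100 * coverage, 100 * min_feature_overlap))
  }
  ref_expr <- reference$reference_expression[feats, , drop = FALSE]
  # align to feature space; absent features mean-imputed from the reference
  aligned <- matrix(rowMeans(ref_expr), nrow = length(feats), ncol = ncol(new_data),
                    dimnames = list(feats, colnames(new_data)))
  aligned[present, ] <- new_data[present, , drop = FALSE]

  if (init == "gaussian") withr_seed(seed)
  Y <- reference$embedding

  coords <- matrix(NA_real_, ncol(aligned), 2L,
                   dimnames = list(colnames(aligned), c("dim1", "dim2")))
  for (j in seq_len(ncol(aligned))) {
    p <- input_affinities(aligned[, j], reference, perplexity = perplexity,
                          metric = metric)
    y0 <- if (init == "weighted") {
      top <- order(-p)[seq_len(min(10L, length(p)))]
      colSums(Y[top, , drop = FALSE] * (p[top] / sum(p[top])))
    } else {
      rnorm(2L, 0, 1e-4)
    }
    coords[j, ] <- descend_point(p, Y, y0, n_iter = n_iter,
                                 eta = learning_rate)
  }

  assigned <- assign_clusters(coords, reference)
  transferred <- transfer_annotation(assigned, reference)
  diag <- remap_diagnostics(aligned, reference, assigned, metric = metric,
                            max_r_warn = max_r_warn, margin_warn = margin_warn)

  samples <- dplyr::left_join(
    tibble(sample_id = rownames(coords),
           dim1 = coords[, 1L], dim2 = coords[, 2L],
           cluster = assigned,
           annotation = transferred[as.character(assigned)]),
    diag, by = "sample_id")

  structure(list(samples = samples,
                 params = list(metric = metric, theta = theta,
                               perplexity = perplexity, seed = as.integer(seed),
                               n_iter = as.integer(n_iter),
                               learning_rate = learning_rate, init = init,
                               max_r_warn = max_r_warn,
                               margin_warn = margin_warn)),
            class = "remap_result")
}

# gradient descent of one embedding point against fixed reference coordinates;
# exact gradient of KL(P||Q) for a single free point:
#   dC/dy = 2 * sum_j (p_j - q_j) (1 + |y - Y_j|^2)^{-1} (y - Y_j)
descend_point <- function(p, Y, y0, n_iter = 500L, eta = 2,
                          momentum_lo = 0.5, momentum_hi = 0.8) {
  y <- y0
  v <- c(0, 0)
  switch_at <- n_iter %/% 2L
  for (iter in seq_len(n_iter)) {
    dy1 <- y[1L] - Y[, 1L]
    dy2 <- y[2L] - Y[, 2L]
    wk <- 1 / (1 + dy1^2 + dy2^2)
    q <- wk / sum(wk)
    coef <- 2 * (p - q) * wk
    grad <- c(sum(coef * dy1), sum(coef * dy2))
    mom <- if (iter <= switch_at) momentum_lo else momentum_hi
    v <- mom * v - eta * grad
    y <- y + v
  }
  y
}

#' Assign map coordinates to the nearest cluster centroid
#'
#' @param coords n x 2 coordinates.
#' @param model A `reference_map` or `mean_shift` object carrying centroids.
#' @return Integer cluster labels; ties go to the lowest cluster id.
#' @export
assign_clusters <- function(coords, model) {
  centroids <- model$centroids
  if (is.null(centroids) || nrow(centroids) == 0L) abort("no centroids available")
  if (!is.matrix(coords)) coords <- matrix(coords, ncol = 2L)
  ids <- as.integer(rownames(centroids))
  ord <- order(ids) # evaluate in id order so which.min ties pick the lowest id
  centroids <- centroids[ord, , drop = FALSE]
  ids <- ids[ord]
  d2 <- outer(coords[, 1L], centroids[, 1L], "-")^2 +
    outer(coords[, 2L], centroids[, 2L], "-")^2
  ids[apply(d2, 1L, which.min)]
}

#' Transfer phenotype annotation by cluster majority vote
#'
#' Each cluster inherits the modal phenotype of its annotated reference
#' members; ties yield `"ambiguous"`, clusters with no annotated member
#' `"unlabeled"`.
#'
#' @param assigned Integer cluster labels for the new samples (any subset of
#'   the map's clusters; used only to define which clusters to report — the
#'   vote is over reference members).
#' @param reference A `reference_map`.
#' @return Named character vector: cluster id -> transferred annotation.
#' @export
transfer_annotation <- function(assigned, reference) {
  check_reference_map(reference)
  clusters <- sort(unique(as.integer(assigned)))
  pheno <- reference$annotations$phenotype
  out <- vapply(clusters, function(c) {
    members <- pheno[reference$cluster_labels == c]
    members <- members[!is.na(members)]
    if (length(members) == 0L) return("unlabeled")
    counts <- sort(table(members), decreasing = TRUE)
    if (length(counts) > 1L && counts[1L] == counts[2L]) return("ambiguous")
    names(counts)[1L]
  }, character(1L))
  setNames(out, as.character(clusters))
}

#' Representativeness diagnostics for remapped samples
#'
#' For each new sample: the highest Pearson correlation to any reference
#' sample (`max_r`), the mean correlation to members of the assigned cluster
#' (`cluster_mean_r`), and the margin over the best other cluster's mean
#' correlation (`margin`). A sample is flagged (`flag = TRUE`) when `max_r`
#' falls below `max_r_warn` or `margin` below `margin_warn` — the pattern
#' produced when the sample's subtype is poorly represented, or absent, in
#' the reference collection.
#'
#' @param new_data Genes x samples matrix aligned to (or covering) the map
#'   features.
#' @param reference A `reference_map`.
#' @param assigned Integer cluster labels for the new samples.
#' @param metric Unused for the correlations themselves (always Pearson);
#'   kept for provenance.
#' @param max_r_warn,margin_warn Warning thresholds.
#' @return Tibble: `sample_id`, `max_r`, `cluster_mean_r`, `margin`, `flag`.
#' @export
remap_diagnostics <- function(new_data, reference, assigned,
                              metric = "correlation",
                              max_r_warn = 0.8, margin_warn = 0.05) {
  check_reference_map(reference)
  feats <- reference$feature_ids
  ref_expr <- reference$reference_expression[feats, , drop = FALSE]
  common <- intersect(feats, rownames(new_data))
  r <- cor(new_data[common, , drop = FALSE], ref_expr[common, , drop = FALSE])
  labels <- reference$cluster_labels
  cluster_ids <- sort(unique(labels))
  # per new sample x reference cluster mean correlation
  mean_r <- vapply(cluster_ids, function(c) {
    rowMeans(r[, labels == c, drop = FALSE])
  }, numeric(nrow(r)))
  if (is.null(dim(mean_r))) mean_r <- matrix(mean_r, nrow = nrow(r))
  colnames(mean_r) <- as.character(cluster_ids)
  idx <- match(as.character(assigned), colnames(mean_r))
  own <- mean_r[cbind(seq_len(nrow(r)), idx)]
  best_other <- vapply(seq_len(nrow(r)), function(i) {
    others <- mean_r[i, -idx[i]]
    if (length(others) == 0L) -Inf else max(others)
  }, numeric(1L))
  max_r <- matrixStats::rowMaxs(r, useNames = FALSE)
  tibble(
    sample_id = rownames(r),
    max_r = max_r,
    cluster_mean_r = unname(own),
    margin = unname(own - best_other),
    flag = max_r < max_r_warn | unname(own - best_other) < margin_warn
  )
}

#' @export
print.remap_result <- function(x, ...) {
  cat(sprintf("<remap_result> %d samples remapped (%s metric), %d flagged\n",
              nrow(x$samples), x$params$metric, sum(x$samples$flag)))
  invisible(x)
}

#' @method tidy remap_result
#' @export
tidy.remap_result <- function(x, ...) x$samples

#' @method glance remap_result
#' @export
glance.remap_result <- function(x, ...) {
  tibble(n_samples = nrow(x$samples),
         n_flagged = sum(x$samples$flag),
         metric = x$params$metric,
         perplexity = x$params$perplexity,
         theta = x$params$theta)
}
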