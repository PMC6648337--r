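#' Build a frozen reference map
#'
#' Runs the map-building pipeline: feature selection (variance-based gene
#' selection by default, PCA scores or their combination as alternatives),
#' Barnes-Hut t-SNE to 2D, Gaussian mean-shift clustering, centroids. The
#' result bundles everything needed to place new samples onto the map later
#' without touching it: selected features, coordinates, clusters, the
#' expression of the reference samples over the selected features, and every
#' parameter used.
#'
#' @param x Genes x samples matrix.
#' @param annotations Sample annotation tibble (`sample_id`, `study_id`,
#'   `phenotype`, `platform`); see [read_annotations()].
#' @param mode Feature selection: `"variable_pct"` (default), `"pca"`, or
#'   `"both"` (variable genes, then PCA on them).
#' @param pct Percentage of most-variable genes (default 15).
#' @param n_components Principal components for the PCA modes.
#' @param perplexity,theta t-SNE parameters (defaults 30 and 0.5).
#' @param bandwidth Mean-shift bandwidth (1.5 for single-entity maps, 2.5 for
#'   full collections).
#' @param seed Integer seed; the map is deterministic given it.
#' @param metric Distance recorded for remapping, `"euclidean"` or
#'   `"correlation"` (the build itself is Euclidean; the metric is consumed
#'   by [remap_samples()]).
#' @param max_iter t-SNE iterations.
#' @return A `reference_map` object.
#' @export
build_reference_map <- function(x, annotations,
                                mode = c("variable_pct", "pca", "both"),
                                pct = 15, n_components = 20,
                                perplexity = 30, theta = 0.5,
                                bandwidth = 1.5, seed = 1L,
                                metric = c("euclidean", "correlation"),
                                max_iter = 1000L) {
  mode <- match.arg(mode)
  metric <- match.arg(metric)
  check_expression(x)
  ann <- align_annotations(x, annotations)

  feat_expr <- if (mode == "pca") x else select_variable_genes(x, pct)
  embed_input <- switch(mode,
    variable_pct = feat_expr,
    pca = t(pca_reduce(x, n_components)),
    both = t(pca_reduce(feat_expr, min(n_components, min(dim(feat_expr)) - 1L)))
  )

  coords <- tsne_embed(embed_input, perplexity = perplexity, theta = theta,
                       seed = seed, max_iter = max_iter)
  ms <- mean_shift(coords, bandwidth = bandwidth)

  structure(list(
    feature_ids = rownames(feat_expr),
    embedding = coords,
    tsne_params = list(perplexity = perplexity, theta = theta,
                       seed = as.integer(seed), metric = metric,
                       mode = mode, pct = pct,
                       n_components = if (mode == "variable_pct") NA_integer_ else as.integer(n_components)),
    cluster_labels = ms$labels,
    centroids = ms$centroids,
    bandwidth = bandwidth,
    annotations = ann,
    reference_expression = feat_expr
  ), class = "reference_map")
}

check_reference_map <- function(map) {
  stopifnot(inherits(map, "reference_map"))
  n <- nrow(map$embedding)
  if (length(map$cluster_labels) != n || nrow(map$annotations) != n) {
    abort("reference map is inconsistent: sample counts differ across fields")
  }
  if (!all(sort(unique(map$cluster_labels)) %in% as.integer(rownames(map$centroids)))) {
    abort("reference map is inconsistent: cluster without centroid")
  }
  if (!all(map$feature_ids %in% rownames(map$reference_expression))) {
    abort("reference map is inconsistent: feature ids absent from stored expression")
  }
  invisible(map)
}

#' @export
print.reference_map <- function(x, ...) {
  cat(sprintf("<reference_map> %d samples, %d features, %d clusters\n",
              nrow(x$embedding), length(x$feature_ids), nrow(x$centroids)))
  cat(sprintf("  t-SNE perplexity %.5g, theta %.5g, seed %d; mean-shift bandwidth %.5g\n",
              x$tsne_params$perplexity, x$tsne_params$theta,
              x$tsne_params$seed, x$bandwidth))
  invisible(x)
}

#' Tidy a reference map into one row per sample
#'
#' @param x A `reference_map`.
#' @param ... Unused.
#' @return Tibble with sample id, coordinates, cluster and annotations.
#' @method tidy reference_map
#' @export
tidy.reference_map <- function(x, ...) {
  dplyr::bind_cols(
    tibble(sample_id = rownames(x$embedding),
           dim1 = x$embedding[, 1L],
           dim2 = x$embedding[, 2L],
           cluster = x$cluster_labels),
    dplyr::select(x$annotations, -"sample_id")
  )
}

#' One-row summary of a reference map
#'
#' @param x A `reference_map`.
#' @param ... Unused.
#' @method glance reference_map
#' @export
glance.reference_map <- function(x, ...) {
  tibble(n_samples = nrow(x$embedding),
         n_features = length(x$feature_ids),
         n_clusters = nrow(x$centroids),
         n_studies = dplyr::n_distinct(x$annotations$study_id),
         perplexity = x$tsne_params$perplexity,
         theta = x$tsne_params$theta,
         bandwidth = x$bandwidth,
         seed = x$tsne_params$seed)
}

#' Save / load a reference map
#'
#' The map is serialized as a directory holding a JSON manifest
#' (parameters, versions) plus human-inspectable TSV payloads: embedding +
#' clusters, centroids, annotations, and the reference expression over the
#' selected features. `load_reference_map(save_reference_map(m))` reproduces
#' every field, coordinates bit-exact.
#'
#' @param map A `reference_map`.
#' @param path Directory to create/read.
#' @return `path` (save) or the `reference_map` (load).
#' @export
save_reference_map <- function(map, path) {
  check_reference_map(map)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    format = "refmap/reference_map",
    version = 1L,
    tsne_params = map$tsne_params,
    bandwidth = map$bandwidth,
    n_samples = nrow(map$embedding),
    n_features = length(map$feature_ids)
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  readr::write_tsv(
    tibble(sample_id = rownames(map$embedding),
           dim1 = fmt_dbl(map$embedding[, 1L]),
           dim2 = fmt_dbl(map$embedding[, 2L]),
           cluster = map$cluster_labels),
    file.path(path, "embedding.tsv"), progress = FALSE)
  readr::write_tsv(
    tibble(cluster = as.integer(rownames(map$centroids)),
           dim1 = fmt_dbl(map$centroids[, 1L]),
           dim2 = fmt_dbl(map$centroids[, 2L])),
    file.path(path, "centroids.tsv"), progress = FALSE)
  write_annotations(map$annotations, file.path(path, "annotations.tsv"))
  expr <- map$reference_expression
  readr::write_tsv(
    dplyr::bind_cols(tibble(gene_id = rownames(expr)),
                     as_tibble(apply(expr, 2L, fmt_dbl, simplify = FALSE))),
    file.path(path, "expression.tsv"), progress = FALSE)
  readr::write_lines(map$feature_ids, file.path(path, "features.txt"))
  invisible(path)
}

# full-precision, locale-independent decimal text; round-trips doubles exactly
fmt_dbl <- function(x) sprintf("%.17g", x)

#' @rdname save_reference_map
#' @export
load_reference_map <- function(path) {
  need <- c("manifest.json", "embedding.tsv", "centroids.tsv",
            "annotations.tsv", "expression.tsv", "features.txt")
  have <- file.exists(file.path(path, need))
  if (!all(have)) {
    abort(sprintf("reference map at '%s' is missing: %s", path,
                  paste(need[!have], collapse = ", ")))
  }
  manifest <- jsonlite::read_json(file.path(path, "manifest.json"),
                                  simplifyVector = TRUE)
  if (!identical(manifest$format, "refmap/reference_map")) {
    abort("not a reference map: unrecognized manifest format")
  }
  if (!identical(as.integer(manifest$version), 1L)) {
    abort(sprintf("unsupported reference map version %s", manifest$version))
  }
  # numeric columns are parsed as text and converted with as.numeric (strtod,
  # correctly rounded) so that %.17g payloads round-trip bit-exactly
  emb_df <- readr::read_tsv(file.path(path, "embedding.tsv"),
                            col_types = "ccci", progress = FALSE)
  cen_df <- readr::read_tsv(file.path(path, "centroids.tsv"),
                            col_types = "icc", progress = FALSE)
  expr <- read_expression(file.path(path, "expression.tsv"))
  embedding <- cbind(dim1 = as.numeric(emb_df$dim1),
                     dim2 = as.numeric(emb_df$dim2))
  rownames(embedding) <- emb_df$sample_id
  centroids <- cbind(dim1 = as.numeric(cen_df$dim1),
                     dim2 = as.numeric(cen_df$dim2))
  rownames(centroids) <- as.character(cen_df$cluster)
  tp <- manifest$tsne_params
  tp$seed <- as.integer(tp$seed)
  tp$n_components <- as.integer(tp$n_components %||% NA_integer_)
  map <- structure(list(
    feature_ids = readr::read_lines(file.path(path, "features.txt"), progress = FALSE),
    embedding = embedding,
    tsne_params = tp,
    cluster_labels = emb_df$cluster,
    centroids = centroids,
    bandwidth = manifest$bandwidth,
    annotations = read_annotations(file.path(path, "annotations.tsv")),
    reference_expression = expr
  ), class = "reference_map")
  check_reference_map(map)
  map
}
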