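#' Build a frozen normalization model from an original probe collection
#'
#' Captures the two inter-sample summaries that quantile normalization and
#' median-polish probe summarization would otherwise have to recompute over
#' the whole collection every time a sample is added: (1) the reference
#' quantile distribution — the across-sample mean of the per-sample sorted
#' value vectors of the (background-corrected, log2) probe intensities; and
#' (2) the per-probe row effects and per-gene overall effects from a two-way
#' median polish of each gene's probes x samples submatrix after quantile
#' normalization. New samples normalized against the model land in the same
#' expression space as the original collection without re-processing it.
#'
#' @param probes Probes x samples numeric matrix (background-corrected log2
#'   intensities, >= 2 samples), probe ids as rownames.
#' @param probe_to_gene Tibble or data frame with columns `probe_id`,
#'   `gene_id` covering every probe row.
#' @param max_iter,eps Median-polish iteration cap and convergence tolerance.
#' @return A `refnorm_model`: `reference_quantiles`, `probe_effects` (named
#'   per probe, on the original-data scale: median-polish row effect plus the
#'   gene's overall effect), `overall_effects` (named per gene),
#'   `probe_to_gene`.
#' @export
build_reference_model <- function(probes, probe_to_gene, max_iter = 10L,
                                  eps = 0.01) {
  if (!is.matrix(probes) || ncol(probes) < 2L) {
    abort("`probes` must be a probes x samples matrix with >= 2 samples")
  }
  if (is.null(rownames(probes))) abort("`probes` needs probe ids as rownames")
  map <- as_tibble(probe_to_gene)
  if (!all(c("probe_id", "gene_id") %in% names(map))) {
    abort("`probe_to_gene` needs columns probe_id and gene_id")
  }
  unmapped <- setdiff(rownames(probes), map$probe_id)
  if (length(unmapped) > 0L) {
    abort(sprintf("probe(s) missing from the probe-to-gene map: %s",
                  paste(head(unmapped, 5L), collapse = ", ")))
  }
  map <- map[match(rownames(probes), map$probe_id), ]

  reference_quantiles <- rowMeans(apply(probes, 2L, sort))

  # quantile-normalize the originals against their own reference distribution,
  # then polish each gene's probes x samples block
  qn <- apply(probes, 2L, map_to_quantiles, ref = reference_quantiles)
  rownames(qn) <- rownames(probes)

  genes <- unique(map$gene_id)
  probe_effects <- setNames(numeric(nrow(probes)), rownames(probes))
  overall_effects <- setNames(numeric(length(genes)), genes)
  for (g in genes) {
    rows <- map$probe_id[map$gene_id == g]
    block <- qn[rows, , drop = FALSE]
    if (nrow(block) == 1L) {
      mp <- list(overall = median(block), row = setNames(0, rows))
    } else {
      fit <- medpolish(block, maxiter = max_iter, eps = eps, trace.iter = FALSE)
      mp <- list(overall = fit$overall, row = setNames(fit$row, rows))
    }
    overall_effects[g] <- mp$overall
    # store probe effects on the original-data scale (row effect + the gene's
    # overall term): subtracting them from a new sample's probes leaves the
    # chip effect alone, so the frozen summary lands in the joint space
    probe_effects[rows] <- mp$row + mp$overall
  }

  structure(list(reference_quantiles = reference_quantiles,
                 probe_effects = probe_effects,
                 overall_effects = overall_effects,
                 probe_to_gene = map),
            class = "refnorm_model")
}

#' Quantile-map a new sample onto the stored reference distribution
#'
#' The value at rank k is replaced by the k-th reference quantile, so the
#' output's sorted values equal the stored reference distribution exactly
#' and the input's ranks are preserved. Tied input values receive the mean
#' of the reference quantiles their rank block spans. The operation is
#' idempotent.
#'
#' @param new_sample Numeric probe vector, length and order matching the
#'   model's probes.
#' @param model A `refnorm_model`.
#' @return The quantile-mapped probe vector (names preserved).
#' @export
quantile_map_to_reference <- function(new_sample, model) {
  stopifnot(inherits(model, "refnorm_model"))
  if (length(new_sample) != length(model$reference_quantiles)) {
    abort(sprintf("sample has %d probes; model expects %d",
                  length(new_sample), length(model$reference_quantiles)))
  }
  map_to_quantiles(new_sample, model$reference_quantiles)
}

map_to_quantiles <- function(x, ref) {
  ord <- order(x)
  out <- numeric(length(x))
  out[ord] <- ref
  # tie blocks share the mean of the reference quantiles they span
  if (anyDuplicated(x)) {
    out <- stats::ave(out, match(x, x), FUN = mean)
  }
  names(out) <- names(x)
  out
}

#' Summarize a quantile-mapped sample to gene level with frozen probe effects
#'
#' Per gene g, expression is `overall_effect_g + median over probes p of
#' (value_p - probe_effect_p)` — the median-polish column-effect update with
#' the row (probe) effects frozen at their original-collection values, so a
#' single new sample is summarized exactly as it would have been inside the
#' original joint fit.
#'
#' @param new_sample_probes Quantile-mapped probe vector (model order).
#' @param model A `refnorm_model`.
#' @return Named numeric vector of gene-level expression.
#' @export
summarize_with_fixed_effects <- function(new_sample_probes, model) {
  stopifnot(inherits(model, "refnorm_model"))
  if (length(new_sample_probes) != length(model$probe_effects)) {
    abort("probe vector length does not match the model")
  }
  resid <- new_sample_probes - model$probe_effects
  split_resid <- split(resid, model$probe_to_gene$gene_id)
  genes <- names(model$overall_effects)
  vapply(genes, function(g) {
    model$overall_effects[[g]] + median(split_resid[[g]])
  }, numeric(1L))
}

#' Normalize new samples into the frozen reference space
#'
#' Convenience wrapper: quantile-maps each column of a probe matrix onto the
#' model's reference distribution, then summarizes to gene level with the
#' frozen probe effects.
#'
#' @param new_probes Probes x samples matrix (model probe order by rownames).
#' @param model A `refnorm_model`.
#' @return Genes x samples matrix of normalized expression.
#' @export
refnorm_apply <- function(new_probes, model) {
  stopifnot(inherits(model, "refnorm_model"))
  if (!is.matrix(new_probes)) new_probes <- as.matrix(new_probes)
  if (!is.null(rownames(new_probes))) {
    missing <- setdiff(model$probe_to_gene$probe_id, rownames(new_probes))
    if (length(missing) > 0L) {
      abort(sprintf("new data lacks probe(s): %s",
                    paste(head(missing, 5L), collapse = ", ")))
    }
    new_probes <- new_probes[model$probe_to_gene$probe_id, , drop = FALSE]
  }
  out <- apply(new_probes, 2L, function(v) {
    summarize_with_fixed_effects(quantile_map_to_reference(v, model), model)
  })
  rownames(out) <- names(model$overall_effects)
  out
}

#' @export
print.refnorm_model <- function(x, ...) {
  cat(sprintf("<refnorm_model> %d probes, %d genes\n",
              length(x$probe_effects), length(x$overall_effects)))
  invisible(x)
}

#' @method tidy refnorm_model
#' @export
tidy.refnorm_model <- function(x, ...) {
  tibble(probe_id = names(x$probe_effects),
         gene_id = x$probe_to_gene$gene_id,
         probe_effect = unname(x$probe_effects),
         overall_effect = unname(x$overall_effects[x$probe_to_gene$gene_id]),
         reference_quantile_mean = mean(x$reference_quantiles))
}

#' Joint quantile normalization + median polish of the original collection
#'
#' The conventional joint pipeline, used to verify that one-at-a-time
#' normalization through a frozen model reproduces the jointly normalized
#' values: quantile-normalize all samples to their common mean distribution,
#' then fit each gene's probes x samples block by two-way median polish and
#' report `overall + column effect` per (gene, sample).
#'
#' @inheritParams build_reference_model
#' @return Genes x samples matrix.
#' @export
joint_normalize <- function(probes, probe_to_gene, max_iter = 10L, eps = 0.01) {
  map <- as_tibble(probe_to_gene)
  map <- map[match(rownames(probes), map$probe_id), ]
  ref <- rowMeans(apply(probes, 2L, sort))
  qn <- apply(probes, 2L, map_to_quantiles, ref = ref)
  rownames(qn) <- rownames(probes)
  genes <- unique(map$gene_id)
  out <- matrix(NA_real_, length(genes), ncol(probes),
                dimnames = list(genes, colnames(probes)))
  for (g in genes) {
    block <- qn[map$probe_id[map$gene_id == g], , drop = FALSE]
    if (nrow(block) == 1L) {
      out[g, ] <- block[1L, ]
    } else {
      fit <- medpolish(block, maxiter = max_iter, eps = eps, trace.iter = FALSE)
      out[g, ] <- fit$overall + fit$col
    }
  }
  out
}
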