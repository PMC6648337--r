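#' Sweep feature-selection settings under the NMI metrics
#'
#' For every setting in the grid and each of `n_seeds` seeds, the harness
#' selects features (a number of principal components, a percentage of most
#' variable genes, or both), embeds with Barnes-Hut t-SNE, clusters with
#' mean-shift, and computes pNMI, eNMI and cNMI against the sample
#' annotations. Reported are the mean and standard deviation over seeds —
#' the multi-seed design separates a setting's systematic behavior from
#' embedding stochasticity. The whole sweep is deterministic given
#' `master_seed` (run seeds are `master_seed + 0 ... n_seeds - 1`).
#'
#' @param x Genes x samples matrix.
#' @param annotations Annotation tibble (`sample_id`, `study_id`,
#'   `phenotype`).
#' @param grid Tibble/data frame of settings with columns `mode`
#'   (`"variable_pct"`, `"pca"` or `"both"`) and, as needed, `pct` and
#'   `n_components`. Optional columns `perplexity` and `bandwidth` override
#'   the defaults per setting.
#' @param n_seeds Seeds per setting (100 mirrors a full evaluation; reduce
#'   for quick runs).
#' @param master_seed Base seed.
#' @param perplexity,bandwidth,max_iter Pipeline defaults used where the
#'   grid does not override them.
#' @return An `nmi_sweep` tibble: one row per setting with
#'   `pnmi_mean/sd`, `enmi_mean/sd`, `cnmi_mean/sd` and `n_seeds`.
#' @export
nmi_sweep <- function(x, annotations, grid, n_seeds = 10L, master_seed = 1L,
                      perplexity = 30, bandwidth = 1.5, max_iter = 500L) {
  check_expression(x)
  ann <- align_annotations(x, annotations)
  grid <- as_tibble(grid)
  if (!("mode" %in% names(grid))) abort("`grid` needs a `mode` column")
  n_seeds <- as.integer(n_seeds)
  if (n_seeds < 1L) abort("`n_seeds` must be >= 1")
  if ("n_components" %in% names(grid)) {
    bad <- grid$mode %in% c("pca", "both") & grid$n_components >= ncol(x)
    if (any(bad, na.rm = TRUE)) {
      abort("a setting requests more principal components than samples")
    }
  }

  or_default <- function(v, d) if (is.null(v) || is.na(v)) d else v
  per_setting <- purrr::pmap(grid, function(...) {
    setting <- list(...)
    pp <- or_default(setting$perplexity, perplexity)
    bw <- or_default(setting$bandwidth, bandwidth)
    runs <- purrr::map(seq_len(n_seeds) - 1L, function(off) {
      map <- build_reference_map(
        x, ann, mode = setting$mode,
        pct = or_default(setting$pct, 15),
        n_components = or_default(setting$n_components, 20),
        perplexity = pp, bandwidth = bw,
        seed = as.integer(master_seed) + off, max_iter = max_iter)
      p <- pnmi(map$cluster_labels, ann$phenotype)
      e <- enmi(map$cluster_labels, ann$study_id)
      tibble(pnmi = p, enmi = e, cnmi = cnmi(p, e))
    })
    runs <- dplyr::bind_rows(runs)
    tibble(pnmi_mean = mean(runs$pnmi), pnmi_sd = sd0(runs$pnmi),
           enmi_mean = mean(runs$enmi), enmi_sd = sd0(runs$enmi),
           cnmi_mean = mean(runs$cnmi), cnmi_sd = sd0(runs$cnmi),
           n_seeds = n_seeds)
  })
  out <- dplyr::bind_cols(grid, dplyr::bind_rows(per_setting))
  class(out) <- c("nmi_sweep", class(out))
  out
}

sd0 <- function(v) if (length(v) < 2L) 0 else sd(v)

#' Plot an NMI sweep report
#'
#' pNMI, eNMI and cNMI means per setting with +/- 1 sd ribbons, one facet
#' per feature-selection mode.
#'
#' @param report An `nmi_sweep` tibble.
#' @return A ggplot object.
#' @export
plot_nmi_sweep <- function(report) {
  report <- as_tibble(report)
  if (!("pct" %in% names(report))) report$pct <- NA_real_
  if (!("n_components" %in% names(report))) report$n_components <- NA_integer_
  long <- report %>%
    dplyr::mutate(setting = ifelse(.data$mode == "pca",
                                   paste0(.data$n_components, " PCs"),
                                   paste0(.data$pct, "% genes"))) %>%
    tidyr::pivot_longer(cols = dplyr::ends_with("_mean"),
                        names_to = "metric", values_to = "mean") %>%
    dplyr::mutate(metric = sub("_mean$", "", .data$metric),
                  sd = dplyr::case_when(
                    .data$metric == "pnmi" ~ .data$pnmi_sd,
                    .data$metric == "enmi" ~ .data$enmi_sd,
                    TRUE ~ .data$cnmi_sd))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$setting, y = .data$mean,
                                     group = .data$metric,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = pmax(.data$mean - .data$sd, 0),
                                          ymax = pmin(.data$mean + .data$sd, 1))) +
    ggplot2::facet_wrap(~ .data$mode, scales = "free_x") +
    ggplot2::labs(x = "feature selection setting", y = "metric (mean over seeds)",
                  colour = NULL) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot a reference map
#'
#' Scatter of the frozen embedding, colored by cluster, phenotype or study.
#'
#' @param object A `reference_map`.
#' @param colour_by `"cluster"`, `"phenotype"` or `"study_id"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot reference_map
#' @export
autoplot.reference_map <- function(object, colour_by = c("cluster", "phenotype", "study_id"),
                                   ...) {
  colour_by <- match.arg(colour_by)
  df <- tidy(object)
  df$colour <- factor(df[[colour_by]])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dim1, y = .data$dim2,
                                   colour = .data$colour)) +
    ggplot2::geom_point(size = 1.5, alpha = 0.8) +
    ggplot2::labs(colour = colour_by, x = "t-SNE 1", y = "t-SNE 2") +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' Plot remapped samples over their reference map
#'
#' Reference samples in grey, remapped samples colored by assigned cluster;
#' flagged (poorly represented) samples are drawn as open triangles.
#'
#' @param object A `remap_result`.
#' @param reference The `reference_map` the samples were placed on.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot remap_result
#' @export
autoplot.remap_result <- function(object, reference, ...) {
  ref_df <- tidy(reference)
  new_df <- object$samples
  ggplot2::ggplot() +
    ggplot2::geom_point(data = ref_df,
                        ggplot2::aes(x = .data$dim1, y = .data$dim2),
                        colour = "grey70", size = 1.2) +
    ggplot2::geom_point(data = new_df,
                        ggplot2::aes(x = .data$dim1, y = .data$dim2,
                                     colour = factor(.data$cluster),
                                     shape = .data$flag),
                        size = 2.2) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 2),
                                labels = c(`FALSE` = "ok", `TRUE` = "flagged")) +
    ggplot2::labs(colour = "assigned cluster", shape = "representativeness",
                  x = "t-SNE 1", y = "t-SNE 2") +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
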