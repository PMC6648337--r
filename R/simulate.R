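#' Describe a synthetic multi-study expression collection
#'
#' The generator emulates the structure that makes multi-study transcriptomics
#' collections hard to integrate: each phenotype carries a planted module of
#' up-regulated genes (the biology), while each study contributes gene-specific
#' additive shifts (the batch effect). A sample from phenotype `k` in study `s`
#' has value
#'
#' \deqn{x_{gi} = \mu_g + \delta\,1[g \in \mathrm{module}(k)] + b_{gs} + \epsilon_{gi}}
#'
#' with gene baselines \eqn{\mu_g \sim N(\mu_0, \sigma_0^2)} on the log2
#' intensity scale, batch shifts \eqn{b_{gs} \sim N(0, \sigma_b^2)} drawn per
#' gene and study, and noise \eqn{\epsilon \sim N(0, \sigma_e^2)}.
#'
#' Defaults describe a collection where the per-gene biological effect exceeds
#' the per-gene batch shift, but background genes outnumber planted genes
#' enough that batch variation dominates in aggregate — the regime in which
#' all-gene or PCA-based clustering groups samples by study while
#' variance-based gene selection recovers the phenotypes.
#'
#' @param n_genes Total genes.
#' @param n_phenotypes Number of planted phenotypes.
#' @param samples_per_phenotype Samples per phenotype.
#' @param n_studies Number of studies; samples are spread round-robin across
#'   studies within phenotype (`study_layout = "balanced"`) or each study
#'   carries a single phenotype (`"confounded"`).
#' @param module_size Up-regulated genes planted per phenotype (disjoint).
#' @param effect_size Log2 effect \eqn{\delta} added to module genes.
#' @param batch_sd Standard deviation \eqn{\sigma_b} of per-(gene, study)
#'   shifts. Set `batch_per_gene = FALSE` for a coarser per-study scalar shift.
#' @param noise_sd Residual standard deviation \eqn{\sigma_e}.
#' @param baseline_mean,baseline_sd Mean and sd of gene baselines \eqn{\mu_g}
#'   (log2 intensity scale).
#' @param batch_per_gene Draw batch shifts per (gene, study) rather than one
#'   scalar per study.
#' @param study_layout `"balanced"` or `"confounded"`.
#' @param missing_phenotype_rate Fraction of samples whose phenotype label is
#'   masked to `NA` in the annotations (truth is never masked).
#' @param rnaseq Emit negative-binomial counts (then log2-CPM transform) in
#'   place of Gaussian log-intensities, exercising the count-data scoring path.
#' @param nb_dispersion Negative-binomial dispersion (size = 1/dispersion)
#'   used when `rnaseq = TRUE`.
#' @return A `simulation_design` list.
#' @export
simulation_design <- function(n_genes = 2000,
                              n_phenotypes = 4,
                              samples_per_phenotype = 25,
                              n_studies = 10,
                              module_size = 40,
                              effect_size = 3,
                              batch_sd = 0.7,
                              noise_sd = 0.6,
                              baseline_mean = 7,
                              baseline_sd = 1.5,
                              batch_per_gene = TRUE,
                              study_layout = c("balanced", "confounded"),
                              missing_phenotype_rate = 0,
                              rnaseq = FALSE,
                              nb_dispersion = 0.1) {
  study_layout <- match.arg(study_layout)
  design <- list(
    n_genes = as.integer(n_genes),
    n_phenotypes = as.integer(n_phenotypes),
    samples_per_phenotype = as.integer(samples_per_phenotype),
    n_studies = as.integer(n_studies),
    module_size = as.integer(module_size),
    effect_size = effect_size,
    batch_sd = batch_sd,
    noise_sd = noise_sd,
    baseline_mean = baseline_mean,
    baseline_sd = baseline_sd,
    batch_per_gene = isTRUE(batch_per_gene),
    study_layout = study_layout,
    missing_phenotype_rate = missing_phenotype_rate,
    rnaseq = isTRUE(rnaseq),
    nb_dispersion = nb_dispersion
  )
  if (design$module_size * design$n_phenotypes > design$n_genes) {
    abort("infeasible design: disjoint modules need module_size * n_phenotypes <= n_genes")
  }
  if (design$batch_sd < 0 || design$noise_sd < 0 || design$baseline_sd < 0) {
    abort("standard deviations must be >= 0")
  }
  if (design$study_layout == "confounded" && design$n_studies < design$n_phenotypes) {
    abort("confounded layout needs at least one study per phenotype")
  }
  structure(design, class = "simulation_design")
}

#' Generate a synthetic multi-study collection
#'
#' @param design A [simulation_design()].
#' @param seed Integer seed; the whole collection is deterministic given it.
#' @return A list with `expression` (genes x samples matrix), `annotations`
#'   (tibble: sample_id, study_id, phenotype, platform), and `truth`
#'   (list: `phenotype` unmasked labels per sample, `modules` planted gene ids
#'   per phenotype).
#' @export
simulate_collection <- function(design = simulation_design(), seed = 1L) {
  stopifnot(inherits(design, "simulation_design"))
  withr_seed(seed)

  G <- design$n_genes
  K <- design$n_phenotypes
  n <- K * design$samples_per_phenotype
  S <- design$n_studies

  gene_ids <- sprintf("g%04d", seq_len(G))
  sample_ids <- sprintf("s%03d", seq_len(n))
  phenotypes <- rep(sprintf("P%d", seq_len(K)), each = design$samples_per_phenotype)

  if (design$study_layout == "balanced") {
    # round-robin within phenotype: every study mixes phenotypes
    studies <- integer(n)
    for (k in seq_len(K)) {
      idx <- which(phenotypes == sprintf("P%d", k))
      studies[idx] <- ((seq_along(idx) - 1L + (k - 1L)) %% S) + 1L
    }
  } else {
    per_ph <- split(seq_len(S), rep(seq_len(K), length.out = S))
    studies <- integer(n)
    for (k in seq_len(K)) {
      idx <- which(phenotypes == sprintf("P%d", k))
      studies[idx] <- rep(per_ph[[k]], length.out = length(idx))
    }
  }
  study_ids <- sprintf("study%02d", studies)

  modules <- split(gene_ids[seq_len(design$module_size * K)],
                   rep(seq_len(K), each = design$module_size))
  names(modules) <- sprintf("P%d", seq_len(K))

  mu <- rnorm(G, design$baseline_mean, design$baseline_sd)
  x <- matrix(mu, nrow = G, ncol = n)
  for (k in seq_len(K)) {
    rows <- match(modules[[k]], gene_ids)
    cols <- which(phenotypes == sprintf("P%d", k))
    x[rows, cols] <- x[rows, cols] + design$effect_size
  }
  if (design$batch_sd > 0) {
    if (design$batch_per_gene) {
      b <- matrix(rnorm(G * S, 0, design$batch_sd), nrow = G)
    } else {
      b <- matrix(rep(rnorm(S, 0, design$batch_sd), each = G), nrow = G)
    }
    x <- x + b[, studies, drop = FALSE]
  }
  if (design$noise_sd > 0) {
    x <- x + matrix(rnorm(G * n, 0, design$noise_sd), nrow = G)
  }

  if (design$rnaseq) {
    # treat the Gaussian log2 surface as log2 expected counts
    lambda <- 2^x
    counts <- matrix(
      rnbinom(G * n, mu = as.vector(lambda), size = 1 / design$nb_dispersion),
      nrow = G)
    lib <- colSums(counts)
    x <- log2(t(t(counts) / lib) * 1e6 + 1)
  }

  dimnames(x) <- list(gene_ids, sample_ids)

  shown <- phenotypes
  if (design$missing_phenotype_rate > 0) {
    mask <- runif(n) < design$missing_phenotype_rate
    shown[mask] <- NA_character_
  }
  ann <- tibble(sample_id = sample_ids,
                study_id = study_ids,
                phenotype = shown,
                platform = if (design$rnaseq) "rnaseq" else "array")

  list(expression = x,
       annotations = ann,
       truth = list(phenotype = setNames(phenotypes, sample_ids),
                    modules = modules))
}

#' Monotone cross-platform distortion
#'
#' Applies a strictly increasing elementwise transform
#' \eqn{f(x) = a + b\,[m + \mathrm{sign}(x-m)\,|x-m|^{\gamma}]} emulating the
#' systematic intensity distortion between measurement platforms. Monotonicity
#' guarantees that within-sample gene ranks are untouched, which is what makes
#' correlation-based remapping robust to the distortion.
#'
#' @param x Genes x samples matrix.
#' @param shift Additive offset `a`.
#' @param scale Multiplicative slope `b`; must be `> 0`.
#' @param power Exponent `gamma` applied around `center`; must be `> 0`.
#' @param center Pivot `m` of the power distortion (log2 intensity units).
#' @return Transformed matrix of identical shape.
#' @export
platform_transform <- function(x, shift = 0, scale = 1, power = 1, center = 7) {
  check_expression(x)
  if (scale <= 0 || power <= 0) {
    abort("non-monotone parameterization: `scale` and `power` must be > 0")
  }
  y <- shift + scale * (center + sign(x - center) * abs(x - center)^power)
  dimnames(y) <- dimnames(x)
  y
}

withr_seed <- function(seed) {
  seed <- as.integer(seed)
  if (is.na(seed)) abort("`seed` must be an integer")
  set.seed(seed)
  invisible(seed)
}
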