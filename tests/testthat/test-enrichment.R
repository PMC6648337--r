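test_that("cluster gene sets capture indicator-like genes and truncate honestly", {
  set.seed(51)
  n <- 30
  labels <- rep(1:3, each = 10)
  x <- matrix(rnorm(40 * n, 7, 0.5), 40, n,
              dimnames = list(sprintf("g%02d", 1:40), sprintf("s%02d", 1:n)))
  x["g01", labels == 2] <- x["g01", labels == 2] + 5 # near-indicator of cluster 2
  sets <- cluster_genesets(x, labels)
  up2 <- sets$genes[[match("cluster2_UP", sets$set)]]
  expect_true("g01" %in% up2)
  expect_lte(length(up2), 20L)
  expect_error(cluster_genesets(x, rep(1, n)), "2 clusters")
  expect_error(cluster_genesets(x[, 1:5], c(1, 1, 1, 2, 2)), "fewer than 3")
})

test_that("planted modules fill the derived up-sets completely", {
  sim <- clean_sim(seed = 52, n_phenotypes = 3, samples_per_phenotype = 20,
                   n_genes = 400, module_size = 30, effect_size = 3,
                   batch_sd = 0.3, noise_sd = 0.4)
  labels <- as.integer(factor(sim$truth$phenotype))
  sets <- cluster_genesets(sim$expression, labels)
  for (k in 1:3) {
    up <- sets$genes[[match(sprintf("cluster%d_UP", k), sets$set)]]
    expect_identical(length(up), 20L)
    expect_true(all(up %in% sim$truth$modules[[sprintf("P%d", k)]]))
  }
})

test_that("enrichment scores equal brute-force walk enumeration", {
  set.seed(53)
  x <- matrix(rnorm(10 * 3, 7, 1), 10, 3,
              dimnames = list(sprintf("g%02d", 1:10), c("s1", "s2", "s3")))
  sets <- gene_sets(c("A", "B"), list(rownames(x)[c(1, 3, 5, 7, 9)],
                                      rownames(x)[c(2, 4, 6, 8, 10)]))
  sc <- gsva_scores(x, sets, tau = 0.25)
  z <- refmap:::kcdf_statistic(x, "gaussian")
  for (j in 1:3) {
    for (s in c("A", "B")) {
      want <- oracle_walk(z[, j], rownames(x),
                          sets$genes[[match(s, sets$set)]], tau = 0.25)
      expect_equal(sc[j, s], want, tolerance = 1e-12)
    }
  }
})

test_that("a set built from a sample's top-statistic genes maximizes that sample", {
  set.seed(54)
  x <- matrix(rnorm(60 * 10, 7, 1), 60, 10,
              dimnames = list(sprintf("g%02d", 1:60), sprintf("s%02d", 1:10)))
  z <- refmap:::kcdf_statistic(x, "gaussian")
  top <- rownames(x)[order(-z[, 4])][1:20]
  sc <- gsva_scores(x, gene_sets("TOP", list(top)))
  expect_gt(sc[4, "TOP"], 0)
  expect_identical(unname(which.max(sc[, "TOP"])), 4L)
})

test_that("reversing a planted module's direction flips the mean score sign", {
  sim <- clean_sim(seed = 55, n_phenotypes = 2, samples_per_phenotype = 15,
                   n_genes = 200, module_size = 25, effect_size = 3)
  x <- sim$expression
  mod <- sim$truth$modules[["P1"]]
  down_version <- x
  down_version[mod, sim$truth$phenotype == "P1"] <-
    down_version[mod, sim$truth$phenotype == "P1"] - 6
  sets <- gene_sets("MOD", list(mod))
  up_scores <- gsva_scores(x, sets)[sim$truth$phenotype == "P1", 1]
  dn_scores <- gsva_scores(down_version, sets)[sim$truth$phenotype == "P1", 1]
  expect_gt(mean(up_scores), 0)
  expect_lt(mean(dn_scores), 0)
})

test_that("the post-ranking walk is invariant under monotone transforms", {
  set.seed(56)
  x <- matrix(rnorm(40 * 6, 7, 1), 40, 6,
              dimnames = list(sprintf("g%02d", 1:40), sprintf("s%02d", 1:6)))
  sets <- gene_sets("S", list(rownames(x)[3:12]))
  z <- refmap:::kcdf_statistic(x, "gaussian")
  a <- refmap:::walk_scores(z, sets, tau = 0.25)
  b <- refmap:::walk_scores(2 * z + 1, sets, tau = 0.25) # rank-preserving
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("undersized sets are skipped with a warning", {
  x <- tiny_expr(30, 5, seed = 57)
  sets <- gene_sets(c("ok", "tiny"),
                    list(rownames(x)[1:10], c("g01", "g02", "nope")))
  expect_warning(sc <- gsva_scores(x, sets), "tiny")
  expect_identical(colnames(sc), "ok")
  expect_error(suppressWarnings(gsva_scores(x, sets[2, ])), "no evaluable")
})

test_that("poisson-kernel scoring accepts counts and rejects continuous input", {
  set.seed(58)
  counts <- matrix(rpois(50 * 6, 20), 50, 6,
                   dimnames = list(sprintf("g%02d", 1:50), sprintf("s%02d", 1:6)))
  counts[1:10, 1:3] <- counts[1:10, 1:3] + 40
  sc <- gsva_scores(counts, gene_sets("HI", list(rownames(counts)[1:10])),
                    kcdf = "poisson")
  expect_gt(mean(sc[1:3, 1]), mean(sc[4:6, 1]))
  expect_error(gsva_scores(counts + 0.5, gene_sets("HI", list(rownames(counts)[1:10])),
                           kcdf = "poisson"), "integer")
})

test_that("empirical p-values honor the counting rule, bins and boundaries", {
  set.seed(59)
  sim <- clean_sim(seed = 59, n_phenotypes = 2, samples_per_phenotype = 10,
                   n_genes = 150, module_size = 23, effect_size = 4,
                   batch_sd = 0.2, noise_sd = 0.3)
  x <- sim$expression
  mod <- sim$truth$modules[["P1"]] # 23 genes -> evaluated against bin 25
  sets <- gene_sets("MOD", list(mod))
  pv <- empirical_pvalues(x, sets, n_permutations = 200, seed = 3)
  expect_identical(unique(pv$bin), 25)
  # strongly planted module: top score in a P1 sample beats all permutations
  best <- pv[pv$sample_id %in% names(sim$truth$phenotype)[sim$truth$phenotype == "P1"], ]
  expect_true(any(best$p_empirical == 0))
  expect_equal(pv$p_pseudo, (pv$p_empirical * 200 + 1) / 201, tolerance = 1e-12)
  expect_true(all(pv$p_adj >= pv$p_empirical))
  expect_error(empirical_pvalues(x, sets, n_permutations = 0), "positive")
  expect_warning(empirical_pvalues(x, sets, n_permutations = 50, seed = 1),
                 "coarse")
})

test_that("nearest-bin resolution breaks ties upward", {
  bins <- default_size_bins()
  expect_identical(refmap:::nearest_bin(23, bins), 25)
  expect_identical(refmap:::nearest_bin(22, bins), 20) # |22-20| < |22-25|
  expect_identical(refmap:::nearest_bin(27.5, bins), 30)
  expect_identical(refmap:::nearest_bin(600, bins), 500)
})

test_that("null-set empirical p-values are uniform", {
  set.seed(60)
  x <- matrix(rnorm(300 * 12, 7, 1), 300, 12,
              dimnames = list(sprintf("g%03d", 1:300), sprintf("s%02d", 1:12)))
  nulls <- gene_sets(sprintf("N%03d", 1:150),
                     purrr::map(1:150, ~ sample(rownames(x), 25)))
  pv <- empirical_pvalues(x, nulls, n_permutations = 300, seed = 7)
  # one sample's worth of p-values, pseudo-count form to avoid mass at 0
  p1 <- pv$p_pseudo[pv$sample_id == "s01"]
  ks <- suppressWarnings(stats::ks.test(p1, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("hypergeometric cluster enrichment matches the combinatorial tail", {
  sig <- matrix(FALSE, 100, 1, dimnames = list(sprintf("s%03d", 1:100), "S"))
  clusters <- rep(1:10, each = 10)
  sig[c(which(clusters == 4)[1:8], which(clusters != 4)[1:12]), 1] <- TRUE
  tab <- cluster_enrichment(sig, clusters)
  row4 <- tab[tab$cluster == 4, ]
  expect_identical(row4$overlap, 8L)
  expect_equal(row4$p_value, oracle_hyper_upper(8, 20, 80, 10), tolerance = 1e-12)

  none <- matrix(FALSE, 20, 1, dimnames = list(paste0("s", 1:20), "S"))
  expect_true(all(cluster_enrichment(none, rep(1:2, each = 10))$p_value == 1))
  all_sig <- matrix(TRUE, 20, 1, dimnames = list(paste0("s", 1:20), "S"))
  expect_true(all(cluster_enrichment(all_sig, rep(1:2, each = 10))$p_value == 1))
})

test_that("matching a map against itself is the identity", {
  sim <- clean_sim(seed = 61, n_phenotypes = 3, samples_per_phenotype = 15,
                   n_genes = 300, module_size = 25, effect_size = 3)
  labels <- as.integer(factor(sim$truth$phenotype))
  sets <- cluster_genesets(sim$expression, labels)
  mm <- match_maps(sets, sim$expression, labels, alpha = 0.001,
                   n_permutations = 200, seed = 5)
  expect_identical(mm$best$best_match, as.integer(mm$best$source_cluster))
})

test_that("score-cluster correlations and the consistency filter apply the rules", {
  small <- tibble::tibble(set = c("A", "A", "B", "B"),
                          cluster = c(1, 2, 1, 2),
                          estimate = c(0.8, -0.5, 0.7, 0.2),
                          p_value = c(0.01, 0.2, 0.06, 0.04),
                          p_adj = c(0.02, 0.3, 0.1, 0.08))
  large <- tibble::tibble(set = c("A", "A", "B", "B"),
                          cluster = c(1, 2, 1, 2),
                          estimate = c(0.9, -0.4, 0.8, -0.3),
                          p_value = c(1e-6, 0.1, 1e-5, 1e-4),
                          p_adj = c(5e-4, 0.2, 2e-4, 5e-4))
  kept <- consistent_enrichment(small, large)
  # A/1: same sign, small p 0.01 < 0.05, large adj 5e-4 < 1e-3 -> kept
  # B/1: small p 0.06 -> excluded; B/2: sign disagreement -> excluded
  expect_identical(nrow(kept), 1L)
  expect_identical(kept$set, "A")
  expect_identical(kept$cluster, 1)

  mismatched <- dplyr::mutate(large, cluster = cluster + 10)
  expect_error(consistent_enrichment(small, mismatched), "cluster ids")

  scores <- matrix(c(2, 2, -1, -1, 0, 0, 1, 1), 4, 2,
                   dimnames = list(paste0("s", 1:4), c("A", "B")))
  tab <- score_cluster_correlation(scores, c(1, 1, 2, 2))
  expect_gt(tab$estimate[tab$set == "A" & tab$cluster == 1], 0.9)
  expect_lt(tab$estimate[tab$set == "A" & tab$cluster == 2], -0.9)
})
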