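# shared map fixture for the remap tests: 5 well-separated phenotypes
remap_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- simulate_collection(
        simulation_design(n_genes = 1000, n_phenotypes = 5,
                          samples_per_phenotype = 50, n_studies = 5,
                          module_size = 30, effect_size = 3,
                          batch_sd = 0.5, noise_sd = 0.5),
        seed = 11)
      hold <- unlist(lapply(split(seq_len(250), sim$truth$phenotype), head, 10))
      map <- build_reference_map(sim$expression[, -hold],
                                 sim$annotations[-hold, ], pct = 15,
                                 perplexity = 30, bandwidth = 2.5, seed = 2,
                                 max_iter = 600)
      cache <<- list(sim = sim, hold = hold, map = map)
    }
    cache
  }
})

test_that("affinity calibration hits the requested perplexity", {
  fx <- remap_fixture()
  map <- fx$map
  v <- fx$sim$expression[map$feature_ids, fx$hold[1]]
  for (perp in c(5, 15, 30)) {
    p <- input_affinities(v, map, perplexity = perp, metric = "euclidean")
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_equal(exp(-sum(p[p > 0] * log(p[p > 0]))), perp, tolerance = 1e-4)
  }
})

test_that("a duplicated reference sample dominates its own affinities", {
  fx <- remap_fixture()
  map <- fx$map
  v <- map$reference_expression[, 7]
  p <- input_affinities(v, map, metric = "euclidean")
  expect_identical(unname(which.max(p)), 7L)
  # positive affine rescaling has correlation distance zero to its source
  p2 <- input_affinities(1.7 * v + 3, map, metric = "correlation")
  expect_identical(unname(which.max(p2)), 7L)
  expect_error(input_affinities(rep(1, length(v)), map, metric = "correlation"),
               "zero-variance")
  expect_error(input_affinities(v[-1], map, metric = "euclidean"), "feature")
})

test_that("duplicates of reference samples return to their source cluster", {
  fx <- remap_fixture()
  map <- fx$map
  dup <- map$reference_expression[, 1:5]
  colnames(dup) <- paste0("dup", 1:5)
  res <- remap_samples(map, dup, metric = "euclidean")
  expect_identical(res$samples$cluster, map$cluster_labels[1:5])
  expect_equal(res$samples$max_r, rep(1, 5), tolerance = 1e-12)
})

test_that("remapping a sample is independent of its batch companions", {
  fx <- remap_fixture()
  map <- fx$map
  newx <- fx$sim$expression[, fx$hold[1:3]]
  colnames(newx) <- c("a", "b", "c")
  r_ab <- remap_samples(map, newx[, c("a", "b")])
  r_ba <- remap_samples(map, newx[, c("b", "a")])
  r_b <- remap_samples(map, newx[, "b", drop = FALSE])
  b1 <- unname(unlist(r_ab$samples[r_ab$samples$sample_id == "b", c("dim1", "dim2")]))
  b2 <- unname(unlist(r_ba$samples[r_ba$samples$sample_id == "b", c("dim1", "dim2")]))
  b3 <- unname(unlist(r_b$samples[1, c("dim1", "dim2")]))
  expect_equal(b1, b2, tolerance = 1e-12)
  expect_equal(b1, b3, tolerance = 1e-12)
})

test_that("remapping never touches the serialized reference map", {
  fx <- remap_fixture()
  map <- fx$map
  dir <- withr::local_tempdir()
  save_reference_map(map, file.path(dir, "m"))
  before <- dir_digest(file.path(dir, "m"))
  loaded <- load_reference_map(file.path(dir, "m"))
  invisible(remap_samples(loaded, fx$sim$expression[, fx$hold[1:5]]))
  save_reference_map(loaded, file.path(dir, "m2"))
  expect_identical(dir_digest(file.path(dir, "m2")), before)
})

test_that("held-out samples recover their planted cluster and annotation", {
  fx <- remap_fixture()
  map <- fx$map
  newx <- fx$sim$expression[, fx$hold]
  res <- remap_samples(map, newx, metric = "euclidean")
  truth_cluster <- majority_map(map$cluster_labels,
                                fx$sim$annotations$phenotype[-fx$hold])
  truth_cluster <- setNames(as.integer(names(truth_cluster))[
    match(fx$sim$annotations$phenotype[fx$hold], truth_cluster)],
    colnames(newx))
  acc <- mean(res$samples$cluster == truth_cluster)
  expect_gte(acc, 0.9)
  ann_acc <- mean(res$samples$annotation == fx$sim$annotations$phenotype[fx$hold])
  expect_gte(ann_acc, 0.9)
})

test_that("feature-coverage and empty-input guards fire", {
  fx <- remap_fixture()
  map <- fx$map
  newx <- fx$sim$expression[, fx$hold[1:2]]
  few <- newx[seq_len(floor(0.5 * length(map$feature_ids))), , drop = FALSE]
  expect_error(remap_samples(map, few), "features")
  expect_error(remap_samples(map, newx[, 0]), "sample")
})

test_that("nearest-centroid assignment matches the exhaustive rule", {
  centroids <- rbind(`1` = c(0, 0), `2` = c(4, 0), `3` = c(0, 4))
  colnames(centroids) <- c("dim1", "dim2")
  model <- list(centroids = centroids)
  expect_identical(assign_clusters(rbind(c(0, 4)), model), 3L)
  # equidistant between clusters 1 and 2 -> lowest id
  expect_identical(assign_clusters(rbind(c(2, 0)), model), 1L)
  set.seed(33)
  pts <- matrix(runif(200, -2, 6), 100, 2)
  got <- assign_clusters(pts, model)
  want <- apply(pts, 1, function(p) {
    which.min(colSums((t(centroids) - p)^2))
  })
  expect_identical(got, as.integer(want))
})

test_that("annotation transfer follows majority voting with documented ties", {
  map <- structure(list(
    feature_ids = c("g1", "g2"),
    embedding = matrix(0, 7, 2, dimnames = list(paste0("s", 1:7), NULL)),
    cluster_labels = c(1L, 1L, 1L, 2L, 2L, 3L, 3L),
    centroids = matrix(0, 3, 2, dimnames = list(c("1", "2", "3"), NULL)),
    annotations = tibble::tibble(
      sample_id = paste0("s", 1:7),
      study_id = "st",
      phenotype = c("A", "A", "B", "A", "B", NA, NA),
      platform = NA_character_),
    reference_expression = matrix(0, 2, 7,
                                  dimnames = list(c("g1", "g2"), paste0("s", 1:7))),
    tsne_params = list(), bandwidth = 1), class = "reference_map")
  out <- transfer_annotation(c(1, 2, 3), map)
  expect_identical(unname(out["1"]), "A")
  expect_identical(unname(out["2"]), "ambiguous")
  expect_identical(unname(out["3"]), "unlabeled")
})

test_that("diagnostic margins equal direct group-mean arithmetic", {
  fx <- remap_fixture()
  map <- fx$map
  newx <- fx$sim$expression[, fx$hold[1:4]]
  assigned <- remap_samples(map, newx)$samples$cluster
  diag <- remap_diagnostics(newx, map, assigned)
  feats <- intersect(map$feature_ids, rownames(newx))
  r <- cor(newx[feats, ], map$reference_expression[feats, ])
  for (i in seq_len(4)) {
    means <- tapply(r[i, ], map$cluster_labels, mean)
    own <- means[as.character(assigned[i])]
    other <- max(means[names(means) != as.character(assigned[i])])
    expect_equal(diag$margin[i], unname(own - other), tolerance = 1e-12)
    expect_equal(diag$max_r[i], max(r[i, ]), tolerance = 1e-12)
  }
})

test_that("cross-platform remapping with correlation distance is concordant", {
  fx <- remap_fixture()
  map <- fx$map
  newx <- fx$sim$expression[, fx$hold]
  plain <- remap_samples(map, newx, metric = "euclidean")
  warped <- remap_samples(map, platform_transform(newx, shift = 1.5,
                                                  scale = 1.2, power = 1.15),
                          metric = "correlation")
  expect_gte(mean(plain$samples$cluster == warped$samples$cluster), 0.85)
})
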