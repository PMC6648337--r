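probe_fixture <- function(seed = 1, n_probes = 200, n_samples = 20,
                          probes_per_gene = 4) {
  set.seed(seed)
  probes <- matrix(rnorm(n_probes * n_samples, 8, 1), n_probes, n_samples,
                   dimnames = list(sprintf("p%03d", seq_len(n_probes)),
                                   sprintf("s%02d", seq_len(n_samples))))
  map <- tibble::tibble(
    probe_id = rownames(probes),
    gene_id = rep(sprintf("g%03d", seq_len(n_probes / probes_per_gene)),
                  each = probes_per_gene))
  list(probes = probes, map = map)
}

test_that("reference quantiles are the across-sample mean sorted vector", {
  fx <- probe_fixture(2, n_probes = 12, n_samples = 2)
  fx$probes[, 2] <- fx$probes[, 1] # identical samples
  model <- build_reference_model(fx$probes, fx$map)
  expect_equal(model$reference_quantiles, sort(fx$probes[, 1]),
               tolerance = 1e-12, ignore_attr = TRUE)
  model2 <- build_reference_model(fx$probes, fx$map)
  expect_identical(model, model2)
})

test_that("probe effects agree with a hand-run median polish", {
  # 4-probe, 3-sample single-gene table, values already quantile-free by
  # construction (each column is a permutation of the same values)
  block <- rbind(c(1, 2, 3), c(2, 3, 1), c(3, 1, 2), c(6, 6, 6)) + 5
  rownames(block) <- paste0("p", 1:4)
  colnames(block) <- paste0("s", 1:3)
  map <- tibble::tibble(probe_id = paste0("p", 1:4), gene_id = "g1")
  model <- build_reference_model(block, map)
  # each column is a permutation of the same values, so quantile
  # normalization to the mean distribution leaves the table unchanged and
  # the model's polish runs on exactly this block
  hand <- stats::medpolish(block, maxiter = 10, eps = 0.01, trace.iter = FALSE)
  expect_equal(unname(model$probe_effects), unname(hand$row + hand$overall),
               tolerance = 1e-12)
  expect_equal(unname(model$overall_effects), unname(hand$overall),
               tolerance = 1e-12)
  expect_error(build_reference_model(block, map[1:3, ]), "missing from")
})

test_that("quantile mapping reproduces the reference distribution exactly", {
  fx <- probe_fixture(3, n_probes = 48, n_samples = 5)
  model <- build_reference_model(fx$probes, fx$map)
  set.seed(9)
  v <- rnorm(48, 9, 2)
  names(v) <- rownames(fx$probes)
  out <- quantile_map_to_reference(v, model)
  expect_equal(sort(unname(out)), unname(model$reference_quantiles),
               tolerance = 1e-12)
  expect_identical(order(out), order(v))
  # idempotence
  expect_equal(quantile_map_to_reference(out, model), out, tolerance = 1e-12)
  # a permutation of the reference quantiles maps to itself
  perm <- sample(model$reference_quantiles)
  names(perm) <- rownames(fx$probes)
  expect_equal(quantile_map_to_reference(perm, model), perm,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(quantile_map_to_reference(v[-1], model), "probes")
})

test_that("tied input values share the mean of their reference quantiles", {
  ref <- c(1, 2, 4, 8, 16)
  x <- c(a = 5, b = 3, c = 3, d = 9, e = 1)
  out <- refmap:::map_to_quantiles(x, ref)
  # ranks: e=1 -> 1; b,c tie over ranks 2,3 -> mean(2,4)=3; a -> 8; d -> 16
  expect_equal(unname(out[c("e", "b", "c", "a", "d")]), c(1, 3, 3, 8, 16))
})

test_that("fixed-effect summarization follows the frozen formula", {
  fx <- probe_fixture(4, n_probes = 20, n_samples = 6, probes_per_gene = 4)
  model <- build_reference_model(fx$probes, fx$map)
  # probe values exactly probe_effects + c -> expression overall + c per gene
  v <- model$probe_effects + 1.5
  expr <- summarize_with_fixed_effects(v, model)
  expect_equal(unname(expr), unname(model$overall_effects + 1.5),
               tolerance = 1e-12)
  # single-probe gene: expression = overall + (value - effect)
  one <- matrix(rnorm(6, 8, 1), 1, 6,
                dimnames = list("pX", paste0("s", 1:6)))
  two <- rbind(one, one + 0.3)
  rownames(two) <- c("pX", "pY")
  m1 <- build_reference_model(two, tibble::tibble(probe_id = c("pX", "pY"),
                                                  gene_id = c("gA", "gB")))
  vv <- c(pX = 7, pY = 9)
  ex <- summarize_with_fixed_effects(vv, m1)
  expect_equal(unname(ex["gA"]),
               unname(m1$overall_effects["gA"] + (7 - m1$probe_effects["pX"])),
               tolerance = 1e-12)
})

test_that("one-at-a-time normalization reproduces the joint pipeline", {
  fx <- probe_fixture(5)
  model <- build_reference_model(fx$probes, fx$map)
  joint <- joint_normalize(fx$probes, fx$map)
  solo <- refnorm_apply(fx$probes, model)
  expect_lt(max(abs(solo - joint)), 0.01)
})

test_that("normalizing new samples never mutates the stored model", {
  fx <- probe_fixture(6, n_probes = 40, n_samples = 5)
  model <- build_reference_model(fx$probes, fx$map)
  snapshot <- unserialize(serialize(model, NULL))
  set.seed(10)
  newp <- matrix(rnorm(40, 8, 1.5), 40, 1,
                 dimnames = list(rownames(fx$probes), "new"))
  invisible(refnorm_apply(newp, model))
  expect_identical(model, snapshot)
})
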