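# Shared fixture builders. Everything is generated in code at test time.

tiny_expr <- function(genes = 6, samples = 4, seed = 1) {
  set.seed(seed)
  matrix(rnorm(genes * samples, 7, 1), genes, samples,
         dimnames = list(sprintf("g%02d", seq_len(genes)),
                         sprintf("s%02d", seq_len(samples))))
}

# small clean collection with well-separated phenotypes, used where a test
# needs a recoverable structure rather than the full default study conditions
clean_sim <- function(seed = 1, n_phenotypes = 3, samples_per_phenotype = 20,
                      n_genes = 400, module_size = 25, effect_size = 3,
                      batch_sd = 0.3, noise_sd = 0.4, n_studies = 4) {
  simulate_collection(
    simulation_design(n_genes = n_genes, n_phenotypes = n_phenotypes,
                      samples_per_phenotype = samples_per_phenotype,
                      n_studies = n_studies, module_size = module_size,
                      effect_size = effect_size, batch_sd = batch_sd,
                      noise_sd = noise_sd),
    seed = seed)
}

# majority phenotype per cluster over a set of reference labels
majority_map <- function(cluster_labels, phenotypes) {
  vapply(split(phenotypes, cluster_labels),
         function(v) names(sort(table(v), decreasing = TRUE))[1L],
         character(1L))
}
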