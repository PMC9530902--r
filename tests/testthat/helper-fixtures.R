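# shared fixtures: small rate tables built in code

runif_seeded <- function(n, min, max, seed) {
  withr::with_seed(seed, stats::runif(n, min, max))
}

# exact noiseless rate table: every (strain, medium) lies on its medium's
# trade-off line, growth rates spread over the medium range
noiseless_rate_table <- function(n_strains = 10, seed = 42) {
  panel <- make_strain_panel(c(MDS = n_strains %/% 2,
                               KHK = n_strains - n_strains %/% 2),
                             seed = seed)
  tr <- sample_true_rates(panel, medium_specs(), sigma_log10 = 0,
                          seed = seed, mu_jitter_sd = 0)
  truth_as_rate_table(tr)
}

# treat true rates as perfectly measured: the estimation layer is bypassed
truth_as_rate_table <- function(true_rates) {
  tab <- true_rates
  tab$growth_rate <- tab$mu_true
  tab$mutation_rate <- tab$m_true
  tab$growth_se <- tab$mutation_se <- 0
  tab$n_replicates <- 1L
  tab
}

# rate table with prescribed per-strain rates, one row per strain x medium
manual_rate_table <- function(strains, media, growth, mutation,
                              collection = "MG", gr = 0L, md = 0L) {
  grid <- expand.grid(strain_id = strains, medium = media,
                      stringsAsFactors = FALSE)
  grid$collection <- collection
  grid$genome_reduced <- gr
  grid$mmr_deficient <- md
  grid$genotype_class <- genotype_class(grid$genome_reduced,
                                        grid$mmr_deficient)
  grid$growth_rate <- growth
  grid$mutation_rate <- mutation
  grid$growth_se <- grid$mutation_se <- 0
  grid$n_replicates <- 1L
  grid
}
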