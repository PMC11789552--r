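# Shared fixture builders. Everything is generated in code at test time.

# Small NB count matrix with named dims, optionally with a planted two-group
# fold change for the first `n_de` genes (groups A/B of size n_per).
small_counts <- function(n_genes = 60, n_per = 6, lfc = 0, n_de = 0,
                         mu = 100, alpha = 0.1, seed = 1) {
  withr::local_seed(seed)
  m <- 2 * n_per
  mult <- matrix(1, n_genes, m)
  if (n_de > 0) mult[seq_len(n_de), seq_len(n_per)] <- 2^lfc
  counts <- matrix(rnbinom(n_genes * m, mu = mu * mult, size = 1 / alpha),
                   n_genes, m,
                   dimnames = list(sprintf("g%03d", 1:n_genes),
                                   sprintf("s%02d", 1:m)))
  list(counts = counts,
       condition = factor(rep(c("A", "B"), each = n_per)))
}

# Cached medium-size network fixture shared by the coexpression tests:
# 1500 genes, four planted modules on a null background.
.fixture_env <- new.env(parent = emptyenv())
network_fixture <- function() {
  if (is.null(.fixture_env$net)) {
    genes <- simulate_genome(genome_spec(n_genes = 1500), 5)
    sim <- simulate_counts(
      design_spec(), effect_class_spec(0, 0, 0, 0, 0),
      module_plant_spec(4, c(40, 60),
                        c("host_race", "stress", "ch_plastic", "none")),
      genes, 6)
    norm <- moderated_log(filter_genes(sim$counts))
    st <- suppressWarnings(pick_soft_threshold(t(norm)))
    ms <- suppressWarnings(coexpression_modules(norm))
    .fixture_env$net <- list(sim = sim, norm = norm, st = st, ms = ms)
  }
  .fixture_env$net
}

# Full small synthetic experiment through the generator.
small_experiment <- function(n_genes = 400, seed = 3,
                             effects = effect_class_spec(),
                             modules = module_plant_spec(0)) {
  genes <- simulate_genome(genome_spec(n_genes = n_genes), seed)
  sim <- simulate_counts(design_spec(), effects, modules, genes, seed + 1)
  c(sim, list(genes = genes))
}
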