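# Shared fixtures, built once per test session and memoised.

.kv_cache <- new.env(parent = emptyenv())

kv_memo <- function(key, expr) {
  if (!exists(key, envir = .kv_cache))
    assign(key, force(expr), envir = .kv_cache)
  get(key, envir = .kv_cache)
}

# the main recovery study: 50 genes, kappa ~ U[1,15], 500 cells
kv_study <- function(noise = 0) {
  key <- paste0("study_", noise)
  kv_memo(key, kappa_recovery_experiment(
    n_genes = 50, n_cells = 500, noise_sd = noise, rng_seed = 11L))
}

# small simulation shared by cheaper tests: 20 genes, 300 cells
kv_small_sim <- function(noise = 0) {
  key <- paste0("small_", noise)
  kv_memo(key, {
    rates <- sample_gene_rates(20, shared_base = TRUE, rng_seed = 7L)
    simulate_cells(rates, n_cells = 300, noise_sd = noise, rng_seed = 7L)
  })
}

# one well-behaved mid-speed gene of the small noiseless simulation,
# fitted; used by fit/scale unit tests
kv_one_fit <- function() {
  kv_memo("one_fit", {
    sim <- kv_small_sim(0)
    g <- 5L
    list(g = g, sim = sim,
         fit = fit_gene_em(sim$data$U[, g], sim$data$S[, g]))
  })
}
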