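# Shared fixtures, computed lazily and cached for the whole test run.
.fixture_env <- new.env(parent = emptyenv())

memo_fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_env))
    assign(name, force(expr), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# High signal-to-noise study-shaped dataset: 3 planted modules of 25 taxa
# among 300 ASVs, strong co-occurrence (loading 2.5), no ultra-rare taxa
# (the network runs on filter-passing taxa, as in the pipeline), GAD-7-like
# trait correlated with module 1 at -0.4.
high_snr_config <- function(n_samples = 200, seed = 11, trait_effect = -0.4)
  sim_config(n_samples = n_samples, n_asvs = 300, n_modules = 3,
             taxa_per_module = 25, module_factor_sd = 2.5,
             rare_fraction = 0, trait_effect = trait_effect, seed = seed)

# Pipeline-ordered preparation: ASV retention filter -> CLR over the full
# closure -> covariate correction, then the network on the kept taxa.
prepare_network_input <- function(ds) {
  kept <- retain_asvs(ds$counts)
  clr <- clr_transform(ds$counts)[, kept]
  x <- residuals(suppressWarnings(eb_correct(clr, ds$metadata)))
  list(x = x, kept = kept, truth = ds$truth$module[kept])
}

planted_fixture <- function() memo_fixture("planted", {
  ds <- simulate_dataset(high_snr_config())
  prep <- prepare_network_input(ds)
  fit <- wcna(prep$x, beta = 3, min_module_size = 25)
  c(list(ds = ds, fit = fit), prep)
})

# Hand-rolled adjusted Rand index (independent of any clustering package).
rand_index_adj <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  exp_idx <- si * sj / n2
  (sij - exp_idx) / ((si + sj) / 2 - exp_idx)
}

# Toy count matrix with exact per-taxon prevalence/MRA control: taxon j is
# present in k_j of n samples at count c_j; a filler column tops every sample
# up to the common depth.
toy_counts <- function(present, count, depth = 10000, n = 10) {
  p <- length(present)
  m <- matrix(0L, n, p)
  for (j in seq_len(p)) if (present[j] > 0) m[seq_len(present[j]), j] <- count[j]
  filler <- depth - rowSums(m)
  stopifnot(all(filler >= 0))
  out <- cbind(m, filler)
  storage.mode(out) <- "integer"
  dimnames(out) <- list(sprintf("S%02d", seq_len(n)),
                        c(sprintf("t%02d", seq_len(p)), "filler"))
  out
}
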