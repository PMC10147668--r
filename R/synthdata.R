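#' Configuration for the synthetic 16S dataset generator
#'
#' Bundles and validates the parameters of \code{\link{simulate_dataset}}.
#' Defaults emulate the kind of cohort the package targets: 178 stool samples,
#' a few thousand amplicon sequence variants (ASVs), three planted
#' co-occurrence modules of 25 taxa whose first module's latent factor is
#' negatively correlated with an anxiety-like trait, log-normal sequencing
#' depth, Dirichlet-multinomial count noise, and age/BMI confounding on a
#' subset of taxa.
#'
#' @param n_samples number of samples (participants).
#' @param n_asvs number of ASVs.
#' @param n_modules number of planted co-occurrence modules.
#' @param taxa_per_module taxa in each planted module.
#' @param module_factor_sd latent co-occurrence strength on the log scale.
#'   The default 2 gives a median within-module CLR correlation above 0.4.
#' @param trait_effect target Pearson correlation between the first module's
#'   latent factor and the anxiety-like trait (GAD-7); in [-1, 1].
#' @param covariate_effects named list of length-2 numeric ranges: per-taxon
#'   log-scale slope range for each covariate (on the standardized covariate).
#' @param covariate_taxa_fraction fraction of taxa receiving covariate slopes.
#' @param depth_log_mean,depth_log_sd log-normal sequencing-depth parameters.
#' @param dispersion Dirichlet concentration scale; smaller values give more
#'   overdispersed counts.
#' @param rare_fraction fraction of background ASVs made sparse (baseline log
#'   abundance shifted down). Planted-module taxa are kept at moderate
#'   abundance: the retain-resolve filter would keep only such taxa anyway.
#' @param taxon_noise_sd log-scale noise scale; per-taxon noise SDs are drawn
#'   uniformly from 0.8 to 1.6 times this value (taxa differ in dispersion).
#' @param na_genus_fraction fraction of ASVs with a missing genus annotation.
#' @param n_missing_age,n_missing_dars samples with missing age / DARS score.
#' @param seed integer RNG seed.
#' @return A validated list of class \code{"sim_config"}.
#' @export
sim_config <- function(n_samples = 178, n_asvs = 2000, n_modules = 3,
                       taxa_per_module = 25, module_factor_sd = 2,
                       trait_effect = -0.4,
                       covariate_effects = list(age = c(-0.3, 0.3),
                                                bmi = c(-0.3, 0.3)),
                       covariate_taxa_fraction = 0.2,
                       depth_log_mean = log(30000), depth_log_sd = 0.35,
                       dispersion = 150, rare_fraction = 0.5,
                       taxon_noise_sd = 1, na_genus_fraction = 0.1,
                       n_missing_age = 2, n_missing_dars = 8, seed = 1) {
  cfg <- list(n_samples = n_samples, n_asvs = n_asvs, n_modules = n_modules,
              taxa_per_module = taxa_per_module,
              module_factor_sd = module_factor_sd, trait_effect = trait_effect,
              covariate_effects = covariate_effects,
              covariate_taxa_fraction = covariate_taxa_fraction,
              depth_log_mean = depth_log_mean, depth_log_sd = depth_log_sd,
              dispersion = dispersion, rare_fraction = rare_fraction,
              taxon_noise_sd = taxon_noise_sd,
              na_genus_fraction = na_genus_fraction,
              n_missing_age = n_missing_age, n_missing_dars = n_missing_dars,
              seed = seed)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  .assert(cfg$n_samples >= 2, "invalid config: n_samples must be >= 2")
  .assert(cfg$n_asvs >= 1, "invalid config: n_asvs must be >= 1")
  .assert(cfg$n_modules >= 0 && cfg$taxa_per_module >= 1,
          "invalid config: module counts must be non-negative")
  .assert(cfg$n_modules * cfg$taxa_per_module <= cfg$n_asvs,
          "invalid config: n_modules * taxa_per_module must be <= n_asvs")
  .assert(abs(cfg$trait_effect) <= 1, "invalid config: |trait_effect| must be <= 1")
  .assert(cfg$module_factor_sd >= 0, "invalid config: module_factor_sd must be >= 0")
  .assert(cfg$dispersion > 0, "invalid config: dispersion must be > 0")
  .assert(cfg$depth_log_sd >= 0, "invalid config: depth_log_sd must be >= 0")
  .assert(cfg$rare_fraction >= 0 && cfg$rare_fraction <= 1,
          "invalid config: rare_fraction must be in [0, 1]")
  .assert(is.list(cfg$covariate_effects) &&
            (length(cfg$covariate_effects) == 0 ||
               !is.null(names(cfg$covariate_effects))),
          "invalid config: covariate_effects must be a named list of ranges")
  for (rng in cfg$covariate_effects)
    .assert(is.numeric(rng) && length(rng) == 2 && rng[1] <= rng[2],
            "invalid config: each covariate effect must be a length-2 range")
  invisible(cfg)
}

#' Generate a synthetic taxonomy table
#'
#' Fabricates a consistent Kingdom-to-Genus lineage for \code{n_asvs} ASVs.
#' Genera are nested within families, families within orders and so on; every
#' genus is used at least once, so \code{n_genera} distinct genus labels occur
#' among annotated ASVs. A fraction of ASVs has a missing (NA) genus, to
#' exercise family-level "_NA" naming during agglomeration. The missing-genus
#' mask is the first draw taken from the seed.
#'
#' @param n_asvs number of ASVs; ids are \code{sp1 ... spN}.
#' @param n_genera number of distinct genera (must be <= n_asvs).
#' @param na_genus_fraction probability that an ASV lacks a genus annotation.
#' @param seed integer RNG seed.
#' @return data.frame with columns taxon_id, Kingdom, Phylum, Class, Order,
#'   Family, Genus.
#' @export
generate_taxonomy <- function(n_asvs, n_genera, na_genus_fraction = 0,
                              seed = 1) {
  .assert(n_genera <= n_asvs, "n_genera must be <= n_asvs")
  .assert(n_genera >= 1, "n_genera must be >= 1")
  with_seed(seed, {
    missing_genus <- stats::runif(n_asvs) < na_genus_fraction
    # every genus used at least once, remainder sampled uniformly
    genus_idx <- c(seq_len(n_genera),
                   if (n_asvs > n_genera)
                     sample.int(n_genera, n_asvs - n_genera, replace = TRUE))
    genus_idx <- genus_idx[sample.int(n_asvs)]
    n_fam <- max(1L, ceiling(n_genera / 3))
    n_ord <- max(1L, ceiling(n_fam / 3))
    n_cls <- max(1L, ceiling(n_ord / 2))
    n_phy <- min(5L, n_cls)
    fam_of_gen <- ((seq_len(n_genera) - 1L) %% n_fam) + 1L
    ord_of_fam <- ((seq_len(n_fam) - 1L) %% n_ord) + 1L
    cls_of_ord <- ((seq_len(n_ord) - 1L) %% n_cls) + 1L
    phy_of_cls <- ((seq_len(n_cls) - 1L) %% n_phy) + 1L
    fam <- fam_of_gen[genus_idx]
    ord <- ord_of_fam[fam]
    cls <- cls_of_ord[ord]
    phy <- phy_of_cls[cls]
    out <- data.frame(
      taxon_id = paste0("sp", seq_len(n_asvs)),
      Kingdom = "Bacteria",
      Phylum = sprintf("Phylum%02d", phy),
      Class = sprintf("Class%02d", cls),
      Order = sprintf("Order%02d", ord),
      Family = sprintf("Family%03d", fam),
      Genus = sprintf("Genus%03d", genus_idx),
      stringsAsFactors = FALSE
    )
    out$Genus[missing_genus] <- NA_character_
    out
  })
}

#' Simulate a synthetic 16S dataset with planted co-occurrence modules
#'
#' Latent log abundances are baseline + module-factor loading + covariate
#' effects + noise; per-sample relative abundances are the softmax of the log
#' abundances (they sum to one before counts are drawn); counts are
#' Dirichlet-multinomial at a log-normally drawn depth. One designated module
#' (the first) has its latent factor correlated with the generated GAD-7-like
#' trait at approximately \code{trait_effect}; PHQ-9 tracks GAD-7 and DARS is
#' reverse-scored. Age and BMI act on a random subset of taxa so the
#' covariate-correction stage has real work to do.
#'
#' @param config a \code{\link{sim_config}} object (or compatible list).
#' @return An object of class \code{"synthetic_dataset"}: list with
#'   \code{counts} (samples x taxa integer matrix), \code{taxonomy},
#'   \code{metadata} (age, bmi, gad7, phq9, dars), and \code{truth}
#'   (per-taxon planted module, per-sample latent factors, loadings).
#' @export
simulate_dataset <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  validate_sim_config(config)
  n <- config$n_samples; p <- config$n_asvs; m <- config$n_modules
  tpm <- config$taxa_per_module
  taxonomy <- generate_taxonomy(p, n_genera = max(1L, round(p / 6)),
                                na_genus_fraction = config$na_genus_fraction,
                                seed = config$seed + 1L)
  with_seed(config$seed, {
    sample_ids <- sprintf("S%03d", seq_len(n))
    taxon_ids <- paste0("sp", seq_len(p))

    age <- pmin(pmax(round(stats::rnorm(n, 42, 12)), 18), 80)
    bmi <- pmin(pmax(round(stats::rnorm(n, 28, 5), 1), 16), 50)

    # planted module membership: 0 = background
    module <- integer(p)
    if (m > 0) {
      planted <- sample.int(p, m * tpm)
      module[planted] <- rep(seq_len(m), each = tpm)
    }

    # planted-module taxa sit at moderate abundance (a co-occurrence signal
    # carried by taxa the prevalence/abundance filters would drop could not
    # have been observed in the first place)
    baseline <- stats::rnorm(p, 0, 1.5)
    baseline[module > 0] <- stats::rnorm(sum(module > 0), 2, 0.5)
    bg <- which(module == 0)
    n_rare <- round(config$rare_fraction * length(bg))
    if (n_rare > 0) {
      rare <- sample(bg, n_rare)
      baseline[rare] <- baseline[rare] - 4
    }

    loading <- numeric(p)
    loading[module > 0] <- config$module_factor_sd *
      stats::runif(sum(module > 0), 0.85, 1.15)
    factors <- matrix(stats::rnorm(n * max(m, 1)), n, max(m, 1))

    X <- matrix(rep(baseline, each = n), n, p)
    if (m > 0)
      for (k in seq_len(m)) {
        idx <- which(module == k)
        X[, idx] <- X[, idx] + outer(factors[, k], loading[idx])
      }

    covs <- list(age = as.numeric(scale(age)), bmi = as.numeric(scale(bmi)))
    cov_slopes <- list()
    for (nm in names(config$covariate_effects)) {
      slopes <- numeric(p)
      hit <- stats::runif(p) < config$covariate_taxa_fraction
      rng <- config$covariate_effects[[nm]]
      slopes[hit] <- stats::runif(sum(hit), rng[1], rng[2])
      cov_slopes[[nm]] <- stats::setNames(slopes, taxon_ids)
      if (nm %in% names(covs))
        X <- X + outer(covs[[nm]], slopes)
    }

    # heterogeneous per-taxon dispersion, as in real surveys
    noise_sd <- config$taxon_noise_sd * stats::runif(p, 0.8, 1.6)
    X <- X + matrix(stats::rnorm(n * p), n, p) %*% diag(noise_sd)

    # compositional closure: relative abundances sum to 1 per sample
    prop <- exp(X - apply(X, 1, max))
    prop <- prop / rowSums(prop)

    depth <- pmax(round(stats::rlnorm(n, config$depth_log_mean,
                                      config$depth_log_sd)), 1000L)
    counts <- matrix(0L, n, p, dimnames = list(sample_ids, taxon_ids))
    for (s in seq_len(n)) {
      alpha <- config$dispersion * prop[s, ]
      g <- stats::rgamma(p, shape = alpha, rate = 1)
      if (all(g == 0)) g[which.max(alpha)] <- 1
      counts[s, ] <- as.integer(stats::rmultinom(1, depth[s], g / sum(g)))
    }

    te <- config$trait_effect
    f1 <- if (m > 0) as.numeric(scale(factors[, 1])) else stats::rnorm(n)
    z <- te * f1 + sqrt(max(0, 1 - te^2)) * stats::rnorm(n)
    gad7 <- pmin(pmax(round(9 + 4.5 * z), 0), 21)
    z2 <- 0.65 * z + sqrt(1 - 0.65^2) * stats::rnorm(n)
    phq9 <- pmin(pmax(round(11 + 5 * z2), 0), 27)
    z3 <- -0.6 * z + sqrt(1 - 0.6^2) * stats::rnorm(n)
    dars <- pmin(pmax(round(40 + 9 * z3), 0), 68)

    metadata <- data.frame(age = age, bmi = bmi, gad7 = gad7, phq9 = phq9,
                           dars = dars, row.names = sample_ids)
    if (config$n_missing_age > 0)
      metadata$age[sample.int(n, min(config$n_missing_age, n))] <- NA
    if (config$n_missing_dars > 0)
      metadata$dars[sample.int(n, min(config$n_missing_dars, n))] <- NA

    truth <- list(
      module = stats::setNames(ifelse(module == 0, "background",
                                      paste0("module", module)), taxon_ids),
      factors = structure(factors, dimnames = list(sample_ids,
                                                   paste0("module", seq_len(max(m, 1))))),
      loading = stats::setNames(loading, taxon_ids),
      trait_factor = f1,
      covariate_slopes = cov_slopes
    )
    structure(list(counts = counts, taxonomy = taxonomy, metadata = metadata,
                   truth = truth, config = config),
              class = "synthetic_dataset")
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic 16S dataset:", nrow(x$counts), "samples x", ncol(x$counts),
      "ASVs\n")
  tab <- table(x$truth$module)
  cat("Planted modules:",
      paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  cat("Median depth:", stats::median(rowSums(x$counts)), "reads\n")
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Writes the count table (TSV), taxonomy (TSV), metadata (CSV) in the formats
#' the readers accept, plus a truth TSV mapping each taxon to its planted
#' module.
#'
#' @param dataset a \code{synthetic_dataset}.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             taxonomy = file.path(dir, "taxonomy.tsv"),
             metadata = file.path(dir, "metadata.csv"),
             truth = file.path(dir, "truth.tsv"))
  write_count_table(dataset$counts, paths["counts"])
  write_taxonomy(dataset$taxonomy, paths["taxonomy"])
  write_metadata(dataset$metadata, paths["metadata"])
  utils::write.table(
    data.frame(taxon_id = names(dataset$truth$module),
               module = unname(dataset$truth$module)),
    paths["truth"], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
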