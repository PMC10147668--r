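#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis with the defaults used
#' throughout the package. Input tables may be given as file paths here, or
#' passed as in-memory objects to \code{\link{run_pipeline}}.
#'
#' @param counts,taxonomy,metadata optional input file paths (TSV counts, TSV
#'   taxonomy, CSV metadata).
#' @param out_dir output directory.
#' @param depth_min,shannon_min,qc_rule sample quality-control settings.
#' @param criteria a \code{\link{filter_criteria}} object.
#' @param pseudocount CLR pseudocount.
#' @param covariates covariates removed before networking; set
#'   \code{correct_covariates = FALSE} for the uncorrected variant.
#' @param correct_covariates logical.
#' @param beta fixed soft-threshold power (NULL to select).
#' @param candidate_betas,r2_target soft-threshold selection settings.
#' @param network_sign "unsigned" or "signed".
#' @param min_module_sizes vector of minimum module sizes; a network is fitted
#'   for each (conventionally 10, 15, 25) and the first is used for the
#'   downstream association stages.
#' @param cut_height,merge_cut_height module detection settings.
#' @param traits trait columns analysed.
#' @param n_boot bootstrap replicates for module stability.
#' @param n_mc_instances Dirichlet Monte-Carlo instances.
#' @param n_trees random-forest trees.
#' @param top_k random-forest consensus rank cutoff.
#' @param edge_thresholds hard correlation thresholds for network export.
#' @param hub_percentile hub designation percentile.
#' @param seed integer seed governing every stochastic stage.
#' @return list of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(counts = NULL, taxonomy = NULL, metadata = NULL,
                            out_dir = "miconet_out",
                            depth_min = 10000, shannon_min = 2.5,
                            qc_rule = "and",
                            criteria = filter_criteria(),
                            pseudocount = 0.5,
                            covariates = c("age", "bmi"),
                            correct_covariates = TRUE,
                            beta = NULL, candidate_betas = 1:10,
                            r2_target = 0.8, network_sign = "unsigned",
                            min_module_sizes = 25, cut_height = 0.97,
                            merge_cut_height = 0.25,
                            traits = c("gad7", "phq9", "dars"),
                            n_boot = 1000, n_mc_instances = 128,
                            n_trees = 1000, top_k = 20,
                            edge_thresholds = c(0.35, 0.2),
                            hub_percentile = 0.95, seed = 1) {
  structure(list(counts = counts, taxonomy = taxonomy, metadata = metadata,
                 out_dir = out_dir, depth_min = depth_min,
                 shannon_min = shannon_min, qc_rule = qc_rule,
                 criteria = criteria, pseudocount = pseudocount,
                 covariates = covariates,
                 correct_covariates = correct_covariates, beta = beta,
                 candidate_betas = candidate_betas, r2_target = r2_target,
                 network_sign = network_sign,
                 min_module_sizes = min_module_sizes, cut_height = cut_height,
                 merge_cut_height = merge_cut_height, traits = traits,
                 n_boot = n_boot, n_mc_instances = n_mc_instances,
                 n_trees = n_trees, top_k = top_k,
                 edge_thresholds = edge_thresholds,
                 hub_percentile = hub_percentile, seed = seed),
            class = "pipeline_config")
}

#' Export a module as a hard-thresholded edge list
#'
#' Edges are taxon pairs within the module whose Pearson correlation strictly
#' exceeds the threshold, weighted by r; nodes not touched by any edge are
#' dropped. Node attributes carry own-module membership, hub flag and (when a
#' taxonomy is supplied) taxonomic order, ready for import into external
#' network viewers.
#'
#' @param x samples x taxa matrix the network was built from.
#' @param labels per-taxon module labels.
#' @param module module name to export.
#' @param r_threshold hard correlation threshold (strict >; default 0.35).
#' @param membership optional taxa x modules membership matrix.
#' @param hub optional named logical hub vector.
#' @param tax_order optional named character vector of taxonomic orders.
#' @return list with \code{edges} (from, to, weight) and \code{nodes}
#'   (taxon, module_membership, hub, tax_order).
#' @export
export_edge_list <- function(x, labels, module, r_threshold = 0.35,
                             membership = NULL, hub = NULL, tax_order = NULL) {
  x <- .check_matrix(x)
  taxa <- names(labels)[labels == module]
  .assert(length(taxa) > 0, sprintf("module '%s' is empty", module))
  if (r_threshold >= 1)
    warning("threshold >= 1 yields an empty edge set", call. = FALSE)
  R <- stats::cor(x[, taxa, drop = FALSE])
  idx <- which(upper.tri(R) & R > r_threshold, arr.ind = TRUE)
  edges <- data.frame(from = taxa[idx[, 1]], to = taxa[idx[, 2]],
                      weight = R[idx], stringsAsFactors = FALSE)
  connected <- unique(c(edges$from, edges$to))
  k <- length(connected)
  nodes <- data.frame(
    taxon = connected,
    module_membership = if (!is.null(membership))
      unname(own_membership(membership, labels)[connected])
    else rep(NA_real_, k),
    hub = if (!is.null(hub)) unname(hub[connected]) else rep(NA, k),
    tax_order = if (!is.null(tax_order)) unname(tax_order[connected])
    else rep(NA_character_, k),
    stringsAsFactors = FALSE)
  list(edges = edges, nodes = nodes)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

.stage <- function(name, expr) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
  message(sprintf("[%s] done in %.1fs", name,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  res
}

#' Run the full co-occurrence analysis pipeline
#'
#' QC -> retain-resolve agglomeration -> CLR -> covariate correction ->
#' network fits over the minimum-module-size grid -> module statistics ->
#' bootstrap stability -> Dirichlet Monte-Carlo GLM + random forest ->
#' consensus tables -> edge-list exports, writing every result table (TSV)
#' and a JSON manifest (parameters, seeds, per-stage record counts) into
#' \code{config$out_dir}. Rerunning from the manifest reproduces every output
#' byte-for-byte.
#'
#' @param config a \code{\link{pipeline_config}} (or the \code{config} entry
#'   of a written manifest). Input paths in the config are read unless
#'   in-memory objects are supplied.
#' @param counts,taxonomy,metadata optional in-memory inputs overriding the
#'   config paths.
#' @return Invisibly, a list with every intermediate object and
#'   \code{out_dir}.
#' @export
run_pipeline <- function(config, counts = NULL, taxonomy = NULL,
                         metadata = NULL) {
  if (is.character(config) && file.exists(config))
    config <- manifest_config(config)
  if (!inherits(config, "pipeline_config"))
    config <- do.call(pipeline_config, config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)

  counts <- counts %||% .stage("read", read_count_table(config$counts))
  taxonomy <- taxonomy %||% read_taxonomy(config$taxonomy)
  metadata <- metadata %||% read_metadata(config$metadata)
  rec <- reconcile_samples(counts, metadata)
  counts <- rec$counts; metadata <- rec$metadata

  qc <- .stage("qc", qc_filter_samples(counts, config$depth_min,
                                       config$shannon_min, config$qc_rule))
  files["qc_report"] <- .write_tsv(qc$report,
                                   file.path(config$out_dir, "qc_report.tsv"))
  counts <- qc$table
  metadata <- metadata[rownames(counts), , drop = FALSE]

  rr <- .stage("agglomerate",
               retain_resolve(counts, taxonomy, config$criteria))
  files["filter_report"] <- .write_tsv(
    rr$report, file.path(config$out_dir, "filter_report.tsv"))
  files["taxa_table"] <- write_count_table(
    rr$counts, file.path(config$out_dir, "retain_resolved_counts.tsv"))
  prov <- data.frame(
    genus = rep(names(rr$provenance), lengths(rr$provenance)),
    asv = unlist(rr$provenance, use.names = FALSE))
  files["provenance"] <- .write_tsv(
    prov, file.path(config$out_dir, "genus_provenance.tsv"))

  clr <- .stage("clr", clr_transform(rr, config$pseudocount))
  if (config$correct_covariates) {
    eb <- .stage("covariate_correction",
                 eb_correct(clr, metadata, config$covariates))
    x <- residuals(eb)
    slopes <- data.frame(taxon = rownames(eb$coef_raw), eb$coef_raw,
                         check.names = FALSE)
    names(slopes)[-1] <- paste0(config$covariates, "_raw")
    slopes <- cbind(slopes, stats::setNames(
      as.data.frame(eb$coef_shrunk), paste0(config$covariates, "_shrunk")))
    files["slopes"] <- .write_tsv(
      slopes, file.path(config$out_dir, "covariate_slopes.tsv"))
  } else {
    eb <- NULL
    x <- clr
    attr(x, "other_clr") <- NULL
    attr(x, "other_in_closure") <- NULL
    attr(x, "pseudocount") <- NULL
  }
  files["clr"] <- .write_tsv(
    data.frame(sample_id = rownames(x), x, check.names = FALSE),
    file.path(config$out_dir, "clr_corrected.tsv"))

  fits <- list(); stabs <- list()
  for (ms in config$min_module_sizes) {
    fit <- .stage(sprintf("network_min%d", ms),
                  wcna(x, beta = config$beta,
                       candidate_betas = config$candidate_betas,
                       r2_target = config$r2_target,
                       network_sign = config$network_sign,
                       min_module_size = ms, cut_height = config$cut_height,
                       merge_cut_height = config$merge_cut_height))
    key <- as.character(ms)
    fits[[key]] <- fit
    files[paste0("modules_", ms)] <- .write_tsv(
      data.frame(taxon = names(fit$modules), module = unname(fit$modules)),
      file.path(config$out_dir, sprintf("modules_min%d.tsv", ms)))
    st <- .stage(sprintf("stability_min%d", ms),
                 module_stability(fit, n_boot = config$n_boot,
                                  seed = config$seed))
    stabs[[key]] <- st
    files[paste0("stability_", ms)] <- .write_tsv(
      as.data.frame(st), file.path(config$out_dir,
                                   sprintf("stability_min%d.tsv", ms)))
  }

  main_key <- as.character(config$min_module_sizes[1])
  fit <- fits[[main_key]]; stab <- stabs[[main_key]]
  traits <- metadata[, intersect(config$traits, names(metadata)),
                     drop = FALSE]
  stats_out <- .stage("module_stats",
                      module_statistics(fit, traits, config$hub_percentile))
  mt <- stats_out$module_trait
  files["module_trait"] <- .write_tsv(
    data.frame(module = rownames(mt$r),
               do.call(cbind, lapply(names(traits), function(tr)
                 stats::setNames(data.frame(mt$r[, tr], mt$p[, tr], mt$n[, tr]),
                                 paste0(tr, c("_r", "_p", "_n"))))),
      check.names = FALSE),
    file.path(config$out_dir, "module_trait.tsv"))
  files["taxa_stats"] <- .write_tsv(
    stats_out$taxa, file.path(config$out_dir, "taxa_statistics.tsv"))

  analysis_cols <- colnames(x)
  instances <- .stage("dirichlet_instances",
                      dirichlet_instances(rr$counts, config$n_mc_instances,
                                          seed = config$seed,
                                          pseudocount = config$pseudocount))
  consensus <- list()
  for (tr in names(traits)) {
    tv <- traits[[tr]]
    al <- .stage(sprintf("aldex_%s", tr),
                 aldex_glm(instances, tv, taxa = analysis_cols))
    files[paste0("aldex_", tr)] <- .write_tsv(
      as.data.frame(al), file.path(config$out_dir,
                                   sprintf("aldex_%s.tsv", tr)))
    rf <- .stage(sprintf("rf_%s", tr),
                 rf_importance(x, tv, n_trees = config$n_trees,
                               seed = config$seed))
    files[paste0("rf_", tr)] <- .write_tsv(
      as.data.frame(rf), file.path(config$out_dir, sprintf("rf_%s.tsv", tr)))
    sig <- stats_out$taxa[stats_out$taxa$trait == tr, ]
    cons <- .stage(sprintf("consensus_%s", tr),
                   consensus_taxa(sig, fit$modules, mt, stab, al, rf, tr,
                                  top_k = config$top_k,
                                  taxon_kind = rr$taxon_kind))
    consensus[[tr]] <- cons
    files[paste0("consensus_", tr)] <- .write_tsv(
      cons, file.path(config$out_dir, sprintf("consensus_%s.tsv", tr)))
  }

  tax_order <- NULL
  if (!is.null(taxonomy)) {
    src <- rr$naming$source[match(colnames(x), rr$naming$name)]
    tax_order <- stats::setNames(
      taxonomy$Order[match(src, taxonomy$taxon_id)], colnames(x))
  }
  for (m in setdiff(unique(fit$modules), "unassigned"))
    for (thr in config$edge_thresholds) {
      ex <- export_edge_list(x, fit$modules, m, thr,
                             membership = stats_out$membership,
                             hub = stats_out$hub, tax_order = tax_order)
      tag <- sprintf("%s_r%s", m, sub("^0[.]", "", format(thr)))
      files[paste0("edges_", tag)] <- .write_tsv(
        ex$edges, file.path(config$out_dir, sprintf("edges_%s.tsv", tag)))
      files[paste0("nodes_", tag)] <- .write_tsv(
        ex$nodes, file.path(config$out_dir, sprintf("nodes_%s.tsv", tag)))
    }

  cfg_plain <- unclass(config)
  cfg_plain$criteria <- unclass(cfg_plain$criteria)
  manifest <- list(
    package_version = as.character(utils::packageVersion("miconet")),
    config = cfg_plain,
    records = list(samples_in = nrow(qc$report),
                   samples_kept = nrow(counts),
                   taxa_final = ncol(x),
                   modules = sum(fit$modules != "unassigned"),
                   files = length(files)))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(list(out_dir = config$out_dir, files = files, qc = qc, rr = rr,
                 clr = clr, eb = eb, x = x, fits = fits, stability = stabs,
                 stats = stats_out, consensus = consensus,
                 manifest = manifest))
}

#' Read the configuration back from a written manifest
#'
#' @param path manifest.json path.
#' @return a \code{pipeline_config} reproducing the run.
#' @export
manifest_config <- function(path) {
  man <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- man$config
  cfg$criteria <- do.call(filter_criteria, as.list(cfg$criteria))
  do.call(pipeline_config, cfg)
}
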