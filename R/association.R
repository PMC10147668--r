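#' Dirichlet Monte-Carlo CLR instances
#'
#' For each sample, draws \code{n_instances} probability vectors from
#' Dirichlet(counts + pseudocount) and CLR-transforms each draw over the full
#' compositional closure (all columns supplied, including any "Other taxa"
#' remainder). The instances propagate the sampling uncertainty of the counts
#' into downstream per-taxon models, the defining mechanism of
#' Dirichlet-Monte-Carlo differential abundance.
#'
#' @param counts samples x taxa integer matrix (the full closure).
#' @param n_instances number of Monte-Carlo instances (>= 2; default 128).
#' @param seed integer RNG seed.
#' @param pseudocount Dirichlet prior mass per taxon (default 0.5).
#' @return list of \code{n_instances} samples x taxa CLR matrices.
#' @export
dirichlet_instances <- function(counts, n_instances = 128, seed = 1,
                                pseudocount = 0.5) {
  .assert(n_instances >= 2, "n_instances must be >= 2")
  .assert(is.matrix(counts) && all(counts >= 0), "counts must be non-negative")
  n <- nrow(counts); p <- ncol(counts)
  alpha <- counts + pseudocount
  with_seed(seed, lapply(seq_len(n_instances), function(i) {
    g <- matrix(stats::rgamma(n * p, shape = alpha, rate = 1), n, p)
    lg <- log(g / rowSums(g))
    out <- lg - rowMeans(lg)
    dimnames(out) <- dimnames(counts)
    out
  }))
}

#' Per-taxon linear models over Dirichlet Monte-Carlo instances
#'
#' For every Monte-Carlo instance and taxon, fits the ordinary linear model
#' CLR ~ standardized trait; the across-instance mean slope is reported as the
#' effect \code{beta} (expected change in CLR abundance per standard deviation
#' of the trait) and the across-instance mean two-sided p-value as the raw p,
#' followed by Benjamini-Hochberg adjustment across taxa. Samples with a
#' missing trait are dropped.
#'
#' @param instances list of CLR matrices from
#'   \code{\link{dirichlet_instances}} (a single matrix is also accepted, in
#'   which case the result is a plain per-taxon regression).
#' @param trait numeric trait vector aligned with the instance rows.
#' @param taxa optional subset of taxon columns to report (e.g. to exclude
#'   the "Other taxa" remainder).
#' @return object of class \code{"aldex_glm"}: data.frame taxon, beta, p,
#'   p_bh, with \code{n_instances} and \code{n} as attributes.
#' @export
aldex_glm <- function(instances, trait, taxa = NULL) {
  if (is.matrix(instances)) instances <- list(instances)
  .assert(length(instances) >= 1, "no instances")
  .assert(all(is.finite(trait) | is.na(trait)), "non-finite trait values")
  ok <- !is.na(trait)
  .assert(sum(ok) >= 3, "trait needs at least 3 non-missing values")
  .assert(stats::sd(trait[ok]) > 0, "constant trait")
  z <- as.numeric(scale(trait[ok]))
  ssz <- sum(z^2)
  n <- sum(ok)
  taxa <- taxa %||% colnames(instances[[1]])
  beta_sum <- p_sum <- stats::setNames(numeric(length(taxa)), taxa)
  for (y in instances) {
    ym <- y[ok, taxa, drop = FALSE]
    yc <- sweep(ym, 2, colMeans(ym))
    b <- as.numeric(crossprod(yc, z)) / ssz
    rss <- colSums(yc^2) - b^2 * ssz
    se <- sqrt(pmax(rss, 0) / (n - 2) / ssz)
    t <- ifelse(se > 0, b / se, sign(b) * Inf)
    p <- pmax(2 * stats::pt(-abs(t), n - 2), .Machine$double.xmin)
    beta_sum <- beta_sum + b
    p_sum <- p_sum + p
  }
  k <- length(instances)
  out <- data.frame(taxon = taxa, beta = unname(beta_sum / k),
                    p = unname(p_sum / k), stringsAsFactors = FALSE)
  out$p_bh <- bh_adjust(out$p)
  attr(out, "n_instances") <- k
  attr(out, "n") <- n
  class(out) <- c("aldex_glm", "data.frame")
  out
}

#' @export
print.aldex_glm <- function(x, ...) {
  cat(sprintf("Dirichlet Monte-Carlo linear models: %d taxa, %d samples, %d instance(s)\n",
              nrow(x), attr(x, "n"), attr(x, "n_instances")))
  cat(sprintf("%d taxa with raw p < 0.05; %d after BH\n",
              sum(x$p < 0.05), sum(x$p_bh < 0.05)))
  invisible(x)
}

#' Random-forest importance ranking for a continuous trait
#'
#' Regresses the trait on the CLR taxon abundances with a random forest and
#' ranks taxa by out-of-bag permutation importance (mean decrease in accuracy,
#' the less biased choice for correlated compositional features). A held-out
#' fraction of samples gives a validation predictive R-squared, which may be
#' at or below zero when the taxa carry little signal for the trait.
#'
#' @param x samples x taxa matrix (corrected CLR).
#' @param trait numeric trait vector aligned with rows.
#' @param n_trees number of trees (default 1000).
#' @param seed integer RNG seed (controls the holdout split and the forest).
#' @param holdout_fraction fraction of samples held out for validation
#'   (default 0.25).
#' @return object of class \code{"rf_importance"}: data.frame taxon,
#'   importance, rank; attributes \code{r2_holdout}, \code{seed}.
#' @export
rf_importance <- function(x, trait, n_trees = 1000, seed = 1,
                          holdout_fraction = 0.25) {
  x <- .check_matrix(x)
  ok <- !is.na(trait)
  x <- x[ok, , drop = FALSE]; trait <- trait[ok]
  .assert(nrow(x) >= 20, "need at least 20 samples")
  .assert(stats::sd(trait) > 0, "constant trait")
  with_seed(seed, {
    n <- nrow(x)
    n_hold <- max(1L, round(holdout_fraction * n))
    hold <- sample.int(n, n_hold)
    rf <- randomForest::randomForest(x[-hold, , drop = FALSE], trait[-hold],
                                     ntree = n_trees, importance = TRUE)
    imp <- randomForest::importance(rf, type = 1)[, 1]
    pred <- stats::predict(rf, x[hold, , drop = FALSE])
    r2 <- 1 - sum((trait[hold] - pred)^2) /
      sum((trait[hold] - mean(trait[hold]))^2)
    out <- data.frame(taxon = colnames(x), importance = unname(imp),
                      stringsAsFactors = FALSE)
    out$rank <- rank(-out$importance, ties.method = "first")
    out <- out[order(out$rank), ]
    rownames(out) <- NULL
    attr(out, "r2_holdout") <- r2
    attr(out, "seed") <- seed
    class(out) <- c("rf_importance", "data.frame")
    out
  })
}

#' @export
print.rf_importance <- function(x, k = 10, ...) {
  cat(sprintf("Random-forest importance ranking (%d taxa); holdout R^2 = %.3f\n",
              nrow(x), attr(x, "r2_holdout")))
  print.data.frame(utils::head(x, k), row.names = FALSE)
  invisible(x)
}

#' Consensus trait-associated taxa
#'
#' Combines the three analytical routes into a consensus table. A taxon is
#' flagged by the network route (WCNA) when it belongs to a VALID module whose
#' eigentaxon-trait correlation is significant (raw p < \code{alpha}) and its
#' own signed taxa-significance raw p < \code{alpha}; by the Dirichlet
#' Monte-Carlo GLM route when its raw p < \code{alpha}; and by the random
#' forest route when its importance rank is <= \code{top_k}. A row is emitted
#' iff the WCNA flag holds AND at least one of the other two does.
#'
#' @param significance \code{\link{taxa_significance}} output for the trait.
#' @param labels per-taxon module labels.
#' @param module_trait \code{\link{module_trait_correlation}} output.
#' @param stability \code{\link{module_stability}} output.
#' @param diff \code{\link{aldex_glm}} output for the trait.
#' @param rf \code{\link{rf_importance}} output for the trait.
#' @param trait trait name (column of \code{module_trait}).
#' @param top_k random-forest rank cutoff (default 20).
#' @param alpha significance level for the WCNA and GLM flags (default 0.05).
#' @param taxon_kind optional per-taxon resolution labels ("ASV"/"genus").
#' @param require_valid_module,require_module_trait logicals exposing the two
#'   WCNA sub-criteria (both default TRUE).
#' @return data.frame: taxon, resolution, module, wcna, random_forest, aldex,
#'   beta, p, p_bh — one row per consensus taxon, ordered by GLM p.
#' @export
consensus_taxa <- function(significance, labels, module_trait, stability,
                           diff, rf, trait, top_k = 20, alpha = 0.05,
                           taxon_kind = NULL, require_valid_module = TRUE,
                           require_module_trait = TRUE) {
  taxa <- significance$taxon
  .assert(setequal(taxa, diff$taxon) && setequal(taxa, rf$taxon),
          "taxon sets of the three methods do not match")
  .assert(trait %in% colnames(module_trait$p), "unknown trait")
  labels <- labels[taxa]

  valid_mods <- if (require_valid_module)
    stability$module[stability$valid] else setdiff(unique(labels), "unassigned")
  sig_mods <- if (require_module_trait) {
    pm <- stats::setNames(module_trait$p[, trait], rownames(module_trait$p))
    names(pm)[!is.na(pm) & pm < alpha]
  } else rownames(module_trait$p)
  wcna_mods <- intersect(valid_mods, sig_mods)

  wcna_flag <- labels %in% wcna_mods &
    significance$p[match(taxa, significance$taxon)] < alpha
  aldex_flag <- diff$p[match(taxa, diff$taxon)] < alpha
  rf_flag <- rf$rank[match(taxa, rf$taxon)] <= top_k

  keep <- wcna_flag & (aldex_flag | rf_flag)
  di <- match(taxa, diff$taxon)
  out <- data.frame(
    taxon = taxa,
    resolution = if (is.null(taxon_kind)) NA_character_
                 else unname(taxon_kind[taxa]),
    module = unname(labels),
    wcna = ifelse(wcna_flag, "YES", ""),
    random_forest = ifelse(rf_flag, "YES", ""),
    aldex = ifelse(aldex_flag, "YES", ""),
    beta = diff$beta[di], p = diff$p[di], p_bh = diff$p_bh[di],
    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "trait") <- trait
  out
}
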