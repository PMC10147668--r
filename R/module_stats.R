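#' Module eigentaxa
#'
#' The eigentaxon of a module is the first principal component of its
#' standardized member taxa across samples: a single per-sample score
#' summarizing the module's abundance. Each eigentaxon is scaled to unit
#' variance and sign-oriented so that its average correlation with the
#' module's taxa is non-negative, so participants with high module abundance
#' have a higher eigentaxon value.
#'
#' @param x samples x taxa matrix (corrected CLR).
#' @param labels per-taxon module labels; "unassigned" taxa are excluded.
#' @param modules which modules to summarize (default all assigned).
#' @return samples x modules numeric matrix of class \code{"eigentaxa"} with
#'   attribute \code{var_explained} (first-PC variance fraction per module).
#' @export
module_eigentaxa <- function(x, labels, modules = NULL) {
  x <- .check_matrix(x)
  labels <- labels[colnames(x)]
  modules <- modules %||% setdiff(unique(labels), "unassigned")
  .assert(length(modules) > 0, "no modules to summarize")
  E <- matrix(NA_real_, nrow(x), length(modules),
              dimnames = list(rownames(x), modules))
  ve <- stats::setNames(numeric(length(modules)), modules)
  for (m in modules) {
    idx <- which(labels == m)
    .assert(length(idx) >= 2,
            sprintf("module '%s' has fewer than 2 taxa", m))
    Xs <- scale(x[, idx, drop = FALSE])
    .assert(!anyNA(Xs), sprintf("constant taxon in module '%s'", m))
    sv <- svd(Xs, nu = 1, nv = 0)
    e <- sv$u[, 1]
    e <- e / stats::sd(e)
    if (mean(stats::cor(e, Xs)) < 0) e <- -e
    E[, m] <- e
    ve[m] <- sv$d[1]^2 / sum(sv$d^2)
  }
  structure(E, var_explained = ve, class = c("eigentaxa", "matrix", "array"))
}

#' Module membership
#'
#' Pearson correlation of every taxon with every module eigentaxon; a taxon's
#' membership in its own module is a proxy for its intramodular connectivity.
#'
#' @param x samples x taxa matrix.
#' @param eigentaxa samples x modules matrix from
#'   \code{\link{module_eigentaxa}}.
#' @return taxa x modules correlation matrix.
#' @export
module_membership <- function(x, eigentaxa) {
  x <- .check_matrix(x)
  stats::cor(x, unclass(eigentaxa))
}

own_membership <- function(membership, labels) {
  labels <- labels[rownames(membership)]
  out <- stats::setNames(rep(NA_real_, nrow(membership)), rownames(membership))
  assigned <- labels != "unassigned" & labels %in% colnames(membership)
  out[assigned] <- membership[cbind(which(assigned), match(labels[assigned],
                                                           colnames(membership)))]
  out
}

.cor_test_p <- function(r, n) {
  p <- rep(NA_real_, length(r))
  ok <- !is.na(r) & n > 2
  t <- r[ok] * sqrt((n[ok] - 2) / pmax(1 - r[ok]^2, .Machine$double.eps))
  p[ok] <- 2 * stats::pt(-abs(t), n[ok] - 2)
  pmax(p, .Machine$double.xmin)
}

#' Taxa significance for a clinical trait
#'
#' Signed Pearson correlation between each taxon and the trait, its absolute
#' value, the two-sided Student-t p-value, and the Benjamini-Hochberg adjusted
#' p-value across taxa. Pairwise-complete samples are used, so missing trait
#' values reduce n rather than dropping taxa.
#'
#' @param x samples x taxa matrix.
#' @param trait numeric trait vector aligned with rows of \code{x}.
#' @return data.frame: taxon, r (signed), abs_r, n, p, p_bh.
#' @export
taxa_significance <- function(x, trait) {
  x <- .check_matrix(x)
  .assert(length(trait) == nrow(x), "trait length must match samples")
  ok <- !is.na(trait)
  .assert(sum(ok) >= 3, "trait needs at least 3 non-missing values")
  .assert(stats::sd(trait[ok]) > 0, "constant trait")
  r <- as.numeric(stats::cor(x[ok, , drop = FALSE], trait[ok]))
  n <- rep(sum(ok), ncol(x))
  p <- .cor_test_p(r, n)
  data.frame(taxon = colnames(x), r = r, abs_r = abs(r), n = n, p = p,
             p_bh = bh_adjust(p), stringsAsFactors = FALSE)
}

#' Module-trait correlation table
#'
#' Pairwise-complete Pearson correlation between each module eigentaxon and
#' each continuous trait, with Student-t p-values and the per-cell sample
#' size. Cells with fewer than 3 paired observations are left missing.
#'
#' @param eigentaxa samples x modules matrix.
#' @param traits data.frame of trait columns aligned with samples.
#' @return object of class \code{"module_trait"}: list of matrices \code{r},
#'   \code{p}, \code{n} (modules x traits).
#' @export
module_trait_correlation <- function(eigentaxa, traits) {
  E <- unclass(eigentaxa)
  traits <- as.data.frame(traits)
  mods <- colnames(E); trs <- names(traits)
  r <- p <- nmat <- matrix(NA_real_, length(mods), length(trs),
                           dimnames = list(mods, trs))
  for (j in seq_along(trs)) {
    tv <- traits[[j]]
    for (i in seq_along(mods)) {
      ok <- !is.na(tv) & !is.na(E[, i])
      nmat[i, j] <- sum(ok)
      if (sum(ok) >= 3 && stats::sd(tv[ok]) > 0) {
        r[i, j] <- stats::cor(E[ok, i], tv[ok])
        p[i, j] <- .cor_test_p(r[i, j], sum(ok))
      }
    }
  }
  structure(list(r = r, p = p, n = nmat), class = "module_trait")
}

#' @export
print.module_trait <- function(x, digits = 3, ...) {
  cat("Module-trait Pearson correlations (p-values in brackets):\n")
  out <- matrix(sprintf("%.*f (%.2g)", digits, x$r, x$p),
                nrow(x$r), ncol(x$r), dimnames = dimnames(x$r))
  print(out, quote = FALSE)
  invisible(x)
}

#' Hub taxa
#'
#' Within each module, taxa whose own-module membership is at or above the
#' module's 95th percentile of own-module memberships (linear-interpolation
#' percentile; ties at the threshold are all hubs, and each module always has
#' at least one hub). Set \code{scope = "all"} to take the percentile across
#' all assigned taxa instead.
#'
#' @param membership taxa x modules matrix from
#'   \code{\link{module_membership}}.
#' @param labels per-taxon module labels.
#' @param percentile hub percentile (default 0.95).
#' @param scope "module" (default) or "all".
#' @return named logical vector: TRUE for hub taxa.
#' @export
hub_taxa <- function(membership, labels, percentile = 0.95,
                     scope = c("module", "all")) {
  scope <- match.arg(scope)
  labels <- labels[rownames(membership)]
  mm_own <- own_membership(membership, labels)
  hub <- stats::setNames(rep(FALSE, length(labels)), names(labels))
  mods <- setdiff(unique(labels), "unassigned")
  if (!length(mods)) return(hub)
  if (scope == "all") {
    thr <- stats::quantile(mm_own[labels != "unassigned"], percentile,
                           na.rm = TRUE, type = 7)
    hub[labels != "unassigned" & !is.na(mm_own) & mm_own >= thr] <- TRUE
    return(hub)
  }
  for (m in mods) {
    idx <- labels == m
    thr <- stats::quantile(mm_own[idx], percentile, na.rm = TRUE, type = 7)
    hub[idx & mm_own >= thr] <- TRUE
  }
  hub
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate correction with monotonicity enforcement.
#'
#' @param p vector of raw p-values in (0, 1].
#' @return adjusted p-values.
#' @export
bh_adjust <- function(p) {
  .assert(all(is.finite(p)) && all(p > 0) && all(p <= 1),
          "p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Full per-taxon module statistics table
#'
#' Convenience wrapper assembling, for a fitted network and a set of traits,
#' the per-taxon own-module membership, hub flag, and signed/absolute taxa
#' significance with raw and BH-adjusted p-values for every trait.
#'
#' @param fit a \code{\link{wcna}} fit.
#' @param traits data.frame of trait columns aligned with the fit's samples.
#' @param percentile hub percentile (default 0.95).
#' @return list with \code{eigentaxa}, \code{membership}, \code{module_trait},
#'   \code{taxa} (long data.frame over taxon x trait), \code{hub}.
#' @export
module_statistics <- function(fit, traits, percentile = 0.95) {
  .assert(inherits(fit, "wcna"), "fit must be a wcna object")
  mods <- setdiff(unique(fit$modules), "unassigned")
  .assert(length(mods) > 0, "no modules in fit")
  E <- module_eigentaxa(fit$data, fit$modules)
  MM <- module_membership(fit$data, E)
  mt <- module_trait_correlation(E, traits)
  hub <- hub_taxa(MM, fit$modules, percentile)
  tabs <- lapply(names(traits), function(tr) {
    ts <- taxa_significance(fit$data, traits[[tr]])
    ts$trait <- tr
    ts
  })
  taxa <- do.call(rbind, tabs)
  taxa$module <- fit$modules[taxa$taxon]
  taxa$module_membership <- own_membership(MM, fit$modules)[taxa$taxon]
  taxa$hub <- hub[taxa$taxon]
  list(eigentaxa = E, membership = MM, module_trait = mt, taxa = taxa,
       hub = hub)
}
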