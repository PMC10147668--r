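#' Jaccard similarity of two taxon sets
#'
#' @param set_a,set_b character vectors (at least one non-empty).
#' @return |intersection| / |union|.
#' @export
jaccard <- function(set_a, set_b) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  .assert(length(set_a) + length(set_b) > 0, "both sets are empty")
  length(intersect(set_a, set_b)) / length(union(set_a, set_b))
}

#' Rebuild networks on bootstrap resamples of the samples
#'
#' Each replicate resamples participants (rows) with replacement to the
#' original n, rebuilds the adjacency, TOM and modules with the SAME network
#' configuration as the original fit (fixed beta and minimum module size: no
#' soft-threshold re-selection), and records each detected module's taxon
#' set. Taxa that become constant within a replicate are dropped from that
#' replicate's network. All resampling indices are drawn up-front from
#' \code{seed}, so the draw is reproducible independently of the per-replicate
#' work.
#'
#' @param fit a \code{\link{wcna}} fit (carries the data and configuration).
#' @param n_boot number of bootstrap replicates.
#' @param seed integer RNG seed.
#' @param reselect_beta logical; if TRUE each replicate re-runs soft-threshold
#'   selection instead of reusing the original beta (default FALSE).
#' @return object of class \code{"bootstrap_modules"}: list with
#'   \code{modules} (per replicate, a named list of taxon sets),
#'   \code{indices} (n_boot x n matrix of resampled row indices),
#'   \code{dropped} (per-replicate constant taxa), \code{seed}.
#' @export
bootstrap_modules <- function(fit, n_boot = 100, seed = 1,
                              reselect_beta = FALSE) {
  .assert(inherits(fit, "wcna"), "fit must be a wcna object")
  .assert(n_boot >= 1, "n_boot must be >= 1")
  x <- fit$data
  n <- nrow(x)
  cfg <- fit$config
  indices <- with_seed(seed,
                       matrix(sample.int(n, n * n_boot, replace = TRUE),
                              nrow = n_boot, ncol = n, byrow = TRUE))
  modules <- vector("list", n_boot)
  dropped <- vector("list", n_boot)
  for (b in seq_len(n_boot)) {
    xb <- x[indices[b, ], , drop = FALSE]
    sds <- apply(xb, 2, stats::sd)
    dropped[[b]] <- colnames(xb)[sds == 0]
    xb <- xb[, sds > 0, drop = FALSE]
    R <- stats::cor(xb)
    beta <- if (reselect_beta)
      as.integer(pick_soft_threshold(R, cfg$candidate_betas, cfg$r2_target,
                                     cfg$network_sign))
    else cfg$beta
    A <- soft_threshold_adjacency(R, beta, cfg$network_sign)
    D <- 1 - topological_overlap(A)
    lab <- suppressWarnings(
      detect_modules(D, cfg$min_module_size, cfg$cut_height))
    attr(lab, "dendrogram") <- NULL
    if (length(setdiff(unique(lab), "unassigned")))
      lab <- merge_modules(lab, xb, cfg$merge_cut_height)
    mods <- setdiff(unique(lab), "unassigned")
    modules[[b]] <- stats::setNames(
      lapply(mods, function(m) names(lab)[lab == m]), mods)
  }
  structure(list(modules = modules, indices = indices, dropped = dropped,
                 seed = seed, n_boot = n_boot),
            class = "bootstrap_modules")
}

#' Match bootstrap modules to original modules by Jaccard similarity
#'
#' Independently for each original module, picks the bootstrap module with the
#' highest Jaccard similarity (one bootstrap module may serve several
#' originals). Ties break toward the larger bootstrap module, then the
#' lexicographically smaller label. A replicate with no modules contributes
#' similarity 0.
#'
#' @param original named list of original module taxon sets.
#' @param bootstrap named list of bootstrap module taxon sets.
#' @return data.frame: original, matched (label or NA), jaccard.
#' @export
match_modules <- function(original, bootstrap) {
  .assert(length(original) > 0, "no original modules")
  out <- data.frame(original = names(original),
                    matched = NA_character_, jaccard = 0,
                    stringsAsFactors = FALSE)
  if (!length(bootstrap)) return(out)
  sizes <- lengths(bootstrap)
  labs <- names(bootstrap)
  for (i in seq_along(original)) {
    js <- vapply(bootstrap, jaccard, 1.0, set_b = original[[i]])
    best <- order(-js, -sizes, labs)[1]
    out$matched[i] <- labs[best]
    out$jaccard[i] <- js[best]
  }
  out
}

#' Bootstrap module-stability validation
#'
#' Module stability is the mean Jaccard similarity between an original
#' module's taxon set and its best-matching module across bootstrap-resampled
#' networks; modules with stability strictly greater than 0.5 are declared
#' valid (the minimum recoverability expected of a genuine cluster).
#' Unassigned taxa are excluded from all sets.
#'
#' @param fit a \code{\link{wcna}} fit.
#' @param n_boot number of bootstrap replicates (1000 for a full analysis;
#'   scale down for exploration).
#' @param seed integer RNG seed.
#' @param boots optional precomputed \code{\link{bootstrap_modules}} result.
#' @return object of class \code{"module_stability"}: data.frame (module,
#'   size, mean_jaccard, valid) with the per-replicate Jaccard matrix as
#'   attribute \code{"replicates"}.
#' @export
module_stability <- function(fit, n_boot = 100, seed = 1, boots = NULL) {
  .assert(inherits(fit, "wcna"), "fit must be a wcna object")
  mods <- setdiff(unique(fit$modules), "unassigned")
  if (!length(mods)) {
    warning("no modules in the original network", call. = FALSE)
    out <- data.frame(module = character(), size = integer(),
                      mean_jaccard = numeric(), valid = logical())
    class(out) <- c("module_stability", "data.frame")
    return(out)
  }
  original <- stats::setNames(
    lapply(mods, function(m) names(fit$modules)[fit$modules == m]), mods)
  boots <- boots %||% bootstrap_modules(fit, n_boot = n_boot, seed = seed)
  reps <- matrix(0, boots$n_boot, length(mods),
                 dimnames = list(NULL, mods))
  for (b in seq_len(boots$n_boot))
    reps[b, ] <- match_modules(original, boots$modules[[b]])$jaccard
  out <- data.frame(module = mods, size = lengths(original)[mods],
                    mean_jaccard = colMeans(reps),
                    valid = colMeans(reps) > 0.5,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "replicates") <- reps
  attr(out, "n_boot") <- boots$n_boot
  attr(out, "seed") <- boots$seed
  class(out) <- c("module_stability", "data.frame")
  out
}

#' @export
print.module_stability <- function(x, ...) {
  cat(sprintf("Module stability over %s bootstrap replicate(s):\n",
              attr(x, "n_boot") %||% "?"))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
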