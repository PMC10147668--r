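#' Pearson correlation matrix of taxa
#'
#' @param x samples x taxa numeric matrix (>= 3 samples, no constant taxon).
#' @return taxa x taxa correlation matrix.
#' @export
correlation_matrix <- function(x) {
  x <- .check_matrix(x)
  .assert(nrow(x) >= 3, "need at least 3 samples")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop(sprintf("constant taxa: %s",
                 paste(colnames(x)[sds == 0], collapse = ", ")), call. = FALSE)
  stats::cor(x)
}

#' Soft-threshold adjacency
#'
#' Unsigned: \code{A = |r|^beta}; signed: \code{A = ((1 + r)/2)^beta}. The
#' diagonal is forced to 1. Raising beta suppresses weak correlations and
#' emphasizes strong ones, the soft analogue of a hard correlation cutoff.
#'
#' @param R correlation matrix.
#' @param beta soft-threshold power (>= 1).
#' @param network_sign "unsigned" (default) or "signed".
#' @return adjacency matrix in [0, 1].
#' @export
soft_threshold_adjacency <- function(R, beta,
                                     network_sign = c("unsigned", "signed")) {
  network_sign <- match.arg(network_sign)
  .assert(beta >= 1, "beta must be >= 1")
  A <- if (network_sign == "unsigned") abs(R)^beta else ((1 + R) / 2)^beta
  diag(A) <- 1
  A
}

#' Scale-free topology fit of a weighted network
#'
#' Connectivity \code{k_i = sum_{j != i} A_ij} is binned into roughly
#' \code{n_bins} equal-width bins; \code{log10} of the bin frequency is
#' regressed on \code{log10} of the bin's mean connectivity over occupied
#' bins. A scale-free network gives a straight, negatively sloped fit.
#'
#' @param A adjacency matrix (or NULL when \code{k} is supplied directly).
#' @param k optional precomputed connectivity vector.
#' @param n_bins number of connectivity bins (default 10).
#' @return list with \code{r2}, \code{slope}, and the binned \code{table}.
#' @export
scale_free_fit <- function(A = NULL, k = NULL, n_bins = 10) {
  if (is.null(k)) {
    .assert(!is.null(A), "supply A or k")
    k <- rowSums(A) - diag(A)
  }
  .assert(all(is.finite(k)), "non-finite connectivities")
  if (max(k) - min(k) < .Machine$double.eps^0.5)
    stop("degenerate network: all connectivities equal", call. = FALSE)
  breaks <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, breaks, include.lowest = TRUE)
  freq <- tabulate(bin, nbins = n_bins)
  occupied <- freq > 0
  .assert(sum(occupied) >= 2, "need at least 2 occupied connectivity bins")
  dk <- tapply(k, bin, mean)[occupied]
  pk <- freq[occupied] / length(k)
  fit <- stats::lm(log10(pk) ~ log10(dk))
  list(r2 = summary(fit)$r.squared, slope = unname(stats::coef(fit)[2]),
       table = data.frame(k = as.numeric(dk), p_k = as.numeric(pk)))
}

#' Select the soft-threshold power by scale-free topology criteria
#'
#' Returns the smallest candidate power whose scale-free fit reaches
#' \code{r2_target} with a negative slope; if none qualifies, the candidate
#' maximizing the fit (a logged fallback).
#'
#' @param R correlation matrix.
#' @param candidate_betas integer candidates (default 1:10).
#' @param r2_target scale-free R-squared target (default 0.8).
#' @param network_sign "unsigned" or "signed".
#' @return chosen beta, with the per-candidate fit table as attribute
#'   \code{"fits"}.
#' @export
pick_soft_threshold <- function(R, candidate_betas = 1:10, r2_target = 0.8,
                                network_sign = c("unsigned", "signed")) {
  network_sign <- match.arg(network_sign)
  .assert(length(candidate_betas) > 0, "no candidate betas")
  fits <- data.frame(beta = candidate_betas, r2 = NA_real_, slope = NA_real_)
  for (i in seq_along(candidate_betas)) {
    A <- soft_threshold_adjacency(R, candidate_betas[i], network_sign)
    f <- tryCatch(scale_free_fit(A), error = function(e) NULL)
    if (!is.null(f)) {
      fits$r2[i] <- f$r2
      fits$slope[i] <- f$slope
    }
  }
  ok <- which(!is.na(fits$r2) & fits$r2 >= r2_target & fits$slope < 0)
  if (length(ok)) {
    beta <- candidate_betas[min(ok)]
  } else {
    .assert(any(!is.na(fits$r2)), "scale-free fit failed for every candidate")
    beta <- candidate_betas[which.max(fits$r2)]
    message(sprintf("no candidate reached scale-free R^2 >= %g; using beta = %d (max R^2 = %.3f)",
                    r2_target, beta, max(fits$r2, na.rm = TRUE)))
  }
  attr(beta, "fits") <- fits
  beta
}

#' Topological overlap matrix
#'
#' \code{T_ij = (l_ij + A_ij) / (min(k_i, k_j) + 1 - A_ij)} for \code{i != j},
#' where \code{l_ij = sum_u A_iu A_uj} over \code{u != i, j} and
#' \code{k_i = sum_{u != i} A_iu}; \code{T_ii = 1}. The overlap counts shared
#' network neighbors, so taxa embedded in the same neighborhood score high
#' even if their direct edge is moderate.
#'
#' @param A adjacency matrix (symmetric, unit diagonal, entries in [0, 1]).
#' @return topological overlap matrix in [0, 1].
#' @export
topological_overlap <- function(A) {
  .assert(isSymmetric(unname(A)), "adjacency must be symmetric")
  n <- nrow(A)
  k <- rowSums(A) - diag(A)
  # l_ij = (A^2)_ij - A_ii A_ij - A_ij A_jj = (A^2)_ij - 2 A_ij (unit diagonal)
  L <- A %*% A - 2 * A
  kmin <- outer(k, k, pmin)
  TOM <- (L + A) / (kmin + 1 - A)
  diag(TOM) <- 1
  dimnames(TOM) <- dimnames(A)
  TOM
}

#' Detect co-occurrence modules from a TOM dissimilarity
#'
#' Average-linkage hierarchical clustering of \code{D = 1 - TOM} followed by a
#' deterministic tree cut: the dendrogram is cut at \code{cut_height} and
#' branches smaller than \code{min_module_size} are left unassigned. Modules
#' are named by size rank in the conventional color order (largest =
#' "turquoise", then "blue", "brown", ...); ties break on first taxon index.
#'
#' @param D dissimilarity matrix (1 - TOM).
#' @param min_module_size smallest taxon count admitted as a module.
#' @param cut_height static cut height on the dissimilarity scale.
#' @return named character vector of module labels ("unassigned" for
#'   background taxa), with the \code{hclust} tree as attribute
#'   \code{"dendrogram"}.
#' @export
detect_modules <- function(D, min_module_size = 25, cut_height = 0.97) {
  .assert(isSymmetric(unname(D)), "D must be symmetric")
  taxa <- colnames(D)
  n <- ncol(D)
  h <- stats::hclust(stats::as.dist(D), method = "average")
  labels <- rep("unassigned", n)
  names(labels) <- taxa
  if (n < max(2, min_module_size)) {
    warning("fewer taxa than min_module_size: all unassigned", call. = FALSE)
    attr(labels, "dendrogram") <- h
    return(labels)
  }
  cl <- stats::cutree(h, h = cut_height)
  sizes <- table(cl)
  big <- as.integer(names(sizes)[sizes >= min_module_size])
  if (length(big)) {
    first_idx <- vapply(big, function(g) min(which(cl == g)), 1L)
    ord <- big[order(-as.integer(sizes[as.character(big)]), first_idx)]
    cols <- module_color_names(length(ord))
    for (i in seq_along(ord)) labels[cl == ord[i]] <- cols[i]
  }
  attr(labels, "dendrogram") <- h
  labels
}

#' Merge modules with similar eigentaxa
#'
#' Computes module eigentaxa, and iteratively merges the pair of modules whose
#' eigentaxon correlation dissimilarity (1 - cor) is smallest, while it is
#' below \code{merge_cut_height}; labels are then re-ranked by size into the
#' conventional color order. With well-separated modules this is a no-op.
#'
#' @param labels module labels (from \code{\link{detect_modules}}).
#' @param x the samples x taxa matrix the network was built from.
#' @param merge_cut_height dissimilarity below which modules merge
#'   (default 0.25); 0 disables merging.
#' @return relabeled module vector.
#' @export
merge_modules <- function(labels, x, merge_cut_height = 0.25) {
  x <- .check_matrix(x)
  lab <- stats::setNames(as.character(labels), names(labels))
  any_merged <- FALSE
  repeat {
    mods <- setdiff(unique(lab), "unassigned")
    if (length(mods) < 2 || merge_cut_height <= 0) break
    E <- module_eigentaxa(x, lab)
    dis <- 1 - stats::cor(E)
    diag(dis) <- Inf
    i <- which(dis == min(dis), arr.ind = TRUE)[1, ]
    if (dis[i[1], i[2]] >= merge_cut_height) break
    a <- colnames(E)[i[1]]; b <- colnames(E)[i[2]]
    sizes <- table(lab)
    keep <- if (sizes[a] >= sizes[b]) a else b
    drop <- setdiff(c(a, b), keep)
    lab[lab == drop] <- keep
    any_merged <- TRUE
  }
  if (!any_merged) return(lab)
  mods <- setdiff(unique(lab), "unassigned")
  if (length(mods)) {
    sizes <- vapply(mods, function(m) sum(lab == m), 1L)
    first_idx <- vapply(mods, function(m) min(which(lab == m)), 1L)
    ord <- mods[order(-sizes, first_idx)]
    cols <- module_color_names(length(ord))
    out <- lab
    for (i in seq_along(ord)) out[lab == ord[i]] <- cols[i]
    lab <- out
  }
  lab
}

#' Fit a weighted taxon co-occurrence network
#'
#' The central fitting function: builds the Pearson correlation matrix of the
#' (covariate-corrected) CLR abundances, raises it to a soft-threshold power
#' chosen by scale-free topology criteria (or fixed via \code{beta}),
#' computes the topological overlap matrix, clusters \code{1 - TOM} by
#' average linkage, cuts the tree into modules of at least
#' \code{min_module_size} taxa, and merges modules with near-identical
#' eigentaxa.
#'
#' @param x samples x taxa numeric matrix (CLR, typically covariate-corrected).
#' @param beta fixed soft-threshold power; if NULL it is selected from
#'   \code{candidate_betas}.
#' @param candidate_betas candidates for soft-threshold selection.
#' @param r2_target scale-free fit target for selection (default 0.8).
#' @param network_sign "unsigned" (default) or "signed" adjacency.
#' @param min_module_size minimum module size (the analysis is typically run
#'   at 10, 15 and 25).
#' @param cut_height dendrogram cut height on the 1 - TOM scale.
#' @param merge_cut_height eigentaxon dissimilarity below which modules merge.
#' @return object of class \code{"wcna"}: correlation, adjacency, TOM and
#'   dissimilarity matrices, the dendrogram, per-taxon module labels (and
#'   pre-merge labels), the beta used plus its selection table, the input
#'   data, and the configuration. Methods: \code{print}, \code{summary},
#'   \code{plot}.
#' @examples
#' ds <- simulate_dataset(sim_config(n_samples = 60, n_asvs = 80,
#'                                   n_modules = 2, taxa_per_module = 15,
#'                                   rare_fraction = 0, seed = 7))
#' fit <- wcna(clr_transform(ds$counts), beta = 3, min_module_size = 10)
#' print(fit)
#' @export
wcna <- function(x, beta = NULL, candidate_betas = 1:10, r2_target = 0.8,
                 network_sign = c("unsigned", "signed"), min_module_size = 25,
                 cut_height = 0.97, merge_cut_height = 0.25) {
  network_sign <- match.arg(network_sign)
  x <- .check_matrix(x)
  .assert(min_module_size >= 2, "min_module_size must be >= 2")
  R <- correlation_matrix(x)
  sft <- NULL
  if (is.null(beta)) {
    beta <- pick_soft_threshold(R, candidate_betas, r2_target, network_sign)
    sft <- attr(beta, "fits")
    beta <- as.integer(beta)
  }
  A <- soft_threshold_adjacency(R, beta, network_sign)
  TOM <- topological_overlap(A)
  D <- 1 - TOM
  pre <- detect_modules(D, min_module_size, cut_height)
  dendro <- attr(pre, "dendrogram")
  attr(pre, "dendrogram") <- NULL
  modules <- if (length(setdiff(unique(pre), "unassigned")) >= 1)
    merge_modules(pre, x, merge_cut_height) else pre
  structure(list(cor = R, adjacency = A, tom = TOM, dissimilarity = D,
                 dendrogram = dendro, modules = modules,
                 premerge_modules = pre, beta = beta, sft = sft, data = x,
                 config = list(beta = beta, network_sign = network_sign,
                               min_module_size = min_module_size,
                               cut_height = cut_height,
                               merge_cut_height = merge_cut_height,
                               candidate_betas = candidate_betas,
                               r2_target = r2_target)),
            class = "wcna")
}

#' @export
print.wcna <- function(x, ...) {
  mods <- setdiff(unique(x$modules), "unassigned")
  cat(sprintf("Weighted taxon co-occurrence network: %d taxa, %d samples\n",
              ncol(x$data), nrow(x$data)))
  cat(sprintf("Soft-threshold beta = %d (%s), min module size = %d\n",
              x$beta, x$config$network_sign, x$config$min_module_size))
  if (length(mods)) {
    sizes <- vapply(mods, function(m) sum(x$modules == m), 1L)
    cat(sprintf("%d module(s): %s; %d unassigned\n", length(mods),
                paste(sprintf("%s (%d)", mods, sizes), collapse = ", "),
                sum(x$modules == "unassigned")))
  } else cat("No modules detected\n")
  invisible(x)
}

#' @export
summary.wcna <- function(object, ...) {
  mods <- setdiff(unique(object$modules), "unassigned")
  within_tom <- vapply(mods, function(m) {
    idx <- which(object$modules == m)
    mean(object$tom[idx, idx][upper.tri(diag(length(idx)))])
  }, 1.0)
  out <- list(
    n_taxa = ncol(object$data), n_samples = nrow(object$data),
    beta = object$beta, sft = object$sft,
    modules = data.frame(
      module = mods,
      size = vapply(mods, function(m) sum(object$modules == m), 1L),
      mean_within_tom = within_tom, row.names = NULL),
    n_unassigned = sum(object$modules == "unassigned"))
  class(out) <- "summary.wcna"
  out
}

#' @export
print.summary.wcna <- function(x, ...) {
  cat(sprintf("wcna fit: %d taxa x %d samples, beta = %d\n",
              x$n_taxa, x$n_samples, x$beta))
  if (!is.null(x$sft)) {
    cat("Soft-threshold selection:\n")
    print(x$sft, row.names = FALSE)
  }
  if (nrow(x$modules)) print(x$modules, row.names = FALSE)
  cat(sprintf("Unassigned taxa: %d\n", x$n_unassigned))
  invisible(x)
}

#' Plot a fitted co-occurrence network dendrogram
#'
#' Dendrogram of the 1 - TOM clustering with a module color bar underneath.
#'
#' @param x a \code{wcna} fit.
#' @param ... passed to \code{plot.hclust}.
#' @export
plot.wcna <- function(x, ...) {
  op <- graphics::par(mar = c(1, 4, 3, 1), mfrow = c(2, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$dendrogram, labels = FALSE, hang = -1,
                 main = "Taxon clustering (1 - TOM)", xlab = "", sub = "", ...)
  ord <- x$dendrogram$order
  cols <- x$modules[ord]
  cols[cols == "unassigned"] <- "grey90"
  cols[!cols %in% grDevices::colors()] <- "grey40"
  graphics::par(mar = c(3, 4, 0, 1))
  graphics::plot(NULL, xlim = c(0.5, length(ord) + 0.5), ylim = c(0, 1),
                 axes = FALSE, xlab = "", ylab = "Module")
  graphics::rect(seq_along(ord) - 0.5, 0, seq_along(ord) + 0.5, 1,
                 col = cols, border = NA)
  invisible(x)
}
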