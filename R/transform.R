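#' Centered log-ratio transformation
#'
#' Per sample, \code{x -> ln(x + pc) - mean(ln(x + pc))} over all components
#' of the compositional closure. For a \code{\link{retain_resolve}} result the
#' closure is the final taxa plus the "Other taxa" remainder: the remainder
#' enters the geometric mean (that is its purpose) but is excluded from the
#' returned analysis matrix, whose per-sample CLR values plus the stored
#' remainder CLR sum to zero. For a plain matrix the closure is all columns.
#'
#' @param x a \code{retain_resolve} object or a samples x taxa count matrix.
#' @param pseudocount positive value added to every count before closure
#'   (default 0.5, the usual Dirichlet-prior convention for 16S zeros).
#' @return samples x taxa numeric matrix of CLR abundances with attributes
#'   \code{pseudocount}, \code{other_in_closure} and (when applicable)
#'   \code{other_clr} (the per-sample CLR of the remainder column).
#' @export
clr_transform <- function(x, pseudocount = 0.5) {
  .assert(pseudocount > 0, "pseudocount must be > 0")
  if (inherits(x, "retain_resolve")) {
    m <- x$counts
    other <- which(colnames(m) == "Other taxa")
  } else {
    m <- x
    other <- integer(0)
  }
  .assert(is.matrix(m) && all(m >= 0), "counts must be a non-negative matrix")
  .assert(all(rowSums(m) > 0), "zero-depth sample")
  lg <- log(m + pseudocount)
  clr <- lg - rowMeans(lg)
  if (length(other)) {
    other_clr <- clr[, other]
    clr <- clr[, -other, drop = FALSE]
    attr(clr, "other_clr") <- other_clr
    attr(clr, "other_in_closure") <- TRUE
  } else {
    attr(clr, "other_in_closure") <- FALSE
  }
  attr(clr, "pseudocount") <- pseudocount
  clr
}

#' Empirical-Bayes-moderated covariate correction
#'
#' Removes linear age/BMI (or other covariate) effects from each taxon's CLR
#' abundance. Per taxon, an ordinary least-squares fit on the standardized
#' covariates gives raw slopes; slopes are then shrunk toward the across-taxa
#' mean slope with weights from an empirical-Bayes variance ratio
#' (per-taxon sampling variance vs the prior variance of slopes estimated
#' across taxa), and residuals are formed from the shrunken fits, re-centered
#' on each taxon's mean. With \code{shrink = FALSE} this reproduces plain OLS
#' residualization exactly. Samples with missing covariate values are
#' mean-imputed for the design matrix only (with a warning) and flagged.
#'
#' @param clr samples x taxa CLR matrix (see \code{\link{clr_transform}}).
#' @param metadata data.frame with rownames = sample ids.
#' @param covariates covariate column names (default age and BMI).
#' @param shrink logical; apply empirical-Bayes slope shrinkage (default TRUE).
#' @return object of class \code{"eb_lm"}: residual matrix plus raw and
#'   shrunken slopes, shrinkage weights, and imputation flags. Use
#'   \code{residuals()} to extract the corrected matrix and \code{coef()} for
#'   the slopes.
#' @export
eb_correct <- function(clr, metadata, covariates = c("age", "bmi"),
                       shrink = TRUE) {
  clr <- .check_matrix(clr, "clr")
  .assert(all(covariates %in% names(metadata)),
          sprintf("covariate(s) missing from metadata: %s",
                  paste(setdiff(covariates, names(metadata)), collapse = ", ")))
  .assert(all(rownames(clr) %in% rownames(metadata)),
          "metadata missing for some samples")
  md <- metadata[rownames(clr), covariates, drop = FALSE]
  n <- nrow(clr)

  imputed <- lapply(md, function(v) which(is.na(v)))
  names(imputed) <- covariates
  Z <- matrix(0, n, length(covariates),
              dimnames = list(rownames(clr), covariates))
  for (j in seq_along(covariates)) {
    v <- md[[j]]
    if (anyNA(v)) {
      warning(sprintf("mean-imputing %d missing value(s) of '%s' for correction",
                      sum(is.na(v)), covariates[j]), call. = FALSE)
      v[is.na(v)] <- mean(v, na.rm = TRUE)
    }
    .assert(stats::sd(v) > 0, sprintf("constant covariate: %s", covariates[j]))
    Z[, j] <- (v - mean(v)) / stats::sd(v)
  }
  if (ncol(Z) > 1) {
    cz <- stats::cor(Z)
    .assert(max(abs(cz[upper.tri(cz)])) < 0.999,
            "covariates are collinear beyond tolerance")
  }

  # OLS on centered response: slopes B = (Z'Z)^-1 Z' Yc
  Yc <- sweep(clr, 2, colMeans(clr))
  ZtZ <- crossprod(Z)
  ZtZinv <- solve(ZtZ)
  B <- ZtZinv %*% crossprod(Z, Yc)                  # covariates x taxa
  fitted <- Z %*% B
  df_res <- n - ncol(Z) - 1
  .assert(df_res > 0, "too few samples for covariate correction")
  sigma2 <- colSums((Yc - fitted)^2) / df_res       # per-taxon residual var
  se2 <- outer(diag(ZtZinv), sigma2)                # covariates x taxa

  if (shrink) {
    prior_mean <- rowMeans(B)
    prior_var <- pmax(apply(B, 1, stats::var) - rowMeans(se2), 1e-12)
    w <- se2 / (se2 + prior_var)                    # shrinkage intensity
    Bs <- (1 - w) * B + w * prior_mean
  } else {
    w <- matrix(0, nrow(B), ncol(B))
    Bs <- B
  }
  resid <- clr - Z %*% Bs                           # keeps taxon means (Z centered)
  structure(list(residuals = resid, coef_raw = t(B), coef_shrunk = t(Bs),
                 shrink_weight = t(w), covariates = covariates,
                 design = Z, imputed = imputed, shrink = shrink),
            class = "eb_lm")
}

#' @export
residuals.eb_lm <- function(object, ...) object$residuals

#' @export
coef.eb_lm <- function(object, which = c("shrunk", "raw"), ...) {
  which <- match.arg(which)
  if (which == "shrunk") object$coef_shrunk else object$coef_raw
}

#' @export
print.eb_lm <- function(x, ...) {
  cat(sprintf("Empirical-Bayes covariate correction (%s): %d taxa, %d samples\n",
              if (x$shrink) "shrinkage on" else "plain OLS",
              ncol(x$residuals), nrow(x$residuals)))
  cat("Covariates:", paste(x$covariates, collapse = ", "), "\n")
  cat(sprintf("Mean shrinkage weight: %.3f\n", mean(x$shrink_weight)))
  invisible(x)
}
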