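#' Filtering criteria for retain-resolve agglomeration
#'
#' A taxon passes when prevalence > \code{prevalence_major} OR (mean relative
#' abundance > mra AND prevalence > \code{prevalence_minor}); inequalities are
#' strict, so boundary values fail. The MRA cut is 0.1% for ASVs and 0.01% for
#' resolved genera.
#'
#' @param prevalence_major major prevalence threshold (default 0.50).
#' @param prevalence_minor minor prevalence threshold (default 0.10).
#' @param mra_asv ASV mean-relative-abundance threshold (default 0.001).
#' @param mra_genus genus mean-relative-abundance threshold (default 0.0001).
#' @return list of class \code{"filter_criteria"}.
#' @export
filter_criteria <- function(prevalence_major = 0.50, prevalence_minor = 0.10,
                            mra_asv = 0.001, mra_genus = 0.0001) {
  for (v in c(prevalence_major, prevalence_minor, mra_asv, mra_genus))
    .assert(v > 0 && v < 1, "criteria must be in (0, 1)")
  .assert(prevalence_minor < prevalence_major,
          "prevalence_minor must be < prevalence_major")
  structure(list(prevalence_major = prevalence_major,
                 prevalence_minor = prevalence_minor,
                 mra_asv = mra_asv, mra_genus = mra_genus),
            class = "filter_criteria")
}

#' Taxon prevalence
#'
#' Fraction of samples in which a taxon has a nonzero count.
#'
#' @param counts samples x taxa matrix.
#' @param taxon optional taxon id(s); default all.
#' @return named numeric vector of proportions.
#' @export
prevalence <- function(counts, taxon = NULL) {
  .assert(nrow(counts) > 0, "empty count table")
  out <- colMeans(counts > 0)
  if (is.null(taxon)) return(out)
  .assert(all(taxon %in% names(out)),
          sprintf("unknown taxon: %s",
                  paste(setdiff(taxon, names(out)), collapse = ", ")))
  out[taxon]
}

#' Mean relative abundance
#'
#' Mean over samples of count / sample depth. \code{depth} defaults to the row
#' sums of \code{counts}; pass the original total depths when \code{counts} is
#' a partial table (e.g. genus-resolved residual counts).
#'
#' @param counts samples x taxa matrix.
#' @param taxon optional taxon id(s); default all.
#' @param depth per-sample total depths used as the denominator.
#' @return named numeric vector of proportions.
#' @export
mean_relative_abundance <- function(counts, taxon = NULL,
                                    depth = rowSums(counts)) {
  .assert(all(depth > 0), "zero-depth sample (run QC first)")
  out <- colMeans(counts / depth)
  if (is.null(taxon)) return(out)
  .assert(all(taxon %in% names(out)),
          sprintf("unknown taxon: %s",
                  paste(setdiff(taxon, names(out)), collapse = ", ")))
  out[taxon]
}

.pass_filter <- function(prev, mra, prev_major, prev_minor, mra_min) {
  prev > prev_major | (mra > mra_min & prev > prev_minor)
}

#' Select ASVs to retain at full resolution
#'
#' An ASV is retained iff prevalence > 50% OR (MRA > 0.1% AND prevalence >
#' 10%), with strict inequalities (defaults from \code{\link{filter_criteria}}).
#'
#' @param counts samples x ASVs matrix.
#' @param criteria a \code{\link{filter_criteria}} object.
#' @return character vector of retained ASV ids.
#' @export
retain_asvs <- function(counts, criteria = filter_criteria()) {
  prev <- prevalence(counts)
  mra <- mean_relative_abundance(counts)
  colnames(counts)[.pass_filter(prev, mra, criteria$prevalence_major,
                                criteria$prevalence_minor, criteria$mra_asv)]
}

#' Agglomerate non-retained ASVs to genus-level taxa
#'
#' Counts of ASVs not in \code{excluded} are summed within groups keyed by the
#' full lineage prefix down to genus (so homonymous genera in different
#' families stay distinct). ASVs lacking a genus annotation are grouped at the
#' deepest annotated rank with an "_NA" placeholder display name (e.g.
#' \code{Family012_NA}).
#'
#' @param counts samples x ASVs matrix.
#' @param taxonomy taxonomy data.frame (see \code{\link{read_taxonomy}}).
#' @param excluded retained ASV ids that must not contribute.
#' @return samples x genus-groups matrix; attributes \code{members} (list of
#'   member ASV ids per group) and \code{total_depth} (original sample depths).
#' @export
resolve_to_genus <- function(counts, taxonomy, excluded = character()) {
  rest <- setdiff(colnames(counts), excluded)
  missing <- setdiff(rest, taxonomy$taxon_id)
  if (length(missing))
    stop(sprintf("ASV(s) absent from taxonomy: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  total_depth <- rowSums(counts)
  tax <- taxonomy[match(rest, taxonomy$taxon_id), , drop = FALSE]
  key <- character(length(rest))
  disp <- character(length(rest))
  for (i in seq_along(rest)) {
    lin <- as.character(tax[i, .tax_ranks])
    known <- which(!is.na(lin) & nzchar(lin))
    deepest <- if (length(known)) max(known) else 0L
    if (deepest == length(.tax_ranks)) {        # genus annotated
      key[i] <- paste(lin[seq_len(deepest)], collapse = "|")
      disp[i] <- lin[deepest]
    } else {                                    # group at deepest rank, _NA
      key[i] <- paste(c(lin[seq_len(deepest)], "NA"), collapse = "|")
      disp[i] <- paste0(if (deepest) lin[deepest] else "Unknown", "_NA")
    }
  }
  groups <- lapply(split(rest, key), sort)  # representative is order-invariant
  keys <- sort(names(groups))
  out <- matrix(0L, nrow(counts), length(keys),
                dimnames = list(rownames(counts), NULL))
  members <- vector("list", length(keys))
  display <- character(length(keys))
  for (j in seq_along(keys)) {
    ids <- groups[[keys[j]]]
    out[, j] <- as.integer(rowSums(counts[, ids, drop = FALSE]))
    members[[j]] <- ids
    display[j] <- disp[match(ids[1], rest)]
  }
  display <- make.unique(display, sep = "#")
  colnames(out) <- display
  names(members) <- display
  attr(out, "members") <- members
  attr(out, "total_depth") <- total_depth
  out
}

#' Filter resolved genus-level taxa
#'
#' Same two-branch rule as \code{\link{retain_asvs}} but with the genus MRA
#' threshold (default 0.01%). MRA uses the original sample depths carried on
#' the resolved table.
#'
#' @param genus_counts output of \code{\link{resolve_to_genus}}.
#' @param criteria a \code{\link{filter_criteria}} object.
#' @param depth per-sample total depths (defaults to the attribute set by
#'   \code{resolve_to_genus}, else row sums).
#' @return character vector of kept genus-group names.
#' @export
filter_genera <- function(genus_counts, criteria = filter_criteria(),
                          depth = NULL) {
  depth <- depth %||% attr(genus_counts, "total_depth") %||% rowSums(genus_counts)
  prev <- prevalence(genus_counts)
  mra <- mean_relative_abundance(genus_counts, depth = depth)
  colnames(genus_counts)[.pass_filter(prev, mra, criteria$prevalence_major,
                                      criteria$prevalence_minor,
                                      criteria$mra_genus)]
}

#' Assemble the final retain-resolved table with an "Other taxa" remainder
#'
#' Final columns are the retained ASVs, the kept genus-level taxa, and one
#' "Other taxa" column holding, per sample, depth minus the final taxon
#' counts. The remainder preserves the compositional closure so the CLR
#' geometry is not distorted by filtering; integer depth conservation is
#' checked and a negative remainder is a hard failure.
#'
#' @param retained retained ASV ids.
#' @param kept_genera kept genus-group names.
#' @param original the original samples x ASVs count matrix.
#' @param genus_counts the resolved genus table (from
#'   \code{\link{resolve_to_genus}} on the same inputs).
#' @param taxonomy optional taxonomy used for display names of retained ASVs
#'   (\code{spN_Genus} / \code{spN_Family_NA} style).
#' @return object of class \code{"retain_resolve"}: list with \code{counts}
#'   (final matrix incl. the "Other taxa" column), \code{taxon_kind}
#'   (ASV/genus/other per final column), \code{provenance} (genus -> member
#'   ASVs), \code{naming} (final name -> source ids), \code{depth}.
#' @export
assemble_with_other <- function(retained, kept_genera, original, genus_counts,
                                taxonomy = NULL) {
  depth <- rowSums(original)
  ret_mat <- original[, retained, drop = FALSE]
  gen_mat <- genus_counts[, kept_genera, drop = FALSE]
  members <- attr(genus_counts, "members")[kept_genera]

  disp_ret <- retained
  if (!is.null(taxonomy) && length(retained)) {
    tax <- taxonomy[match(retained, taxonomy$taxon_id), , drop = FALSE]
    lab <- ifelse(!is.na(tax$Genus), tax$Genus,
                  ifelse(!is.na(tax$Family), paste0(tax$Family, "_NA"),
                         "Unknown_NA"))
    disp_ret <- paste(retained, lab, sep = "_")
  }
  disp_gen <- kept_genera
  if (length(kept_genera))
    disp_gen <- paste(vapply(members, `[`, "", 1), kept_genera, sep = "_")

  final <- cbind(ret_mat, gen_mat)
  colnames(final) <- c(disp_ret, disp_gen)
  other <- depth - rowSums(final)
  if (any(other < 0))
    stop("negative 'Other taxa' remainder: depth bookkeeping bug", call. = FALSE)
  final <- cbind(final, `Other taxa` = as.integer(other))
  storage.mode(final) <- "integer"

  naming <- data.frame(
    name = colnames(final),
    kind = c(rep("ASV", length(retained)), rep("genus", length(kept_genera)),
             "other"),
    source = c(retained, kept_genera, "remainder"),
    stringsAsFactors = FALSE)
  structure(list(counts = final,
                 taxon_kind = stats::setNames(naming$kind, naming$name),
                 provenance = stats::setNames(members, disp_gen),
                 naming = naming, depth = depth),
            class = "retain_resolve")
}

#' Retain-resolve agglomeration
#'
#' The two-tier dimension reduction for ASV tables: (1) retain common ASVs
#' (prevalence > 50% OR MRA > 0.1% AND prevalence > 10%); (2) agglomerate the
#' remaining ASVs to genus-level taxa and filter those (prevalence > 50% OR
#' MRA > 0.01% AND prevalence > 10%); (3) carry an "Other taxa" per-sample
#' remainder so columns still partition each sample's depth exactly. The
#' result is a mixed ASV-level / genus-level taxon set.
#'
#' @param counts samples x ASVs integer matrix (post-QC).
#' @param taxonomy taxonomy data.frame.
#' @param criteria a \code{\link{filter_criteria}} object.
#' @return A \code{"retain_resolve"} object (see
#'   \code{\link{assemble_with_other}}) with an additional \code{report}
#'   data.frame of per-taxon prevalence, MRA, decision and branch.
#' @export
retain_resolve <- function(counts, taxonomy, criteria = filter_criteria()) {
  retained <- retain_asvs(counts, criteria)
  genus_counts <- resolve_to_genus(counts, taxonomy, excluded = retained)
  kept <- filter_genera(genus_counts, criteria)
  res <- assemble_with_other(retained, kept, counts, genus_counts, taxonomy)

  prev_a <- prevalence(counts); mra_a <- mean_relative_abundance(counts)
  branch_a <- ifelse(prev_a > criteria$prevalence_major, "prevalence",
                     ifelse(mra_a > criteria$mra_asv &
                              prev_a > criteria$prevalence_minor,
                            "mra+prevalence", "failed"))
  rep_a <- data.frame(taxon = colnames(counts), level = "ASV",
                      prevalence = prev_a, mra = mra_a,
                      decision = colnames(counts) %in% retained,
                      branch = branch_a, stringsAsFactors = FALSE)
  res$report <- rep_a
  if (ncol(genus_counts) > 0) {
    prev_g <- prevalence(genus_counts)
    mra_g <- mean_relative_abundance(genus_counts,
                                     depth = attr(genus_counts, "total_depth"))
    branch_g <- ifelse(prev_g > criteria$prevalence_major, "prevalence",
                       ifelse(mra_g > criteria$mra_genus &
                                prev_g > criteria$prevalence_minor,
                              "mra+prevalence", "failed"))
    rep_g <- data.frame(taxon = colnames(genus_counts), level = "genus",
                        prevalence = prev_g, mra = mra_g,
                        decision = colnames(genus_counts) %in% kept,
                        branch = branch_g, stringsAsFactors = FALSE)
    res$report <- rbind(rep_a, rep_g)
  }
  rownames(res$report) <- NULL
  res$criteria <- criteria
  res
}

#' @export
print.retain_resolve <- function(x, ...) {
  cat(sprintf("Retain-resolved taxon set: %d ASV + %d genus-level taxa (+ Other) over %d samples\n",
              sum(x$taxon_kind == "ASV"), sum(x$taxon_kind == "genus"),
              nrow(x$counts)))
  cat(sprintf("Mean 'Other taxa' share of depth: %.2f%%\n",
              100 * mean(x$counts[, "Other taxa"] / x$depth)))
  invisible(x)
}
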