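#' Read a sample-by-taxon count table
#'
#' Tab-separated matrix of non-negative integer read counts. Orientation is
#' auto-detected from the header sentinel: a first column named
#' \code{sample_id} means samples are rows; \code{taxon_id} means taxa are
#' rows (the matrix is transposed to samples x taxa).
#'
#' @param path file path.
#' @return integer matrix, samples x taxa, with dimnames.
#' @export
read_count_table <- function(path) {
  .assert(file.exists(path), sprintf("file not found: %s", path))
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  sentinel <- names(df)[1]
  .assert(sentinel %in% c("sample_id", "taxon_id"),
          "first column must be 'sample_id' or 'taxon_id' (orientation sentinel)")
  ids <- as.character(df[[1]])
  .assert(all(nzchar(ids)), "empty row labels in count table")
  if (anyDuplicated(ids))
    stop(sprintf("duplicated %s label(s): %s", sentinel,
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  cols <- names(df)[-1]
  if (anyDuplicated(cols))
    stop(sprintf("duplicated column label(s): %s",
                 paste(unique(cols[duplicated(cols)]), collapse = ", ")),
         call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m) || any(is.na(m)) || any(m < 0) || any(m != round(m)))
    stop("counts must be non-negative integers", call. = FALSE)
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  if (sentinel == "taxon_id") m <- t(m)
  m
}

#' Write a count table as TSV (samples in rows)
#' @param counts samples x taxa integer matrix with dimnames.
#' @param path output file.
#' @return Invisibly, \code{path}.
#' @export
write_count_table <- function(counts, path) {
  df <- data.frame(sample_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.tax_ranks <- c("Kingdom", "Phylum", "Class", "Order", "Family", "Genus")

#' Read / write a taxonomy lineage table
#'
#' TSV with columns taxon_id, Kingdom, Phylum, Class, Order, Family, Genus.
#' Empty fields become NA (unannotated ranks).
#'
#' @param path file path.
#' @return data.frame with taxon_id plus the six rank columns.
#' @export
read_taxonomy <- function(path) {
  .assert(file.exists(path), sprintf("file not found: %s", path))
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  .assert(identical(names(df), c("taxon_id", .tax_ranks)),
          "taxonomy must have columns taxon_id, Kingdom..Genus in order")
  if (anyDuplicated(df$taxon_id))
    stop("duplicated taxon_id in taxonomy", call. = FALSE)
  df
}

#' @rdname read_taxonomy
#' @param taxonomy data.frame as returned by \code{read_taxonomy}.
#' @export
write_taxonomy <- function(taxonomy, path) {
  utils::write.table(taxonomy, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

.meta_ranges <- list(age = c(0, 120), bmi = c(5, 100), gad7 = c(0, 21),
                     phq9 = c(0, 27), dars = c(0, 68))

#' Read / write per-sample clinical metadata
#'
#' CSV with columns sample_id, age, bmi, gad7, phq9, dars. Scores are
#' validated against their instrument ranges (GAD-7 0-21, PHQ-9 0-27, DARS
#' 0-68) when present; age and DARS may be missing.
#'
#' @param path file path.
#' @param columns optional named character vector remapping file column names
#'   onto the canonical ones, e.g. \code{c(gad7 = "GAD7_total")}.
#' @return data.frame with rownames = sample_id.
#' @export
read_metadata <- function(path, columns = NULL) {
  .assert(file.exists(path), sprintf("file not found: %s", path))
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(columns))
    for (canon in names(columns)) {
      .assert(columns[[canon]] %in% names(df),
              sprintf("mapped column '%s' not in file", columns[[canon]]))
      names(df)[names(df) == columns[[canon]]] <- canon
    }
  .assert("sample_id" %in% names(df), "metadata needs a sample_id column")
  if (anyDuplicated(df$sample_id))
    stop("duplicated sample_id in metadata", call. = FALSE)
  out <- data.frame(row.names = df$sample_id)
  for (v in names(.meta_ranges)) {
    vals <- if (v %in% names(df)) df[[v]] else NA_real_
    rng <- .meta_ranges[[v]]
    bad <- !is.na(vals) & (vals < rng[1] | vals > rng[2])
    if (any(bad))
      stop(sprintf("metadata validation error: %s=%s outside range [%g, %g]",
                   v, paste(vals[bad], collapse = ","), rng[1], rng[2]),
           call. = FALSE)
    out[[v]] <- vals
  }
  out
}

#' @rdname read_metadata
#' @param metadata data.frame with rownames = sample_id.
#' @export
write_metadata <- function(metadata, path) {
  df <- data.frame(sample_id = rownames(metadata), metadata,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Reconcile the sample sets of a count table and metadata
#'
#' Takes the intersection of sample ids (preserving count-table order) and
#' reports mismatches with a message.
#'
#' @param counts samples x taxa matrix.
#' @param metadata data.frame with rownames = sample_id.
#' @return list(counts, metadata) restricted to the common samples.
#' @export
reconcile_samples <- function(counts, metadata) {
  common <- intersect(rownames(counts), rownames(metadata))
  .assert(length(common) > 0, "no samples shared between counts and metadata")
  only_c <- setdiff(rownames(counts), common)
  only_m <- setdiff(rownames(metadata), common)
  if (length(only_c) || length(only_m))
    message(sprintf("reconcile_samples: dropped %d count-only and %d metadata-only sample(s)",
                    length(only_c), length(only_m)))
  list(counts = counts[common, , drop = FALSE],
       metadata = metadata[common, , drop = FALSE])
}

#' Shannon diversity index (natural log)
#'
#' H = -sum p_i ln p_i over taxa with nonzero counts; the alpha-diversity
#' statistic used for sample quality control.
#'
#' @param x non-negative count vector, or a samples x taxa matrix (per-row H).
#' @param base logarithm base (default e, i.e. nats).
#' @return numeric scalar or per-sample vector.
#' @export
shannon_index <- function(x, base = exp(1)) {
  if (is.matrix(x)) {
    .assert(all(rowSums(x) > 0), "all-zero sample row(s)")
    return(as.numeric(vegan::diversity(x, index = "shannon", base = base)))
  }
  .assert(all(x >= 0), "counts must be non-negative")
  .assert(sum(x) > 0, "all-zero count vector")
  as.numeric(vegan::diversity(rbind(x), index = "shannon", base = base))
}

#' Quality-control filter on sequencing depth and alpha diversity
#'
#' Flags samples with low depth or low Shannon index and removes those meeting
#' the removal rule: with \code{rule = "and"} (default), a sample is removed
#' only when it concurrently fails both thresholds; with \code{"or"}, failing
#' either suffices. Defaults (10,000 reads, H = 2.5) are configurable
#' conventions, chosen so that a degenerate stool sample with ~5,000 reads and
#' H = 2.0 is excluded.
#'
#' @param counts samples x taxa integer matrix.
#' @param depth_min minimum acceptable depth (reads).
#' @param shannon_min minimum acceptable Shannon index (nats).
#' @param rule \code{"and"} (concurrent failure) or \code{"or"}.
#' @return list with \code{table} (filtered matrix) and \code{report}
#'   (class \code{"qc_report"}: per-sample depth, Shannon, flags, removed).
#' @export
qc_filter_samples <- function(counts, depth_min = 10000, shannon_min = 2.5,
                              rule = c("and", "or")) {
  rule <- match.arg(rule)
  .assert(depth_min > 0 && shannon_min > 0, "QC thresholds must be positive")
  depth <- rowSums(counts)
  .assert(all(depth > 0), "sample(s) with zero depth")
  shannon <- shannon_index(counts)
  low_depth <- depth < depth_min
  low_alpha <- shannon < shannon_min
  removed <- if (rule == "and") low_depth & low_alpha else low_depth | low_alpha
  if (all(removed))
    stop("QC would remove every sample (degenerate dataset)", call. = FALSE)
  report <- data.frame(sample_id = rownames(counts), depth = depth,
                       shannon = shannon, low_depth = low_depth,
                       low_alpha_diversity = low_alpha, removed = removed,
                       row.names = NULL, stringsAsFactors = FALSE)
  attr(report, "thresholds") <- list(depth_min = depth_min,
                                     shannon_min = shannon_min, rule = rule)
  class(report) <- c("qc_report", "data.frame")
  list(table = counts[!removed, , drop = FALSE], report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  th <- attr(x, "thresholds")
  cat(sprintf("QC report: %d sample(s); removed %d (rule '%s', depth < %g, Shannon < %g)\n",
              nrow(x), sum(x$removed), th$rule, th$depth_min, th$shannon_min))
  if (any(x$removed)) print.data.frame(x[x$removed, ], row.names = FALSE)
  invisible(x)
}
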