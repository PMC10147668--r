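test_that("prevalence and MRA match brute-force per-column computations", {
  m <- toy_counts(present = c(3, 0, 10), count = c(5, 0, 20))
  expect_equal(unname(prevalence(m, "t01")), 0.3)  # 3 of 10 samples
  expect_equal(unname(prevalence(m, "t02")), 0)
  expect_error(prevalence(m, "nope"), "unknown taxon")

  # a constant relative abundance taxon: count 200 of depth 10000 everywhere
  m2 <- toy_counts(present = c(10), count = c(200))
  expect_equal(unname(mean_relative_abundance(m2, "t01")), 0.02)
  expect_equal(unname(mean_relative_abundance(m2, "filler")), 0.98)

  ds <- simulate_dataset(sim_config(n_samples = 178, n_asvs = 50,
                                    n_modules = 0, taxa_per_module = 1,
                                    seed = 13))
  prev <- prevalence(ds$counts)
  mra <- mean_relative_abundance(ds$counts)
  depth <- rowSums(ds$counts)
  for (j in sample(ncol(ds$counts), 10)) {
    expect_equal(unname(prev[j]), sum(ds$counts[, j] > 0) / nrow(ds$counts))
    expect_equal(unname(mra[j]), mean(ds$counts[, j] / depth))
  }
  expect_error(mean_relative_abundance(rbind(c(0L, 0L))), "zero-depth")
})

test_that("ASV retention follows the two-branch rule with strict inequalities", {
  # taxa engineered to hit each branch of: prev > 0.5 OR (mra > 0.001 & prev > 0.1)
  m <- toy_counts(
    present = c(6, 3, 1, 5, 2, 1),
    count   = c(2,  70, 600, 1, 200, 5))
  # t01: prev .6 > .5 (branch 1, tiny mra)          -> retained
  # t02: prev .3, mra 21/1e5 = 2.1e-3 > 1e-3        -> retained (branch 2)
  # t03: prev .1, mra 6e-3 (fails prev > .1 strict) -> dropped
  # t04: prev .5 (not > .5), mra 5e-7               -> dropped (boundary)
  # t05: prev .2, mra 4e-3                          -> retained
  # t06: prev .1, mra 5e-5                          -> dropped
  kept <- retain_asvs(m, filter_criteria())
  expect_setequal(setdiff(kept, "filler"), c("t01", "t02", "t05"))

  # enumerated truth table replicated independently
  prev <- prevalence(m); mra <- mean_relative_abundance(m)
  manual <- names(prev)[prev > 0.5 | (mra > 0.001 & prev > 0.1)]
  expect_setequal(kept, manual)
})

test_that("genus resolution groups by lineage and handles missing genus", {
  counts <- matrix(c(1L, 2L, 3L, 10L,  4L, 7L,
                     2L, 1L, 0L,  5L, 11L, 3L), 2, 6, byrow = TRUE,
                   dimnames = list(c("S1", "S2"), paste0("sp", 1:6)))
  tax <- data.frame(
    taxon_id = paste0("sp", 1:6),
    Kingdom = "Bacteria", Phylum = "P", Class = "C", Order = "O",
    Family = c("F1", "F1", "F1", "F2", "F2", "F2"),
    Genus = c("G1", "G1", "G1", "G2", NA, NA),
    stringsAsFactors = FALSE)
  g <- resolve_to_genus(counts, tax, excluded = character())
  # sp1-3 share genus G1: counts (1,2,3) -> 6 in S1
  expect_equal(unname(g[, "G1"]), c(6L, 3L))
  expect_equal(unname(g[, "G2"]), c(10L, 5L))
  # sp5, sp6 lack genus -> grouped at family as F2_NA
  expect_true("F2_NA" %in% colnames(g))
  expect_equal(unname(g[, "F2_NA"]), c(11L, 14L))
  # retained ASVs never contribute
  g2 <- resolve_to_genus(counts, tax, excluded = c("sp1", "sp2"))
  expect_equal(unname(g2[, "G1"]), c(3L, 0L))
  expect_error(resolve_to_genus(counts, tax[-3, ], character()), "sp3")
})

test_that("homonymous genera in different families stay distinct", {
  counts <- matrix(1L, 2, 2, dimnames = list(c("S1", "S2"), c("a", "b")))
  tax <- data.frame(taxon_id = c("a", "b"), Kingdom = "K", Phylum = "P",
                    Class = "C", Order = "O", Family = c("F1", "F2"),
                    Genus = c("G", "G"), stringsAsFactors = FALSE)
  g <- resolve_to_genus(counts, tax)
  expect_identical(ncol(g), 2L)
})

test_that("genus filtering applies the genus MRA threshold with strict boundaries", {
  # 10 samples, depth 10000; genus counts built directly
  m <- toy_counts(present = c(2, 2, 5), count = c(10, 2, 1))
  attr(m, "total_depth") <- rowSums(m)
  # t01: prev .2, mra 2e-4 > 1e-4  -> kept
  # t02: prev .2, mra 4e-5         -> dropped
  # t03: prev .5 (not > .5), mra 5e-5 -> dropped (strict boundary)
  kept <- filter_genera(m, filter_criteria())
  expect_setequal(setdiff(kept, "filler"), "t01")
})

test_that("the assembled table partitions every sample's depth exactly", {
  ds <- simulate_dataset(sim_config(n_samples = 40, n_asvs = 150,
                                    n_modules = 2, taxa_per_module = 10,
                                    seed = 17))
  rr <- retain_resolve(ds$counts, ds$taxonomy)
  expect_identical(unname(rowSums(rr$counts)), unname(rowSums(ds$counts)))
  expect_true(all(rr$counts[, "Other taxa"] >= 0))
  # no ASV appears both retained and inside a genus group
  retained <- rr$naming$source[rr$naming$kind == "ASV"]
  grouped <- unlist(rr$provenance, use.names = FALSE)
  expect_length(intersect(retained, grouped), 0)
  # column count equals independently recomputed retained + kept + 1
  kept_asv <- retain_asvs(ds$counts)
  g <- resolve_to_genus(ds$counts, ds$taxonomy, kept_asv)
  kept_gen <- filter_genera(g)
  expect_identical(ncol(rr$counts),
                   length(kept_asv) + length(kept_gen) + 1L)
})

test_that("all-retained input leaves an all-zero remainder", {
  counts <- matrix(c(50L, 43L, 60L, 47L), 2, 2,
                   dimnames = list(c("S1", "S2"), c("sp1", "sp2")))
  tax <- data.frame(taxon_id = c("sp1", "sp2"), Kingdom = "K", Phylum = "P",
                    Class = "C", Order = "O", Family = "F", Genus = c("G1", "G2"),
                    stringsAsFactors = FALSE)
  rr <- retain_resolve(counts, tax)
  expect_true(all(rr$counts[, "Other taxa"] == 0))
  # depth 100 with final taxa summing to 93 leaves 7
  g <- resolve_to_genus(counts, tax, excluded = c("sp1", "sp2"))
  m2 <- rbind(S1 = c(93L, 7L), S2 = c(93L, 14L))
  colnames(m2) <- c("spA", "spB")
  taxB <- data.frame(taxon_id = c("spA", "spB"), Kingdom = "K", Phylum = "P",
                     Class = "C", Order = "O", Family = "F", Genus = c("GA", "GB"),
                     stringsAsFactors = FALSE)
  gB <- resolve_to_genus(m2, taxB, excluded = "spA")
  res <- assemble_with_other("spA", character(0), m2, gB, taxB)
  expect_equal(unname(res$counts[, "Other taxa"]), c(7L, 14L))
})

test_that("loosening thresholds never shrinks the retained set", {
  ds <- simulate_dataset(sim_config(n_samples = 60, n_asvs = 120,
                                    n_modules = 1, taxa_per_module = 10,
                                    seed = 30))
  strict <- retain_asvs(ds$counts, filter_criteria())
  loose <- retain_asvs(ds$counts,
                       filter_criteria(prevalence_major = 0.4,
                                       prevalence_minor = 0.05,
                                       mra_asv = 5e-4))
  expect_true(all(strict %in% loose))
})

test_that("taxon order does not affect the retain-resolve result", {
  ds <- simulate_dataset(sim_config(n_samples = 30, n_asvs = 80, n_modules = 1,
                                    taxa_per_module = 8, seed = 21))
  perm <- sample(ncol(ds$counts))
  rr1 <- retain_resolve(ds$counts, ds$taxonomy)
  rr2 <- retain_resolve(ds$counts[, perm], ds$taxonomy)
  expect_setequal(colnames(rr1$counts), colnames(rr2$counts))
  expect_identical(rr1$counts[, sort(colnames(rr1$counts))],
                   rr2$counts[, sort(colnames(rr1$counts))])
})
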