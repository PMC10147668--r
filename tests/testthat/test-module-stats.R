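test_that("eigentaxa summarize modules with unit variance and positive orientation", {
  set.seed(10)
  n <- 60
  f <- rnorm(n)
  # module of near-identical profiles
  x <- cbind(f, f, f) + matrix(rnorm(n * 3, 0, 1e-6), n, 3)
  colnames(x) <- c("a", "b", "c")
  lab <- setNames(rep("m1", 3), colnames(x))
  E <- module_eigentaxa(x, lab)
  expect_equal(sd(E[, "m1"]), 1, tolerance = 1e-12)
  expect_equal(unname(cor(E[, "m1"], x[, "a"])), 1, tolerance = 1e-6)
  expect_gte(attr(E, "var_explained")[["m1"]], 0.999)

  # two perfectly anti-correlated taxa: |cor| = 1 with opposite signs
  y <- cbind(p = f, q = -f + rnorm(n, 0, 1e-8))
  Ey <- module_eigentaxa(y, setNames(rep("m", 2), colnames(y)))
  cors <- cor(Ey[, 1], y)
  expect_equal(abs(unname(cors[1, ])), c(1, 1), tolerance = 1e-6)
  expect_lt(prod(cors), 0)

  expect_error(module_eigentaxa(y, setNames(c("m", "unassigned"), colnames(y))),
               "fewer than 2")
})

test_that("eigentaxa equal the dense-SVD first component up to sign", {
  set.seed(11)
  x <- matrix(rnorm(50 * 8), 50, 8, dimnames = list(NULL, paste0("t", 1:8)))
  x[, 1:4] <- x[, 1:4] + rnorm(50)        # give the block real structure
  lab <- setNames(rep("mod", 8), colnames(x))
  E <- module_eigentaxa(x, lab)
  # oracle: first eigenvector of the standardized covariance, scored and scaled
  Xs <- scale(x)
  ev <- eigen(cov(Xs), symmetric = TRUE)
  score <- Xs %*% ev$vectors[, 1]
  score <- score / sd(score)
  if (mean(cor(score, Xs)) < 0) score <- -score
  expect_equal(unname(E[, 1]), unname(score[, 1]), tolerance = 1e-8)
  expect_equal(attr(E, "var_explained")[["mod"]],
               ev$values[1] / sum(ev$values), tolerance = 1e-10)
})

test_that("module membership separates own-module from foreign taxa", {
  fx <- planted_fixture()
  E <- module_eigentaxa(fx$x, fx$fit$modules)
  MM <- module_membership(fx$x, E)
  expect_true(all(MM >= -1 & MM <= 1))
  assigned <- names(fx$fit$modules)[fx$fit$modules != "unassigned"]
  own <- abs(MM[cbind(assigned, fx$fit$modules[assigned])])
  foreign <- vapply(assigned, function(t) {
    others <- setdiff(colnames(MM), fx$fit$modules[[t]])
    max(abs(MM[t, others]))
  }, 1.0)
  expect_gte(mean(own > foreign), 0.95)
})

test_that("membership of an independent taxon is near zero at large n", {
  set.seed(12)
  n <- 500
  f <- rnorm(n)
  x <- cbind(sapply(1:6, function(i) f + rnorm(n, 0, 0.5)), rnorm(n))
  colnames(x) <- c(paste0("m", 1:6), "lone")
  lab <- setNames(c(rep("mod", 6), "unassigned"), colnames(x))
  MM <- module_membership(x, module_eigentaxa(x, lab))
  expect_lt(abs(MM["lone", "mod"]), 0.15)
  expect_gt(min(MM[paste0("m", 1:6), "mod"]), 0.8)
})

test_that("taxa significance reproduces the Student-t transform exactly", {
  # construct a taxon with exact r = 0.5 against the trait (n = 11)
  n <- 11
  z <- scale(seq_len(n))[, 1]
  w <- scale(resid(lm(rnorm(n) ~ z)))[, 1]
  w <- w / sqrt(sum(w^2) / (n - 1))
  y <- 0.5 * z + sqrt(0.75) * w
  x <- cbind(taxon1 = y, taxon2 = z)
  ts <- taxa_significance(x, z)
  expect_equal(ts$r[1], 0.5, tolerance = 1e-12)
  t_expected <- 0.5 * sqrt((n - 2) / (1 - 0.25))
  expect_equal(ts$p[1], 2 * pt(-t_expected, n - 2), tolerance = 1e-12)
  expect_equal(ts$p[1], 0.1173, tolerance = 1e-3)
  # taxon identical to the trait
  expect_equal(ts$r[2], 1)
  expect_lt(ts$p[2], 1e-12)
  expect_identical(ts$abs_r, abs(ts$r))
  expect_true(all(ts$p_bh >= ts$p))
  expect_error(taxa_significance(x, rep(1, n)), "constant")
})

test_that("module-trait correlations recover construction and respect missingness", {
  set.seed(13)
  n <- 200
  E <- cbind(m1 = rnorm(n), m2 = rnorm(n))
  E <- scale(E)
  traits <- data.frame(linked = E[, "m1"] + rnorm(n, 0, 0.2),
                       shuffled = sample(E[, "m1"]))
  traits$sparse <- c(E[1:2, "m2"], rep(NA, n - 2))
  mt <- module_trait_correlation(E, traits)
  expect_gt(mt$r["m1", "linked"], 0.9)
  expect_lt(abs(mt$r["m1", "shuffled"]), 0.15)
  expect_true(is.na(mt$r["m1", "sparse"]))   # fewer than 3 pairs
  expect_identical(mt$n["m1", "sparse"], 2)
  expect_identical(mt$n["m1", "linked"], as.numeric(n))
  expect_output(print(mt), "linked")
})

test_that("hub designation follows the within-module 95th percentile", {
  # 20 distinct memberships: only the maximum clears the percentile
  mm <- matrix(seq(0.05, 1, length.out = 20), ncol = 1,
               dimnames = list(paste0("t", 1:20), "mod"))
  lab <- setNames(rep("mod", 20), rownames(mm))
  hubs <- hub_taxa(mm, lab)
  expect_identical(names(which(hubs)), "t20")
  # exactly the quantile-threshold count by enumeration
  thr <- quantile(mm[, 1], 0.95, type = 7)
  expect_identical(sum(hubs), sum(mm[, 1] >= thr))

  # two-taxon module: the higher membership taxon is the hub
  mm2 <- matrix(c(0.9, 0.4), ncol = 1,
                dimnames = list(c("hi", "lo"), "mod"))
  h2 <- hub_taxa(mm2, setNames(rep("mod", 2), c("hi", "lo")))
  expect_identical(names(which(h2)), "hi")

  # ties at the threshold are all hubs
  mm3 <- matrix(rep(0.7, 5), ncol = 1,
                dimnames = list(paste0("t", 1:5), "mod"))
  h3 <- hub_taxa(mm3, setNames(rep("mod", 5), rownames(mm3)))
  expect_true(all(h3))

  # hub set shrinks (or stays) as the percentile rises
  fx <- planted_fixture()
  MM <- module_membership(fx$x, module_eigentaxa(fx$x, fx$fit$modules))
  h90 <- hub_taxa(MM, fx$fit$modules, percentile = 0.90)
  h99 <- hub_taxa(MM, fx$fit$modules, percentile = 0.99)
  expect_true(all(names(which(h99)) %in% names(which(h90))))
  # every module has at least one hub
  for (m in setdiff(unique(fx$fit$modules), "unassigned"))
    expect_gte(sum(h90[fx$fit$modules == m]), 1)
})

test_that("BH adjustment matches the step-up computation and its properties", {
  bh_oracle <- function(p) {
    n <- length(p)
    o <- order(p, decreasing = TRUE)
    ro <- order(o)
    pmin(1, cummin(n / (n:1) * p[o]))[ro]
  }
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  set.seed(14)
  for (i in 1:50) {
    p <- runif(sample(3:200, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_oracle(p), tolerance = 1e-14)
    perm <- sample(length(p))
    expect_equal(bh_adjust(p[perm]), adj[perm])       # order-invariant
  }
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})
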