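test_that("correlation matrix matches a brute-force oracle and guards inputs", {
  set.seed(4)
  x <- matrix(rnorm(200), 20, 10,
              dimnames = list(NULL, paste0("t", 1:10)))
  R <- correlation_matrix(x)
  expect_equal(unname(diag(R)), rep(1, 10))
  for (i in 1:9) for (j in (i + 1):10) {
    xi <- x[, i] - mean(x[, i]); xj <- x[, j] - mean(x[, j])
    expect_equal(R[i, j], sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2)),
                 tolerance = 1e-12)
  }
  y <- cbind(a = x[, 1], b = -scale(x[, 1])[, 1])
  expect_equal(correlation_matrix(cbind(y, c = x[, 2]))["a", "b"], -1)
  xc <- x; xc[, 3] <- 7
  expect_error(correlation_matrix(xc), "t3")
  expect_error(correlation_matrix(x[1:2, ]), "3 samples")
})

test_that("soft-threshold adjacency has its closed forms", {
  R <- matrix(c(1, -0.5, -0.5, 1), 2, 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(soft_threshold_adjacency(R, 3)["a", "b"], 0.125)
  R0 <- matrix(c(1, 0, 0, 1), 2, 2)
  expect_equal(soft_threshold_adjacency(R0, 3, "signed")[1, 2], 0.125)
  R1 <- matrix(c(1, -1, -1, 1), 2, 2)
  expect_equal(soft_threshold_adjacency(R1, 3)[1, 2], 1)
})

test_that("raising beta weakens every off-diagonal adjacency", {
  set.seed(5)
  x <- matrix(rnorm(300), 30, 10, dimnames = list(NULL, paste0("t", 1:10)))
  R <- correlation_matrix(x)
  A2 <- soft_threshold_adjacency(R, 2)
  A5 <- soft_threshold_adjacency(R, 5)
  expect_true(all(A5 <= A2 + 1e-15))
})

test_that("scale-free fit scores an exact power law near 1 and noise lower", {
  # frequencies proportional to 1/k: log p(k) = -log k + c exactly
  k <- rep(1:10, times = round(2000 / (1:10)))
  f_pl <- scale_free_fit(k = k)
  expect_gte(f_pl$r2, 0.95)
  expect_lt(f_pl$slope, 0)

  set.seed(6)
  x <- matrix(rnorm(40 * 60), 40, 60, dimnames = list(NULL, paste0("t", 1:60)))
  A <- soft_threshold_adjacency(correlation_matrix(x), 1)
  f_noise <- scale_free_fit(A)
  expect_lt(f_noise$r2, f_pl$r2)

  expect_error(scale_free_fit(k = rep(3, 10)), "degenerate")
})

test_that("soft-threshold selection follows the documented rule", {
  fx <- planted_fixture()
  R <- fx$fit$cor
  beta <- pick_soft_threshold(R, 1:6, r2_target = 0.8)
  fits <- attr(beta, "fits")
  # the selection rule applied independently to the per-candidate table
  ok <- which(!is.na(fits$r2) & fits$r2 >= 0.8 & fits$slope < 0)
  expected <- if (length(ok)) fits$beta[min(ok)] else fits$beta[which.max(fits$r2)]
  expect_identical(as.integer(beta), as.integer(expected))

  # vacuous target: smallest candidate with negative slope
  b0 <- pick_soft_threshold(R, 1:6, r2_target = 0)
  fits0 <- attr(b0, "fits")
  expect_identical(as.integer(b0),
                   as.integer(fits0$beta[which(fits0$slope < 0)[1]]))

  # single candidate comes back regardless of fit
  expect_identical(as.integer(suppressMessages(
    pick_soft_threshold(R, 3, r2_target = 0.999999))), 3L)
})

test_that("topological overlap matches hand values and the cubic oracle", {
  # two taxa joined by a unit edge and nothing else
  A <- matrix(c(1, 1, 1, 1), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(topological_overlap(A)["a", "b"], 1)
  # disconnected pair with no shared neighbours
  A0 <- diag(2); dimnames(A0) <- list(c("a", "b"), c("a", "b"))
  expect_equal(topological_overlap(A0)["a", "b"], 0)

  tom_oracle <- function(A) {
    n <- nrow(A)
    k <- rowSums(A) - diag(A)
    T <- diag(n)
    for (i in seq_len(n)) for (j in seq_len(n)) if (i != j) {
      l <- 0
      for (u in seq_len(n)) if (u != i && u != j) l <- l + A[i, u] * A[u, j]
      T[i, j] <- (l + A[i, j]) / (min(k[i], k[j]) + 1 - A[i, j])
    }
    dimnames(T) <- dimnames(A)
    T
  }
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(5:30, 1)
    W <- matrix(runif(n * n), n, n)
    A <- (W + t(W)) / 2
    diag(A) <- 1
    dimnames(A) <- list(paste0("t", 1:n), paste0("t", 1:n))
    expect_equal(topological_overlap(A), tom_oracle(A), tolerance = 1e-12)
  }
})

test_that("adjacency and TOM commute with taxon permutations", {
  fx <- planted_fixture()
  x <- fx$x[, 1:40]
  perm <- sample(40)
  A1 <- soft_threshold_adjacency(correlation_matrix(x), 3)
  A2 <- soft_threshold_adjacency(correlation_matrix(x[, perm]), 3)
  expect_equal(A2, A1[perm, perm], tolerance = 1e-14)
  expect_equal(topological_overlap(A2), topological_overlap(A1)[perm, perm],
               tolerance = 1e-12)
})

test_that("planted blocks are recovered block-pure and deterministically", {
  # three orthogonal latent factors, 25 taxa each, low noise
  set.seed(8)
  n <- 120
  f <- matrix(rnorm(n * 3), n, 3)
  x <- cbind(f[, rep(1, 25)], f[, rep(2, 25)], f[, rep(3, 25)]) +
    matrix(rnorm(n * 75, 0, 0.6), n, 75)
  colnames(x) <- paste0("t", 1:75)
  A <- soft_threshold_adjacency(correlation_matrix(x), 3)
  D <- 1 - topological_overlap(A)
  lab <- detect_modules(D, min_module_size = 25)
  truth <- rep(c("m1", "m2", "m3"), each = 25)
  expect_length(setdiff(unique(lab), "unassigned"), 3)
  expect_gte(rand_index_adj(lab, truth), 0.999)
  # determinism
  lab2 <- detect_modules(D, min_module_size = 25)
  expect_identical(unname(lab), unname(lab2))
  # min size above any cluster leaves everything unassigned
  expect_warning(lab3 <- detect_modules(D[1:10, 1:10], min_module_size = 25),
                 "unassigned")
  expect_true(all(lab3 == "unassigned"))
})

test_that("module labels follow the size-ranked colour convention", {
  fx <- planted_fixture()
  lab <- fx$fit$modules
  mods <- setdiff(unique(lab), "unassigned")
  expect_setequal(mods, c("turquoise", "blue", "brown"))
  sizes <- table(lab[lab != "unassigned"])
  expect_true(sizes[["turquoise"]] >= sizes[["blue"]] &&
                sizes[["blue"]] >= sizes[["brown"]])
})

test_that("near-duplicate modules merge below the cut height, distinct ones do not", {
  set.seed(9)
  n <- 100
  f <- matrix(rnorm(n * 2), n, 2)
  # 30 taxa all driven by factor 1, split artificially into two labels
  x <- cbind(f[, rep(1, 30)], f[, rep(2, 15)]) +
    matrix(rnorm(n * 45, 0, 0.4), n, 45)
  colnames(x) <- paste0("t", 1:45)
  lab <- setNames(c(rep("alpha", 15), rep("beta", 15), rep("gamma", 15)),
                  colnames(x))
  merged <- merge_modules(lab, x, merge_cut_height = 0.25)
  expect_length(setdiff(unique(merged), "unassigned"), 2)
  # the two halves of factor 1 now share a label
  expect_length(unique(merged[1:30]), 1)

  # orthogonal modules stay put and keep their sizes
  lab2 <- setNames(c(rep("turquoise", 30), rep("blue", 15)), colnames(x))
  same <- merge_modules(lab2, x, merge_cut_height = 0.25)
  expect_identical(same, lab2)
  # cut height zero always leaves labels unchanged
  expect_identical(merge_modules(lab, x, merge_cut_height = 0), lab)
})

test_that("wcna returns a coherent fit object with working methods", {
  fx <- planted_fixture()
  fit <- fx$fit
  expect_s3_class(fit, "wcna")
  A <- fit$adjacency
  expect_true(isSymmetric(unname(A)))
  expect_true(all(A >= 0 & A <= 1))
  expect_equal(unname(diag(fit$tom)), rep(1, ncol(A)))
  expect_true(all(fit$tom >= -1e-12 & fit$tom <= 1 + 1e-12))
  expect_true(all(fit$dissimilarity >= -1e-12 & fit$dissimilarity <= 1 + 1e-12))
  expect_length(fit$modules, ncol(fx$x))
  expect_output(print(fit), "module")
  s <- summary(fit)
  expect_output(print(s), "beta")
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit))
})
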