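## adjacency whose connectivities follow a prescribed profile k (up to a
## small quadratic distortion): a_ij proportional to k_i * k_j
adj_from_connectivity <- function(k) {
  p <- length(k)
  a <- outer(k, k) / sum(k)
  a <- a / max(a[upper.tri(a)]) * 0.9
  diag(a) <- 1
  dimnames(a) <- list(sprintf("g%03d", 1:p), sprintf("g%03d", 1:p))
  a
}

test_that("scale_free_fit is near 1 on an exact discretized power law", {
  ## place nodes exactly at 10 connectivity levels with counts following
  ## k^-2, so the binned log-log regression is linear by construction
  centers <- seq(7, 48, length.out = 10)
  counts <- round(45000 * centers^-2)
  k <- rep(centers, counts)
  a <- adj_from_connectivity(k)
  fit <- scale_free_fit(a, bins = 10)
  expect_gte(fit$r_squared, 0.99)
  expect_lt(fit$slope, 0)
  ## independent least-squares check on the same binning
  conn <- rowSums(a) - 1
  bins <- cut(conn, 10, include.lowest = TRUE)
  freq <- as.vector(tapply(conn, bins, length)) / length(conn)
  mk <- as.vector(tapply(conn, bins, mean))
  keep <- !is.na(freq)
  ref <- summary(lm(log10(freq[keep]) ~ log10(mk[keep])))$r.squared
  expect_equal(fit$r_squared, ref, tolerance = 1e-12)
})

test_that("a uniform-random adjacency fits scale-free topology poorly", {
  set.seed(10)
  p <- 300
  a <- matrix(runif(p * p), p, p); a <- (a + t(a)) / 2; diag(a) <- 1
  dimnames(a) <- list(sprintf("g%03d", 1:p), sprintf("g%03d", 1:p))
  fit_unif <- scale_free_fit(a, bins = 10)
  centers <- seq(7, 48, length.out = 10)
  ks <- rep(centers, round(45000 * centers^-2))
  fit_pl <- scale_free_fit(adj_from_connectivity(ks), bins = 10)
  expect_gt(fit_pl$r_squared, fit_unif$r_squared + 0.2)
})

test_that("scale_free_fit rejects degenerate inputs", {
  a <- matrix(0.5, 20, 20); diag(a) <- 1
  expect_error(scale_free_fit(a), "identical")
  expect_error(scale_free_fit(matrix(1, 2, 2)), "10 genes")
})

test_that("pick_soft_threshold returns the smallest qualifying power", {
  set.seed(21)
  sim <- planted_modules_scenario(n_blocks = 4, genes_per_block = 40,
                                  within_corr = 0.6, between_corr = 0.05,
                                  n_samples = 300, seed = 21)
  corr <- cor(t(sim$expression))
  powers <- 1:12
  chosen <- suppressWarnings(
    pick_soft_threshold(corr, target_r2 = 0.8, powers = powers))
  diag <- attr(chosen, "diagnostics")
  ## oracle scan over the same powers
  r2 <- sapply(powers, function(b) {
    scale_free_fit(soft_threshold_adjacency(corr, b))$r_squared
  })
  expect_equal(diag$r_squared, r2, tolerance = 1e-12)
  qual <- which(r2 >= 0.8)
  if (length(qual) > 0) {
    expect_equal(as.integer(chosen), powers[qual[1]])
  }
  ## target 0: first power always qualifies
  expect_equal(as.integer(pick_soft_threshold(corr, target_r2 = 0,
                                              powers = powers)), 1L)
  ## unreachable target: argmax with a warning
  expect_warning(fb <- pick_soft_threshold(corr, target_r2 = 0.99999,
                                           powers = powers),
                 "argmax")
  expect_equal(as.integer(fb), powers[which.max(r2)])
  ## monotone in target: a lower target never selects a larger power
  t_hi <- suppressWarnings(pick_soft_threshold(corr, 0.9, powers))
  t_lo <- suppressWarnings(pick_soft_threshold(corr, 0.5, powers))
  expect_lte(as.integer(t_lo), as.integer(t_hi))
})

test_that("topological overlap matches brute-force summation", {
  set.seed(33)
  for (rep in 1:10) {
    a <- matrix(runif(25), 5, 5); a <- (a + t(a)) / 2; diag(a) <- 1
    dimnames(a) <- list(letters[1:5], letters[1:5])
    tom <- topological_overlap(a)
    expect_equal(unname(tom), brute_tom(a), tolerance = 1e-12)
    expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
    expect_equal(unname(diag(tom)), rep(1, 5))
    expect_equal(tom, t(tom))
  }
})

test_that("topological overlap boundary cases", {
  a0 <- diag(6); dimnames(a0) <- list(letters[1:6], letters[1:6])
  expect_equal(max(abs(topological_overlap(a0)[upper.tri(a0)])), 0)
  a1 <- matrix(1, 6, 6); dimnames(a1) <- dimnames(a0)
  expect_equal(min(topological_overlap(a1)), 1)
})

test_that("hierarchical clustering separates clean blocks exactly", {
  sim <- planted_modules_scenario(n_blocks = 2, genes_per_block = 45,
                                  within_corr = 0.8, between_corr = 0.05,
                                  n_samples = 400, seed = 8)
  corr <- cor(t(sim$expression))
  tom <- topological_overlap(soft_threshold_adjacency(corr, 6))
  asg <- hierarchical_modules(tom, min_module_size = 30)
  expect_equal(dplyr::n_distinct(asg$module_id), 2)
  tab <- table(asg$module_id, sim$labels$module_id)
  expect_equal(max(tab["M1", ]), sum(asg$module_id == "M1"))
  expect_equal(max(tab["M2", ]), sum(asg$module_id == "M2"))
  ## size contract
  expect_true(all(table(asg$module_id) >= 30))
})

test_that("clustering plus k-means refinement recovers planted modules", {
  sim <- planted_modules_scenario(n_blocks = 3, genes_per_block = 50,
                                  within_corr = 0.7, between_corr = 0.1,
                                  n_samples = 400, seed = 15)
  corr <- cor(t(sim$expression))
  tom <- topological_overlap(soft_threshold_adjacency(corr, 6))
  asg <- hierarchical_modules(tom, min_module_size = 35)
  ref <- kmeans_refine(tom, asg)
  ari <- mclust::adjustedRandIndex(ref$module_id, sim$labels$module_id)
  expect_gte(ari, 0.9)
})

test_that("k-means refinement descends and respects fixpoints", {
  sim <- planted_modules_scenario(n_blocks = 2, genes_per_block = 40,
                                  within_corr = 0.75, between_corr = 0.05,
                                  n_samples = 300, seed = 77)
  corr <- cor(t(sim$expression))
  tom <- topological_overlap(soft_threshold_adjacency(corr, 6))
  asg <- hierarchical_modules(tom, min_module_size = 30)
  ref <- kmeans_refine(tom, asg)
  obj <- attr(ref, "metadata")$objective
  expect_true(all(diff(obj) <= 1e-8))
  ## a fixpoint is returned unchanged
  ref2 <- kmeans_refine(tom, ref)
  expect_equal(ref2$module_id, ref$module_id)
  ## a few planted mislabels are repaired
  bad <- asg
  flip <- c(1, 41)
  bad$module_id[flip] <- rev(bad$module_id[flip])
  fixed <- kmeans_refine(tom, bad)
  expect_gte(mclust::adjustedRandIndex(fixed$module_id, sim$labels$module_id),
             0.99)
})

test_that("hierarchical clustering refuses too few genes", {
  tom <- diag(10); dimnames(tom) <- list(letters[1:10], letters[1:10])
  expect_error(hierarchical_modules(tom, min_module_size = 40), "at least")
})
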