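test_that("full-order partial correlations match pairwise inversion", {
  set.seed(7)
  for (rep in 1:20) {
    x <- matrix(rnorm(60 * 5), 60, 5, dimnames = list(NULL, letters[1:5]))
    s <- sufficient_stats(x)
    fm <- full_order_partial_corr_matrix(s, letters[1:5])
    for (i in 1:4) for (j in (i + 1):5) {
      expect_equal(fm[i, j],
                   partial_correlation(s, letters[i], letters[j],
                                       letters[setdiff(1:5, c(i, j))]),
                   tolerance = 1e-10)
    }
  }
})

test_that("full-order matrix reduces to raw correlation for 2 members", {
  s <- sufficient_stats(matrix(rnorm(80), 40, 2,
                               dimnames = list(NULL, c("a", "b"))))
  fm <- full_order_partial_corr_matrix(s, c("a", "b"))
  expect_equal(fm["a", "b"], s$corr["a", "b"], tolerance = 1e-12)
})

test_that("diagonal correlation gives zero full-order partial correlations", {
  corr <- diag(4); dimnames(corr) <- list(letters[1:4], letters[1:4])
  s <- sufficient_stats(corr = corr, n = 100)
  fm <- full_order_partial_corr_matrix(s, letters[1:4])
  expect_equal(max(abs(fm[upper.tri(fm)])), 0)
})

test_that("dual filter removes the chain shortcut with its separating set", {
  set.seed(4)
  n <- 5000
  x <- rnorm(n); y <- 0.9 * x + rnorm(n); z <- 0.9 * y + rnorm(n)
  s <- sufficient_stats(cbind(x = x, y = y, z = z))
  g <- complete_graph(tibble::tibble(id = c("x", "y", "z"), tier = "gene"))
  out <- dual_filter_pass(g, s)
  keys <- skeleton_keys(out)
  expect_setequal(keys, c("x y", "y z"))
  expect_equal(sepset(out, "x", "z"), "y")
})

test_that("no surviving edge crosses independent gene blocks", {
  set.seed(5)
  n <- 2000
  b1 <- matrix(rnorm(n * 4), n, 4) %*% matrix(runif(16, 0.3, 0.8), 4)
  b2 <- matrix(rnorm(n * 4), n, 4) %*% matrix(runif(16, 0.3, 0.8), 4)
  x <- cbind(b1, b2)
  colnames(x) <- paste0("g", 1:8)
  s <- sufficient_stats(x)
  g <- complete_graph(tibble::tibble(id = colnames(x), tier = "gene"))
  out <- dual_filter_pass(g, s)
  ed <- tidy(out)
  in1 <- paste0("g", 1:4)
  cross <- sum(xor(ed$from %in% in1, ed$to %in% in1))
  ## cross-block population correlation is 0: allow the binomial
  ## false-positive margin at alpha = 0.05 over 16 cross pairs
  expect_lte(cross, 3)
})

test_that("surviving-edge fraction on a global null is near alpha", {
  set.seed(19)
  p <- 25; n <- 2000
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("v", 1:p)))
  s <- sufficient_stats(x)
  g <- complete_graph(tibble::tibble(id = colnames(x), tier = "gene"))
  out <- dual_filter_pass(g, s)
  frac <- nrow(tidy(out)) / choose(p, 2)
  ## both dual tests must retain the edge; the joint rate is below alpha
  ## but of the same order
  expect_lt(frac, 0.05 + 3 * sqrt(0.05 * 0.95 / choose(p, 2)))
})

test_that("marginal filter keeps exactly the marginally dependent pairs", {
  set.seed(23)
  x <- matrix(rnorm(200 * 8), 200, 8, dimnames = list(NULL, paste0("v", 1:8)))
  x[, 2] <- x[, 1] * 0.8 + rnorm(200, sd = 0.5)
  s <- sufficient_stats(x)
  g <- complete_graph(tibble::tibble(id = colnames(x), tier = "gene"))
  out <- marginal_filter(g, s, alpha = 0.05)
  ## direct enumeration oracle
  expected <- character(0)
  for (i in 1:7) for (j in (i + 1):8) {
    p_ <- cor.test(x[, i], x[, j])$p.value
    if (p_ <= 0.05) expected <- c(expected, paste0("v", i, " v", j))
  }
  expect_setequal(skeleton_keys(out), expected)
  ## removed pairs carry the empty separating set
  expect_true(all(lengths(out$sepsets) == 0))
})

test_that("the filter is sound under a d-separation oracle", {
  for (s_ in 1:20) {
    dag <- rand_gene_dag(7, edge_prob = 0.35, seed = 500 + s_)
    eng <- ci_engine_oracle(dag, log = FALSE)
    g <- complete_graph(dag$nodes)
    out <- dual_filter_pass(g, eng)
    true_keys <- skeleton_keys(dag)
    expect_true(all(true_keys %in% skeleton_keys(out)))
  }
})

test_that("filtering is monotone, idempotent and orientation-free", {
  set.seed(31)
  x <- matrix(rnorm(500 * 10), 500, 10,
              dimnames = list(NULL, paste0("v", 1:10)))
  s <- sufficient_stats(x)
  g <- complete_graph(tibble::tibble(id = colnames(x), tier = "gene"))
  f1 <- dual_filter_pass(g, s)
  expect_true(all(skeleton_keys(f1) %in% skeleton_keys(g)))
  expect_true(all(tidy(f1)$state == "undirected"))
  f2 <- dual_filter_pass(f1, s)
  f3 <- dual_filter_pass(f2, s)
  expect_identical(f3$amat, f2$amat)
})

test_that("deeper dual marching is available and still sound under oracle", {
  dag <- rand_gene_dag(7, edge_prob = 0.4, seed = 999)
  eng <- ci_engine_oracle(dag, log = FALSE)
  out <- dual_filter_pass(complete_graph(dag$nodes), eng,
                          filter_config(max_depth = 3))
  expect_true(all(skeleton_keys(dag) %in% skeleton_keys(out)))
})
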