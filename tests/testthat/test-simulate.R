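test_that("edge probability extremes give the expected edge counts", {
  sc0 <- sim_scenario(n_genes = 8, edge_prob = 0, seed = 2)
  t0 <- simulate_dag(sc0)
  ed <- tidy(t0$dag)
  gg <- sum(!grepl("^snp", ed$from) & ed$to != "outcome")
  expect_equal(gg, 0)
  sc1 <- sim_scenario(n_genes = 8, edge_prob = 1, seed = 2)
  t1 <- simulate_dag(sc1)
  ed1 <- tidy(t1$dag)
  gg1 <- sum(!grepl("^snp", ed1$from) & ed1$to != "outcome")
  expect_equal(gg1, choose(8, 2))
})

test_that("expected_degree parameterization fixes sparsity", {
  sc <- sim_scenario(n_genes = 41, expected_degree = 2)
  expect_equal(sc$edge_prob, 2 / 40)
})

test_that("generated structures are acyclic over many draws", {
  for (s in 1:100) {
    tr <- simulate_dag(sim_scenario(n_genes = 8, edge_prob = 0.4,
                                    n_samples = 10, seed = s))
    d <- dir_mat(tr$dag)
    ## cycle-detection oracle: repeated leaf stripping must consume all nodes
    alive <- rep(TRUE, nrow(d))
    repeat {
      leaves <- which(alive & colSums(d[alive, , drop = FALSE]) == 0)
      if (length(leaves) == 0) break
      alive[leaves] <- FALSE
      d[leaves, ] <- FALSE
    }
    expect_false(any(alive))
  }
})

test_that("true outcome ancestors equal brute-force path enumeration", {
  for (s in 1:10) {
    tr <- simulate_dag(sim_scenario(n_genes = 6, edge_prob = 0.3,
                                    n_samples = 10, seed = 40 + s))
    expect_setequal(tr$true_outcome_ancestors,
                    brute_ancestors(tr$dag, "outcome"))
  }
})

test_that("a single structural edge reproduces its implied correlation", {
  ## A -> B with coefficient b and unit noise: cor(A, B) = b / sqrt(b^2 + 1)
  sc <- sim_scenario(n_genes = 2, edge_prob = 1, snp_per_gene = 0,
                     n_samples = 5000, outcome_type = "continuous",
                     outcome_parents = 1, seed = 6)
  tr <- simulate_dag(sc)
  sim <- simulate_data(tr, sc)
  co <- tr$coefficients
  ge <- co[co$to != "outcome", ]
  b <- ge$coefficient
  pop <- b / sqrt(b^2 + 1)
  est <- cor(sim$expression[ge$from, ], sim$expression[ge$to, ])
  se <- (1 - pop^2) / sqrt(5000)
  expect_lt(abs(est - pop), 3 * se)
})

test_that("a zero-effect SNP decorrelates from its gene", {
  sc <- sim_scenario(n_genes = 3, edge_prob = 0, snp_per_gene = 1,
                     snp_effect_range = c(0, 0), n_samples = 4000, seed = 9)
  tr <- simulate_dag(sc)
  sim <- simulate_data(tr, sc)
  for (k in seq_len(nrow(sim$iv_map))) {
    r <- cor(sim$genotypes[sim$iv_map$snp_id[k], ],
             sim$expression[sim$iv_map$gene_id[k], ])
    expect_lt(abs(r), 3 / sqrt(4000))
  }
})

test_that("the generator is bit-reproducible from its seed", {
  sc <- sim_scenario(n_genes = 6, n_samples = 100, seed = 123)
  t1 <- simulate_dag(sc); d1 <- simulate_data(t1, sc)
  t2 <- simulate_dag(sc); d2 <- simulate_data(t2, sc)
  expect_identical(t1$coefficients, t2$coefficients)
  expect_identical(d1$expression, d2$expression)
  expect_identical(d1$genotypes, d2$genotypes)
  expect_identical(d1$outcome, d2$outcome)
})

test_that("binary outcomes are a balanced median split", {
  sc <- sim_scenario(n_genes = 5, n_samples = 500, seed = 31)
  sim <- simulate_data(simulate_dag(sc), sc)
  expect_setequal(unique(sim$outcome), c(0L, 1L))
  expect_equal(mean(sim$outcome), 0.5, tolerance = 0.01)
})

test_that("genotype dosages stay in [0, 2] and respect MAF bounds", {
  sc <- sim_scenario(n_genes = 10, n_samples = 300, maf_range = c(0.1, 0.4),
                     seed = 77)
  tr <- simulate_dag(sc)
  sim <- simulate_data(tr, sc)
  expect_true(all(sim$genotypes %in% 0:2))
  expect_true(all(tr$mafs$maf >= 0.1 & tr$mafs$maf <= 0.4))
})

test_that("planted-module generation honours its contracts", {
  sim <- planted_modules_scenario(n_blocks = 2, genes_per_block = 30,
                                  within_corr = 0.9, between_corr = 0,
                                  n_samples = 600, seed = 3)
  corr <- cor(t(sim$expression))
  cross <- corr[1:30, 31:60]
  expect_lt(abs(mean(cross)), 0.03)
  ## sampled correlation matrices are symmetric PSD
  ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-10)
  ## within == between is a degenerate but valid boundary
  flat <- planted_modules_scenario(2, 20, 0.5, 0.5, 50, seed = 1)
  expect_equal(dim(flat$expression), c(40L, 50L))
  ## invalid correlation orderings are rejected up front
  expect_error(planted_modules_scenario(2, 30, 0.5, 0.7, 50))
})
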