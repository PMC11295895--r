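snp_gene_nodes <- function() {
  tibble::tibble(id = c("rs1", "rs2", "g1", "g2"),
                 tier = c("variant", "variant", "gene", "gene"))
}

test_that("variant edges are oriented away from variants, others untouched", {
  g <- mixed_graph(snp_gene_nodes(), tibble::tibble(
    from = c("rs1", "rs2", "g1", "rs1"),
    to = c("g1", "g2", "g2", "rs2"),
    state = "undirected"))
  out <- orient_variant_edges(g)
  ed <- tidy(out)
  expect_equal(ed$state[ed$from == "rs1" & ed$to == "g1"], "directed")
  expect_equal(ed$state[ed$from == "rs2" & ed$to == "g2"], "directed")
  expect_equal(ed$state[ed$from == "g1" & ed$to == "g2"], "undirected")
  ## variant-variant edge stays undirected
  expect_equal(ed$state[ed$from == "rs1" & ed$to == "rs2"], "undirected")
  ## count contract: exactly the variant-phenotype edges became arrows
  expect_equal(sum(ed$state == "directed"), 2)
})

test_that("a collider is oriented and a chain is left alone", {
  set.seed(13)
  n <- 8000
  ## collider x -> z <- y
  x <- rnorm(n); y <- rnorm(n); z <- 0.7 * x + 0.7 * y + rnorm(n)
  s <- sufficient_stats(cbind(x = x, y = y, z = z))
  nodes <- tibble::tibble(id = c("x", "y", "z"), tier = "gene")
  sk <- refine_skeleton(complete_graph(nodes), s)
  out <- orient_v_structures(sk, s)
  ed <- tidy(out)
  expect_setequal(ed$state, "directed")
  expect_setequal(paste(ed$from, ed$to), c("x z", "y z"))

  ## chain x -> z -> y: sepset is {z}, no orientation from this step
  x2 <- rnorm(n); z2 <- 0.8 * x2 + rnorm(n); y2 <- 0.8 * z2 + rnorm(n)
  s2 <- sufficient_stats(cbind(x = x2, y = y2, z = z2))
  sk2 <- refine_skeleton(complete_graph(nodes), s2)
  out2 <- orient_v_structures(sk2, s2)
  expect_true(all(tidy(out2)$state == "undirected"))
})

test_that("oracle v-structure discovery is exact on SNP-anchored DAGs", {
  for (s_ in 1:25) {
    sc <- sim_scenario(n_genes = sample(4:7, 1), edge_prob = 0.35,
                       snp_per_gene = 1, seed = 800 + s_)
    truth <- simulate_dag(sc)
    eng <- ci_engine_oracle(truth$dag, log = FALSE)
    sk <- refine_skeleton(complete_graph(truth$dag$nodes), eng)
    sk <- orient_variant_edges(sk)
    out <- orient_v_structures(sk, eng)
    ## every true v-structure must be oriented, and no false ones
    ## (restricting to phenotype-phenotype arrows; variant arrows are
    ## fixed by the MR principle, not by collider discovery)
    truev <- mrdualpc:::v_structures(truth$dag)
    d <- dir_mat(out)
    for (k in seq_len(nrow(truev))) {
      expect_true(d[truev$x[k], truev$z[k]])
      expect_true(d[truev$y[k], truev$z[k]])
    }
    ## any directed gene -> gene arrow after this step must belong to a
    ## true v-structure
    ids <- out$nodes$id
    tier <- out$nodes$tier
    arr <- which(d, arr.ind = TRUE)
    for (k in seq_len(nrow(arr))) {
      a <- ids[arr[k, 1]]; b <- ids[arr[k, 2]]
      if (tier[arr[k, 1]] == "variant") next
      expect_true(any((truev$x == a | truev$y == a) & truev$z == b))
    }
  }
})

test_that("propagation applies the closure rules to fixpoint", {
  nodes <- tibble::tibble(id = c("a", "b", "c"), tier = "gene")
  ## R1: a -> b, b - c, a and c non-adjacent  =>  b -> c
  g1 <- mixed_graph(nodes, tibble::tibble(
    from = c("a", "b"), to = c("b", "c"),
    state = c("directed", "undirected")))
  out1 <- propagate_orientations(g1)
  expect_equal(tidy(out1)$state, c("directed", "directed"))
  expect_true(dir_mat(out1)["b", "c"])
  ## R2: a -> b -> c with a - c  =>  a -> c
  g2 <- mixed_graph(nodes, tibble::tibble(
    from = c("a", "b", "a"), to = c("b", "c", "c"),
    state = c("directed", "directed", "undirected")))
  out2 <- propagate_orientations(g2)
  expect_true(dir_mat(out2)["a", "c"])
})

test_that("propagation equals brute-force rule application on random graphs", {
  for (s_ in 1:20) {
    dag <- rand_gene_dag(sample(4:8, 1), edge_prob = 0.4, seed = 900 + s_)
    ## start from the skeleton with true v-structures oriented (the state
    ## propagation sees in practice)
    cp <- true_cpdag(dag)
    start <- mixed_graph(dag$nodes)
    start$amat <- dag$amat | t(dag$amat)
    storage.mode(start$amat) <- "integer"
    vs <- mrdualpc:::v_structures(dag)
    for (k in seq_len(nrow(vs))) {
      start$amat[vs$z[k], vs$x[k]] <- 0L
      start$amat[vs$z[k], vs$y[k]] <- 0L
    }
    out <- propagate_orientations(start)
    brute <- brute_propagate(start$amat, rep(FALSE, nrow(start$amat)))
    expect_identical(out$amat, brute)
    ## and the closure of skeleton + v-structures is the CPDAG
    expect_identical(out$amat, cp$amat)
  }
})

test_that("full orientation recovers a SNP -> gene -> outcome chain", {
  set.seed(5000)
  n <- 5000
  snp <- rbinom(n, 2, 0.3)
  g1 <- 0.8 * scale(snp)[, 1] + rnorm(n)
  out_ <- 0.8 * g1 + rnorm(n)
  s <- sufficient_stats(cbind(rs1 = snp, g1 = g1, outcome = out_))
  nodes <- tibble::tibble(id = c("rs1", "g1", "outcome"),
                          tier = c("variant", "gene", "outcome"))
  sk <- refine_skeleton(complete_graph(nodes), s)
  res <- run_orientation(sk, s)
  ed <- tidy(res)
  expect_setequal(paste(ed$from, ed$to, ed$state),
                  c("rs1 g1 directed", "g1 outcome directed"))
})

test_that("no arrowhead ever points into a variant node", {
  for (s_ in 1:10) {
    sc <- sim_scenario(n_genes = 6, n_samples = 800, edge_prob = 0.3,
                       seed = 1000 + s_)
    truth <- simulate_dag(sc)
    sim <- simulate_data(truth, sc)
    res <- run_module(sim$expression, sim$genotypes, sim$outcome,
                      sim$iv_map, rownames(sim$expression),
                      log_tests = FALSE)
    d <- dir_mat(res$graph)
    vars <- res$graph$nodes$tier == "variant"
    expect_equal(sum(d[, vars]), 0)
  }
})

test_that("skeleton with no variants and no unshielded triples stays undirected", {
  set.seed(3)
  n <- 4000
  x <- rnorm(n); y <- 0.8 * x + rnorm(n)   # single edge: no triples
  s <- sufficient_stats(cbind(x = x, y = y))
  nodes <- tibble::tibble(id = c("x", "y"), tier = "gene")
  sk <- refine_skeleton(complete_graph(nodes), s)
  res <- run_orientation(sk, s)
  expect_true(all(tidy(res)$state == "undirected"))
})
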