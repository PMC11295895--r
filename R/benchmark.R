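#' Machine-independent benchmark: pre-filtered vs complete-graph search
#'
#' For each module size and replicate, simulates an eQTL module, builds
#' one shared set of sufficient statistics, and runs two methods from the
#' same complete graph: the baseline (PC-stable skeleton on the complete
#' graph, then orientation — the MRPC-style search) and MRdualPC (the
#' dual-order pre-filter, then the same skeleton refinement and
#' orientation). The primary metric is the number of CI tests executed —
#' the hardware-independent mechanism behind the speedup; wall time is
#' recorded for context but never asserted.
#'
#' Sizes count nodes including IVs and the outcome: a size-`m` run uses
#' `floor((m - 1) / 2)` genes with one SNP instrument each.
#'
#' @param sizes Integer module sizes (total nodes), each >= 10.
#' @param replicates Replicates per size.
#' @param scenario Template [sim_scenario()]; `n_genes`, `snp_per_gene`
#'   and `seed` are overridden per run.
#' @param seed Integer master seed.
#' @param alpha Significance level of all CI tests.
#' @param dual_depth Depth of the dual-order filter.
#' @return A `benchmark_result` tibble: one row per size x replicate x
#'   method with `ci_tests_total`, `ci_tests_order_ge1` (skeleton and
#'   orientation stages), `skeleton_edge_count`, `n_causal_ancestors`,
#'   `wall_seconds`, `seed`.
#' @export
run_benchmark <- function(sizes = c(50, 100, 200, 400), replicates = 5,
                          scenario = sim_scenario(expected_degree = 2),
                          seed = 1, alpha = 0.05, dual_depth = 1) {
  stopifnot(all(sizes >= 10), replicates >= 1, abs(seed) < 2^20)
  rows <- list()
  for (si in seq_along(sizes)) {
    m <- sizes[si]
    n_genes <- max(2L, (m - 1L) %/% 2L)
    for (r in seq_len(replicates)) {
      run_seed <- seed * 1000L + si * 100L + r
      sc <- scenario
      sc$n_genes <- n_genes
      sc$snp_per_gene <- 1L
      sc$seed <- run_seed
      if (!is.null(sc$expected_degree)) {
        sc$edge_prob <- min(1, sc$expected_degree / max(1, n_genes - 1))
      }
      truth <- simulate_dag(sc)
      sim <- simulate_data(truth, sc)
      dat <- cbind(t(sim$expression), t(sim$genotypes),
                   outcome = as.numeric(sim$outcome))
      colnames(dat) <- c(rownames(sim$expression), rownames(sim$genotypes),
                         "outcome")
      stats_ <- sufficient_stats(dat)
      nodes <- truth$dag$nodes
      for (method in c("MRPC_baseline", "MRdualPC")) {
        engine <- ci_engine_fisher(stats_, alpha = alpha, log = FALSE)
        t0 <- proc.time()[["elapsed"]]
        g <- complete_graph(nodes)
        if (method == "MRdualPC") {
          g <- dual_filter_pass(g, engine,
                                filter_config(alpha = alpha,
                                              max_depth = dual_depth))
        }
        g <- refine_skeleton(g, engine, skeleton_config(alpha = alpha))
        skel_edges <- nrow(tidy(g))
        g <- run_orientation(g, engine, orientation_config(alpha = alpha))
        wall <- proc.time()[["elapsed"]] - t0
        cnt <- ci_test_counts(engine)
        rows[[length(rows) + 1L]] <- tibble(
          size = m, n_nodes = nrow(nodes), replicate = r, method = method,
          ci_tests_total = cnt$n_tests,
          ci_tests_order_ge1 = refine_order_ge1_count(engine),
          skeleton_edge_count = skel_edges,
          n_causal_ancestors = length(
            intersect(causal_ancestors(g, "outcome"),
                      nodes$id[nodes$tier == "gene"])),
          wall_seconds = wall, seed = run_seed)
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("benchmark_result", class(out))
  out
}

## order >= 1 tests executed during the skeleton-refinement and
## orientation stages (the counts the pre-filter is meant to shrink)
refine_order_ge1_count <- function(engine) {
  env <- engine$env
  unname(env$by_stage["skeleton"] + env$by_stage["orient"] -
           env$order0_by_stage["skeleton"] - env$order0_by_stage["orient"])
}

#' Skeleton and orientation agreement between two graphs
#'
#' @param g1,g2 `mixed_graph`s over identical node sets.
#' @return A one-row tibble: `skeleton_jaccard` (Jaccard index of the
#'   undirected edge sets, 1 when both are empty) and
#'   `orientation_agreement` (fraction of shared edges with identical
#'   state; reported as 1 with `empty_overlap = TRUE` when no edges are
#'   shared).
#' @export
concordance <- function(g1, g2) {
  if (!setequal(g1$nodes$id, g2$nodes$id)) {
    abort("`g1` and `g2` must share the same node set.")
  }
  e1 <- tidy(g1); e2 <- tidy(g2)
  k1 <- pair_key(e1$from, e1$to)
  k2 <- pair_key(e2$from, e2$to)
  inter <- intersect(k1, k2)
  union_ <- union(k1, k2)
  jac <- if (length(union_) == 0) 1 else length(inter) / length(union_)
  if (length(inter) == 0) {
    return(tibble(skeleton_jaccard = jac, orientation_agreement = 1,
                  n_shared_edges = 0L, empty_overlap = TRUE))
  }
  state1 <- edge_state_key(g1, inter)
  state2 <- edge_state_key(g2, inter)
  tibble(skeleton_jaccard = jac,
         orientation_agreement = mean(state1 == state2),
         n_shared_edges = length(inter), empty_overlap = FALSE)
}

## canonical state string for an unordered pair key
edge_state_key <- function(g, keys) {
  vapply(keys, function(k) {
    xy <- strsplit(k, "\r", fixed = TRUE)[[1]]
    a <- g$amat[xy[1], xy[2]]; b <- g$amat[xy[2], xy[1]]
    if (a == 1L && b == 1L) "und" else if (a == 1L) "fwd" else "rev"
  }, character(1), USE.NAMES = FALSE)
}

#' @method autoplot benchmark_result
#' @export
autoplot.benchmark_result <- function(object, metric = c("ci_tests_total",
                                                         "wall_seconds"),
                                      ...) {
  metric <- match.arg(metric)
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$n_nodes, y = .data[[metric]],
                               colour = .data$method)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::stat_summary(fun = stats::median, geom = "line") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "nodes (genes + IVs + outcome)",
                  y = gsub("_", " ", metric), colour = NULL) +
    ggplot2::theme_minimal()
}
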