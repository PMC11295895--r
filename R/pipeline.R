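#' Remove covariate effects from expression data
#'
#' Replaces each gene's values by the residuals of an ordinary
#' least-squares regression on the covariates (intercept included), so the
#' downstream correlation structure is free of those effects.
#'
#' @param expression Genes x samples numeric matrix.
#' @param covariates Data frame or matrix with one row per sample.
#' @return The residualized expression matrix (same shape; gene means
#'   approximately 0).
#' @export
residualize_covariates <- function(expression, covariates) {
  expression <- as.matrix(expression)
  cov_df <- as.data.frame(covariates)
  if (nrow(cov_df) != ncol(expression)) {
    abort("`covariates` must have one row per expression sample (column).")
  }
  X <- stats::model.matrix(~ ., data = cov_df)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[seq(qrX$rank + 1, ncol(X))]]
    abort(paste0("Covariate design matrix is rank deficient; collinear ",
                 "column(s): ", paste(bad, collapse = ", ")))
  }
  res <- t(qr.resid(qrX, t(expression)))
  dimnames(res) <- dimnames(expression)
  res
}

#' Causal network inference for one gene module
#'
#' Assembles sufficient statistics over a module's genes, their SNP
#' instruments and the outcome, then runs the MRdualPC stages: marginal
#' (or dual-order) pre-filtering, PC-stable skeleton refinement, and
#' MR-principled orientation. Genes with a fully directed path to the
#' outcome are reported as its causal ancestors.
#'
#' @param expression Genes x samples numeric matrix (rownames = gene ids).
#' @param genotypes SNPs x samples dosage matrix (rownames = SNP ids).
#' @param outcome Numeric vector (binary or continuous), one value per
#'   sample, in the same sample order.
#' @param iv_map Data frame with columns `snp_id`, `gene_id`.
#' @param module_genes Character vector of gene ids in the module.
#' @param alpha Significance level for all CI tests.
#' @param filter `"marginal"` (order-0 pre-filter, the per-module default),
#'   `"dual"` (dual-order filter) or `"none"`.
#' @param dual_depth `max_depth` of [dual_filter_pass()] when
#'   `filter = "dual"`.
#' @param drop_no_iv Drop module genes with no mapped SNP instrument
#'   (default `TRUE`); with `FALSE` they are retained as pure phenotype
#'   nodes and flagged.
#' @param assume_independent_ivs Treat the IV set as pre-pruned to mutual
#'   independence (the standard LD-clumping step that produces eQTL
#'   instruments): variant-variant edges are excluded from the search a
#'   priori, with the empty separating set recorded. Set `FALSE` if the
#'   supplied instruments may be correlated.
#' @param log_tests Keep the full CI-test log in the result.
#' @param module_id Optional label carried into the result.
#' @return A `module_result`: list with `module_id`, `graph` (oriented
#'   `mixed_graph`), `causal_ancestor_genes`, `ci_test_counts` (one-row
#'   tibble), `ci_log` (tibble or `NULL`), `genes`, `snps`, `warnings`.
#' @export
run_module <- function(expression, genotypes, outcome, iv_map, module_genes,
                       alpha = 0.05,
                       filter = c("marginal", "dual", "none"),
                       dual_depth = 1, drop_no_iv = TRUE,
                       assume_independent_ivs = TRUE, log_tests = TRUE,
                       module_id = NULL) {
  filter <- match.arg(filter)
  expression <- as.matrix(expression)
  genotypes <- as.matrix(genotypes)
  iv_map <- as_tibble(iv_map)
  if (length(module_genes) == 0) abort("`module_genes` must be non-empty.")
  if (ncol(expression) != length(outcome) ||
      (nrow(genotypes) > 0 && ncol(genotypes) != length(outcome))) {
    abort("Sample counts of expression, genotypes and outcome must match.")
  }
  warnings <- character(0)
  missing_genes <- setdiff(module_genes, rownames(expression))
  if (length(missing_genes) > 0) {
    warnings <- c(warnings, paste0("Genes absent from expression, skipped: ",
                                   paste(missing_genes, collapse = ", ")))
    warn(warnings[length(warnings)])
    module_genes <- setdiff(module_genes, missing_genes)
  }
  if (length(module_genes) == 0) abort("No module genes left after filtering.")

  iv_sub <- iv_map[iv_map$gene_id %in% module_genes, , drop = FALSE]
  missing_snps <- setdiff(iv_sub$snp_id, rownames(genotypes))
  if (length(missing_snps) > 0) {
    warnings <- c(warnings, paste0("IV SNPs absent from genotypes, skipped: ",
                                   paste(missing_snps, collapse = ", ")))
    iv_sub <- iv_sub[!iv_sub$snp_id %in% missing_snps, , drop = FALSE]
  }
  no_iv <- setdiff(module_genes, iv_sub$gene_id)
  if (length(no_iv) > 0) {
    if (drop_no_iv) {
      warnings <- c(warnings, paste0("Genes with no IV dropped: ",
                                     paste(no_iv, collapse = ", ")))
      module_genes <- setdiff(module_genes, no_iv)
      if (length(module_genes) == 0) {
        abort("No module genes with instruments; set `drop_no_iv = FALSE` to keep them.")
      }
    } else {
      warnings <- c(warnings, paste0("Genes with no IV retained as pure ",
                                     "phenotype nodes: ",
                                     paste(no_iv, collapse = ", ")))
    }
  }
  snps <- unique(iv_sub$snp_id)

  dat <- cbind(t(expression[module_genes, , drop = FALSE]),
               t(genotypes[snps, , drop = FALSE]),
               outcome = as.numeric(outcome))
  colnames(dat) <- c(module_genes, snps, "outcome")
  stats_ <- sufficient_stats(dat)
  engine <- ci_engine_fisher(stats_, alpha = alpha, log = log_tests)

  nodes <- tibble(id = c(module_genes, snps, "outcome"),
                  tier = c(rep("gene", length(module_genes)),
                           rep("variant", length(snps)), "outcome"))
  g <- complete_graph(nodes)
  if (assume_independent_ivs && length(snps) >= 2) {
    ## background knowledge: clumped IVs are mutually independent, so no
    ## variant-variant edge can be real
    vp <- utils::combn(snps, 2)
    g <- remove_edges_batch(g, vp[1, ], vp[2, ],
                            rep(list(character(0)), ncol(vp)))
  }
  g <- switch(filter,
              marginal = marginal_filter(g, engine, alpha = alpha),
              dual = dual_filter_pass(g, engine,
                                      filter_config(alpha = alpha,
                                                    max_depth = dual_depth)),
              none = g)
  g <- refine_skeleton(g, engine, skeleton_config(alpha = alpha))
  g <- run_orientation(g, engine, orientation_config(alpha = alpha))
  anc <- causal_ancestors(g, "outcome")
  structure(
    list(module_id = module_id %||% "module",
         graph = g,
         causal_ancestor_genes = intersect(anc, module_genes),
         ci_test_counts = ci_test_counts(engine),
         ci_log = if (log_tests) ci_log(engine) else NULL,
         genes = module_genes, snps = snps,
         warnings = c(warnings, engine$env$warnings)),
    class = "module_result")
}

#' @export
print.module_result <- function(x, ...) {
  cat(sprintf("<module_result %s: %d genes, %d IVs, %d causal ancestors, %d CI tests>\n",
              x$module_id, length(x$genes), length(x$snps),
              length(x$causal_ancestor_genes), x$ci_test_counts$n_tests))
  invisible(x)
}

#' @method tidy module_result
#' @export
tidy.module_result <- function(x, ...) tidy(x$graph)

#' @method glance module_result
#' @export
glance.module_result <- function(x, ...) {
  tibble(module_id = x$module_id, n_genes = length(x$genes),
         n_snps = length(x$snps),
         n_causal_ancestors = length(x$causal_ancestor_genes),
         n_ci_tests = x$ci_test_counts$n_tests,
         n_edges = nrow(tidy(x$graph)),
         n_warnings = length(x$warnings))
}

#' Run causal inference across all modules
#'
#' Applies [run_module()] to every module of an assignment in
#' deterministic (sorted module id) order.
#'
#' @inheritParams run_module
#' @param assignment A `module_assignment` (tibble `gene_id`,
#'   `module_id`), e.g. from [hierarchical_modules()] / [kmeans_refine()].
#' @param ... Passed on to [run_module()].
#' @return A `module_results` list of `module_result` objects, with the
#'   reporting-bin summary available via [summarize_modules()].
#' @export
run_all_modules <- function(expression, genotypes, outcome, iv_map,
                            assignment, ...) {
  mods <- sort(unique(assignment$module_id))
  results <- purrr::map(mods, function(m) {
    run_module(expression, genotypes, outcome, iv_map,
               module_genes = assignment$gene_id[assignment$module_id == m],
               module_id = m, ...)
  })
  structure(results, class = "module_results")
}

#' @method glance module_results
#' @export
glance.module_results <- function(x, ...) {
  dplyr::bind_rows(purrr::map(x, glance))
}

#' Reporting-bin summary over module results
#'
#' Counts modules with at least 1, 5, 50 and 100 causal ancestor genes of
#' the outcome.
#'
#' @param results A `module_results` list.
#' @return A one-row tibble with `n_modules`, `n_ge1`, `n_ge5`, `n_ge50`,
#'   `n_ge100` and `total_ancestors`.
#' @export
summarize_modules <- function(results) {
  counts <- vapply(results, function(r) length(r$causal_ancestor_genes),
                   integer(1))
  tibble(n_modules = length(results),
         n_ge1 = sum(counts >= 1), n_ge5 = sum(counts >= 5),
         n_ge50 = sum(counts >= 50), n_ge100 = sum(counts >= 100),
         total_ancestors = sum(counts))
}

#' Gene-set over-representation test
#'
#' One-sided hypergeometric test of whether `ancestors` are enriched for
#' `reference` genes within `universe`: p = P(X >= overlap). The odds
#' ratio uses the Haldane 0.5 correction when any contingency cell is 0.
#'
#' @param ancestors,reference Character vectors of gene ids, both subsets
#'   of `universe`.
#' @param universe Character vector (the background gene set).
#' @return An `overlap_result`: list with `odds_ratio`, `p_value`,
#'   `overlap_count` and the 2x2 `contingency` table.
#' @export
overlap_test <- function(ancestors, reference, universe) {
  ancestors <- unique(as.character(ancestors))
  reference <- unique(as.character(reference))
  universe <- unique(as.character(universe))
  if (length(universe) == 0) abort("`universe` must be non-empty.")
  if (length(setdiff(ancestors, universe)) > 0 ||
      length(setdiff(reference, universe)) > 0) {
    abort("`ancestors` and `reference` must be subsets of `universe`.")
  }
  a <- length(intersect(ancestors, reference))
  b <- length(setdiff(ancestors, reference))
  c_ <- length(setdiff(reference, ancestors))
  d <- length(universe) - a - b - c_
  p <- stats::phyper(a - 1, length(reference),
                     length(universe) - length(reference),
                     length(ancestors), lower.tail = FALSE)
  or <- if (min(a, b, c_, d) == 0) {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
  } else {
    (a * d) / (b * c_)
  }
  cont <- matrix(c(a, b, c_, d), 2, 2, byrow = TRUE,
                 dimnames = list(c("in_ancestors", "not_ancestors"),
                                 c("in_reference", "not_reference")))
  structure(list(odds_ratio = or, p_value = p, overlap_count = a,
                 contingency = cont),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("<overlap_result: overlap = %d, OR = %.3g, p = %.3g>\n",
              x$overlap_count, x$odds_ratio, x$p_value))
  invisible(x)
}

#' @method tidy overlap_result
#' @export
tidy.overlap_result <- function(x, ...) {
  tibble(overlap_count = x$overlap_count, odds_ratio = x$odds_ratio,
         p_value = x$p_value,
         n_ancestors = sum(x$contingency[1, ]),
         n_reference = sum(x$contingency[, 1]),
         n_universe = sum(x$contingency))
}
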