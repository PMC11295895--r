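#' Simulation scenario for synthetic eQTL network data
#'
#' Describes the generating model the package's recovery tests run
#' against: a random DAG over genes with linear-Gaussian structural
#' equations, each gene instrumented by independent SNPs
#' (Binomial(2, MAF) dosages entering the model standardized), and a
#' downstream outcome with a handful of gene parents, optionally
#' dichotomized at the median of its latent liability (a near-balanced
#' case/control design). Defaults describe a sparse 50-gene module with
#' strong effects at n = 2000.
#'
#' @param n_genes Number of genes.
#' @param n_samples Number of samples.
#' @param edge_prob Probability of a gene-gene edge (respecting a random
#'   topological order). Default 0.04 gives expected gene degree about 2.
#' @param expected_degree Alternative sparsity parameterization: when
#'   given, `edge_prob` is derived as `expected_degree / (n_genes - 1)` so
#'   mean gene-gene degree stays constant as modules grow (regulatory
#'   networks are sparse at every scale).
#' @param snp_per_gene SNP instruments per gene (0 for none).
#' @param maf_range Minor-allele-frequency range, within (0, 0.5].
#' @param beta_range Range of absolute gene-gene and gene-outcome
#'   structural coefficients (signs random).
#' @param snp_effect_range Range of absolute SNP-on-gene effects.
#' @param noise_sd Standard deviation of each structural-equation noise.
#' @param outcome_parents Number of gene parents of the outcome.
#' @param outcome_type `"binary"` (liability dichotomized at its median) or
#'   `"continuous"`.
#' @param pleiotropy_prob Probability that a SNP also affects one extra,
#'   randomly chosen gene (0 by default: clean instruments).
#' @param seed Integer seed; the generator is bit-reproducible given the
#'   scenario.
#' @return A `sim_scenario` list.
#' @export
sim_scenario <- function(n_genes = 50, n_samples = 2000, edge_prob = 0.04,
                         expected_degree = NULL,
                         snp_per_gene = 1, maf_range = c(0.05, 0.5),
                         beta_range = c(0.5, 1),
                         snp_effect_range = c(0.5, 1), noise_sd = 1,
                         outcome_parents = 3,
                         outcome_type = c("binary", "continuous"),
                         pleiotropy_prob = 0, seed = 1) {
  outcome_type <- match.arg(outcome_type)
  if (!is.null(expected_degree)) {
    stopifnot(expected_degree >= 0)
    edge_prob <- min(1, expected_degree / max(1, n_genes - 1))
  }
  stopifnot(n_genes >= 1, n_samples >= 4,
            edge_prob >= 0, edge_prob <= 1, snp_per_gene >= 0,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            beta_range[1] <= beta_range[2],
            snp_effect_range[1] <= snp_effect_range[2],
            noise_sd > 0, outcome_parents >= 1,
            pleiotropy_prob >= 0, pleiotropy_prob <= 1,
            abs(seed) < 2^30)
  structure(list(n_genes = as.integer(n_genes),
                 n_samples = as.integer(n_samples), edge_prob = edge_prob,
                 expected_degree = expected_degree,
                 snp_per_gene = as.integer(snp_per_gene),
                 maf_range = maf_range, beta_range = beta_range,
                 snp_effect_range = snp_effect_range, noise_sd = noise_sd,
                 outcome_parents = as.integer(min(outcome_parents, n_genes)),
                 outcome_type = outcome_type,
                 pleiotropy_prob = pleiotropy_prob,
                 seed = as.integer(seed)),
            class = "sim_scenario")
}

draw_signed <- function(n, range) {
  stats::runif(n, range[1], range[2]) * sample(c(-1, 1), n, replace = TRUE)
}

#' Draw a ground-truth causal structure
#'
#' Samples a random topological order over genes, gene-gene edges at
#' `edge_prob` respecting that order, `snp_per_gene` variant parents per
#' gene, and an outcome node with `outcome_parents` gene parents. All
#' structural coefficients are drawn from the scenario's ranges with random
#' signs. The result is acyclic by construction.
#'
#' @param scenario A [sim_scenario()].
#' @return A `ground_truth` object: list with `dag` (fully directed
#'   `mixed_graph`), `coefficients` (tibble `from`, `to`, `coefficient`),
#'   `mafs` (tibble `snp_id`, `maf`), `iv_map` (tibble `snp_id`,
#'   `gene_id`), `true_outcome_ancestors` (character) and the scenario.
#' @export
simulate_dag <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  set.seed(scenario$seed)
  ng <- scenario$n_genes
  genes <- sprintf("g%03d", seq_len(ng))
  topo <- sample(genes)                      # causal order
  from <- character(0); to <- character(0)
  if (ng >= 2) {
    for (i in seq_len(ng - 1)) {
      for (j in seq(i + 1, ng)) {
        if (stats::runif(1) < scenario$edge_prob) {
          from <- c(from, topo[i]); to <- c(to, topo[j])
        }
      }
    }
  }
  coef_tbl <- tibble(from = from, to = to,
                     coefficient = draw_signed(length(from),
                                               scenario$beta_range))
  ## SNP instruments
  snps <- character(0)
  iv_map <- tibble(snp_id = character(0), gene_id = character(0))
  if (scenario$snp_per_gene > 0) {
    for (gi in seq_len(ng)) {
      for (k in seq_len(scenario$snp_per_gene)) {
        s <- sprintf("snp_%s_%d", genes[gi], k)
        snps <- c(snps, s)
        iv_map <- dplyr::bind_rows(iv_map,
                                   tibble(snp_id = s, gene_id = genes[gi]))
        coef_tbl <- dplyr::bind_rows(
          coef_tbl,
          tibble(from = s, to = genes[gi],
                 coefficient = draw_signed(1, scenario$snp_effect_range)))
        if (scenario$pleiotropy_prob > 0 &&
            stats::runif(1) < scenario$pleiotropy_prob && ng > 1) {
          extra <- sample(setdiff(genes, genes[gi]), 1)
          coef_tbl <- dplyr::bind_rows(
            coef_tbl,
            tibble(from = s, to = extra,
                   coefficient = draw_signed(1, scenario$snp_effect_range)))
        }
      }
    }
  }
  mafs <- tibble(snp_id = snps,
                 maf = stats::runif(length(snps), scenario$maf_range[1],
                                    scenario$maf_range[2]))
  ## outcome parents
  out_pa <- sort(sample(genes, scenario$outcome_parents))
  coef_tbl <- dplyr::bind_rows(
    coef_tbl,
    tibble(from = out_pa, to = "outcome",
           coefficient = draw_signed(length(out_pa), scenario$beta_range)))

  nodes <- tibble(id = c(snps, genes, "outcome"),
                  tier = c(rep("variant", length(snps)),
                           rep("gene", ng), "outcome"))
  dag <- mixed_graph(nodes,
                     tibble(from = coef_tbl$from, to = coef_tbl$to,
                            state = "directed"))
  truth <- structure(
    list(dag = dag, coefficients = coef_tbl, mafs = mafs, iv_map = iv_map,
         true_outcome_ancestors = causal_ancestors(dag, "outcome"),
         scenario = scenario),
    class = "ground_truth")
  truth
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth: %d nodes, %d edges, %d true outcome ancestors>\n",
              nrow(x$dag$nodes), nrow(x$coefficients),
              length(x$true_outcome_ancestors)))
  invisible(x)
}

#' Generate data from a ground-truth structure
#'
#' Genotype dosages are drawn Binomial(2, MAF) independently per SNP and
#' enter the structural equations standardized; each gene is the
#' coefficient-weighted sum of its parents plus Gaussian noise, generated
#' in topological order; the outcome is a linear combination of its gene
#' parents plus noise, dichotomized at its median for the binary-liability
#' design. Output columns are samples. A fixed scenario seed makes the
#' output bit-identical across calls.
#'
#' @param truth A [simulate_dag()] result.
#' @param scenario The matching [sim_scenario()]; defaults to the one
#'   stored in `truth`.
#' @return A `sim_data` list: `expression` (genes x samples), `genotypes`
#'   (raw dosages, SNPs x samples), `outcome` (named numeric vector),
#'   `iv_map` (tibble `snp_id`, `gene_id`), `sample_ids`.
#' @export
simulate_data <- function(truth, scenario = truth$scenario) {
  stopifnot(inherits(truth, "ground_truth"))
  set.seed(scenario$seed + 1L)
  n <- scenario$n_samples
  samples <- sprintf("s%05d", seq_len(n))
  snps <- truth$mafs$snp_id
  genes <- truth$dag$nodes$id[truth$dag$nodes$tier == "gene"]

  geno <- matrix(0L, nrow = length(snps), ncol = n,
                 dimnames = list(snps, samples))
  geno_std <- matrix(0, nrow = length(snps), ncol = n,
                     dimnames = list(snps, samples))
  for (i in seq_along(snps)) {
    geno[i, ] <- stats::rbinom(n, 2, truth$mafs$maf[i])
    s <- stats::sd(geno[i, ])
    geno_std[i, ] <- if (s > 0) (geno[i, ] - mean(geno[i, ])) / s else 0
  }

  d <- directed_amat(truth$dag)
  ids <- truth$dag$nodes$id
  ord <- topo_order(d)
  expr <- matrix(NA_real_, nrow = length(genes), ncol = n,
                 dimnames = list(genes, samples))
  coef_key <- stats::setNames(truth$coefficients$coefficient,
                              paste(truth$coefficients$from,
                                    truth$coefficients$to, sep = "\r"))
  node_values <- matrix(0, nrow = length(ids), ncol = n,
                        dimnames = list(ids, samples))
  node_values[snps, ] <- geno_std[snps, , drop = FALSE]
  outcome_latent <- NULL
  for (v in ord) {
    id <- ids[v]
    if (id %in% snps) next
    pa <- ids[d[, v]]
    val <- stats::rnorm(n, 0, scenario$noise_sd)
    for (p_ in pa) {
      val <- val + coef_key[[paste(p_, id, sep = "\r")]] * node_values[p_, ]
    }
    node_values[id, ] <- val
    if (id == "outcome") outcome_latent <- val else expr[id, ] <- val
  }
  outcome <- outcome_latent
  if (scenario$outcome_type == "binary") {
    outcome <- as.integer(outcome_latent >= stats::median(outcome_latent))
  }
  names(outcome) <- samples
  structure(list(expression = expr, genotypes = geno, outcome = outcome,
                 iv_map = truth$iv_map, sample_ids = samples),
            class = "sim_data")
}

#' Block-structured expression data with planted modules
#'
#' Draws samples from a multivariate Gaussian whose correlation matrix has
#' equicorrelated blocks (`within_corr` inside each planted module,
#' `between_corr` across modules) — the fixture for clustering-recovery
#' tests.
#'
#' @param n_blocks Number of planted modules.
#' @param genes_per_block Genes per module.
#' @param within_corr,between_corr Correlations inside / across blocks;
#'   `0 <= between_corr <= within_corr < 1`.
#' @param n_samples Number of samples.
#' @param seed Integer seed.
#' @return List with `expression` (genes x samples) and `labels`
#'   (tibble `gene_id`, `module_id` of planted assignments).
#' @export
planted_modules_scenario <- function(n_blocks = 3, genes_per_block = 60,
                                     within_corr = 0.7, between_corr = 0.1,
                                     n_samples = 500, seed = 1) {
  stopifnot(between_corr >= 0, between_corr <= within_corr, within_corr < 1)
  p <- n_blocks * genes_per_block
  lab <- rep(seq_len(n_blocks), each = genes_per_block)
  sigma <- matrix(between_corr, p, p)
  for (b in seq_len(n_blocks)) {
    idx <- which(lab == b)
    sigma[idx, idx] <- within_corr
  }
  diag(sigma) <- 1
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) {
    abort(paste0("Implied block correlation matrix is not positive definite ",
                 "(smallest eigenvalue ", format(min(ev)), "); reduce ",
                 "`between_corr` or `within_corr`."))
  }
  set.seed(seed)
  z <- matrix(stats::rnorm(n_samples * p), n_samples, p)
  x <- z %*% chol(sigma)
  genes <- sprintf("g%03d", seq_len(p))
  expr <- t(x)
  dimnames(expr) <- list(genes, sprintf("s%05d", seq_len(n_samples)))
  list(expression = expr,
       labels = tibble(gene_id = genes,
                       module_id = sprintf("M%d", lab)))
}
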