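#' Graph serialization
#'
#' Writes a `mixed_graph` as (a) an edge-list TSV with columns `source`,
#' `target`, `state`, (b) GraphML with a `tier` attribute per node and a
#' `state` attribute per edge (via igraph), or (c) SIF
#' (`source relation target`) for network viewers.
#'
#' @param g A `mixed_graph`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_graph_tsv <- function(g, path) {
  ed <- tidy(g)
  readr::write_tsv(tibble(source = ed$from, target = ed$to,
                          state = ed$state), path)
  invisible(path)
}

#' @rdname write_graph_tsv
#' @export
write_graph_graphml <- function(g, path) {
  igraph::write_graph(as_igraph(g), path, format = "graphml")
  invisible(path)
}

#' @rdname write_graph_tsv
#' @export
write_graph_sif <- function(g, path) {
  ed <- tidy(g)
  rel <- ifelse(ed$state == "directed", "causes", "associates")
  writeLines(paste(ed$from, rel, ed$to, sep = "\t"), path)
  invisible(path)
}

#' Convert a mixed graph to igraph
#'
#' Directed igraph where an undirected edge is encoded by
#' `state = "undirected"` on a single arc; node `tier` is carried as a
#' vertex attribute.
#'
#' @param g A `mixed_graph`.
#' @return An `igraph` object.
#' @export
as_igraph <- function(g) {
  ed <- tidy(g)
  igraph::graph_from_data_frame(
    as.data.frame(ed), directed = TRUE,
    vertices = as.data.frame(g$nodes))
}

#' Read/write the package's tabular input formats
#'
#' Expression and genotype tables are TSV with variables in rows (first
#' column the gene/SNP id, remaining columns samples); the outcome table
#' has columns `sample_id`, `value`; the IV map has `snp_id`, `gene_id`;
#' the module table has `gene_id`, `module_id`.
#'
#' @param path File path.
#' @return `read_matrix_tsv()` returns a numeric matrix with rownames;
#'   the other readers return tibbles; writers return `path` invisibly.
#' @export
read_matrix_tsv <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(tbl[, -1])
  rownames(m) <- as.character(tbl[[1]])
  storage.mode(m) <- "double"
  m
}

#' @rdname read_matrix_tsv
#' @param m Matrix with rownames (variables) and colnames (samples).
#' @param id_col Name of the first (id) column.
#' @export
write_matrix_tsv <- function(m, path, id_col = "id") {
  tbl <- as_tibble(m, rownames = id_col)
  readr::write_tsv(tbl, path)
  invisible(path)
}

#' @rdname read_matrix_tsv
#' @export
read_outcome_tsv <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  stats::setNames(as.numeric(tbl$value), tbl$sample_id)
}

#' @rdname read_matrix_tsv
#' @export
read_iv_map_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(.default = readr::col_character()))
}

#' @rdname read_matrix_tsv
#' @export
read_modules_tsv <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  new_module_assignment(tbl[c("gene_id", "module_id")],
                        list(method = "file", path = path))
}

#' Write a simulated dataset in the CLI's TSV dialects
#'
#' Writes `expression.tsv`, `genotypes.tsv`, `outcome.tsv`, `iv_map.tsv`
#' and the ground-truth `truth_edges.tsv` (+ `truth_ancestors.tsv`) so a
#' simulate -> infer round trip can run through files.
#'
#' @param sim A [simulate_data()] result.
#' @param truth The matching [simulate_dag()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix_tsv(sim$expression, file.path(dir, "expression.tsv"),
                   id_col = "gene_id")
  write_matrix_tsv(sim$genotypes, file.path(dir, "genotypes.tsv"),
                   id_col = "snp_id")
  readr::write_tsv(tibble(sample_id = names(sim$outcome),
                          value = as.numeric(sim$outcome)),
                   file.path(dir, "outcome.tsv"))
  readr::write_tsv(sim$iv_map, file.path(dir, "iv_map.tsv"))
  write_graph_tsv(truth$dag, file.path(dir, "truth_edges.tsv"))
  writeLines(truth$true_outcome_ancestors,
             file.path(dir, "truth_ancestors.tsv"))
  invisible(dir)
}

#' Write per-module inference outputs
#'
#' For each module: the oriented graph as edge-list TSV, GraphML and SIF,
#' the causal-ancestor gene list, the CI-test log (when kept), and a JSON
#' summary with the reporting bins.
#'
#' @param results A `module_results` list (or single `module_result`).
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_module_results <- function(results, dir) {
  if (inherits(results, "module_result")) results <- list(results)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (r in results) {
    stem <- file.path(dir, r$module_id)
    write_graph_tsv(r$graph, paste0(stem, "_edges.tsv"))
    write_graph_graphml(r$graph, paste0(stem, "_graph.graphml"))
    write_graph_sif(r$graph, paste0(stem, "_graph.sif"))
    readr::write_tsv(tibble(gene_id = r$causal_ancestor_genes),
                     paste0(stem, "_ancestors.tsv"))
    if (!is.null(r$ci_log)) {
      readr::write_tsv(r$ci_log, paste0(stem, "_ci_log.tsv"))
    }
  }
  summary <- summarize_modules(results)
  jsonlite::write_json(
    c(as.list(summary),
      list(per_module = lapply(results, function(r) {
        list(module_id = r$module_id,
             n_genes = length(r$genes), n_snps = length(r$snps),
             n_causal_ancestors = length(r$causal_ancestor_genes),
             n_ci_tests = r$ci_test_counts$n_tests)
      }))),
    file.path(dir, "summary.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
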