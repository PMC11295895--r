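#' Soft-threshold adjacency from a correlation matrix
#'
#' Unsigned weighted-network adjacency: `a_ij = |cor_ij|^beta`. Raising to
#' the power `beta` suppresses weak correlations so the network's degree
#' distribution can approximate a power law (scale-free topology).
#'
#' @param corr Symmetric correlation matrix.
#' @param beta Soft-thresholding power (integer >= 1).
#' @return Adjacency matrix in `[0, 1]` with unit diagonal and attribute
#'   `beta`.
#' @export
soft_threshold_adjacency <- function(corr, beta) {
  stopifnot(beta >= 1)
  a <- abs(corr)^beta
  diag(a) <- 1
  attr(a, "beta") <- beta
  a
}

#' Scale-free topology fit of a weighted network
#'
#' Computes each gene's connectivity `k_i = sum_{j != i} a_ij`, bins the
#' connectivities into equal-width bins, and regresses
#' `log10(frequency)` on `log10(mean connectivity)` over non-empty bins.
#' A high R-squared indicates an approximately power-law degree
#' distribution.
#'
#' @param adj Adjacency matrix (see [soft_threshold_adjacency()]).
#' @param bins Number of connectivity bins (>= 5).
#' @return A one-row tibble with `r_squared`, `slope`, `bins_used`.
#' @export
scale_free_fit <- function(adj, bins = 10) {
  p <- nrow(adj)
  if (p < 10) abort("At least 10 genes are required for a scale-free fit.")
  if (bins < 5) abort("`bins` must be >= 5.")
  k <- rowSums(adj) - diag(adj)
  if (max(k) - min(k) < 1e-12) {
    abort("All connectivities are identical; scale-free fit undefined.")
  }
  cut_idx <- cut(k, breaks = bins, include.lowest = TRUE)
  freq <- tapply(k, cut_idx, length)
  mean_k <- tapply(k, cut_idx, mean)
  keep <- !is.na(freq) & freq > 0 & mean_k > 0
  freq <- freq[keep] / length(k)
  mean_k <- mean_k[keep]
  if (length(freq) < 2) abort("Too few non-empty bins for the regression.")
  fit <- stats::lm(log10(freq) ~ log10(mean_k))
  tibble(r_squared = summary(fit)$r.squared,
         slope = unname(stats::coef(fit)[2]),
         bins_used = length(freq))
}

#' Choose the soft-thresholding power for scale-free topology
#'
#' Scans candidate powers in ascending order and returns the smallest
#' whose [scale_free_fit()] R-squared reaches `target_r2`; if none
#' qualifies, the power maximizing R-squared is returned with a warning.
#'
#' @param corr Gene-gene correlation matrix.
#' @param target_r2 Target scale-free R-squared (default 0.85).
#' @param powers Candidate powers, ascending.
#' @param bins Connectivity bins for the fit.
#' @return The chosen power (integer) with attribute `diagnostics`: a
#'   tibble with `power`, `r_squared`, `slope`, `mean_connectivity`.
#' @export
pick_soft_threshold <- function(corr, target_r2 = 0.85, powers = 1:20,
                                bins = 10) {
  if (length(powers) == 0) abort("`powers` must be non-empty.")
  if (is.unsorted(powers)) abort("`powers` must be ascending.")
  diag_rows <- purrr::map(powers, function(b) {
    adj <- soft_threshold_adjacency(corr, b)
    fit <- tryCatch(scale_free_fit(adj, bins = bins),
                    error = function(e) tibble(r_squared = NA_real_,
                                               slope = NA_real_,
                                               bins_used = NA_integer_))
    dplyr::mutate(fit, power = b,
                  mean_connectivity = mean(rowSums(adj) - 1))
  })
  diagnostics <- dplyr::bind_rows(diag_rows)[
    , c("power", "r_squared", "slope", "mean_connectivity", "bins_used")]
  ok <- which(!is.na(diagnostics$r_squared) &
                diagnostics$r_squared >= target_r2)
  if (length(ok) > 0) {
    chosen <- diagnostics$power[ok[1]]
  } else {
    chosen <- diagnostics$power[which.max(diagnostics$r_squared)]
    warn(sprintf("No candidate power reached R^2 = %g; returning argmax power %d (R^2 = %.3f).",
                 target_r2, chosen,
                 max(diagnostics$r_squared, na.rm = TRUE)))
  }
  structure(as.integer(chosen), diagnostics = diagnostics)
}

#' Topological overlap matrix
#'
#' Unsigned TOM (Zhang-Horvath form): for `i != j`,
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `k_i = sum_{u != i} a_iu`, and unit diagonal. Two genes overlap both
#' through their direct adjacency and through shared neighbours;
#' `1 - TOM` is the clustering dissimilarity.
#'
#' @param adj Adjacency matrix.
#' @return TOM matrix in `[0, 1]` with unit diagonal.
#' @export
topological_overlap <- function(adj) {
  a <- as.matrix(adj)
  diag(a) <- 0
  L <- a %*% a                     # shared-neighbour weight, u != i,j by diag 0
  k <- rowSums(a)
  kmin <- outer(k, k, pmin)
  tom <- (L + a) / (kmin + 1 - a)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adj)
  tom
}

new_module_assignment <- function(tbl, metadata) {
  structure(tbl, class = c("module_assignment", class(tibble())),
            metadata = metadata)
}

## relabel clusters deterministically: M1 = largest, ties by first gene
relabel_modules <- function(genes, labels) {
  sizes <- table(labels)
  first <- tapply(seq_along(labels), labels, min)
  ord <- order(-as.vector(sizes[names(first)]), as.vector(first))
  map <- stats::setNames(sprintf("M%d", seq_along(ord)), names(first)[ord])
  tibble(gene_id = genes, module_id = unname(map[as.character(labels)]))
}

## average dissimilarity between two clusters
avg_diss <- function(diss, ia, ib) mean(diss[ia, ib])

#' Hierarchical module detection on TOM dissimilarities
#'
#' Average-linkage hierarchical clustering of `1 - TOM`, cut either at a
#' fixed dissimilarity height (default) or to a requested module count,
#' followed by two merge steps: clusters whose average inter-cluster
#' dissimilarity falls below `merge_cut_height` are merged, and clusters
#' smaller than `min_module_size` are absorbed into their nearest cluster
#' by average dissimilarity. This parameterized cut plays the role of a
#' dynamic tree cut while keeping every step explicit and reproducible.
#'
#' @param tom TOM matrix from [topological_overlap()].
#' @param min_module_size Minimum genes per final module (default 40).
#' @param n_modules_hint Optional requested number of initial clusters
#'   (overrides `cut_height`).
#' @param cut_height Static tree-cut height on the dissimilarity scale.
#' @param merge_cut_height Merge clusters closer than this average
#'   dissimilarity (default 0.3).
#' @return A `module_assignment`: tibble (`gene_id`, `module_id`) with cut
#'   parameters stored in `attr(, "metadata")`.
#' @export
hierarchical_modules <- function(tom, min_module_size = 40,
                                 n_modules_hint = NULL, cut_height = 0.99,
                                 merge_cut_height = 0.3) {
  p <- nrow(tom)
  genes <- rownames(tom) %||% sprintf("g%03d", seq_len(p))
  if (p < 2 * min_module_size) {
    abort(sprintf("Need at least 2 * min_module_size = %d genes; got %d.",
                  2 * min_module_size, p))
  }
  diss <- 1 - tom
  hc <- stats::hclust(stats::as.dist(diss), method = "average")
  labels <- if (!is.null(n_modules_hint)) {
    stats::cutree(hc, k = n_modules_hint)
  } else {
    stats::cutree(hc, h = cut_height)
  }
  ## merge clusters with low average inter-cluster dissimilarity
  repeat {
    cl <- sort(unique(labels))
    if (length(cl) < 2) break
    best <- NULL; best_d <- Inf
    for (ai in seq_len(length(cl) - 1)) {
      for (bi in seq(ai + 1, length(cl))) {
        d_ <- avg_diss(diss, labels == cl[ai], labels == cl[bi])
        if (d_ < best_d) { best_d <- d_; best <- c(cl[ai], cl[bi]) }
      }
    }
    if (best_d >= merge_cut_height) break
    labels[labels == best[2]] <- best[1]
  }
  ## absorb clusters below the minimum size into their nearest cluster
  repeat {
    sizes <- table(labels)
    if (length(sizes) < 2) break
    small <- names(sizes)[sizes < min_module_size]
    if (length(small) == 0) break
    s <- small[which.min(sizes[small])]
    others <- setdiff(names(sizes), s)
    d_ <- vapply(others, function(o) {
      avg_diss(diss, labels == as.integer(s), labels == as.integer(o))
    }, numeric(1))
    labels[labels == as.integer(s)] <- as.integer(others[which.min(d_)])
  }
  new_module_assignment(
    relabel_modules(genes, labels),
    list(method = "hierarchical", cut_height = cut_height,
         n_modules_hint = n_modules_hint,
         min_module_size = min_module_size,
         merge_cut_height = merge_cut_height))
}

#' k-means refinement of a module assignment
#'
#' Lloyd iterations on the rows of the TOM dissimilarity matrix (each gene
#' embedded as its vector of dissimilarities to all genes), with centroids
#' initialized from the per-module mean rows of `init` and `k` fixed to
#' `init`'s module count. The within-cluster sum of squared distances is
#' non-increasing across iterations; a module emptied during iteration is
#' dropped with a warning.
#'
#' @param tom TOM matrix.
#' @param init A `module_assignment` covering all genes in `tom`.
#' @param max_iter Maximum Lloyd iterations.
#' @return A refined `module_assignment`; `attr(, "metadata")` records the
#'   per-iteration objective trajectory.
#' @export
kmeans_refine <- function(tom, init, max_iter = 100) {
  genes <- rownames(tom) %||% init$gene_id
  if (!setequal(genes, init$gene_id)) {
    abort("`init` must label exactly the genes of `tom`.")
  }
  D <- 1 - tom
  lab <- init$module_id[match(genes, init$gene_id)]
  mods <- sort(unique(lab))
  objective <- numeric(0)
  dropped <- character(0)
  for (iter in seq_len(max_iter)) {
    ## centroids: per-module mean dissimilarity rows
    cent <- do.call(rbind, lapply(mods, function(m) {
      colMeans(D[lab == m, , drop = FALSE])
    }))
    ## squared distances of every gene row to every centroid
    cross <- D %*% t(cent)
    d2 <- outer(rowSums(D^2), rep(1, nrow(cent))) - 2 * cross +
      outer(rep(1, nrow(D)), rowSums(cent^2))
    new_idx <- max.col(-d2, ties.method = "first")
    new_lab <- mods[new_idx]
    if (iter == 1) {
      ## objective of the initial assignment under its own centroids
      objective <- sum(d2[cbind(seq_len(nrow(D)), match(lab, mods))])
    }
    objective <- c(objective, sum(d2[cbind(seq_len(nrow(D)), new_idx)]))
    empty <- setdiff(mods, unique(new_lab))
    if (length(empty) > 0) {
      warn(paste0("Module(s) emptied during k-means refinement: ",
                  paste(empty, collapse = ", ")))
      dropped <- c(dropped, empty)
      mods <- setdiff(mods, empty)
    }
    if (all(new_lab == lab)) { lab <- new_lab; break }
    lab <- new_lab
  }
  new_module_assignment(
    relabel_modules(genes, lab),
    list(method = "kmeans_refine", iterations = length(objective),
         objective = objective, dropped = dropped,
         init_metadata = attr(init, "metadata")))
}
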