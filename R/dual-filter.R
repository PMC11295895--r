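#' Configuration for the dual-order pre-filter
#'
#' @param alpha Significance level of each CI test.
#' @param max_depth How many dual steps inward to take. Depth 1 tests each
#'   pair at order 0 and at the full neighbour order `k` only; depth `d`
#'   additionally tests conditioning sets of sizes `1, k-1`, ...,
#'   `d-1, k-d+1`.
#' @param lambda Shrinkage intensity for singular sub-correlation matrices.
#' @param max_sets At depths beyond 1, the number of candidate conditioning
#'   sets tried per edge and per size (correlation-guided; see Details of
#'   [dual_filter_pass()]).
#' @return A `filter_config` list.
#' @export
filter_config <- function(alpha = 0.05, max_depth = 1, lambda = 1e-3,
                          max_sets = 20) {
  stopifnot(alpha > 0, alpha < 1, max_depth >= 1, lambda >= 0, max_sets >= 1)
  structure(list(alpha = alpha, max_depth = as.integer(max_depth),
                 lambda = lambda, max_sets = as.integer(max_sets)),
            class = "filter_config")
}

## index pairs (i < j, node order) of edges currently present
edge_pairs <- function(g) {
  inc <- (g$amat | t(g$amat))
  which(inc & upper.tri(inc), arr.ind = TRUE)
}

## vectorized order-0 Fisher tests on index pairs (into stats); returns
## logical vector `independent`, and records the batch
order0_batch <- function(engine, ids_x, ids_y, stage) {
  if (engine$type == "fisher") {
    st <- engine$stats
    rho <- st$corr[cbind(ids_x, ids_y)]
    rc <- pmax(pmin(rho, 1 - 1e-12), -(1 - 1e-12))
    stat <- sqrt(st$n - 3) * abs(atanh(rc))
    p <- 2 * stats::pnorm(stat, lower.tail = FALSE)
    record_batch(engine, ids_x, ids_y, 0L, stat, p, stage)
    p > engine$alpha
  } else {
    vapply(seq_along(ids_x), function(k) {
      ci_test(engine, ids_x[k], ids_y[k], character(0), stage)$independent
    }, logical(1))
  }
}

#' Full-order partial correlations in one inversion
#'
#' Inverts the correlation sub-matrix over `members` once and reads off,
#' for every pair, the partial correlation given all remaining members:
#' `rho_ij.rest = -P_ij / sqrt(P_ii P_jj)`. This single inversion is what
#' makes the dual-order filter cheap: one matrix solve replaces one
#' high-order test per pair.
#'
#' @param stats A [sufficient_stats()] object.
#' @param members Character vector of node ids (at least 2).
#' @param lambda Shrinkage intensity used if the sub-matrix is singular;
#'   the result then carries attribute `flagged = TRUE`.
#' @return A symmetric matrix of full-order partial correlations with unit
#'   diagonal, dimnames `members`.
#' @export
full_order_partial_corr_matrix <- function(stats, members, lambda = 1e-3) {
  members <- as.character(members)
  if (length(members) < 2) abort("`members` must contain at least 2 nodes.")
  sub <- stats$corr[members, members]
  flagged <- FALSE
  P <- tryCatch(solve(sub), error = function(e) NULL)
  if (is.null(P) || !all(is.finite(P))) {
    P <- shrunk_solve(sub, lambda)
    flagged <- TRUE
  }
  dinv <- 1 / sqrt(diag(P))
  out <- -P * tcrossprod(dinv)
  diag(out) <- 1
  out <- (out + t(out)) / 2
  dimnames(out) <- list(members, members)
  if (flagged) attr(out, "flagged") <- TRUE
  out
}

## p-value of a Fisher z test given a partial correlation, n, |S|
fisher_p <- function(rho, n, ord) {
  rc <- pmax(pmin(rho, 1 - 1e-12), -(1 - 1e-12))
  stat <- sqrt(n - ord - 3) * abs(atanh(rc))
  2 * stats::pnorm(stat, lower.tail = FALSE)
}

#' Dual-order edge pre-filter
#'
#' The initial edge-reduction step of MRdualPC. Each remaining edge (x, y)
#' is tested for independence conditioning simultaneously on the empty set
#' (order 0) and on the full set of x's other neighbours (order `k`, via a
#' single precision-matrix inversion when the graph is complete). With
#' `max_depth > 1` the filter then marches inward, testing conditioning
#' sets of size `d` together with their complements of size `k - d`. An
#' edge is removed — and the first independence-witnessing set recorded as
#' its separating set — the first time any test reports independence.
#'
#' Neighbour sets are frozen at the start of the pass (synchronous
#' deletion, PC-stable style), so the result does not depend on the order
#' in which edges are visited. At depths beyond 1, candidate subsets of
#' size `d` are drawn from x's neighbours sorted by descending marginal
#' correlation with x, taking at most `max_sets` subsets in deterministic
#' lexicographic order.
#'
#' @param g An undirected `mixed_graph`.
#' @param engine A `ci_engine`, or a [sufficient_stats()] object (wrapped
#'   with `config$alpha`).
#' @param config A [filter_config()].
#' @return The filtered `mixed_graph` (edge set a subset of the input's;
#'   all edges still undirected).
#' @export
dual_filter_pass <- function(g, engine, config = filter_config()) {
  engine <- as_engine(engine, alpha = config$alpha, lambda = config$lambda)
  ed <- tidy(g)
  if (any(ed$state == "directed")) abort("`g` must be fully undirected.")
  ids <- g$nodes$id
  adj <- adjacency_list(g)                       # frozen at pass start
  pairs <- edge_pairs(g)
  if (nrow(pairs) == 0) return(g)
  px <- ids[pairs[, 1]]; py <- ids[pairs[, 2]]

  removed <- rep(FALSE, nrow(pairs))
  sepsets <- vector("list", nrow(pairs))

  ## order-0 sweep
  ind0 <- order0_batch(engine, px, py, "filter")
  removed[ind0] <- TRUE
  sepsets[ind0] <- list(character(0))

  ## full-order sweep on order-0 survivors
  full_mat <- NULL                               # lazy shared inversion
  all_full <- function() {
    if (is.null(full_mat) && engine$type == "fisher" && length(ids) >= 3) {
      full_mat <<- full_order_partial_corr_matrix(engine$stats, ids,
                                                  lambda = engine$lambda)
    }
    full_mat
  }
  n_all <- length(ids)
  for (e in which(!removed)) {
    x <- px[e]; y <- py[e]
    K <- ids[setdiff(adj[[pairs[e, 1]]], pairs[e, 2])]
    if (length(K) == 0) next                     # order 0 already tested
    if (engine$type == "fisher" &&
        length(K) == n_all - 2 && n_all >= 3) {
      fm <- all_full()
      rho <- fm[x, y]
      df <- engine$stats$n - length(K) - 3
      if (df < 1) next                           # refuse: keep the edge
      p <- fisher_p(rho, engine$stats$n, length(K))
      record_test(engine, x, y, K, sqrt(df) * abs(atanh(pmax(pmin(rho, 1 - 1e-12), -(1 - 1e-12)))), p, "filter")
      if (p > engine$alpha) {
        removed[e] <- TRUE
        sepsets[[e]] <- K
      }
    } else {
      res <- ci_test(engine, x, y, K, "filter")
      if (res$independent) {
        removed[e] <- TRUE
        sepsets[[e]] <- K
      }
    }
  }

  ## inward march (opt-in depths beyond 1)
  if (config$max_depth > 1) {
    for (d in seq_len(config$max_depth - 1)) {
      for (e in which(!removed)) {
        x <- px[e]; y <- py[e]
        K <- ids[setdiff(adj[[pairs[e, 1]]], pairs[e, 2])]
        k <- length(K)
        if (k <= d || d >= k - d) next           # orders already covered
        Ks <- if (engine$type == "fisher") {
          K[order(-abs(engine$stats$corr[x, K]), match(K, ids))]
        } else {
          K
        }
        subs <- utils::combn(seq_len(k), d, simplify = FALSE)
        subs <- subs[seq_len(min(length(subs), config$max_sets))]
        for (s_idx in subs) {
          S1 <- Ks[s_idx]
          S2 <- setdiff(K, S1)
          hit <- NULL
          if (ci_test(engine, x, y, S1, "filter")$independent) {
            hit <- S1
          } else if (ci_test(engine, x, y, S2, "filter")$independent) {
            hit <- S2
          }
          if (!is.null(hit)) {
            removed[e] <- TRUE
            sepsets[[e]] <- hit
            break
          }
        }
      }
    }
  }

  keep <- which(removed)
  g <- remove_edges_batch(g, px[keep], py[keep], sepsets[keep])
  g
}

#' Marginal (order-0) edge filter
#'
#' The per-module pre-step: edges whose endpoints show no evidence of
#' marginal dependence (Fisher's z p-value above `alpha`) are removed, with
#' the empty set recorded as the separating set.
#'
#' @inheritParams dual_filter_pass
#' @param alpha Significance level.
#' @return The filtered `mixed_graph`.
#' @export
marginal_filter <- function(g, engine, alpha = 0.05) {
  engine <- as_engine(engine, alpha = alpha)
  ed <- tidy(g)
  if (any(ed$state == "directed")) abort("`g` must be fully undirected.")
  ids <- g$nodes$id
  pairs <- edge_pairs(g)
  if (nrow(pairs) == 0) return(g)
  px <- ids[pairs[, 1]]; py <- ids[pairs[, 2]]
  ind <- order0_batch(engine, px, py, "filter")
  g <- remove_edges_batch(g, px[ind], py[ind],
                          rep(list(character(0)), sum(ind)))
  g
}
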