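#' Configuration for PC skeleton refinement
#'
#' @param alpha Significance level of each CI test.
#' @param max_order Highest conditioning-set size tried; `Inf` (default)
#'   lets the search terminate naturally when no edge has a large enough
#'   neighbourhood.
#' @param stable Use PC-stable synchronous deletion (neighbourhoods frozen
#'   per order), making the result independent of edge visiting order.
#'   `FALSE` gives the original sequential PC behaviour.
#' @param lambda Shrinkage intensity for singular sub-correlation matrices.
#' @return A `skeleton_config` list.
#' @export
skeleton_config <- function(alpha = 0.05, max_order = Inf, stable = TRUE,
                            lambda = 1e-3) {
  stopifnot(alpha > 0, alpha < 1, max_order >= 0)
  structure(list(alpha = alpha, max_order = max_order, stable = stable,
                 lambda = lambda),
            class = "skeleton_config")
}

#' PC-style skeleton refinement
#'
#' Ascending-order conditional-independence deletion: at order
#' `l = 0, 1, 2, ...`, every remaining edge (x, y) for which an endpoint
#' has at least `l` other neighbours is tested against every size-`l`
#' subset of that endpoint's neighbourhood (both endpoints tried,
#' deterministic lexicographic enumeration in node order). The first
#' independence deletes the edge and records the subset as its separating
#' set. The search stops when no edge admits a neighbourhood of the current
#' order. The input may be a complete graph or the output of
#' [dual_filter_pass()] / [marginal_filter()] — a pre-filtered input is the
#' mechanism that makes the search fast, since far fewer edges survive to
#' the expensive higher orders.
#'
#' @param g An undirected `mixed_graph`.
#' @param engine A `ci_engine` or [sufficient_stats()] object.
#' @param config A [skeleton_config()].
#' @return The refined skeleton with a complete separating-set table.
#' @export
refine_skeleton <- function(g, engine, config = skeleton_config()) {
  engine <- as_engine(engine, alpha = config$alpha, lambda = config$lambda)
  ed <- tidy(g)
  if (any(ed$state == "directed")) abort("`g` must be fully undirected.")
  ids <- g$nodes$id
  eix <- engine_index(engine, ids)     # graph position -> engine position

  l <- 0L
  repeat {
    if (l > config$max_order) break
    adj_frozen <- adjacency_list(g)            # PC-stable: per-order freeze
    pairs <- edge_pairs(g)
    if (nrow(pairs) == 0) break
    any_candidate <- FALSE
    removed <- rep(FALSE, nrow(pairs))
    hits <- vector("list", nrow(pairs))
    for (e in seq_len(nrow(pairs))) {
      i <- pairs[e, 1]; j <- pairs[e, 2]
      x <- ids[i]; y <- ids[j]
      if (!config$stable && !has_edge(g, x, y)) next
      adj_now <- if (config$stable) adj_frozen else adjacency_list(g)
      nb_x <- setdiff(adj_now[[i]], j)
      nb_y <- setdiff(adj_now[[j]], i)
      hit <- NULL
      if (l == 0L) {
        any_candidate <- TRUE
        if (ci_test_int(engine, eix[i], eix[j], integer(0), "skeleton")) {
          hit <- character(0)
        }
      } else {
        sides <- list(nb_x, nb_y)
        for (s in 1:2) {
          nb <- sides[[s]]
          if (length(nb) < l) next
          any_candidate <- TRUE
          ## enumerate positions, not values: combn(x, m) with scalar x
          ## would expand to seq_len(x)
          subs <- utils::combn(seq_along(nb), l, simplify = FALSE)
          for (pos in subs) {
            S_idx <- nb[pos]
            ## avoid re-testing a subset already tried from the other side
            if (s == 2 && all(S_idx %in% nb_x)) next
            if (ci_test_int(engine, eix[i], eix[j], eix[S_idx], "skeleton")) {
              hit <- ids[S_idx]
              break
            }
          }
          if (!is.null(hit)) break
        }
      }
      if (!is.null(hit)) {
        removed[e] <- TRUE
        if (config$stable) {
          hits[[e]] <- hit               # delete synchronously after the order
        } else {
          g <- remove_edge(g, x, y, hit)
        }
      }
    }
    if (config$stable && any(removed)) {
      keep <- which(removed)
      g <- remove_edges_batch(g, ids[pairs[keep, 1]], ids[pairs[keep, 2]],
                              hits[keep])
    }
    if (l > 0L && !any_candidate) break
    l <- l + 1L
  }
  g
}
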