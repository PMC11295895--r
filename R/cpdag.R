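#' The CPDAG of a DAG by compelled-edge labelling
#'
#' Computes the completed partially directed acyclic graph (the
#' Markov-equivalence-class representative) of a fully directed acyclic
#' `mixed_graph` using Chickering's edge-ordering and compelled/reversible
#' labelling procedure. This is a reference construction, deliberately
#' implemented by a different algorithm than the package's own
#' orientation-rule closure, so the two can check each other.
#'
#' @param dag A fully directed acyclic `mixed_graph`.
#' @return A `mixed_graph` with compelled edges directed and reversible
#'   edges undirected.
#' @export
true_cpdag <- function(dag) {
  d <- directed_amat(dag)
  if (any(dag$amat == 1L & t(dag$amat) == 1L)) {
    abort("`dag` must be fully directed.")
  }
  p <- nrow(d)
  ids <- dag$nodes$id
  ord <- topo_order(d)                 # ord[k] = node index at position k
  pos <- integer(p); pos[ord] <- seq_len(p)

  ## --- order the edges ---
  edges <- which(d, arr.ind = TRUE)    # columns: from, to
  m <- nrow(edges)
  edge_order <- integer(m)
  ordered <- rep(FALSE, m)
  i <- 0
  while (any(!ordered)) {
    un <- which(!ordered)
    ## lowest-ordered head with an unordered incoming edge
    y_pos <- min(pos[edges[un, 2]])
    cand <- un[pos[edges[un, 2]] == y_pos]
    ## highest-ordered tail among those
    x_pos <- max(pos[edges[cand, 1]])
    e <- cand[pos[edges[cand, 1]] == x_pos][1]
    i <- i + 1
    edge_order[e] <- i
    ordered[e] <- TRUE
  }

  ## --- label the edges ---
  ## 0 = unknown, 1 = compelled, 2 = reversible
  lab <- rep(0L, m)
  eidx <- function(from, to) which(edges[, 1] == from & edges[, 2] == to)
  in_edges <- function(to) which(edges[, 2] == to)
  for (e in order(edge_order)) {
    if (lab[e] != 0L) next
    x <- edges[e, 1]; y <- edges[e, 2]
    done <- FALSE
    for (ew in in_edges(x)) {
      if (lab[ew] != 1L) next
      w <- edges[ew, 1]
      if (!d[w, y]) {
        ## w -> x compelled and w not a parent of y: x -> y and every
        ## unknown edge into y become compelled
        ie <- in_edges(y)
        lab[ie[lab[ie] == 0L]] <- 1L
        done <- TRUE
        break
      } else {
        lab[eidx(w, y)] <- 1L
      }
    }
    if (!done) {
      ## any z -> y with z != x and z not a parent of x?
      zs <- which(d[, y])
      zs <- zs[zs != x]
      zs <- zs[!d[zs, x]]
      ie <- in_edges(y)
      if (length(zs) > 0) {
        lab[ie[lab[ie] == 0L]] <- 1L
      } else {
        lab[ie[lab[ie] == 0L]] <- 2L
      }
    }
  }

  amat <- matrix(0L, p, p, dimnames = list(ids, ids))
  for (e in seq_len(m)) {
    x <- edges[e, 1]; y <- edges[e, 2]
    if (lab[e] == 1L) {
      amat[x, y] <- 1L
    } else {
      amat[x, y] <- 1L
      amat[y, x] <- 1L
    }
  }
  new_mixed_graph(dag$nodes, amat, dag$sepsets)
}

## v-structures (unshielded colliders) of a fully directed DAG, as a tibble
## with x < z ordering on the spouse pair
v_structures <- function(dag) {
  d <- directed_amat(dag)
  adj <- d | t(d)
  ids <- dag$nodes$id
  out <- list()
  for (z in seq_len(nrow(d))) {
    pa <- which(d[, z])
    if (length(pa) < 2) next
    for (a_i in seq_len(length(pa) - 1)) {
      for (b_i in seq(a_i + 1, length(pa))) {
        a <- pa[a_i]; b <- pa[b_i]
        if (!adj[a, b]) {
          out[[length(out) + 1L]] <- tibble(x = ids[min(a, b)],
                                            z = ids[z],
                                            y = ids[max(a, b)])
        }
      }
    }
  }
  if (length(out) == 0) {
    return(tibble(x = character(0), z = character(0), y = character(0)))
  }
  dplyr::bind_rows(out)
}
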