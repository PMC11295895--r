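## d-separation on a directed adjacency matrix (TRUE at [i,j] means i -> j),
## by the ancestral moral graph construction: restrict to ancestors of
## {x, y} and S, moralize (marry parents, drop directions), delete S, and
## test undirected connectivity of x and y.
d_separated_amat <- function(dmat, ids, x, y, S) {
  xi <- match(x, ids); yi <- match(y, ids)
  si <- match(S, ids)
  if (anyNA(c(xi, yi, si))) abort("Unknown node id in d-separation query.")
  d_sep_idx(dmat, xi, yi, si)
}

## index-based core of the d-separation oracle
d_sep_idx <- function(dmat, xi, yi, si) {
  p <- nrow(dmat)
  ## ancestors (incl. selves) of query nodes
  anc <- rep(FALSE, p)
  frontier <- c(xi, yi, si)
  anc[frontier] <- TRUE
  while (length(frontier) > 0) {
    pa <- which(rowSums(dmat[, frontier, drop = FALSE]) > 0)
    frontier <- pa[!anc[pa]]
    anc[frontier] <- TRUE
  }
  keep <- which(anc)
  d2 <- dmat[keep, keep, drop = FALSE]
  m <- d2 | t(d2)
  ## marry parents of each common child
  for (k in seq_along(keep)) {
    pa <- which(d2[, k])
    if (length(pa) >= 2) m[pa, pa] <- TRUE
  }
  diag(m) <- FALSE
  ## delete conditioning nodes, test connectivity
  drop <- match(si, keep)
  ok <- setdiff(seq_along(keep), drop)
  m <- m[ok, ok, drop = FALSE]
  xs <- match(xi, keep[ok]); ys <- match(yi, keep[ok])
  seen <- rep(FALSE, length(ok))
  seen[xs] <- TRUE
  frontier <- xs
  while (length(frontier) > 0) {
    nb <- which(rowSums(m[, frontier, drop = FALSE]) > 0)
    frontier <- nb[!seen[nb]]
    seen[frontier] <- TRUE
    if (seen[ys]) return(FALSE)
  }
  !seen[ys]
}

#' Exact d-separation query on a DAG
#'
#' Answers whether `x` and `y` are d-separated given `S` in a fully
#' directed acyclic `mixed_graph`, via the ancestral moral graph. Used as
#' the infallible oracle when verifying that the constraint-based search
#' recovers true structure.
#'
#' @param dag A fully directed acyclic `mixed_graph`.
#' @param x,y Node ids.
#' @param S Conditioning set (character vector, may be empty).
#' @return `TRUE` if `x` and `y` are d-separated given `S`.
#' @export
d_separated <- function(dag, x, y, S = character(0)) {
  d_separated_amat(directed_amat(dag), dag$nodes$id, x, y, as.character(S))
}

## topological order of a directed adjacency matrix; errors on cycles
topo_order <- function(dmat) {
  p <- nrow(dmat)
  indeg <- colSums(dmat)
  order <- integer(0)
  avail <- which(indeg == 0)
  indeg[avail] <- NA
  while (length(avail) > 0) {
    v <- avail[1]
    avail <- avail[-1]
    order <- c(order, v)
    ch <- which(dmat[v, ])
    for (c_ in ch) {
      indeg[c_] <- indeg[c_] - 1
      if (!is.na(indeg[c_]) && indeg[c_] == 0) {
        avail <- c(avail, c_)
        indeg[c_] <- NA
      }
    }
  }
  if (length(order) < p) abort("Graph is not acyclic.")
  order
}
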