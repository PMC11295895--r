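#' @importFrom rlang .data abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

node_tiers <- c("variant", "gene", "outcome")

pair_key <- function(x, y) {
  paste(pmin(x, y), pmax(x, y), sep = "\r")
}

new_mixed_graph <- function(nodes, amat, sepsets = list()) {
  structure(
    list(nodes = nodes, amat = amat, sepsets = sepsets),
    class = "mixed_graph"
  )
}

#' Construct a tiered mixed graph
#'
#' A `mixed_graph` holds nodes on three tiers (`"variant"`, `"gene"`,
#' `"outcome"`), edges that are either undirected or directed, and the
#' separating sets recorded when edges are deleted during constraint-based
#' search. Directed edges may never point into a `variant` node: genetic
#' variants are causally upstream of molecular phenotypes, which is the
#' Mendelian randomization assumption that anchors edge orientation.
#'
#' Iteration over nodes and node pairs always follows the order of the
#' `nodes` table, so repeated runs are reproducible.
#'
#' @param nodes A data frame with columns `id` (unique character) and `tier`
#'   (one of `"variant"`, `"gene"`, `"outcome"`). At most one outcome node
#'   is allowed.
#' @param edges Optional data frame with columns `from`, `to` and `state`
#'   (`"undirected"` or `"directed"`); `directed` means `from -> to`.
#' @return A `mixed_graph` object.
#' @examples
#' g <- mixed_graph(
#'   tibble::tibble(id = c("rs1", "A", "B"), tier = c("variant", "gene", "gene")),
#'   tibble::tibble(from = c("rs1", "A"), to = c("A", "B"),
#'                  state = c("directed", "undirected"))
#' )
#' tidy(g)
#' @export
mixed_graph <- function(nodes, edges = NULL) {
  nodes <- as_tibble(nodes)
  if (!all(c("id", "tier") %in% names(nodes))) {
    abort("`nodes` must have columns `id` and `tier`.")
  }
  nodes <- nodes[c("id", "tier")]
  nodes$id <- as.character(nodes$id)
  nodes$tier <- as.character(nodes$tier)
  if (anyDuplicated(nodes$id)) {
    abort(paste0("Duplicate node ids: ",
                 paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", ")))
  }
  if (!all(nodes$tier %in% node_tiers)) {
    abort("`tier` must be one of \"variant\", \"gene\", \"outcome\".")
  }
  if (sum(nodes$tier == "outcome") > 1) {
    abort("A graph may contain at most one outcome node.")
  }
  p <- nrow(nodes)
  if (p == 0) abort("`nodes` must be non-empty.")
  amat <- matrix(0L, p, p, dimnames = list(nodes$id, nodes$id))
  g <- new_mixed_graph(nodes, amat)
  if (!is.null(edges) && nrow(as.data.frame(edges)) > 0) {
    edges <- as_tibble(edges)
    for (r in seq_len(nrow(edges))) {
      g <- add_edge(g, edges$from[r], edges$to[r],
                    state = edges$state[r] %||% "undirected")
    }
  }
  g
}

#' Complete undirected graph over a node set
#'
#' The starting point of constraint-based structure learning: every pair of
#' nodes joined by an undirected edge and no separating sets recorded.
#'
#' @inheritParams mixed_graph
#' @return A `mixed_graph` with `p(p-1)/2` undirected edges.
#' @export
complete_graph <- function(nodes) {
  g <- mixed_graph(nodes)
  g$amat[] <- 1L
  diag(g$amat) <- 0L
  g
}

check_node <- function(g, id, arg = "node") {
  if (length(id) != 1 || !id %in% g$nodes$id) {
    abort(sprintf("Unknown %s id: %s", arg, paste(id, collapse = ", ")))
  }
  invisible(id)
}

add_edge <- function(g, from, to, state = "undirected") {
  check_node(g, from, "from"); check_node(g, to, "to")
  if (from == to) abort("Self-loops are not allowed.")
  if (!state %in% c("undirected", "directed")) {
    abort("`state` must be \"undirected\" or \"directed\".")
  }
  if (state == "directed" && node_tier(g, to) == "variant") {
    abort(sprintf("Directed edge %s -> %s points into a variant node.", from, to))
  }
  g$amat[from, to] <- 1L
  g$amat[to, from] <- if (state == "undirected") 1L else 0L
  g$sepsets[[pair_key(from, to)]] <- NULL
  g
}

node_tier <- function(g, id) g$nodes$tier[match(id, g$nodes$id)]

#' @export
print.mixed_graph <- function(x, ...) {
  ed <- tidy(x)
  cat(sprintf("<mixed_graph: %d nodes (%d variant, %d gene, %d outcome), %d edges (%d directed)>\n",
              nrow(x$nodes), sum(x$nodes$tier == "variant"),
              sum(x$nodes$tier == "gene"), sum(x$nodes$tier == "outcome"),
              nrow(ed), sum(ed$state == "directed")))
  invisible(x)
}

#' Edge table of a mixed graph
#'
#' @param x A `mixed_graph`.
#' @param ... Unused.
#' @return A tibble with columns `from`, `to`, `state`. Undirected edges are
#'   listed once with endpoints in node order.
#' @method tidy mixed_graph
#' @export
tidy.mixed_graph <- function(x, ...) {
  a <- x$amat
  p <- nrow(a)
  ids <- rownames(a)
  from <- character(0); to <- character(0); state <- character(0)
  if (p >= 2) {
    und <- which(a == 1L & t(a) == 1L & upper.tri(a), arr.ind = TRUE)
    dir <- which(a == 1L & t(a) == 0L, arr.ind = TRUE)
    from <- c(ids[und[, 1]], ids[dir[, 1]])
    to <- c(ids[und[, 2]], ids[dir[, 2]])
    state <- c(rep("undirected", nrow(und)), rep("directed", nrow(dir)))
  }
  out <- tibble(from = from, to = to, state = state)
  out[order(match(out$from, ids), match(out$to, ids)), ]
}

#' @method glance mixed_graph
#' @export
glance.mixed_graph <- function(x, ...) {
  ed <- tidy(x)
  tibble(
    n_nodes = nrow(x$nodes),
    n_variants = sum(x$nodes$tier == "variant"),
    n_genes = sum(x$nodes$tier == "gene"),
    n_edges = nrow(ed),
    n_directed = sum(ed$state == "directed"),
    n_undirected = sum(ed$state == "undirected"),
    n_sepsets = length(x$sepsets)
  )
}

#' Degree of graph nodes
#'
#' Counts edges incident to each node regardless of orientation state.
#'
#' @param g A `mixed_graph`.
#' @param v Optional node id(s); defaults to all nodes.
#' @return A named integer vector of degrees.
#' @export
node_degree <- function(g, v = NULL) {
  inc <- (g$amat | t(g$amat))
  deg <- rowSums(inc)
  storage.mode(deg) <- "integer"
  if (is.null(v)) return(deg)
  for (id in v) check_node(g, id)
  deg[v]
}

has_edge <- function(g, x, y) g$amat[x, y] == 1L || g$amat[y, x] == 1L

#' Separating set recorded for a node pair
#'
#' @param g A `mixed_graph`.
#' @param x,y Node ids.
#' @return A character vector of node ids, or `NULL` if no separating set
#'   has been recorded for the pair.
#' @export
sepset <- function(g, x, y) {
  check_node(g, x); check_node(g, y)
  g$sepsets[[pair_key(x, y)]]
}

remove_edge <- function(g, x, y, sepset = character(0)) {
  g$amat[x, y] <- 0L
  g$amat[y, x] <- 0L
  g$sepsets[[pair_key(x, y)]] <- as.character(sepset)
  g
}

## vectorized removal: one amat write and one sepset-list write for the
## whole batch (per-edge removal copies the sepset list each call, which
## is quadratic over a large filtering pass)
remove_edges_batch <- function(g, xs, ys, seps) {
  if (length(xs) == 0) return(g)
  g$amat[cbind(xs, ys)] <- 0L
  g$amat[cbind(ys, xs)] <- 0L
  g$sepsets[pair_key(xs, ys)] <- seps
  g
}

## adjacency (any edge state) as list of integer indices, in node order
adjacency_list <- function(g) {
  inc <- (g$amat | t(g$amat))
  apply(inc, 1, which, simplify = FALSE)
}

directed_amat <- function(g) {
  (g$amat == 1L) & (t(g$amat) == 0L)
}

has_directed_cycle <- function(g) {
  d <- directed_amat(g)
  ## Kahn's algorithm on the directed part
  indeg <- colSums(d)
  active <- rep(TRUE, nrow(d))
  repeat {
    src <- which(active & indeg == 0)
    if (length(src) == 0) break
    for (s in src) {
      indeg[d[s, ]] <- indeg[d[s, ]] - 1
      active[s] <- FALSE
    }
  }
  any(active & (rowSums(d) > 0 | indeg > 0))
}

#' Causal ancestors of a target node
#'
#' Returns every node with a fully directed path to `target`. Undirected or
#' partially oriented edges are never traversed: only edges whose
#' orientation has been established count as causal. If the directed part of
#' the graph contains a cycle (which finite-sample orientation can produce),
#' ancestors are still well defined by reachability and a warning is
#' attached to the result.
#'
#' @param g A `mixed_graph`.
#' @param target A node id present in `g`.
#' @return A character vector of ancestor ids (excluding `target`), in node
#'   order. Carries attribute `cyclic = TRUE` when the directed part of the
#'   graph is cyclic.
#' @export
causal_ancestors <- function(g, target) {
  check_node(g, target, "target")
  d <- directed_amat(g)
  ids <- g$nodes$id
  t_i <- match(target, ids)
  ## reverse BFS over directed edges
  seen <- rep(FALSE, length(ids))
  frontier <- t_i
  while (length(frontier) > 0) {
    parents <- which(rowSums(d[, frontier, drop = FALSE]) > 0)
    new <- parents[!seen[parents]]
    seen[new] <- TRUE
    frontier <- new
  }
  seen[t_i] <- FALSE
  out <- ids[seen]
  if (has_directed_cycle(g)) {
    warn("Directed part of the graph contains a cycle; ancestors computed by reachability.")
    attr(out, "cyclic") <- TRUE
  }
  out
}

## internal invariant check used by tests and after orientation
assert_no_variant_heads <- function(g) {
  d <- directed_amat(g)
  heads <- colSums(d) > 0
  bad <- heads & (g$nodes$tier == "variant")
  if (any(bad)) {
    abort(paste0("Directed edge points into variant node(s): ",
                 paste(g$nodes$id[bad], collapse = ", ")))
  }
  invisible(TRUE)
}
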