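## Independent reference implementations used to check the package's
## primitives. Deliberately written as plain brute force, sharing no code
## with the implementation under test.

## random gene-only DAG as a fully directed mixed_graph
rand_gene_dag <- function(p, edge_prob = 0.3, seed = 1) {
  set.seed(seed)
  ids <- sprintf("n%02d", seq_len(p))
  ord <- sample(ids)
  from <- character(0); to <- character(0)
  for (i in seq_len(p - 1)) {
    for (j in seq(i + 1, p)) {
      if (runif(1) < edge_prob) {
        from <- c(from, ord[i]); to <- c(to, ord[j])
      }
    }
  }
  mixed_graph(tibble::tibble(id = ids, tier = "gene"),
              tibble::tibble(from = from, to = to, state = "directed"))
}

## directed adjacency (i -> j) of a mixed_graph, as a logical matrix
dir_mat <- function(g) (g$amat == 1L) & (t(g$amat) == 0L)

## brute-force ancestors by exhaustive directed-path enumeration
brute_ancestors <- function(g, target) {
  d <- dir_mat(g)
  ids <- g$nodes$id
  ti <- match(target, ids)
  anc <- character(0)
  for (s in seq_along(ids)) {
    if (s == ti) next
    ## DFS path search s -> ti over directed edges
    stack <- list(s)
    seen <- rep(FALSE, length(ids))
    found <- FALSE
    while (length(stack) > 0 && !found) {
      v <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      if (v == ti) { found <- TRUE; break }
      if (seen[v]) next
      seen[v] <- TRUE
      for (w in which(d[v, ])) stack[[length(stack) + 1L]] <- w
    }
    if (found) anc <- c(anc, ids[s])
  }
  anc
}

## residual-correlation definition of partial correlation
resid_parcor <- function(data, x, y, S) {
  if (length(S) == 0) return(cor(data[, x], data[, y]))
  rx <- resid(lm(data[, x] ~ data[, S, drop = FALSE]))
  ry <- resid(lm(data[, y] ~ data[, S, drop = FALSE]))
  cor(rx, ry)
}

## element-by-element topological overlap
brute_tom <- function(adj) {
  a <- as.matrix(adj)
  diag(a) <- 0
  p <- nrow(a)
  out <- diag(p)
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      if (i == j) next
      l <- 0
      for (u in seq_len(p)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
      ki <- sum(a[i, -i]); kj <- sum(a[j, -j])
      out[i, j] <- (l + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
    }
  }
  out
}

## brute-force one-sided hypergeometric tail P(X >= a)
brute_hyper_tail <- function(a, n_ref, n_universe, n_anc) {
  ks <- a:min(n_ref, n_anc)
  if (a > min(n_ref, n_anc)) return(0)
  sum(choose(n_ref, ks) * choose(n_universe - n_ref, n_anc - ks)) /
    choose(n_universe, n_anc)
}

## exhaustive orientation-rule application on an adjacency-state matrix
## (1/1 = undirected, 1/0 = directed); mirrors the constraints (no head at
## a variant, no new cycle) with independent, unoptimized code
brute_propagate <- function(amat, is_var) {
  p <- nrow(amat)
  makes_cycle <- function(m, a, b) {
    m[a, b] <- 1L; m[b, a] <- 0L
    d <- (m == 1L) & (t(m) == 0L)
    ## DFS from b searching for a
    stack <- which(d[b, ])
    seen <- rep(FALSE, p)
    while (length(stack) > 0) {
      v <- stack[1]; stack <- stack[-1]
      if (v == a) return(TRUE)
      if (seen[v]) next
      seen[v] <- TRUE
      stack <- c(stack, which(d[v, ]))
    }
    FALSE
  }
  repeat {
    changed <- FALSE
    for (a in seq_len(p)) for (b in seq_len(p)) {
      if (a == b) next
      if (!(amat[a, b] == 1L && amat[b, a] == 1L)) next   # need undirected
      if (is_var[b]) next
      dirm <- (amat == 1L) & (t(amat) == 0L)
      adj <- (amat == 1L) | (t(amat) == 1L)
      fire <- FALSE
      ## R1
      for (c_ in seq_len(p)) {
        if (dirm[c_, a] && !adj[c_, b] && c_ != b) fire <- TRUE
      }
      ## R2
      for (c_ in seq_len(p)) {
        if (dirm[a, c_] && dirm[c_, b]) fire <- TRUE
      }
      ## R3
      for (c_ in seq_len(p)) for (d_ in seq_len(p)) {
        if (c_ == d_) next
        if (amat[a, c_] == 1L && amat[c_, a] == 1L &&
            amat[a, d_] == 1L && amat[d_, a] == 1L &&
            dirm[c_, b] && dirm[d_, b] && !adj[c_, d_]) fire <- TRUE
      }
      ## R4
      for (c_ in seq_len(p)) for (d_ in seq_len(p)) {
        if (c_ == d_) next
        if (adj[a, d_] && dirm[d_, c_] && dirm[c_, b] &&
            !adj[d_, b] && d_ != b) fire <- TRUE
      }
      if (fire && !makes_cycle(amat, a, b)) {
        amat[a, b] <- 1L
        amat[b, a] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  amat
}

## CPDAG by full enumeration of Markov-equivalent DAGs (skeleton +
## v-structure match); feasible up to ~12 edges
enum_cpdag <- function(dag) {
  d <- dir_mat(dag)
  p <- nrow(d)
  edges <- which((d | t(d)) & upper.tri(d), arr.ind = TRUE)
  m <- nrow(edges)
  stopifnot(m <= 14)
  vstructs <- function(dd) {
    out <- character(0)
    for (z in seq_len(p)) {
      pa <- which(dd[, z])
      if (length(pa) < 2) next
      for (a in pa) for (b in pa) {
        if (a < b && !dd[a, b] && !dd[b, a]) {
          out <- c(out, paste(a, z, b))
        }
      }
    }
    sort(out)
  }
  acyclic <- function(dd) {
    deg <- colSums(dd)
    alive <- rep(TRUE, p)
    repeat {
      src <- which(alive & deg == 0)
      if (length(src) == 0) break
      for (s in src) { deg[dd[s, ]] <- deg[dd[s, ]] - 1; alive[s] <- FALSE }
    }
    !any(alive)
  }
  target_v <- vstructs(d)
  seen_fwd <- rep(FALSE, m); seen_rev <- rep(FALSE, m)
  for (mask in 0:(2^m - 1)) {
    dd <- matrix(FALSE, p, p)
    bits <- as.logical(bitwAnd(mask, 2^(seq_len(m) - 1)))
    for (e in seq_len(m)) {
      if (bits[e]) dd[edges[e, 1], edges[e, 2]] <- TRUE
      else dd[edges[e, 2], edges[e, 1]] <- TRUE
    }
    if (!acyclic(dd)) next
    if (!identical(vstructs(dd), target_v)) next
    for (e in seq_len(m)) {
      if (bits[e]) seen_fwd[e] <- TRUE else seen_rev[e] <- TRUE
    }
  }
  amat <- matrix(0L, p, p, dimnames = list(dag$nodes$id, dag$nodes$id))
  for (e in seq_len(m)) {
    i <- edges[e, 1]; j <- edges[e, 2]
    if (seen_fwd[e]) amat[i, j] <- 1L
    if (seen_rev[e]) amat[j, i] <- 1L
  }
  amat
}

## the package's oracle search composed end to end
oracle_learn <- function(dag, prefilter = TRUE) {
  eng <- ci_engine_oracle(dag, log = FALSE)
  g <- complete_graph(dag$nodes)
  if (prefilter) g <- dual_filter_pass(g, eng)
  g <- refine_skeleton(g, eng)
  run_orientation(g, eng, orientation_config(confirm_with_test = TRUE))
}

## amat comparison helper
expect_same_graph <- function(g1, amat2) {
  expect_identical(g1$amat[rownames(amat2), colnames(amat2)], amat2)
}

skeleton_keys <- function(g) {
  ed <- tidy(g)
  paste(pmin(ed$from, ed$to), pmax(ed$from, ed$to))
}
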