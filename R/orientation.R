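#' Configuration for MR-principled edge orientation
#'
#' @param alpha Significance level of confirmatory CI tests.
#' @param confirm_with_test Re-test each candidate collider triple
#'   (x independent of y given the stored separating set, dependent given
#'   the collider candidate) rather than trusting stored separating sets
#'   alone.
#' @return An `orientation_config` list.
#' @export
orientation_config <- function(alpha = 0.05, confirm_with_test = TRUE) {
  stopifnot(alpha > 0, alpha < 1)
  structure(list(alpha = alpha, confirm_with_test = confirm_with_test),
            class = "orientation_config")
}

log_conflict <- function(g, type, x, y, z = NA_character_) {
  row <- tibble(type = type, x = x, y = y, z = z)
  g$conflicts <- if (is.null(g$conflicts)) row else dplyr::bind_rows(g$conflicts, row)
  g
}

#' Orient variant edges under the Mendelian randomization principle
#'
#' Every edge between a `variant` node and a non-variant node is directed
#' variant -> phenotype: genotypes can predict phenotypic change but not
#' the reverse. Variant-variant edges and all other edges are untouched.
#'
#' @param g A `mixed_graph` skeleton (all edges undirected).
#' @return The graph with variant edges directed.
#' @export
orient_variant_edges <- function(g) {
  ids <- g$nodes$id
  is_var <- g$nodes$tier == "variant"
  pairs <- edge_pairs(g)
  for (e in seq_len(nrow(pairs))) {
    i <- pairs[e, 1]; j <- pairs[e, 2]
    if (is_var[i] && !is_var[j]) {
      g$amat[j, i] <- 0L
    } else if (is_var[j] && !is_var[i]) {
      g$amat[i, j] <- 0L
    }
  }
  g
}

#' Discover and orient v-structures
#'
#' For each unshielded triple x - z - y (x and y non-adjacent), the triple
#' is oriented as a collider x -> z <- y when z is not in the recorded
#' separating set of (x, y) and — when `config$confirm_with_test` — a
#' confirmatory pair of CI tests agrees: x and y independent given the
#' stored separating set but dependent given {z}. Orientations that would
#' point into a variant node are skipped and logged as conflicts, existing
#' variant -> phenotype arrows are never reversed, and two triples claiming
#' opposite directions on the same edge cancel (the edge stays undirected,
#' logged as a conflict).
#'
#' @param g A `mixed_graph` with variant edges already oriented.
#' @param engine A `ci_engine` or [sufficient_stats()] object; may be
#'   `NULL` when `config$confirm_with_test` is `FALSE`.
#' @param config An [orientation_config()].
#' @return The graph with discovered colliders oriented.
#' @export
orient_v_structures <- function(g, engine = NULL,
                                config = orientation_config()) {
  confirm <- config$confirm_with_test
  if (confirm && is.null(engine)) {
    abort("`engine` is required when `confirm_with_test` is TRUE.")
  }
  if (!is.null(engine)) engine <- as_engine(engine, alpha = config$alpha)
  ids <- g$nodes$id
  p <- length(ids)
  inc <- (g$amat | t(g$amat))
  is_var <- g$nodes$tier == "variant"
  prop <- matrix(FALSE, p, p)            # proposed arrowheads tail -> head
  ## hashed sepset lookup ([[ on a long named list is a linear scan)
  sepenv <- if (length(g$sepsets) > 0) list2env(g$sepsets) else new.env()

  for (z in seq_len(p)) {
    nb <- which(inc[z, ])
    if (length(nb) < 2) next
    for (ai in seq_len(length(nb) - 1)) {
      for (bi in seq(ai + 1, length(nb))) {
        x <- nb[ai]; y <- nb[bi]
        if (inc[x, y]) next              # shielded
        sep <- sepenv[[pair_key(ids[x], ids[y])]]
        if (is.null(sep)) next           # no separation evidence recorded
        if (ids[z] %in% sep) next
        if (confirm) {
          t_sep <- ci_test(engine, ids[x], ids[y], sep, "orient")
          t_z <- ci_test(engine, ids[x], ids[y], ids[z], "orient")
          if (!(t_sep$independent && !t_z$independent)) next
        }
        if (is_var[z]) {
          g <- log_conflict(g, "variant_head", ids[x], ids[y], ids[z])
          next
        }
        prop[x, z] <- TRUE
        prop[y, z] <- TRUE
      }
    }
  }

  ## apply proposals, cancelling contradictory claims
  for (i in seq_len(p - 1)) {
    for (j in seq(i + 1, p)) {
      if (!prop[i, j] && !prop[j, i]) next
      if (prop[i, j] && prop[j, i]) {
        g$amat[i, j] <- 1L; g$amat[j, i] <- 1L
        g <- log_conflict(g, "opposite_v_structures", ids[i], ids[j])
        next
      }
      tail <- if (prop[i, j]) i else j
      head <- if (prop[i, j]) j else i
      ## never reverse an established arrow (variant -> phenotype)
      if (g$amat[head, tail] == 1L && g$amat[tail, head] == 0L) {
        g <- log_conflict(g, "would_reverse_arrow", ids[tail], ids[head])
        next
      }
      g$amat[tail, head] <- 1L
      g$amat[head, tail] <- 0L
    }
  }
  g
}

## try to orient a -> b; respects the variant-head prohibition and refuses
## orientations that would close a directed cycle
try_orient <- function(g, a, b, is_var) {
  if (is_var[b]) return(list(g = g, changed = FALSE))
  g2 <- g
  g2$amat[a, b] <- 1L
  g2$amat[b, a] <- 0L
  if (has_directed_cycle(g2)) return(list(g = g, changed = FALSE))
  list(g = g2, changed = TRUE)
}

#' Propagate orientations to closure
#'
#' Applies the standard orientation-propagation (Meek) rules to fixpoint:
#' no rule may create a new v-structure or a directed cycle, and — the MR
#' constraint — no rule may orient into a variant node. All input
#' orientations are preserved.
#'
#' @param g A `mixed_graph` with v-structures oriented.
#' @return The graph with all compelled orientations propagated.
#' @export
propagate_orientations <- function(g) {
  ids <- g$nodes$id
  p <- length(ids)
  is_var <- g$nodes$tier == "variant"
  repeat {
    changed <- FALSE
    a_ <- g$amat
    und <- (a_ == 1L) & (t(a_) == 1L)
    dir <- (a_ == 1L) & (t(a_) == 0L)
    inc <- und | dir | t(dir)
    pairs <- which(und & upper.tri(und), arr.ind = TRUE)
    for (e in seq_len(nrow(pairs))) {
      i <- pairs[e, 1]; j <- pairs[e, 2]
      if (!und[i, j]) next                 # oriented earlier in this scan
      for (ordered in list(c(i, j), c(j, i))) {
        a <- ordered[1]; b <- ordered[2]
        fire <- FALSE
        ## R1: c -> a, c and b non-adjacent  =>  a -> b
        if (any(dir[, a] & !inc[, b] & seq_len(p) != b)) fire <- TRUE
        ## R2: a -> c -> b  =>  a -> b
        if (!fire && any(dir[a, ] & dir[, b])) fire <- TRUE
        ## R3: a - c, a - d, c -> b, d -> b, c and d non-adjacent
        if (!fire) {
          cand <- which(und[a, ] & dir[, b])
          if (length(cand) >= 2) {
            sub <- inc[cand, cand, drop = FALSE]
            diag(sub) <- TRUE
            if (any(!sub)) fire <- TRUE
          }
        }
        ## R4: d adjacent to a, d -> c -> b, d and b non-adjacent
        if (!fire) {
          ds <- which(inc[a, ] & !inc[, b] & seq_len(p) != b)
          for (d_ in ds) {
            if (any(dir[d_, ] & dir[, b])) { fire <- TRUE; break }
          }
        }
        if (fire) {
          res <- try_orient(g, a, b, is_var)
          if (res$changed) {
            g <- res$g
            und[a, b] <- FALSE; und[b, a] <- FALSE
            dir[a, b] <- TRUE
            changed <- TRUE
          }
          break
        }
      }
    }
    if (!changed) break
  }
  g
}

#' Full MR-principled orientation of a skeleton
#'
#' Composition of [orient_variant_edges()], [orient_v_structures()] and
#' [propagate_orientations()]. The result never contains a directed edge
#' pointing into a variant node.
#'
#' @inheritParams orient_v_structures
#' @param g A final skeleton (undirected `mixed_graph` with separating
#'   sets recorded).
#' @return The oriented `mixed_graph`.
#' @export
run_orientation <- function(g, engine = NULL,
                            config = orientation_config()) {
  if (is.null(engine) && config$confirm_with_test) {
    config$confirm_with_test <- FALSE
  }
  g <- orient_variant_edges(g)
  g <- orient_v_structures(g, engine, config)
  g <- propagate_orientations(g)
  assert_no_variant_heads(g)
  g
}
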