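#' Sufficient statistics for Gaussian conditional-independence testing
#'
#' Every conditional-independence (CI) test in the package reads from a
#' single sufficient-statistic object: the sample correlation matrix over
#' all nodes (variants, genes, outcome) and the sample count. Holding the
#' statistics once means the filter, skeleton and orientation stages all
#' test against exactly the same data.
#'
#' @param data A numeric matrix or data frame with samples in rows and
#'   variables in columns (column names become node ids), or `NULL` when
#'   `corr` is supplied directly.
#' @param corr Optional pre-computed correlation matrix (symmetric, unit
#'   diagonal, dimnames = node ids). Requires `n`.
#' @param n Sample count; taken from `nrow(data)` when `data` is given.
#' @return A `sufficient_stats` object: list with elements `corr`, `n` and
#'   `index` (named position lookup).
#' @examples
#' x <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, c("a", "b", "c", "d")))
#' s <- sufficient_stats(x)
#' partial_correlation(s, "a", "b", c("c", "d"))
#' @export
sufficient_stats <- function(data = NULL, corr = NULL, n = NULL) {
  if (is.null(corr)) {
    m <- as.matrix(data)
    if (is.null(colnames(m))) colnames(m) <- paste0("V", seq_len(ncol(m)))
    storage.mode(m) <- "double"
    n <- nrow(m)
    corr <- stats::cor(m)
    ## constant columns give NA correlations; treat as uncorrelated
    if (anyNA(corr)) {
      corr[is.na(corr)] <- 0
      diag(corr) <- 1
      warn("Zero-variance variables detected; their correlations set to 0.")
    }
  } else {
    corr <- as.matrix(corr)
    if (is.null(n)) abort("`n` is required when `corr` is supplied.")
    if (is.null(rownames(corr))) {
      rownames(corr) <- colnames(corr) <- paste0("V", seq_len(ncol(corr)))
    }
  }
  if (nrow(corr) != ncol(corr) || max(abs(corr - t(corr))) > 1e-8) {
    abort("Correlation matrix must be square and symmetric.")
  }
  if (n < 4) abort("At least 4 samples are required.")
  structure(
    list(corr = corr, n = as.integer(n),
         index = stats::setNames(seq_len(ncol(corr)), colnames(corr))),
    class = "sufficient_stats"
  )
}

#' @export
print.sufficient_stats <- function(x, ...) {
  cat(sprintf("<sufficient_stats: %d variables, n = %d>\n",
              ncol(x$corr), x$n))
  invisible(x)
}

## regularized inverse used when a sub-correlation matrix is singular
## (|S| + 2 > n, duplicated variables): shrink toward the identity.
shrunk_solve <- function(r, lambda = 1e-3) {
  solve(r * (1 - lambda) + diag(lambda, nrow(r)))
}

#' Partial correlation from sufficient statistics
#'
#' Computes the partial correlation of `x` and `y` given the conditioning
#' set `S` by inverting the `(|S|+2) x (|S|+2)` sub-correlation matrix and
#' normalizing the off-diagonal precision entry:
#' `rho = -P[x,y] / sqrt(P[x,x] P[y,y])`. With `S` empty this is the raw
#' correlation. A singular sub-matrix falls back to a shrinkage inverse
#' (`corr * (1 - lambda) + lambda * I`) and the result carries attribute
#' `flagged = TRUE`.
#'
#' @inheritParams fisher_z_test
#' @param lambda Shrinkage intensity of the fallback inverse.
#' @return The partial correlation (numeric scalar, possibly with attribute
#'   `flagged`).
#' @export
partial_correlation <- function(stats, x, y, S = character(0), lambda = 1e-3) {
  idx <- stats$index
  S <- as.character(S)
  if (x == y) abort("`x` and `y` must differ.")
  if (x %in% S || y %in% S) abort("`x` and `y` must not be in `S`.")
  miss <- setdiff(c(x, y, S), names(idx))
  if (length(miss) > 0) abort(paste0("Unknown node id(s): ", paste(miss, collapse = ", ")))
  if (length(S) == 0) return(stats$corr[x, y])
  sub <- stats$corr[c(x, y, S), c(x, y, S)]
  flagged <- FALSE
  P <- tryCatch(solve(sub), error = function(e) NULL)
  if (is.null(P) || !all(is.finite(P))) {
    P <- shrunk_solve(sub, lambda)
    flagged <- TRUE
  }
  rho <- -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
  if (!is.finite(rho)) {
    rho <- 0
    flagged <- TRUE
  }
  if (flagged) attr(rho, "flagged") <- TRUE
  rho
}

#' Fisher's z conditional-independence test
#'
#' Tests `x` independent of `y` given `S` under Gaussianity via the Fisher
#' transform of the partial correlation: `z = atanh(rho)`,
#' `statistic = sqrt(n - |S| - 3) * |z|`, two-sided p-value from the
#' standard normal. `|rho|` is clamped to `1 - 1e-12` before `atanh` so
#' collinear variables do not produce infinities.
#'
#' If `n - |S| - 3 < 1` the test is refused: the result reports
#' `independent = FALSE` (the edge is retained — never delete an edge on an
#' invalid test) with `refused = TRUE` and an `NA` p-value.
#'
#' @param stats A [sufficient_stats()] object.
#' @param x,y Node ids.
#' @param S Character vector of conditioning node ids (may be empty).
#' @param alpha Significance level in (0, 1); `independent` is
#'   `p_value > alpha`.
#' @param lambda Shrinkage intensity for singular sub-matrices.
#' @return A one-row tibble with columns `partial_corr`, `z`, `statistic`,
#'   `p_value`, `independent`, `refused`, `flagged`.
#' @export
fisher_z_test <- function(stats, x, y, S = character(0), alpha = 0.05,
                          lambda = 1e-3) {
  if (!(alpha > 0 && alpha < 1)) abort("`alpha` must be in (0, 1).")
  S <- as.character(S)
  df <- stats$n - length(S) - 3
  if (df < 1) {
    warn(sprintf("Fisher's z test refused for (%s, %s): n - |S| - 3 = %d < 1; edge retained.",
                 x, y, df))
    return(tibble(partial_corr = NA_real_, z = NA_real_, statistic = NA_real_,
                  p_value = NA_real_, independent = FALSE, refused = TRUE,
                  flagged = FALSE))
  }
  rho <- partial_correlation(stats, x, y, S, lambda = lambda)
  flagged <- isTRUE(attr(rho, "flagged"))
  rho <- as.numeric(rho)
  rc <- max(min(rho, 1 - 1e-12), -(1 - 1e-12))
  z <- atanh(rc)
  stat <- sqrt(df) * abs(z)
  p <- 2 * stats::pnorm(stat, lower.tail = FALSE)
  tibble(partial_corr = rho, z = z, statistic = stat, p_value = p,
         independent = p > alpha, refused = FALSE, flagged = flagged)
}

## fast internal Fisher path on integer indices into the correlation matrix
## (the search loops run hundreds of thousands of tests)
fisher_core <- function(corr, n, xi, yi, Si, lambda = 1e-3) {
  df <- n - length(Si) - 3
  if (df < 1) {
    return(list(rho = NA_real_, statistic = NA_real_, p_value = NA_real_,
                independent = FALSE, refused = TRUE))
  }
  if (length(Si) == 0) {
    rho <- corr[xi, yi]
  } else if (length(Si) == 1) {
    ## closed-form first-order recursion (hot path of the skeleton search)
    rxy <- corr[xi, yi]; rxz <- corr[xi, Si]; ryz <- corr[yi, Si]
    den <- (1 - rxz * rxz) * (1 - ryz * ryz)
    rho <- if (den <= 1e-24) 0 else (rxy - rxz * ryz) / sqrt(den)
  } else {
    sub <- corr[c(xi, yi, Si), c(xi, yi, Si)]
    P <- tryCatch(solve(sub), error = function(e) NULL)
    if (is.null(P) || !all(is.finite(P))) P <- shrunk_solve(sub, lambda)
    rho <- -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
    if (!is.finite(rho)) rho <- 0
  }
  rc <- max(min(rho, 1 - 1e-12), -(1 - 1e-12))
  stat <- sqrt(df) * abs(atanh(rc))
  p <- 2 * stats::pnorm(stat, lower.tail = FALSE)
  list(rho = rho, statistic = stat, p_value = p, independent = NA,
       refused = FALSE)
}

## ---------------------------------------------------------------------------
## CI-test engines
##
## The filter/skeleton/orientation stages are written against an "engine"
## abstraction so the same search code runs with the finite-sample Fisher's z
## test or with an exact d-separation oracle on a known DAG. Engines carry a
## mutable environment recording every executed test (the audit log behind
## the CI-test-count benchmark).

new_ci_engine <- function(type, alpha, fields) {
  env <- new.env(parent = emptyenv())
  env$n_total <- 0
  env$by_order <- numeric(0)
  env$by_stage <- c(filter = 0, skeleton = 0, orient = 0)
  env$order0_by_stage <- c(filter = 0, skeleton = 0, orient = 0)
  env$records <- list()
  env$warnings <- character(0)
  structure(c(list(type = type, alpha = alpha, env = env), fields),
            class = "ci_engine")
}

#' CI-test engines: Fisher's z or d-separation oracle
#'
#' `ci_engine_fisher()` wraps a [sufficient_stats()] object; every call to
#' [ci_test()] runs Fisher's z at level `alpha`. `ci_engine_oracle()` wraps
#' a known DAG and answers tests exactly by d-separation — used to verify
#' that the search machinery recovers the true structure when the tests are
#' infallible. Both engines count and (optionally) log every executed test;
#' retrieve the log with [ci_log()] and the counts with [ci_test_counts()].
#'
#' @param stats A [sufficient_stats()] object.
#' @param alpha Significance level for `independent` decisions.
#' @param lambda Shrinkage intensity for singular sub-matrices.
#' @param log Keep a full per-test record (set `FALSE` for large benchmark
#'   runs; counts are always kept).
#' @return A `ci_engine` object.
#' @export
ci_engine_fisher <- function(stats, alpha = 0.05, lambda = 1e-3, log = TRUE) {
  stopifnot(inherits(stats, "sufficient_stats"))
  new_ci_engine("fisher", alpha, list(stats = stats, lambda = lambda, log = log))
}

#' @rdname ci_engine_fisher
#' @param dag A fully directed acyclic `mixed_graph` (ground truth).
#' @export
ci_engine_oracle <- function(dag, log = TRUE) {
  stopifnot(inherits(dag, "mixed_graph"))
  d <- directed_amat(dag)
  new_ci_engine("oracle", 0.5, list(dmat = d, ids = dag$nodes$id, log = log))
}

record_test <- function(engine, x, y, S, statistic, p_value, stage) {
  env <- engine$env
  ord <- length(S)
  env$n_total <- env$n_total + 1
  if (length(env$by_order) < ord + 1) {
    env$by_order <- c(env$by_order, numeric(ord + 1 - length(env$by_order)))
  }
  env$by_order[ord + 1] <- env$by_order[ord + 1] + 1
  env$by_stage[stage] <- env$by_stage[stage] + 1
  if (ord == 0) env$order0_by_stage[stage] <- env$order0_by_stage[stage] + 1
  if (isTRUE(engine$log)) {
    env$records[[length(env$records) + 1L]] <-
      list(x = x, y = y,
           conditioning_set = paste(S, collapse = ","),
           order = ord, statistic = statistic, p_value = p_value,
           stage = stage)
  }
  invisible(NULL)
}

## bulk-record a vectorized batch of tests (all same order & stage)
record_batch <- function(engine, x, y, order, statistic, p_value, stage) {
  env <- engine$env
  k <- length(x)
  if (k == 0) return(invisible(NULL))
  env$n_total <- env$n_total + k
  if (length(env$by_order) < order + 1) {
    env$by_order <- c(env$by_order, numeric(order + 1 - length(env$by_order)))
  }
  env$by_order[order + 1] <- env$by_order[order + 1] + k
  env$by_stage[stage] <- env$by_stage[stage] + k
  if (order == 0) env$order0_by_stage[stage] <- env$order0_by_stage[stage] + k
  if (isTRUE(engine$log)) {
    env$records[[length(env$records) + 1L]] <-
      tibble(x = x, y = y, conditioning_set = "",
             order = order, statistic = statistic, p_value = p_value,
             stage = stage)
  }
  invisible(NULL)
}

## id -> engine position lookup used once per search call site
engine_index <- function(engine, ids) {
  if (engine$type == "fisher") {
    ix <- unname(engine$stats$index[ids])
  } else {
    ix <- match(ids, engine$ids)
  }
  if (anyNA(ix)) abort("Node id(s) missing from the CI-test engine.")
  ix
}

engine_node_ids <- function(engine) {
  if (engine$type == "fisher") names(engine$stats$index) else engine$ids
}

## integer fast path: returns the independence decision only. record-keeping
## identical to ci_test(); avoids string conversions in the search loops.
ci_test_int <- function(engine, xi, yi, Si, stage) {
  env <- engine$env
  ord <- length(Si)
  env$n_total <- env$n_total + 1
  if (length(env$by_order) < ord + 1) {
    env$by_order <- c(env$by_order, numeric(ord + 1 - length(env$by_order)))
  }
  env$by_order[ord + 1] <- env$by_order[ord + 1] + 1
  env$by_stage[stage] <- env$by_stage[stage] + 1
  if (ord == 0) env$order0_by_stage[stage] <- env$order0_by_stage[stage] + 1
  if (engine$type == "fisher") {
    res <- fisher_core(engine$stats$corr, engine$stats$n, xi, yi, Si,
                       lambda = engine$lambda)
    if (isTRUE(engine$log)) {
      ids <- engine_node_ids(engine)
      env$records[[length(env$records) + 1L]] <-
        list(x = ids[xi], y = ids[yi],
             conditioning_set = paste(ids[Si], collapse = ","),
             order = ord, statistic = res$statistic, p_value = res$p_value,
             stage = stage)
    }
    if (res$refused) FALSE else res$p_value > engine$alpha
  } else {
    ind <- d_sep_idx(engine$dmat, xi, yi, Si)
    if (isTRUE(engine$log)) {
      ids <- engine_node_ids(engine)
      env$records[[length(env$records) + 1L]] <-
        list(x = ids[xi], y = ids[yi],
             conditioning_set = paste(ids[Si], collapse = ","),
             order = ord, statistic = NA_real_,
             p_value = if (ind) 1 else 0, stage = stage)
    }
    ind
  }
}

#' Run one conditional-independence test through an engine
#'
#' @param engine A `ci_engine`.
#' @param x,y Node ids.
#' @param S Conditioning set (character vector).
#' @param stage One of `"filter"`, `"skeleton"`, `"orient"` — recorded in
#'   the test log.
#' @return A list with at least `p_value` and `independent`.
#' @export
ci_test <- function(engine, x, y, S = character(0), stage = "skeleton") {
  S <- as.character(S)
  if (engine$type == "fisher") {
    idx <- engine$stats$index
    res <- fisher_core(engine$stats$corr, engine$stats$n,
                       idx[[x]], idx[[y]], unname(idx[S]),
                       lambda = engine$lambda)
    if (isTRUE(res$refused)) {
      engine$env$warnings <- c(engine$env$warnings,
                               sprintf("refused:%s,%s|%d", x, y, length(S)))
    }
    record_test(engine, x, y, S, res$statistic, res$p_value, stage)
    list(p_value = res$p_value,
         independent = if (res$refused) FALSE else res$p_value > engine$alpha,
         statistic = res$statistic, partial_corr = res$rho,
         refused = res$refused)
  } else {
    ind <- d_separated_amat(engine$dmat, engine$ids, x, y, S)
    p <- if (ind) 1 else 0
    record_test(engine, x, y, S, NA_real_, p, stage)
    list(p_value = p, independent = ind, statistic = NA_real_,
         partial_corr = NA_real_, refused = FALSE)
  }
}

#' Audit log and counts of executed CI tests
#'
#' @param engine A `ci_engine`.
#' @return `ci_log()`: a tibble with one row per executed test (columns
#'   `x`, `y`, `conditioning_set`, `order`, `statistic`, `p_value`,
#'   `stage`). `ci_test_counts()`: a one-row tibble with `n_tests`,
#'   `n_order0`, `n_order_ge1` and per-stage counts.
#' @export
ci_log <- function(engine) {
  recs <- engine$env$records
  if (length(recs) == 0) {
    return(tibble(x = character(0), y = character(0),
                  conditioning_set = character(0), order = integer(0),
                  statistic = numeric(0), p_value = numeric(0),
                  stage = character(0)))
  }
  rows <- purrr::map(recs, function(r) {
    if (inherits(r, "tbl_df")) r else as_tibble(r)
  })
  out <- dplyr::bind_rows(rows)
  out$order <- as.integer(out$order)
  out
}

#' @rdname ci_log
#' @export
ci_test_counts <- function(engine) {
  env <- engine$env
  byo <- env$by_order
  tibble(
    n_tests = env$n_total,
    n_order0 = if (length(byo) >= 1) byo[1] else 0,
    n_order_ge1 = env$n_total - (if (length(byo) >= 1) byo[1] else 0),
    n_filter = unname(env$by_stage["filter"]),
    n_skeleton = unname(env$by_stage["skeleton"]),
    n_orient = unname(env$by_stage["orient"])
  )
}

#' Write a CI-test log to TSV
#'
#' @param engine A `ci_engine`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ci_log <- function(engine, path) {
  readr::write_tsv(ci_log(engine), path)
  invisible(path)
}

## coerce a sufficient_stats or engine argument to an engine
as_engine <- function(x, alpha = 0.05, lambda = 1e-3) {
  if (inherits(x, "ci_engine")) return(x)
  if (inherits(x, "sufficient_stats")) {
    return(ci_engine_fisher(x, alpha = alpha, lambda = lambda))
  }
  abort("Expected a `ci_engine` or `sufficient_stats` object.")
}
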