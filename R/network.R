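#' Centered log-ratio transform
#'
#' Per sample, `x -> log((x + pseudocount) / g)` with `g` the geometric mean
#' of `x + pseudocount`; each transformed sample (row of the result) sums to
#' zero. The transform maps compositional count data onto a scale where
#' covariance-based association inference is meaningful.
#'
#' @param counts taxa-by-sample matrix (or [abundance_table]).
#' @param pseudocount positive offset added before taking logs. Default: 1
#'   for integer tables, otherwise the smallest positive observed value
#'   (averaged tables contain fractions).
#' @return samples-by-taxa matrix of CLR values with attribute
#'   `pseudocount`.
#' @export
clr_transform <- function(counts, pseudocount = NULL) {
  if (inherits(counts, "abundance_table")) counts <- counts$counts
  counts <- as.matrix(counts)
  if (length(counts) == 0) stop("zero-size table")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (is.null(pseudocount)) {
    pos <- counts[counts > 0]
    pseudocount <- if (all(counts == round(counts))) 1
      else if (length(pos)) min(pos) else 1
  }
  x <- t(counts) + pseudocount            # samples x taxa
  lg <- log(x)
  out <- lg - rowMeans(lg)
  attr(out, "pseudocount") <- pseudocount
  out
}

# column-standardize (center, population sd); zero-variance columns -> 0
standardize_cols <- function(x) {
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  s <- sqrt(colMeans(xc^2))
  bad <- s == 0 | !is.finite(s)
  s[bad] <- 1
  xs <- sweep(xc, 2, s, "/")
  xs[, bad] <- 0
  attr(xs, "zero_variance") <- bad
  xs
}

#' Regularization path for neighborhood selection
#'
#' `lambda_max` is the largest absolute pairwise correlation of the
#' column-standardized CLR data — at that penalty the lasso selects nothing.
#' The path is log-spaced from `lambda_max` down to
#' `lambda_max * min_ratio`. Constant columns are ignored (they cannot form
#' edges).
#'
#' @param clr samples-by-taxa CLR matrix ([clr_transform]).
#' @param n_lambda path length (default 20).
#' @param min_ratio smallest lambda as a fraction of `lambda_max`
#'   (default 0.01).
#' @return Decreasing positive vector of length `n_lambda`.
#' @export
lambda_path <- function(clr, n_lambda = 20, min_ratio = 0.01) {
  if (ncol(clr) < 2) stop("need at least 2 taxa")
  xs <- standardize_cols(clr)
  C <- crossprod(xs) / nrow(xs)
  diag(C) <- 0
  lmax <- max(abs(C))
  if (lmax == 0) lmax <- .Machine$double.eps
  if (n_lambda == 1) return(lmax)
  exp(seq(log(lmax), log(lmax * min_ratio), length.out = n_lambda))
}

#' Node-wise lasso neighborhoods
#'
#' For each taxon j, an L1-penalized least-squares regression of its
#' standardized CLR column on all other columns, solved by cyclic coordinate
#' descent (tolerance 1e-7) in Gram form with warm starts along the path.
#'
#' @param clr samples-by-taxa CLR matrix.
#' @param lambda a single penalty or a decreasing path.
#' @return If one lambda: p-by-p coefficient matrix with zero diagonal, row
#'   j holding the regression of taxon j on the rest. If a path: a
#'   p-by-p-by-L array.
#' @export
neighborhood_lasso <- function(clr, lambda) {
  if (nrow(clr) < 3) stop("need at least 3 samples")
  xs <- standardize_cols(clr)
  C <- crossprod(xs) / nrow(xs)
  C[attr(xs, "zero_variance"), ] <- 0
  C[, attr(xs, "zero_variance")] <- 0
  arr <- mb_neighborhoods(C, as.numeric(lambda), 1e-7, 1e5)
  dn <- colnames(clr)
  if (length(lambda) == 1L) {
    out <- arr[, , 1]
    dimnames(out) <- list(dn, dn)
    out
  } else {
    dimnames(arr) <- list(dn, dn, NULL)
    arr
  }
}

#' Stability-based selection of the regularization level
#'
#' Draws `n_reps` subsamples of size `b = min(floor(10 sqrt(n)),
#' floor(0.8 n))` without replacement, fits the node-wise lasso path on
#' each, and records edge-inclusion frequencies `theta_e` under the OR rule.
#' Instability `D(lambda)` is the mean over all possible edges of
#' `2 theta (1 - theta)`. D is monotonized by a running maximum from the
#' sparse end and the smallest lambda (densest graph) whose monotonized
#' instability stays at or below `instability_threshold` is selected. If no
#' lambda qualifies the sparsest one is returned with a warning. With
#' `n_reps = 1` every frequency is 0 or 1, D is identically zero and the
#' densest lambda is selected — a documented degenerate case.
#'
#' @param clr samples-by-taxa CLR matrix.
#' @param path decreasing lambda path.
#' @param n_reps number of subsamples (default 20).
#' @param instability_threshold selection threshold (default 0.05).
#' @param seed integer seed for the subsampling.
#' @return list with `lambda` (selected), `index`, `instability` (raw D per
#'   lambda), `monotone` (monotonized D), `b` (subsample size).
#' @export
stars_select <- function(clr, path, n_reps = 20,
                         instability_threshold = 0.05, seed = 1L) {
  if (any(diff(path) > 0)) stop("path must be decreasing")
  n <- nrow(clr); p <- ncol(clr)
  b <- min(floor(10 * sqrt(n)), floor(0.8 * n))
  if (b < 3) stop("too few samples for stability subsampling")
  npair <- p * (p - 1) / 2
  freq <- matrix(0, npair, length(path))
  with_seed(seed, {
    for (r in seq_len(n_reps)) {
      idx <- sample.int(n, b)
      xs <- standardize_cols(clr[idx, , drop = FALSE])
      C <- crossprod(xs) / b
      zv <- attr(xs, "zero_variance")
      C[zv, ] <- 0; C[, zv] <- 0
      arr <- mb_neighborhoods(C, as.numeric(path), 1e-7, 1e5)
      freq <- freq + edge_union_counts(arr)
    }
  })
  theta <- freq / n_reps
  D <- colMeans(2 * theta * (1 - theta))
  Dbar <- cummax(D)                       # index 1 = lambda_max (sparse end)
  ok <- which(Dbar <= instability_threshold)
  if (length(ok) == 0) {
    warning("all instabilities above threshold; returning sparsest lambda")
    index <- 1L
  } else index <- max(ok)
  list(lambda = path[index], index = index, instability = D,
       monotone = Dbar, b = b, n_reps = n_reps, seed = seed)
}

#' Symmetrize node-wise coefficients into a signed network
#'
#' An edge (j, k) exists when either directed coefficient is nonzero; its
#' weight is the mean of the two and its sign the sign of that mean. Exactly
#' opposite coefficients cancel, the edge is dropped and the conflict
#' logged.
#'
#' @param beta square coefficient matrix with zero diagonal
#'   ([neighborhood_lasso]).
#' @param lambda optional selected penalty, stored as provenance.
#' @param seed optional seed provenance.
#' @return A `signed_network`: list with `nodes`, `edges` (data.frame
#'   `from`, `to`, `weight`, `sign`), `selected_lambda`, `conflicts`.
#' @export
symmetrize <- function(beta, lambda = NA_real_, seed = NA_integer_) {
  stopifnot(nrow(beta) == ncol(beta))
  p <- nrow(beta)
  nodes <- rownames(beta)
  if (is.null(nodes)) nodes <- paste0("taxon_", seq_len(p))
  w <- (beta + t(beta)) / 2
  present <- (beta != 0) | (t(beta) != 0)
  conflict <- present & (w == 0)
  keep <- present & !conflict
  idx <- which(keep & upper.tri(keep), arr.ind = TRUE)
  edges <- data.frame(from = nodes[idx[, 1]], to = nodes[idx[, 2]],
                      weight = w[idx],
                      sign = ifelse(w[idx] > 0, "+", "-"),
                      stringsAsFactors = FALSE)
  ncf <- sum(conflict & upper.tri(conflict))
  structure(list(nodes = nodes, edges = edges, selected_lambda = lambda,
                 conflicts = ncf, seed = seed),
            class = "signed_network")
}

#' @export
print.signed_network <- function(x, ...) {
  cat(sprintf("signed_network: %d nodes, %d edges (%d +, %d -)",
              length(x$nodes), nrow(x$edges),
              sum(x$edges$sign == "+"), sum(x$edges$sign == "-")))
  if (!is.na(x$selected_lambda))
    cat(sprintf(", lambda = %.4g", x$selected_lambda))
  cat("\n")
  if (x$conflicts > 0)
    cat(sprintf("  %d sign-conflict edge(s) dropped\n", x$conflicts))
  invisible(x)
}

# unsigned igraph skeleton of a signed_network (isolated nodes kept)
as_igraph_skeleton <- function(net) {
  igraph::graph_from_data_frame(net$edges[, c("from", "to")],
                                directed = FALSE,
                                vertices = data.frame(name = net$nodes))
}

#' Infer a signed co-occurrence network from a count table
#'
#' Pipeline: drop zero-variance taxa for this sample set (their identity is
#' recorded — the replicate's node set), CLR transform, build the lambda
#' path, pick lambda by stability selection, refit the node-wise lasso on
#' the full data at the selected lambda, symmetrize.
#'
#' @param table an [abundance_table] or taxa-by-sample matrix (>= 10
#'   samples).
#' @param pseudocount passed to [clr_transform].
#' @param n_lambda,min_ratio path parameters ([lambda_path]).
#' @param stars_reps,instability_threshold stability parameters
#'   ([stars_select]).
#' @param seed integer seed for the stability subsampling.
#' @return A `signed_network`; dropped taxa in `$dropped`, the stability
#'   summary in `$stars`.
#' @export
infer_network <- function(table, pseudocount = NULL, n_lambda = 20,
                          min_ratio = 0.01, stars_reps = 20,
                          instability_threshold = 0.05, seed = 1L) {
  counts <- if (inherits(table, "abundance_table")) table$counts else
    as.matrix(table)
  if (ncol(counts) < 10) stop("fewer than 10 samples")
  # sort samples by ID so the subsampling stream is invariant to input order
  counts <- counts[, order(colnames(counts)), drop = FALSE]
  v <- apply(counts, 1, function(r) max(r) > min(r))
  dropped <- rownames(counts)[!v]
  counts <- counts[v, , drop = FALSE]
  if (nrow(counts) < 2) stop("fewer than 2 variable taxa")
  cl <- clr_transform(counts, pseudocount)
  path <- lambda_path(cl, n_lambda, min_ratio)
  st <- stars_select(cl, path, stars_reps, instability_threshold, seed)
  beta <- neighborhood_lasso(cl, st$lambda)
  net <- symmetrize(beta, lambda = st$lambda, seed = seed)
  net$dropped <- dropped
  net$stars <- st
  net
}
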