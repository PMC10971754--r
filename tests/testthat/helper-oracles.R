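# Independent brute-force oracles and fixture builders used across tests.
# Everything here is deliberately naive (enumeration, O(n^3) loops) and
# shares no code with the package implementations it checks.

# build a signed_network directly from an edge data.frame
make_net <- function(nodes, from = character(0), to = character(0),
                     sign = character(0), weight = NULL) {
  if (is.null(weight))
    weight <- ifelse(sign == "+", 0.1, -0.1)
  structure(list(nodes = nodes,
                 edges = data.frame(from = from, to = to, weight = weight,
                                    sign = sign, stringsAsFactors = FALSE),
                 selected_lambda = NA_real_, conflicts = 0L,
                 seed = NA_integer_),
            class = "signed_network")
}

# adjacency matrix of a signed_network's unsigned skeleton
net_adjacency <- function(net) {
  n <- length(net$nodes)
  A <- matrix(0, n, n, dimnames = list(net$nodes, net$nodes))
  if (nrow(net$edges)) {
    A[cbind(net$edges$from, net$edges$to)] <- 1
    A[cbind(net$edges$to, net$edges$from)] <- 1
  }
  A
}

# network from an adjacency matrix with random-but-seeded signs
net_from_adjacency <- function(A, seed = 1) {
  n <- nrow(A)
  nodes <- sprintf("v%02d", seq_len(n))
  idx <- which(A == 1 & upper.tri(A), arr.ind = TRUE)
  set.seed(seed)
  sgn <- sample(c("+", "-"), nrow(idx), replace = TRUE)
  make_net(nodes, nodes[idx[, 1]], nodes[idx[, 2]], sgn)
}

# ---- graph metric oracles ------------------------------------------------

# Floyd-Warshall average shortest path over mutually reachable pairs
oracle_apl <- function(A) {
  n <- nrow(A)
  D <- ifelse(A > 0, 1, Inf); diag(D) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  vals <- D[upper.tri(D)]
  vals <- vals[is.finite(vals)]
  if (!length(vals)) NA_real_ else mean(vals)
}

# global transitivity by triple/triangle enumeration
oracle_transitivity <- function(A) {
  n <- nrow(A)
  tri <- 0; triples <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
    if (i == j || j == k || i == k) next
    if (A[i, j] && A[j, k]) {
      triples <- triples + 1           # ordered path i-j-k (center j)
      if (A[i, k]) tri <- tri + 1
    }
  }
  if (triples == 0) 0 else tri / triples
}

# enumerate all set partitions of 1..n (restricted growth strings)
all_partitions <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  rec <- function(prefix, maxb) {
    if (length(prefix) == n) { out[[length(out) + 1L]] <<- prefix; return() }
    for (b in seq_len(maxb + 1L))
      rec(c(prefix, b), max(maxb, b))
  }
  rec(1L, 1L)
  out
}

newman_q <- function(A, membership) {
  m <- sum(A) / 2
  if (m == 0) return(0)
  deg <- rowSums(A)
  q <- 0
  for (c in unique(membership)) {
    idx <- membership == c
    ec <- sum(A[idx, idx]) / 2
    dc <- sum(deg[idx])
    q <- q + ec / m - (dc / (2 * m))^2
  }
  q
}

# maximum modularity over all partitions (exact, tiny graphs only)
oracle_max_modularity <- function(A) {
  if (sum(A) == 0) return(0)
  max(vapply(all_partitions(nrow(A)), function(p) newman_q(A, p), numeric(1)))
}

# hub scores by shifted power iteration (Perron vector of A + I)
oracle_hub <- function(A, iter = 20000, tol = 1e-13) {
  n <- nrow(A)
  if (sum(A) == 0) return(rep(0, n))
  B <- A + diag(n)
  v <- rep(1 / sqrt(n), n)
  for (i in seq_len(iter)) {
    w <- B %*% v
    w <- w / sqrt(sum(w^2))
    if (max(abs(w - v)) < tol) break
    v <- w
  }
  v <- abs(as.vector(v))
  v[v < 1e-10] <- 0
  v / max(v)
}

# is the top eigenvalue of A simple? (hub scores only well-defined then)
top_gap_simple <- function(A, tol = 1e-8) {
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  length(ev) < 2 || (ev[1] - ev[2]) > tol
}

# ---- zeta oracle ---------------------------------------------------------

# mean shared-species count over all i-site combinations, by set operations
oracle_zeta <- function(presence, i) {
  sets <- apply(presence > 0, 1, which, simplify = FALSE)
  combos <- combn(length(sets), i, simplify = FALSE)
  mean(vapply(combos, function(cb)
    length(Reduce(intersect, sets[cb])), numeric(1)))
}

# ---- lasso QP oracle -----------------------------------------------------

# exhaustive active-set search for min (1/2n)||y - Xb||^2 + lambda||b||_1
oracle_lasso <- function(X, y, lambda) {
  n <- nrow(X); p <- ncol(X)
  best <- NULL; best_obj <- Inf
  signs <- expand.grid(rep(list(c(-1, 0, 1)), p))
  for (r in seq_len(nrow(signs))) {
    s <- as.numeric(signs[r, ])
    act <- which(s != 0)
    b <- rep(0, p)
    if (length(act)) {
      Xa <- X[, act, drop = FALSE]
      rhs <- crossprod(Xa, y) / n - lambda * s[act]
      sol <- tryCatch(solve(crossprod(Xa) / n, rhs), error = function(e) NULL)
      if (is.null(sol)) next
      if (any(sign(sol) != s[act])) next   # sign pattern must be consistent
      b[act] <- sol
    }
    obj <- sum((y - X %*% b)^2) / (2 * n) + lambda * sum(abs(b))
    if (obj < best_obj) { best_obj <- obj; best <- b }
  }
  best
}

# standardize columns to zero mean / unit population sd
std_cols <- function(x) apply(x, 2, function(c) {
  c <- c - mean(c); s <- sqrt(mean(c^2)); if (s > 0) c / s else c * 0
})
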