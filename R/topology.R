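#' Edge counts by sign
#'
#' @param net a `signed_network`.
#' @return list `total`, `positive`, `negative`, `ratio` (positive/negative;
#'   `NA` when there are no negative edges).
#' @export
edge_counts <- function(net) {
  stopifnot(inherits(net, "signed_network"))
  pos <- sum(net$edges$sign == "+")
  neg <- sum(net$edges$sign == "-")
  list(total = pos + neg, positive = pos, negative = neg,
       ratio = if (neg > 0) pos / neg else NA_real_)
}

#' Average shortest-path length
#'
#' Mean shortest-path length over all unordered pairs of distinct,
#' mutually reachable nodes of the unsigned, unweighted skeleton;
#' disconnected pairs are excluded rather than counted as infinite. `NA`
#' when no pair is reachable.
#'
#' @param net a `signed_network`.
#' @return numeric scalar (or `NA`).
#' @export
average_path_length <- function(net) {
  if (nrow(net$edges) == 0) return(NA_real_)
  g <- as_igraph_skeleton(net)
  apl <- igraph::mean_distance(g, directed = FALSE, unconnected = TRUE)
  if (is.nan(apl)) NA_real_ else apl
}

# degree sequence incl. isolated nodes
degree_sequence <- function(net) {
  deg <- setNames(rep(0L, length(net$nodes)), net$nodes)
  if (nrow(net$edges)) {
    t1 <- table(net$edges$from)
    t2 <- table(net$edges$to)
    deg[names(t1)] <- deg[names(t1)] + as.integer(t1)
    deg[names(t2)] <- deg[names(t2)] + as.integer(t2)
  }
  deg
}

#' Degree heterogeneity
#'
#' Coefficient of variation of the degree sequence (population standard
#' deviation over the mean); 0 for regular graphs and when the mean degree
#' is 0.
#'
#' @param net a `signed_network`.
#' @return numeric scalar `H >= 0`.
#' @export
heterogeneity <- function(net) {
  k <- degree_sequence(net)
  m <- mean(k)
  if (m == 0) return(0)
  sqrt(mean((k - m)^2)) / m
}

#' Louvain modularity with seeded restarts
#'
#' Runs the Louvain community-detection heuristic on the unsigned,
#' unweighted skeleton `n_restarts` times under seeded random vertex
#' permutations and reports the best Newman modularity Q and its partition.
#' Edgeless networks get Q = 0 by convention.
#'
#' @param net a `signed_network`.
#' @param n_restarts number of restarts (default 10).
#' @param seed integer seed.
#' @return list `Q`, `membership` (named integer vector).
#' @export
modularity_louvain <- function(net, n_restarts = 10, seed = 1L) {
  n <- length(net$nodes)
  if (nrow(net$edges) == 0)
    return(list(Q = 0, membership = setNames(seq_len(max(n, 0)), net$nodes)))
  g <- as_igraph_skeleton(net)
  best_q <- -Inf; best_m <- NULL
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      perm <- sample.int(n)
      gp <- igraph::permute(g, perm)
      cl <- igraph::cluster_louvain(gp)
      q <- igraph::modularity(gp, igraph::membership(cl))
      if (q > best_q) {
        best_q <- q
        mem <- igraph::membership(cl)
        # map back to original vertex order
        best_m <- setNames(as.integer(mem[perm]),
                           igraph::V(g)$name)
      }
    }
  })
  list(Q = best_q, membership = best_m[net$nodes])
}

#' Global clustering coefficient (transitivity)
#'
#' `3 * triangles / connected triples` on the unsigned skeleton; 0 when the
#' graph has no connected triples.
#'
#' @param net a `signed_network`.
#' @return numeric scalar in `[0, 1]`.
#' @export
clustering_coefficient <- function(net) {
  if (nrow(net$edges) == 0) return(0)
  g <- as_igraph_skeleton(net)
  tr <- igraph::transitivity(g, type = "global")
  if (is.nan(tr)) 0 else tr
}

#' Kleinberg hub scores
#'
#' For an undirected graph the hub and authority scores coincide and are
#' the principal eigenvector of the adjacency matrix, here computed by a
#' dense symmetric eigendecomposition, taken elementwise non-negative and
#' normalized so the maximum is 1. Isolated nodes (and nodes outside the
#' dominant component) score 0. Intended for the full-group network, not the
#' subsampled ensemble replicates.
#'
#' @param net a `signed_network`.
#' @return A `hub_report`: list with `scores` (named, in `[0, 1]`) and
#'   `flag` (`scores >= 0.5`).
#' @export
hub_scores <- function(net) {
  n <- length(net$nodes)
  scores <- setNames(rep(0, n), net$nodes)
  if (nrow(net$edges) > 0) {
    A <- matrix(0, n, n, dimnames = list(net$nodes, net$nodes))
    A[cbind(net$edges$from, net$edges$to)] <- 1
    A[cbind(net$edges$to, net$edges$from)] <- 1
    ev <- eigen(A, symmetric = TRUE)
    v <- abs(ev$vectors[, 1])
    v[v < 1e-10] <- 0
    scores[] <- v / max(v)
  }
  structure(list(scores = scores, flag = scores >= 0.5),
            class = "hub_report")
}

#' Hub taxa above a score threshold
#'
#' @param report a `hub_report` from [hub_scores].
#' @param threshold minimum score (default 0.5).
#' @return Character vector of taxa with score `>= threshold`, by
#'   descending score, ties broken by taxon ID.
#' @export
hub_taxa <- function(report, threshold = 0.5) {
  stopifnot(inherits(report, "hub_report"))
  s <- report$scores[report$scores >= threshold]
  names(s)[order(-s, names(s))]
}

#' Signed neighbors of a taxon
#'
#' @param net a `signed_network`.
#' @param taxon node ID present in the network.
#' @return list `positive`, `negative`: the taxon's partners split by edge
#'   sign.
#' @export
signed_neighbors <- function(net, taxon) {
  if (!(taxon %in% net$nodes)) stop(sprintf("unknown taxon '%s'", taxon))
  e <- net$edges
  hit <- e$from == taxon | e$to == taxon
  partner <- as.character(ifelse(e$from[hit] == taxon, e$to[hit],
                                 e$from[hit]))
  list(positive = sort(partner[e$sign[hit] == "+"]),
       negative = sort(partner[e$sign[hit] == "-"]))
}

#' All topology measures for one network
#'
#' The per-replicate record: total nodes, total edges, positive and negative
#' edge counts, their ratio, average path length, heterogeneity, Louvain
#' modularity, average degree, and global clustering coefficient.
#'
#' @param net a `signed_network`.
#' @param replicate_id,group optional bookkeeping labels.
#' @param seed seed for the Louvain restarts.
#' @return One-row `data.frame` (a topology record).
#' @export
topology_record <- function(net, replicate_id = NA_integer_,
                            group = NA_character_, seed = 1L) {
  ec <- edge_counts(net)
  n <- length(net$nodes)
  data.frame(
    group = group, replicate = replicate_id,
    total_nodes = n,
    total_edges = ec$total,
    positive_edges = ec$positive,
    negative_edges = ec$negative,
    pos_neg_ratio = ec$ratio,
    average_path_length = average_path_length(net),
    heterogeneity = heterogeneity(net),
    modularity = modularity_louvain(net, seed = seed)$Q,
    average_degree = if (n > 0) 2 * ec$total / n else NA_real_,
    clustering_coefficient = clustering_coefficient(net),
    stringsAsFactors = FALSE)
}
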