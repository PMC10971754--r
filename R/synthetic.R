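#' Generate a planted conditional-dependence graph
#'
#' Draws an Erdos-Renyi edge set over `n_taxa` nodes, assigns each edge a
#' sign and a partial-association magnitude, and embeds it symmetrically in a
#' precision (inverse covariance) matrix whose diagonal is inflated until the
#' matrix is safely positive definite. The planted edge set is the ground
#' truth against which network inference is scored.
#'
#' @param n_taxa number of taxa (nodes).
#' @param edge_density expected fraction of the `choose(n_taxa, 2)` pairs
#'   that receive an edge; may be 0 (empty graph), must be < 1.
#' @param positive_fraction fraction of edges given a positive sign.
#' @param magnitude_range length-2 positive interval from which absolute
#'   partial-association magnitudes are drawn uniformly.
#' @param seed integer seed; fully determines the output.
#'
#' @return A `planted_graph`: list with `n_taxa`, `edges` (data.frame
#'   `from`, `to`, `sign`, `magnitude`), `precision` and `seed`.
#' @export
generate_planted_graph <- function(n_taxa, edge_density = 0.05,
                                   positive_fraction = 0.5,
                                   magnitude_range = c(0.15, 0.35),
                                   seed = 1L) {
  stopifnot(n_taxa >= 1, edge_density >= 0, edge_density < 1,
            all(magnitude_range > 0), length(magnitude_range) == 2)
  with_seed(seed, {
    pairs <- if (n_taxa >= 2) t(combn(n_taxa, 2)) else
      matrix(integer(0), ncol = 2)
    keep <- if (nrow(pairs)) runif(nrow(pairs)) < edge_density else logical(0)
    ed <- pairs[keep, , drop = FALSE]
    m <- nrow(ed)
    sgn <- if (m) ifelse(runif(m) < positive_fraction, 1, -1) else numeric(0)
    mag <- if (m) runif(m, magnitude_range[1], magnitude_range[2]) else numeric(0)
    P <- diag(1, n_taxa)
    if (m) {
      # precision off-diagonal sign is the NEGATIVE of the partial
      # correlation sign, so a "+" edge gets a negative precision entry
      for (e in seq_len(m)) {
        v <- -sgn[e] * mag[e]
        P[ed[e, 1], ed[e, 2]] <- v
        P[ed[e, 2], ed[e, 1]] <- v
      }
    }
    # inflate diagonal until smallest eigenvalue >= 0.1
    steps <- 0L
    while (min(eigen(P, symmetric = TRUE, only.values = TRUE)$values) < 0.1) {
      diag(P) <- diag(P) * 1.1
      steps <- steps + 1L
      if (steps > 100L)
        stop("could not make precision positive-definite in 100 inflation steps")
    }
    taxa <- sprintf("taxon_%03d", seq_len(n_taxa))
    dimnames(P) <- list(taxa, taxa)
    edges <- data.frame(
      from = if (m) taxa[ed[, 1]] else character(0),
      to = if (m) taxa[ed[, 2]] else character(0),
      sign = sgn, magnitude = mag, stringsAsFactors = FALSE)
    structure(list(n_taxa = n_taxa, taxa = taxa, edges = edges,
                   precision = P, seed = seed),
              class = "planted_graph")
  })
}

#' Simulate a compositional count table from a planted graph
#'
#' Latent per-sample log-abundances are multivariate normal with covariance
#' equal to the inverse of the planted precision matrix; a softmax maps them
#' to a composition, and counts are a multinomial draw at a lognormal
#' sequencing depth scaled by a per-batch multiplier. This is the
#' logistic-normal-multinomial model that the CLR-based inference stage
#' assumes, so edge recovery is well posed.
#'
#' @param graph a `planted_graph`.
#' @param n_samples number of samples (>= 2).
#' @param mean_depth median sequencing depth (counts per sample).
#' @param depth_dispersion lognormal sdlog of depth variation.
#' @param batch_labels character vector of per-sample batch labels, recycled
#'   to `n_samples`.
#' @param batch_effects named numeric vector of per-batch depth multipliers.
#' @param seed integer seed.
#'
#' @return An [abundance_table] with metadata columns `batch`, `run_group`
#'   and `population`.
#' @export
simulate_counts <- function(graph, n_samples, mean_depth = 1e4,
                            depth_dispersion = 0.3,
                            batch_labels = "A",
                            batch_effects = c(A = 1),
                            seed = 1L) {
  stopifnot(inherits(graph, "planted_graph"), n_samples >= 2,
            mean_depth > 0, depth_dispersion >= 0)
  batch <- rep_len(as.character(batch_labels), n_samples)
  if (!all(batch %in% names(batch_effects)))
    stop("every batch label needs a multiplier in batch_effects")
  p <- graph$n_taxa
  Sigma <- solve(graph$precision)
  R <- chol(Sigma)
  with_seed(seed, {
    Z <- matrix(rnorm(n_samples * p), n_samples, p) %*% R  # samples x taxa
    comp <- exp(Z - apply(Z, 1, max))
    comp <- comp / rowSums(comp)
    depth <- rlnorm(n_samples, log(mean_depth), depth_dispersion) *
      unname(batch_effects[batch])
    depth <- pmax(1L, as.integer(round(depth)))
    if (any(depth <= 0)) stop("non-positive sequencing depth")
    counts <- vapply(seq_len(n_samples),
                     function(i) rmultinom(1, depth[i], comp[i, ])[, 1],
                     numeric(p))
    rownames(counts) <- graph$taxa
    colnames(counts) <- sprintf("sample_%04d", seq_len(n_samples))
    meta <- data.frame(population = "SYN", biomass_g = NA_real_,
                       batch = batch,
                       run_group = colnames(counts),
                       row.names = colnames(counts),
                       stringsAsFactors = FALSE)
    tab <- abundance_table(counts, taxonomy = NULL, metadata = meta)
    note(tab, sprintf("simulate_counts: seed=%d depth=%g", seed, mean_depth))
  })
}

#' Synthetic taxonomy for a set of taxa
#'
#' Assigns each taxon a nested synthetic lineage (domain Bacteria) so that
#' rank conglomeration has something to merge: taxa are grouped into
#' `n_genera` genera, genera into families, and so on up to class.
#'
#' @param taxa character vector of taxon IDs.
#' @param n_genera,n_families,n_orders,n_classes number of distinct labels
#'   at each rank.
#' @param seed integer seed.
#' @return data.frame with rownames `taxa` and columns `domain`, `class`,
#'   `order`, `family`, `genus`, `species`.
#' @export
synthetic_taxonomy <- function(taxa, n_genera = max(2L, length(taxa) %/% 3L),
                               n_families = max(2L, n_genera %/% 2L),
                               n_orders = max(2L, n_families %/% 2L),
                               n_classes = max(2L, n_orders %/% 2L),
                               seed = 1L) {
  n <- length(taxa)
  with_seed(seed, {
    genus <- sprintf("g%02d", sample.int(n_genera, n, replace = TRUE))
    g2f <- setNames(sprintf("f%02d", sample.int(n_families, n_genera, TRUE)),
                    sprintf("g%02d", seq_len(n_genera)))
    f2o <- setNames(sprintf("o%02d", sample.int(n_orders, n_families, TRUE)),
                    sprintf("f%02d", seq_len(n_families)))
    o2c <- setNames(sprintf("c%02d", sample.int(n_classes, n_orders, TRUE)),
                    sprintf("o%02d", seq_len(n_orders)))
    fam <- g2f[genus]; ord <- f2o[fam]; cls <- o2c[ord]
    data.frame(domain = "Bacteria", class = unname(cls), order = unname(ord),
               family = unname(fam), genus = genus, species = taxa,
               row.names = taxa, stringsAsFactors = FALSE)
  })
}

#' Attach biomass values that define quantile groups
#'
#' Two modes mirror how topology-biomass signal can arise. In
#' `per-group-graph` mode each quantile group's counts come from a different
#' planted graph; biomass values are drawn inside disjoint per-group bands so
#' the empirical quartiles recover the group structure exactly. In
#' `covariate-link` mode a single table is given and biomass is drawn
#' lognormal around a monotone function of a per-sample community summary
#' (standardised Shannon diversity), so quantile membership tracks the
#' community with strength `slope`.
#'
#' @param tables a single [abundance_table] (`covariate-link`) or a list of
#'   one table per quantile group (`per-group-graph`).
#' @param mode `"per-group-graph"` or `"covariate-link"`.
#' @param link_params list; for `covariate-link`: `slope` (on the log scale,
#'   default 0.5), `meanlog` (default `log(125)`, the observed median for
#'   farm-grown sporophytes), `sdlog` residual spread (default 0.4). For
#'   `per-group-graph`: `band_width` (default 100 g per group).
#' @param seed integer seed.
#'
#' @return A list: `table` (merged [abundance_table] with `biomass_g` filled
#'   in), `biomass` named vector, and `group` the implied quantile labels.
#' @export
simulate_biomass_groups <- function(tables,
                                    mode = c("per-group-graph", "covariate-link"),
                                    link_params = list(), seed = 1L) {
  mode <- match.arg(mode)
  lp <- modifyList(list(slope = 0.5, meanlog = log(125), sdlog = 0.4,
                        band_width = 100), link_params)
  if (mode == "per-group-graph") {
    stopifnot(is.list(tables), length(tables) >= 2)
    k <- length(tables)
    ns <- vapply(tables, function(t) ncol(t$counts), integer(1))
    if (sum(ns) < 8) stop("fewer than 8 samples: quartiles degenerate")
    with_seed(seed, {
      counts <- NULL; biomass <- numeric(0); group <- character(0)
      for (g in seq_len(k)) {
        cg <- tables[[g]]$counts
        colnames(cg) <- sprintf("Q%d_%s", g, colnames(cg))
        # union of taxa, zero-filling taxa absent from a group
        if (is.null(counts)) counts <- cg else {
          all_taxa <- union(rownames(counts), rownames(cg))
          pad <- function(m) {
            out <- matrix(0, length(all_taxa), ncol(m),
                          dimnames = list(all_taxa, colnames(m)))
            out[rownames(m), ] <- m
            out
          }
          counts <- cbind(pad(counts), pad(cg))
        }
        biomass <- c(biomass, setNames(
          runif(ncol(cg), (g - 1) * lp$band_width + 1, g * lp$band_width),
          colnames(cg)))
        group <- c(group, rep(sprintf("Q%d", g), ncol(cg)))
      }
      meta <- data.frame(population = "SYN", biomass_g = unname(biomass),
                         batch = "A", run_group = names(biomass),
                         row.names = names(biomass), stringsAsFactors = FALSE)
      tab <- abundance_table(counts, metadata = meta)
      list(table = tab, biomass = biomass,
           group = setNames(group, names(biomass)))
    })
  } else {
    stopifnot(inherits(tables, "abundance_table"))
    n <- ncol(tables$counts)
    if (n < 8) stop("fewer than 8 samples: quartiles degenerate")
    with_seed(seed, {
      shannon <- apply(tables$counts, 2, function(x) {
        p <- x[x > 0] / sum(x)
        -sum(p * log(p))
      })
      z <- if (sd(shannon) > 0) (shannon - mean(shannon)) / sd(shannon)
           else rep(0, n)
      biomass <- rlnorm(n, lp$meanlog + lp$slope * z, lp$sdlog)
      names(biomass) <- colnames(tables$counts)
      tab <- tables
      if (is.null(tab$metadata))
        tab$metadata <- data.frame(population = "SYN", batch = "A",
                                   run_group = colnames(tab$counts),
                                   row.names = colnames(tab$counts),
                                   stringsAsFactors = FALSE)
      tab$metadata$biomass_g <- unname(biomass)
      qa <- assign_quantiles(tab$metadata, k = 4)
      list(table = tab, biomass = biomass, group = qa$labels)
    })
  }
}

#' Specification for a community-assembly simulation
#'
#' @param mode `"niche"` or `"stochastic"`.
#' @param n_sites number of sites (gametophyte microbiomes).
#' @param pool_size species pool size.
#' @param prevalence occupancy probability (stochastic mode); scalar or
#'   length-`pool_size`.
#' @param sigma niche breadth (niche mode); scalar or per-species. Default
#'   one tenth of the optimum spread.
#' @param seed integer seed.
#' @return An `assembly_sim_spec` list.
#' @export
assembly_sim_spec <- function(mode = c("stochastic", "niche"), n_sites = 60,
                              pool_size = 500, prevalence = 0.5,
                              sigma = 0.1, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(n_sites >= 1, pool_size >= 1,
            all(prevalence >= 0), all(prevalence <= 1), all(sigma > 0))
  structure(list(mode = mode, n_sites = n_sites, pool_size = pool_size,
                 prevalence = prevalence, sigma = sigma, seed = seed),
            class = "assembly_sim_spec")
}

#' Generate a presence-absence site-by-species matrix
#'
#' Stochastic mode: independent Bernoulli occupancy with species-specific
#' prevalence (random assembly). Niche mode: sites are placed uniformly on a
#' one-dimensional gradient, each species has a Gaussian response curve with
#' optimum `mu_s ~ U(0, 1)` and breadth `sigma_s`, and occupancy is a
#' Bernoulli draw at `exp(-(x_j - mu_s)^2 / (2 sigma_s^2))`
#' (niche-differentiated assembly).
#'
#' When `sigma` is a scalar it sets the breadth scale and per-species
#' breadths are drawn as `sigma / sqrt(g_s)` with `g_s ~ Exp(1)`: most
#' species are narrow specialists but a heavy tail of broad generalists
#' exists. This niche-breadth heterogeneity is what produces the nested,
#' power-law zeta decline characteristic of niche assembly (the decay rates
#' of species' multi-site co-occurrence become gamma-mixed, and a gamma
#' mixture of exponentials has an exact power-law tail). Pass a length-
#' `pool_size` vector to fix the breadths instead.
#'
#' @param spec an [assembly_sim_spec].
#' @return Binary matrix, sites in rows, species in columns.
#' @export
generate_assembly_community <- function(spec) {
  stopifnot(inherits(spec, "assembly_sim_spec"))
  if (spec$pool_size == 0) stop("pool_size must be positive")
  with_seed(spec$seed, {
    S <- spec$pool_size; n <- spec$n_sites
    if (spec$mode == "stochastic") {
      p <- rep_len(spec$prevalence, S)
      occ <- matrix(rbinom(n * S, 1, rep(p, each = n)), n, S)
    } else {
      x <- runif(n)                      # site positions on the gradient
      mu <- runif(S)                     # species optima
      sig <- if (length(spec$sigma) == 1)
        spec$sigma / sqrt(stats::rexp(S)) else rep_len(spec$sigma, S)
      prob <- exp(-(outer(x, mu, "-"))^2 / (2 * rep(sig^2, each = n)))
      occ <- matrix(rbinom(n * S, 1, prob), n, S)
    }
    dimnames(occ) <- list(sprintf("site_%02d", seq_len(n)),
                          sprintf("sp_%04d", seq_len(S)))
    attr(occ, "spec") <- spec
    occ
  })
}

#' Generate topology features with ordinal labels from a known model
#'
#' Features are standard normal; ordinal labels follow the proportional-odds
#' model `logit P(Y <= j) = theta_j - x %*% beta`. Ground truth for testing
#' ordinal-regression recovery.
#'
#' @param n number of rows (replicate networks).
#' @param beta true coefficient vector (length = number of features).
#' @param theta strictly increasing cutpoints; `length(theta) + 1` ordinal
#'   categories.
#' @param seed integer seed.
#' @return list with `X` (matrix) and `y` (ordered factor).
#' @export
generate_topology_table <- function(n, beta, theta, seed = 1L) {
  stopifnot(n >= 1, length(theta) >= 1)
  if (is.unsorted(theta, strictly = TRUE))
    stop("theta must be strictly increasing")
  k <- length(beta)
  with_seed(seed, {
    X <- matrix(rnorm(n * max(k, 1L)), n, max(k, 1L))
    colnames(X) <- sprintf("f%d", seq_len(ncol(X)))
    eta <- if (k) drop(X[, seq_len(k), drop = FALSE] %*% beta) else rep(0, n)
    cum <- vapply(theta, function(t) plogis(t - eta), numeric(n))
    cum <- cbind(cum, 1)
    u <- runif(n)
    y <- apply(u <= cum, 1, which.max)   # first threshold exceeded
    y <- factor(sprintf("Q%d", y),
                levels = sprintf("Q%d", seq_len(length(theta) + 1)),
                ordered = TRUE)
    list(X = if (k) X[, seq_len(k), drop = FALSE] else X[, 0, drop = FALSE],
         y = y)
  })
}
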