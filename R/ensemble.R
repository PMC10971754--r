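#' Run a subsampled network ensemble per group
#'
#' For every group and replicate, `n_per` samples are drawn without
#' replacement (the study's regime: 50 individuals drawn 100 times per
#' biomass quantile or population), a network is inferred and its topology
#' record computed. Replicate seeds are derived from the master seed by a
#' counter scheme on (group label, replicate index), so results do not
#' depend on the order in which groups are evaluated.
#'
#' @param table an [abundance_table].
#' @param groups named vector/factor mapping sample ID to group label.
#' @param n_per subsample size per replicate (default 50).
#' @param n_reps replicates per group (default 100).
#' @param seed master seed.
#' @param ... further arguments passed to [infer_network].
#' @return An `ensemble_result`: list with `records` (data.frame of
#'   topology records, one row per replicate) and the run parameters.
#' @export
run_ensemble <- function(table, groups, n_per = 50, n_reps = 100,
                         seed = 1L, ...) {
  stopifnot(inherits(table, "abundance_table"))
  groups <- setNames(as.character(groups), names(groups))
  groups <- groups[!is.na(groups)]
  if (!all(names(groups) %in% colnames(table$counts)))
    stop("group names must be sample IDs of the table")
  labs <- sort(unique(groups))
  sizes <- table(groups)
  small <- names(sizes)[sizes < n_per]
  if (length(small))
    stop(sprintf("group(s) smaller than n_per=%d: %s", n_per,
                 paste(small, collapse = ", ")))
  recs <- vector("list", length(labs) * n_reps)
  i <- 0L
  for (g in labs) {
    ids <- sort(names(groups)[groups == g])
    for (r in seq_len(n_reps)) {
      s_draw <- derive_seed(seed, g, r)
      s_net <- derive_seed(seed, g, r + n_reps)
      pick <- with_seed(s_draw, sample(ids, n_per))
      sub <- subset_table(table, samples = pick)
      net <- infer_network(sub, seed = s_net, ...)
      i <- i + 1L
      recs[[i]] <- cbind(topology_record(net, replicate_id = r, group = g,
                                         seed = s_net),
                         seed = s_draw)
    }
  }
  structure(list(records = do.call(rbind, recs), n_per = n_per,
                 n_reps = n_reps, seed = seed, groups = labs),
            class = "ensemble_result")
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf("ensemble_result: %d groups x %d replicates (n_per = %d)\n",
              length(x$groups), x$n_reps, x$n_per))
  invisible(x)
}

# star codes used in the study's figure legends
significance_code <- function(p) {
  ifelse(is.na(p), NA_character_,
         ifelse(p <= 1e-4, "****",
                ifelse(p <= 1e-3, "***",
                       ifelse(p <= 0.01, "**",
                              ifelse(p <= 0.05, "*", "ns")))))
}

#' Compare a topology metric across groups
#'
#' Kruskal-Wallis rank test across all groups plus two-sided pairwise
#' Wilcoxon rank-sum tests (unadjusted, like the study's star codes; set
#' `adjust = "holm"` to correct). A metric that is a single constant in all
#' groups gives p = 1 by convention.
#'
#' @param result an `ensemble_result` (or its `records` data.frame).
#' @param metric column name of the metric to compare.
#' @param adjust p-adjustment method for the pairwise table
#'   (default "none").
#' @return list with `metric`, `kruskal_p`, `code`, `pairwise` (data.frame
#'   `group1`, `group2`, `p`, `code`).
#' @export
compare_groups <- function(result, metric, adjust = "none") {
  records <- if (inherits(result, "ensemble_result")) result$records else result
  if (!(metric %in% colnames(records))) stop("unknown metric: ", metric)
  vals <- records[[metric]]
  grp <- factor(records$group)
  ok <- !is.na(vals)
  if (!any(ok)) stop(sprintf("metric '%s' has no non-missing values", metric))
  vals <- vals[ok]; grp <- droplevels(grp[ok])
  if (nlevels(grp) < 2) stop("need at least 2 groups")
  overall <- if (length(unique(vals)) == 1) 1 else
    suppressWarnings(kruskal.test(vals, grp)$p.value)
  labs <- levels(grp)
  pw <- t(combn(labs, 2))
  pvals <- apply(pw, 1, function(ab) {
    x <- vals[grp == ab[1]]; y <- vals[grp == ab[2]]
    if (length(unique(c(x, y))) == 1) return(1)
    suppressWarnings(wilcox.test(x, y, alternative = "two.sided")$p.value)
  })
  pvals <- stats::p.adjust(pvals, method = adjust)
  list(metric = metric, kruskal_p = overall,
       code = significance_code(overall),
       pairwise = data.frame(group1 = pw[, 1], group2 = pw[, 2], p = pvals,
                             code = significance_code(pvals),
                             stringsAsFactors = FALSE))
}

#' Per-group summary of the topology records
#'
#' Mean and standard deviation of every metric per group — the shape of the
#' study's summary table of network topology factors.
#'
#' @param result an `ensemble_result`.
#' @return data.frame with one row per (group, metric).
#' @export
summarize_ensemble <- function(result) {
  records <- result$records
  metrics <- setdiff(colnames(records), c("group", "replicate", "seed"))
  out <- do.call(rbind, lapply(metrics, function(m) {
    agg <- aggregate(records[[m]], by = list(group = records$group),
                     FUN = function(v) c(mean = mean(v, na.rm = TRUE),
                                         sd = sd(v, na.rm = TRUE)))
    data.frame(group = agg$group, metric = m,
               mean = agg$x[, "mean"], sd = agg$x[, "sd"],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
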