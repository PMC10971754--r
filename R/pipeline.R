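#' Write a full synthetic input set to disk
#'
#' Generates planted graphs, per-quantile-group count tables, taxonomy,
#' metadata, the planted edge list, and presence-absence assembly matrices,
#' and writes them as TSVs — every input the pipeline needs, with known
#' ground truth.
#'
#' @param dir output directory (created if needed).
#' @param n_taxa,n_groups,n_per_group world size.
#' @param edge_densities per-group planted edge densities (recycled).
#' @param mean_depth,depth_dispersion sequencing-depth model.
#' @param seed master seed.
#' @return Invisible list of written paths plus the ground-truth objects.
#' @export
simulate_dataset <- function(dir, n_taxa = 100, n_groups = 4,
                             n_per_group = 60,
                             edge_densities = c(0.02, 0.04, 0.07, 0.1),
                             mean_depth = 5e3, depth_dispersion = 0.3,
                             seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  edge_densities <- rep_len(edge_densities, n_groups)
  graphs <- lapply(seq_len(n_groups), function(g)
    generate_planted_graph(n_taxa, edge_densities[g],
                           seed = derive_seed(seed, "graph", g)))
  tables <- lapply(seq_len(n_groups), function(g)
    simulate_counts(graphs[[g]], n_per_group, mean_depth, depth_dispersion,
                    batch_labels = c("A", "B"),
                    batch_effects = c(A = 1, B = 1.5),
                    seed = derive_seed(seed, "counts", g)))
  sim <- simulate_biomass_groups(tables, mode = "per-group-graph",
                                 seed = derive_seed(seed, "biomass", 0))
  tab <- sim$table
  tab$taxonomy <- synthetic_taxonomy(rownames(tab$counts),
                                     seed = derive_seed(seed, "tax", 0))
  # batch labels follow the per-group tables
  batches <- unlist(lapply(tables, function(t) t$metadata$batch))
  tab$metadata$batch <- batches
  paths <- list(counts = file.path(dir, "abundance.tsv"),
                taxonomy = file.path(dir, "taxonomy.tsv"),
                metadata = file.path(dir, "metadata.tsv"),
                planted = file.path(dir, "planted_edges.tsv"),
                assembly = file.path(dir, "assembly_presence.tsv"))
  write_abundance(tab, paths$counts, paths$taxonomy, paths$metadata)
  planted <- do.call(rbind, lapply(seq_len(n_groups), function(g)
    cbind(group = sprintf("Q%d", g), graphs[[g]]$edges)))
  write.table(planted, paths$planted, sep = "\t", quote = FALSE,
              row.names = FALSE)
  occ <- generate_assembly_community(
    assembly_sim_spec("niche", n_sites = n_per_group, pool_size = n_taxa,
                      seed = derive_seed(seed, "assembly", 0)))
  write_tsv(occ, paths$assembly, id_col = "site")
  invisible(list(paths = paths, table = tab, graphs = graphs,
                 group = sim$group))
}

#' Run the full analysis pipeline
#'
#' Preprocess, split samples into biomass quantile groups, run the
#' subsampled network ensemble per taxonomic rank, regress biomass quantile
#' on topology (collinearity screen, exhaustive and stepwise AIC selection,
#' reconciliation, odds-ratio interpretation), and classify community
#' assembly from zeta decline. Writes all result tables plus a JSON manifest
#' into `config$output_dir`.
#'
#' @param config a validated config list ([read_config] or
#'   [default_config]-shaped).
#' @return The output directory, invisibly; results also returned in
#'   `attr(, "results")`.
#' @export
run_pipeline <- function(config) {
  cfg <- modifyList(default_config(), config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("kelpnet")),
                   seed = cfg$seed, stages = list())
  tab <- read_abundance(cfg$inputs$counts, cfg$inputs$taxonomy,
                        cfg$inputs$metadata)
  manifest$stages$input <- list(taxa = nrow(tab$counts),
                                samples = ncol(tab$counts))
  tab <- preprocess_pipeline(tab)
  manifest$stages$preprocess <- list(taxa = nrow(tab$counts),
                                     samples = ncol(tab$counts),
                                     log = tab$log)
  qa <- assign_quantiles(tab$metadata, k = cfg$quantiles)
  manifest$stages$quantiles <- list(cuts = qa$cuts,
                                    sizes = as.list(table(qa$labels)))
  results <- list()
  for (rank in cfg$ranks) {
    rt <- conglomerate(tab, rank)
    ens <- run_ensemble(rt, qa$labels[colnames(rt$counts)],
                        n_per = cfg$ensemble$n_per,
                        n_reps = cfg$ensemble$n_reps,
                        seed = derive_seed(cfg$seed, rank, 1),
                        pseudocount = cfg$inference$pseudocount,
                        n_lambda = cfg$inference$n_lambda,
                        min_ratio = cfg$inference$min_ratio,
                        stars_reps = cfg$inference$n_reps,
                        instability_threshold =
                          cfg$inference$instability_threshold)
    write_tsv(ens$records, file.path(cfg$output_dir,
                                     sprintf("metrics_%s.tsv", rank)),
              id_col = "row")
    summ <- summarize_ensemble(ens)
    write_tsv(summ, file.path(cfg$output_dir,
                              sprintf("metrics_summary_%s.tsv", rank)),
              id_col = "row")
    # group comparisons
    metrics <- c("total_nodes", "total_edges", "pos_neg_ratio",
                 "average_path_length", "modularity", "average_degree",
                 "heterogeneity", "clustering_coefficient")
    comps <- do.call(rbind, lapply(metrics, function(m) {
      cc <- tryCatch(compare_groups(ens, m), error = function(e) NULL)
      if (is.null(cc)) return(NULL)
      data.frame(metric = m, kruskal_p = cc$kruskal_p, code = cc$code,
                 stringsAsFactors = FALSE)
    }))
    write_tsv(comps, file.path(cfg$output_dir,
                               sprintf("comparisons_%s.tsv", rank)),
              id_col = "row")
    # ordinal regression of quantile on topology
    feats <- multicollinearity_screen(ens$records, r_max = cfg$regression$r_max)
    X <- ens$records[, feats, drop = FALSE]
    y <- factor(ens$records$group, levels = levels(qa$labels),
                ordered = TRUE)
    sel <- reconcile(best_subset(X, y), stepwise_aic(X, y), X, y)
    fit <- polr_fit(X[, sel, drop = FALSE], y)
    ors <- data.frame(feature = as.character(sel),
                      beta = as.numeric(fit$coefficients),
                      se = as.numeric(fit$se), p = as.numeric(fit$p),
                      odds_ratio = as.numeric(fit$odds_ratio),
                      direction = character(length(sel)),
                      fold = numeric(length(sel)),
                      stringsAsFactors = FALSE)
    for (ri in seq_len(nrow(ors))) {
      ip <- interpret_odds_ratio(ors$odds_ratio[ri])
      ors$direction[ri] <- ip$direction; ors$fold[ri] <- ip$fold
    }
    write_tsv(ors, file.path(cfg$output_dir,
                             sprintf("odds_ratios_%s.tsv", rank)),
              id_col = "row")
    # hub taxa on the full-group networks (not the ensemble replicates)
    hubs <- do.call(rbind, lapply(levels(qa$labels), function(g) {
      ids <- names(qa$labels)[!is.na(qa$labels) & qa$labels == g]
      ids <- intersect(ids, colnames(rt$counts))
      net <- infer_network(subset_table(rt, samples = ids),
                           pseudocount = cfg$inference$pseudocount,
                           n_lambda = cfg$inference$n_lambda,
                           min_ratio = cfg$inference$min_ratio,
                           stars_reps = cfg$inference$n_reps,
                           instability_threshold =
                             cfg$inference$instability_threshold,
                           seed = derive_seed(cfg$seed, paste0("hub", rank), 1))
      hr <- hub_scores(net)
      data.frame(group = g, taxon = names(hr$scores),
                 score = unname(hr$scores), hub = unname(hr$flag),
                 stringsAsFactors = FALSE)
    }))
    write_tsv(hubs, file.path(cfg$output_dir, sprintf("hubs_%s.tsv", rank)),
              id_col = "row")
    results[[rank]] <- list(ensemble = ens, selected = sel, fit = fit,
                            comparisons = comps, hubs = hubs)
  }
  # zeta assembly per rank and quantile group
  pres <- lapply(setNames(cfg$ranks, cfg$ranks), function(rank) {
    rt <- conglomerate(tab, rank)
    lapply(setNames(levels(qa$labels), levels(qa$labels)), function(g) {
      ids <- names(qa$labels)[!is.na(qa$labels) & qa$labels == g]
      to_presence_absence(subset_table(rt, samples = intersect(
        ids, colnames(rt$counts))))
    })
  })
  zr <- assembly_report(pres, orders = cfg$zeta$orders,
                        seed = derive_seed(cfg$seed, "zeta", 1),
                        n_combos = cfg$zeta$n_combos)
  write_tsv(zr, file.path(cfg$output_dir, "assembly_report.tsv"),
            id_col = "row")
  results$assembly <- zr
  manifest$stages$done <- TRUE
  jsonlite::write_json(manifest, file.path(cfg$output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  out <- cfg$output_dir
  attr(out, "results") <- results
  invisible(out)
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `preprocess`, `network`, `zeta`, `run`. Each
#' takes `--config <yaml>` plus optional `--seed` and `--out` overrides.
#' Invoke from Rscript:
#' `Rscript -e 'kelpnet::kelpnet_cli()' simulate --out data/ --seed 1`.
#'
#' @param args character vector of CLI arguments (default
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Invisibly, the subcommand's result.
#' @export
kelpnet_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0)
    stop("usage: kelpnet <simulate|preprocess|network|zeta|run> [--config f] [--seed s] [--out dir]")
  cmd <- args[1]
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) && i < length(args)) args[i + 1] else default
  }
  seed <- as.integer(opt("--seed", "1"))
  out <- opt("--out", "kelpnet_out")
  switch(cmd,
    simulate = invisible(simulate_dataset(out, seed = seed)),
    preprocess = {
      cfg <- read_config(opt("--config"))
      tab <- read_abundance(cfg$inputs$counts, cfg$inputs$taxonomy,
                            cfg$inputs$metadata)
      tab <- preprocess_pipeline(tab)
      dir.create(out, showWarnings = FALSE, recursive = TRUE)
      write_abundance(tab, file.path(out, "processed.tsv"))
      jsonlite::write_json(list(log = tab$log),
                           file.path(out, "provenance.json"),
                           auto_unbox = TRUE, pretty = TRUE)
      invisible(tab)
    },
    network = {
      cfg <- read_config(opt("--config"))
      tab <- read_abundance(cfg$inputs$counts, cfg$inputs$taxonomy,
                            cfg$inputs$metadata)
      net <- infer_network(tab, seed = seed)
      dir.create(out, showWarnings = FALSE, recursive = TRUE)
      write_network(net, file.path(out, "edges.tsv"),
                    file.path(out, "network.graphml"))
      invisible(net)
    },
    zeta = {
      cfg <- read_config(opt("--config"))
      tab <- read_abundance(cfg$inputs$counts, cfg$inputs$taxonomy,
                            cfg$inputs$metadata)
      dec <- zeta_decline(to_presence_absence(tab),
                          min(max(cfg$zeta$orders), ncol(tab$counts)),
                          seed = seed)
      fd <- fit_decline(dec)
      dir.create(out, showWarnings = FALSE, recursive = TRUE)
      jsonlite::write_json(fd, file.path(out, "zeta.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
      invisible(fd)
    },
    run = {
      cfg <- read_config(opt("--config"))
      cfg$seed <- seed
      cfg$output_dir <- out
      invisible(run_pipeline(cfg))
    },
    stop("unknown subcommand: ", cmd))
}
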