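# strict TSV reader: header row, first column = row ID, unique IDs
read_tsv_matrix <- function(path, numeric = TRUE) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 1) stop("malformed TSV (no columns): ", path)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop(sprintf("duplicated row ID '%s' in %s",
                 ids[duplicated(ids)][1], path))
  df <- df[, -1, drop = FALSE]
  rownames(df) <- ids
  if (numeric) {
    for (cn in colnames(df)) {
      v <- suppressWarnings(as.numeric(df[[cn]]))
      if (anyNA(v) && !anyNA(df[[cn]]))
        stop(sprintf("non-numeric cell in column '%s' of %s", cn, path))
      df[[cn]] <- v
    }
    as.matrix(df)
  } else df
}

write_tsv <- function(x, path, id_col = "id") {
  df <- as.data.frame(x, check.names = FALSE)
  df <- cbind(setNames(data.frame(rownames(df), stringsAsFactors = FALSE),
                       id_col), df)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an abundance table from TSV files
#'
#' The abundance TSV has taxa in rows (first column = taxon ID) and samples
#' in columns; the taxonomy TSV maps taxon ID to rank labels; the metadata
#' TSV maps sample ID to `population`, `biomass_g`, `batch`, `run_group`.
#'
#' @param counts_path,taxonomy_path,metadata_path file paths; the last two
#'   are optional.
#' @return An [abundance_table].
#' @export
read_abundance <- function(counts_path, taxonomy_path = NULL,
                           metadata_path = NULL) {
  counts <- read_tsv_matrix(counts_path, numeric = TRUE)
  taxonomy <- if (!is.null(taxonomy_path))
    read_tsv_matrix(taxonomy_path, numeric = FALSE) else NULL
  metadata <- if (!is.null(metadata_path)) {
    md <- read_tsv_matrix(metadata_path, numeric = FALSE)
    if (!is.null(md$biomass_g))
      md$biomass_g <- suppressWarnings(as.numeric(md$biomass_g))
    md
  } else NULL
  abundance_table(counts, taxonomy, metadata)
}

#' Write an abundance table to TSV files
#'
#' @param table an [abundance_table].
#' @param counts_path,taxonomy_path,metadata_path output paths (taxonomy /
#'   metadata written only when present and a path is given).
#' @return `counts_path`, invisibly.
#' @export
write_abundance <- function(table, counts_path, taxonomy_path = NULL,
                            metadata_path = NULL) {
  stopifnot(inherits(table, "abundance_table"))
  write_tsv(table$counts, counts_path, id_col = "taxon_id")
  if (!is.null(taxonomy_path) && !is.null(table$taxonomy))
    write_tsv(table$taxonomy, taxonomy_path, id_col = "taxon_id")
  if (!is.null(metadata_path) && !is.null(table$metadata))
    write_tsv(table$metadata, metadata_path, id_col = "sample_id")
  invisible(counts_path)
}

#' Write a signed network as an edge-list TSV and optionally GraphML
#'
#' The TSV has columns `taxon_i`, `taxon_j`, `weight`, `sign`; the GraphML
#' export carries `weight` and `sign` as edge attributes and includes
#' isolated nodes.
#'
#' @param net a `signed_network`.
#' @param path edge-list TSV path.
#' @param graphml_path optional GraphML path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, graphml_path = NULL) {
  stopifnot(inherits(net, "signed_network"))
  df <- data.frame(taxon_i = net$edges$from, taxon_j = net$edges$to,
                   weight = net$edges$weight, sign = net$edges$sign,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(graphml_path)) {
    g <- igraph::graph_from_data_frame(
      net$edges[, c("from", "to", "weight", "sign")], directed = FALSE,
      vertices = data.frame(name = net$nodes))
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  invisible(path)
}

#' Read a signed network from an edge-list TSV
#'
#' @param path edge-list TSV written by [write_network].
#' @param nodes optional full node set (to retain isolated nodes).
#' @return A `signed_network`.
#' @export
read_network <- function(path, nodes = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("taxon_i", "taxon_j", "weight", "sign")
  if (!all(need %in% colnames(df)))
    stop("edge list must have columns ", paste(need, collapse = ", "))
  if (is.null(nodes)) nodes <- sort(unique(c(df$taxon_i, df$taxon_j)))
  structure(list(nodes = nodes,
                 edges = data.frame(from = df$taxon_i, to = df$taxon_j,
                                    weight = df$weight, sign = df$sign,
                                    stringsAsFactors = FALSE),
                 selected_lambda = NA_real_, conflicts = 0L,
                 seed = NA_integer_),
            class = "signed_network")
}

# ---- run configuration ---------------------------------------------------

default_config <- function() {
  list(
    inputs = list(counts = NULL, taxonomy = NULL, metadata = NULL),
    ranks = c("order", "family", "genus", "species"),
    quantiles = 4L,
    ensemble = list(n_per = 50L, n_reps = 100L),
    inference = list(pseudocount = NULL, n_lambda = 20L, min_ratio = 0.01,
                     n_reps = 20L, instability_threshold = 0.05),
    regression = list(r_max = 0.9, p_threshold = 0.01),
    zeta = list(orders = c(3L, 5L, 10L, 20L, 50L), n_combos = 1000L),
    seed = 1L,
    output_dir = "kelpnet_out")
}

#' Read and validate a YAML run configuration
#'
#' Unknown top-level keys are rejected; referenced input files must exist;
#' the seed must be an integer. Missing keys take package defaults.
#'
#' @param path YAML file.
#' @return Validated config list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  def <- default_config()
  unknown <- setdiff(names(cfg), names(def))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- modifyList(def, cfg)
  if (!is.numeric(cfg$seed) || cfg$seed != round(cfg$seed))
    stop("seed must be an integer")
  for (f in c("counts", "taxonomy", "metadata")) {
    p <- cfg$inputs[[f]]
    if (!is.null(p) && !file.exists(p))
      stop(sprintf("input file for '%s' does not exist: %s", f, p))
  }
  if (is.null(cfg$inputs$counts)) stop("config must name an abundance table")
  if (is.null(cfg$inputs$metadata)) stop("config must name a metadata table")
  cfg
}
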