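#' Remove rare taxa (singletons and doubletons)
#'
#' Drops taxa whose total abundance summed over all samples is at or below
#' `threshold` (default 2, i.e. singletons and doubletons). Row order of the
#' surviving taxa is preserved. The threshold applies to fractional totals
#' too, so the same rule can be re-applied after replicate-run averaging.
#'
#' @param table an [abundance_table].
#' @param threshold drop taxa with row total `<= threshold`.
#' @return The filtered [abundance_table].
#' @export
remove_rare_taxa <- function(table, threshold = 2) {
  stopifnot(inherits(table, "abundance_table"))
  keep <- rowSums(table$counts) > threshold
  out <- subset_table(table, taxa = which(keep))
  note(out, sprintf("remove_rare_taxa: dropped %d of %d taxa (total <= %g)",
                    sum(!keep), length(keep), threshold))
}

#' Normalize library sizes ("by sequencer")
#'
#' Each sample is rescaled to relative abundances and multiplied by the
#' global median raw library size, removing depth differences between
#' sequencing batches while leaving within-sample proportions untouched.
#' All-zero samples are left as zeros and flagged in the log.
#'
#' @param table an [abundance_table]; every sample must have a `batch` label
#'   in its metadata.
#' @return The normalized [abundance_table]; per-sample scale factors are
#'   stored in `attr(, "scale_factors")` of the counts.
#' @export
normalize_by_batch <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  if (is.null(table$metadata) || is.null(table$metadata$batch))
    stop("every sample needs a batch label for normalization")
  depth <- colSums(table$counts)
  target <- median(depth[depth > 0])
  zero <- depth == 0
  fac <- ifelse(zero, 1, target / depth)
  table$counts <- sweep(table$counts, 2, fac, "*")
  attr(table$counts, "scale_factors") <- fac
  table <- note(table, sprintf(
    "normalize_by_batch: total-sum scaling to global median depth %g", target))
  if (any(zero))
    table <- note(table, sprintf(
      "normalize_by_batch: %d all-zero sample(s) left unchanged: %s",
      sum(zero), paste(colnames(table$counts)[zero], collapse = ", ")))
  table
}

#' Average replicate sequencing runs
#'
#' Samples sharing a `run_group` label are replicate sequencing runs of one
#' biological sample; their counts are averaged per taxon into a single
#' column named after the run group. Population and biomass must agree
#' within a group. Rare taxa whose averaged totals drop to or below the
#' threshold are then removed again.
#'
#' @param table an [abundance_table] with `run_group` metadata.
#' @param refilter re-apply [remove_rare_taxa] afterwards (default TRUE).
#' @return The averaged [abundance_table], one column per run group.
#' @export
average_replicate_runs <- function(table, refilter = TRUE) {
  stopifnot(inherits(table, "abundance_table"))
  if (is.null(table$metadata) || is.null(table$metadata$run_group))
    stop("run_group metadata required")
  rg <- as.character(table$metadata$run_group)
  groups <- unique(rg)
  for (g in groups) {
    idx <- rg == g
    for (fld in c("population", "biomass_g")) {
      if (!is.null(table$metadata[[fld]])) {
        v <- unique(table$metadata[[fld]][idx])
        v <- v[!is.na(v)]
        if (length(v) > 1)
          stop(sprintf("run group '%s' spans different biological samples (%s)",
                       g, fld))
      }
    }
  }
  counts <- vapply(groups,
                   function(g) rowMeans(table$counts[, rg == g, drop = FALSE]),
                   numeric(nrow(table$counts)))
  counts <- matrix(counts, nrow = nrow(table$counts),
                   dimnames = list(rownames(table$counts), groups))
  first <- match(groups, rg)
  meta <- table$metadata[first, , drop = FALSE]
  rownames(meta) <- groups
  meta$run_group <- groups
  out <- abundance_table(counts, taxonomy = table$taxonomy, metadata = meta)
  out$log <- c(table$log, sprintf(
    "average_replicate_runs: %d runs -> %d samples", length(rg), length(groups)))
  if (refilter) out <- remove_rare_taxa(out)
  out
}

#' Keep bacterial taxa only
#'
#' Removes taxa whose domain label is not "Bacteria" (eukaryotes, archaea,
#' unlabelled) and any taxon carrying a mitochondrial or chloroplast label at
#' any rank.
#'
#' @param table an [abundance_table] with a `domain` taxonomy column.
#' @return The filtered [abundance_table].
#' @export
keep_bacteria <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  if (is.null(table$taxonomy) || is.null(table$taxonomy$domain))
    stop("taxonomy with a domain column required")
  dom <- tolower(as.character(table$taxonomy$domain))
  keep <- !is.na(dom) & dom == "bacteria"
  organelle <- apply(table$taxonomy, 1, function(r)
    any(grepl("mitochond|chloroplast", tolower(as.character(r)))))
  keep <- keep & !organelle
  miss <- sum(is.na(dom))
  out <- subset_table(table, taxa = which(keep))
  out <- note(out, sprintf(
    "keep_bacteria: kept %d of %d taxa (%d missing domain dropped)",
    sum(keep), length(keep), miss))
  out
}

#' Conglomerate taxa to a taxonomic rank
#'
#' Sums counts over taxa sharing the same label at `rank`; taxa unclassified
#' at that rank are dropped and their total mass is recorded in the log.
#'
#' @param table an [abundance_table] with taxonomy.
#' @param rank one of `"class"`, `"order"`, `"family"`, `"genus"`,
#'   `"species"`.
#' @return An [abundance_table] with one row per distinct rank label.
#' @export
conglomerate <- function(table, rank = c("class", "order", "family",
                                         "genus", "species")) {
  stopifnot(inherits(table, "abundance_table"))
  rank <- match.arg(rank)
  if (is.null(table$taxonomy) || !(rank %in% colnames(table$taxonomy)))
    stop(sprintf("rank '%s' absent from taxonomy", rank))
  lab <- as.character(table$taxonomy[[rank]])
  classified <- !is.na(lab) & lab != ""
  dropped_mass <- sum(table$counts[!classified, , drop = FALSE])
  cts <- table$counts[classified, , drop = FALSE]
  lab <- lab[classified]
  labels <- unique(lab)
  agg <- rowsum(cts, group = lab, reorder = FALSE)
  agg <- agg[labels, , drop = FALSE]
  # taxonomy of the merged rows: keep ranks at or above `rank` where the
  # label is unanimous among members, NA otherwise
  ranks <- c("domain", "class", "order", "family", "genus", "species")
  upto <- ranks[seq_len(match(rank, ranks))]
  upto <- intersect(upto, colnames(table$taxonomy))
  tx <- do.call(rbind, lapply(labels, function(l) {
    rows <- table$taxonomy[classified, , drop = FALSE][lab == l, upto,
                                                       drop = FALSE]
    vapply(rows, function(col) {
      u <- unique(as.character(col))
      if (length(u) == 1) u else NA_character_
    }, character(1))
  }))
  tx <- as.data.frame(tx, stringsAsFactors = FALSE)
  rownames(tx) <- labels
  out <- abundance_table(agg, taxonomy = tx, metadata = table$metadata)
  out$log <- c(table$log, sprintf(
    "conglomerate(%s): %d taxa -> %d labels; unclassified mass dropped = %g",
    rank, nrow(table$counts), length(labels), dropped_mass))
  out
}

#' Assign biomass quantile groups
#'
#' Cut points are placed at the empirical k-quantiles of wet biomass. The
#' lowest group is closed above by the first cut (`<=`), all later groups
#' are lower-exclusive / upper-inclusive, so ties at a cut point fall into
#' the lower group — the same interval convention as "<= 63.92 g",
#' "> 63.92 g and <= 125 g".
#'
#' @param metadata data.frame with a `biomass_g` column, or a numeric vector
#'   of biomass values.
#' @param k number of groups (default 4 quartiles).
#' @param cuts optional explicit thresholds (length `k - 1`, non-decreasing)
#'   overriding the empirical quantiles — e.g. to reuse published cut
#'   points.
#' @return A `quantile_assignment`: list with `labels` (ordered factor
#'   Q1..Qk, named by sample; NA biomass gives NA label) and `cuts`
#'   (k-1 thresholds in g).
#' @export
assign_quantiles <- function(metadata, k = 4, cuts = NULL) {
  biomass <- if (is.numeric(metadata)) metadata else metadata$biomass_g
  if (is.null(biomass)) stop("biomass_g column required")
  nm <- if (is.numeric(metadata)) names(metadata) else rownames(metadata)
  ok <- !is.na(biomass)
  if (sum(ok) < k) stop("need at least k samples with non-missing biomass")
  if (!is.null(cuts)) {
    stopifnot(length(cuts) == k - 1, !is.unsorted(cuts))
  } else cuts <- if (k > 1)
    unname(quantile(biomass[ok], probs = seq_len(k - 1) / k)) else numeric(0)
  lev <- sprintf("Q%d", seq_len(k))
  labels <- cut(biomass, breaks = c(-Inf, cuts, Inf), labels = lev,
                right = TRUE, ordered_result = TRUE)
  names(labels) <- nm
  structure(list(labels = labels, cuts = cuts, k = k),
            class = "quantile_assignment")
}

#' Convert counts to a presence-absence site-by-species matrix
#'
#' Samples become "sites" (rows); an entry is 1 iff the count is strictly
#' positive, so fractional post-averaging counts register as presence.
#'
#' @param table an [abundance_table] or a taxa-by-sample numeric matrix.
#' @return Binary matrix, samples (sites) in rows, taxa (species) in columns.
#' @export
to_presence_absence <- function(table) {
  counts <- if (inherits(table, "abundance_table")) table$counts else
    as.matrix(table)
  out <- t(counts > 0) * 1L
  out
}

#' Full preprocessing pipeline
#'
#' Fixed stage order: rare-taxon filter, batch normalization, replicate-run
#' averaging (with the rare filter re-applied), bacterial filter, optional
#' rank conglomeration.
#'
#' @param table an [abundance_table] with taxonomy and metadata.
#' @param rank optional rank for [conglomerate]; `NULL` keeps the original
#'   taxa.
#' @return The processed [abundance_table], provenance in `$log`.
#' @export
preprocess_pipeline <- function(table, rank = NULL) {
  table <- remove_rare_taxa(table)
  table <- normalize_by_batch(table)
  table <- average_replicate_runs(table)
  table <- keep_bacteria(table)
  if (!is.null(rank)) table <- conglomerate(table, rank)
  table
}
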