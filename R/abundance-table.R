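#' Abundance table container
#'
#' The central data structure of the package: a taxa-by-sample matrix of
#' (possibly averaged, hence fractional) counts with an optional taxonomy
#' table and per-sample metadata attached. Mirrors the shotgun-derived SSU
#' abundance tables produced for kelp gametophyte germplasm cultures.
#'
#' @param counts numeric matrix, taxa in rows, samples in columns; both
#'   dimensions must carry unique names.
#' @param taxonomy optional `data.frame` with one row per taxon (rownames =
#'   taxon IDs) and any of the columns `domain`, `class`, `order`, `family`,
#'   `genus`, `species`. Missing labels are `NA`.
#' @param metadata optional `data.frame` with one row per sample (rownames =
#'   sample IDs); recognised columns are `population`, `biomass_g`, `batch`
#'   and `run_group`.
#'
#' @return An object of class `abundance_table` with elements `counts`,
#'   `taxonomy`, `metadata` and a `log` character vector of provenance notes.
#' @export
abundance_table <- function(counts, taxonomy = NULL, metadata = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("taxon_", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("sample_", seq_len(ncol(counts)))
  if (anyDuplicated(rownames(counts)))
    stop("duplicated taxon IDs in abundance table")
  if (anyDuplicated(colnames(counts)))
    stop("duplicated sample IDs in abundance table")
  if (any(counts < 0, na.rm = TRUE)) stop("counts must be non-negative")
  if (!is.null(taxonomy)) {
    taxonomy <- as.data.frame(taxonomy)
    if (!all(rownames(counts) %in% rownames(taxonomy)))
      stop("taxonomy missing rows for some taxa")
    taxonomy <- taxonomy[rownames(counts), , drop = FALSE]
  }
  if (!is.null(metadata)) {
    metadata <- as.data.frame(metadata)
    if (!setequal(rownames(metadata), colnames(counts)))
      stop("metadata rows must exactly match sample IDs")
    metadata <- metadata[colnames(counts), , drop = FALSE]
  }
  structure(list(counts = counts, taxonomy = taxonomy, metadata = metadata,
                 log = character(0)),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d taxa x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  if (!is.null(x$taxonomy))
    cat("  taxonomy ranks:", paste(colnames(x$taxonomy), collapse = ", "), "\n")
  if (!is.null(x$metadata))
    cat("  metadata fields:", paste(colnames(x$metadata), collapse = ", "), "\n")
  if (length(x$log)) cat("  log:", length(x$log), "entries\n")
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$counts)

# internal: append provenance note
note <- function(x, msg) {
  x$log <- c(x$log, msg)
  x
}

#' Subset an abundance table by taxa and/or samples
#'
#' @param x an `abundance_table`.
#' @param taxa,samples character or logical/integer index vectors.
#' @return The subsetted `abundance_table`.
#' @export
subset_table <- function(x, taxa = NULL, samples = NULL) {
  stopifnot(inherits(x, "abundance_table"))
  if (!is.null(taxa)) {
    x$counts <- x$counts[taxa, , drop = FALSE]
    if (!is.null(x$taxonomy))
      x$taxonomy <- x$taxonomy[rownames(x$counts), , drop = FALSE]
  }
  if (!is.null(samples)) {
    x$counts <- x$counts[, samples, drop = FALSE]
    if (!is.null(x$metadata))
      x$metadata <- x$metadata[colnames(x$counts), , drop = FALSE]
  }
  x
}
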