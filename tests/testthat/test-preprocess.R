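make_table <- function(counts, tax = NULL, meta = NULL) {
  abundance_table(counts, tax, meta)
}

test_that("rare-taxon filter removes totals at or below the threshold", {
  counts <- matrix(c(1, 0, 0, 2, 5, 0), nrow = 3, byrow = TRUE,
                   dimnames = list(c("t1", "t2", "t3"), c("a", "b")))
  out <- remove_rare_taxa(make_table(counts))
  expect_identical(rownames(out$counts), "t3")   # totals (1, 2, 5)

  # boundary: 3 kept
  counts2 <- matrix(c(2, 0, 3, 0), nrow = 2, byrow = TRUE,
                    dimnames = list(c("lo", "hi"), c("a", "b")))
  out2 <- remove_rare_taxa(make_table(counts2))
  expect_identical(rownames(out2$counts), "hi")
})

test_that("batch normalization equalizes depth, preserves proportions", {
  counts <- cbind(a = c(20, 80), b = c(80, 320))   # same proportions
  rownames(counts) <- c("t1", "t2")
  meta <- data.frame(batch = c("X", "X"), row.names = c("a", "b"))
  out <- normalize_by_batch(make_table(counts, meta = meta))
  expect_equal(out$counts[, "a"], out$counts[, "b"])
  # equal depths: unchanged up to the common median factor
  counts3 <- cbind(a = c(10, 30), b = c(25, 15))
  rownames(counts3) <- c("t1", "t2")
  out3 <- normalize_by_batch(make_table(counts3, meta = meta))
  expect_equal(out3$counts, counts3, ignore_attr = TRUE)
  # all-zero sample flagged and unchanged
  counts4 <- cbind(a = c(5, 5), b = c(0, 0))
  rownames(counts4) <- c("t1", "t2")
  out4 <- normalize_by_batch(make_table(counts4, meta = meta))
  expect_equal(unname(out4$counts[, "b"]), c(0, 0))
  expect_true(any(grepl("all-zero", out4$log)))
})

test_that("replicate-run averaging means counts and refilters", {
  counts <- cbind(r1 = c(10, 4), r2 = c(20, 0))
  rownames(counts) <- c("t1", "t2")
  meta <- data.frame(run_group = c("s1", "s1"), population = c("LC", "LC"),
                     biomass_g = c(50, 50), batch = c("A", "B"),
                     row.names = c("r1", "r2"))
  out <- average_replicate_runs(make_table(counts, meta = meta))
  expect_equal(unname(out$counts["t1", "s1"]), 15)
  # t2 averaged to 2 -> removed by the second rare filter
  expect_false("t2" %in% rownames(out$counts))

  # group of one run: unchanged
  meta2 <- data.frame(run_group = c("s1", "s2"), row.names = c("r1", "r2"))
  out2 <- average_replicate_runs(make_table(counts, meta = meta2),
                                 refilter = FALSE)
  expect_equal(unname(out2$counts), unname(counts))

  # run group spanning two biological samples errors
  meta3 <- data.frame(run_group = c("s1", "s1"), biomass_g = c(10, 20),
                      row.names = c("r1", "r2"))
  expect_error(average_replicate_runs(make_table(counts, meta = meta3)),
               "spans")
})

test_that("bacterial filter drops organelles, archaea and unlabelled taxa", {
  counts <- matrix(10, 5, 2,
                   dimnames = list(paste0("t", 1:5), c("a", "b")))
  tax <- data.frame(
    domain = c("Bacteria", "Bacteria", "Archaea", "Eukaryota", NA),
    order = c("o1", "Chloroplast", "o2", "o3", "o4"),
    row.names = paste0("t", 1:5))
  out <- keep_bacteria(make_table(counts, tax))
  expect_identical(rownames(out$counts), "t1")

  tax2 <- data.frame(domain = c("Bacteria", "Bacteria", "Bacteria",
                                "Archaea", "Archaea"),
                     row.names = paste0("t", 1:5))
  expect_equal(nrow(keep_bacteria(make_table(counts, tax2))$counts), 3)
})

test_that("conglomeration sums within labels and drops unclassified", {
  counts <- matrix(c(3, 1, 4, 2, 7, 5), nrow = 3, byrow = TRUE,
                   dimnames = list(paste0("t", 1:3), c("a", "b")))
  tax <- data.frame(domain = "Bacteria",
                    family = c("F1", "F1", NA),
                    genus = c("g1", "g2", "g3"),
                    row.names = paste0("t", 1:3))
  out <- conglomerate(make_table(counts, tax), "family")
  expect_equal(unname(out$counts["F1", ]), c(3 + 4, 1 + 2))
  expect_false(any(grepl("g3", rownames(out$counts))))
  expect_error(conglomerate(make_table(counts), "family"))

  # nested associativity on fully-labelled random fixtures
  for (s in 1:3) {
    set.seed(s)
    n <- 20
    tax_full <- synthetic_taxonomy(paste0("t", 1:n), seed = s)
    cts <- matrix(rpois(n * 6, 20), n, 6,
                  dimnames = list(paste0("t", 1:n), paste0("s", 1:6)))
    tb <- make_table(cts, tax_full)
    via_genus <- conglomerate(conglomerate(tb, "genus"), "family")
    direct <- conglomerate(tb, "family")
    ord <- rownames(direct$counts)
    expect_equal(via_genus$counts[ord, ], direct$counts[ord, ])
  }
})

test_that("quantile assignment follows the lower-inclusive tie convention", {
  qa <- assign_quantiles(setNames(1:8, paste0("s", 1:8)), k = 4)
  expect_equal(as.vector(table(qa$labels)), rep(2L, 4))
  expect_equal(as.character(qa$labels[c(1, 3, 5, 7)]),
               c("Q1", "Q2", "Q3", "Q4"))

  # k = 1: everyone in Q1
  qa1 <- assign_quantiles(c(5, 7, 9), k = 1)
  expect_true(all(qa1$labels == "Q1"))

  # ties at a cut fall into the lower group
  qa2 <- assign_quantiles(c(1, 2, 2, 4), k = 2)
  expect_equal(as.character(qa2$labels), c("Q1", "Q1", "Q1", "Q2"))

  # the published cut points are a fixture of the interval convention:
  # <= 63.92 | (63.92, 125] | (125, 211] | > 211
  qa3 <- assign_quantiles(c(63.92, 64, 125, 125.5, 211, 212), k = 4,
                          cuts = c(63.92, 125, 211))
  expect_equal(as.character(qa3$labels),
               c("Q1", "Q2", "Q2", "Q3", "Q3", "Q4"))

  expect_error(assign_quantiles(c(NA_real_, NA_real_), k = 2))
})

test_that("presence-absence conversion is strict positivity on sites", {
  counts <- matrix(c(2, 0, 1, 1), nrow = 2, byrow = TRUE,
                   dimnames = list(c("t1", "t2"), c("a", "b")))
  pa <- to_presence_absence(make_table(counts))
  # taxa-side pattern [[2,0],[1,1]] -> [[1,0],[1,1]], transposed to sites
  expect_equal(unname(t(pa)), matrix(c(1, 0, 1, 1), 2, byrow = TRUE))
  expect_equal(rownames(pa), c("a", "b"))   # samples become sites
  # fractional post-averaging counts register as presence
  expect_equal(unname(to_presence_absence(matrix(0.5))), matrix(1))
})

test_that("full pipeline composes in the fixed order and is stable", {
  set.seed(42)
  g <- generate_planted_graph(30, 0.05, seed = 1)
  tab <- simulate_counts(g, 24, mean_depth = 500, seed = 2)
  tab$taxonomy <- synthetic_taxonomy(rownames(tab$counts), seed = 3)
  tab$metadata$run_group <- rep(sprintf("s%02d", 1:12), each = 2)
  tab$metadata$biomass_g <- rep(runif(12, 10, 300), each = 2)
  out <- preprocess_pipeline(tab, rank = "genus")
  expect_s3_class(out, "abundance_table")
  expect_equal(ncol(out$counts), 12)
  expect_true(all(rowSums(out$counts) > 2))
  # idempotence up to normalization scale: re-running changes nothing but
  # a common per-sample factor
  out2 <- preprocess_pipeline(out)
  ratio <- out2$counts / out$counts[rownames(out2$counts), ]
  ratio <- ratio[is.finite(ratio)]
  expect_lt(diff(range(ratio)), 1e-9)
})
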