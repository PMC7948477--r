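make_matrix <- function(ints, conditions = NULL, donors = NULL) {
  n <- nrow(ints); m <- ncol(ints)
  if (is.null(rownames(ints))) rownames(ints) <- sprintf("P%02d", 1:n)
  if (is.null(colnames(ints))) colnames(ints) <- sprintf("s%02d", 1:m)
  meta <- data.frame(
    sample_id = colnames(ints),
    donor = donors %||% sprintf("d%02d", seq_len(m)),
    condition = conditions %||% rep("A", m),
    stringsAsFactors = FALSE)
  abundance_matrix(ints, meta, setNames(rep(3L, n), rownames(ints)))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("per-sample sum normalization divides columns by their totals", {
  am <- make_matrix(matrix(c(2, 3, 5), 3, 1))
  out <- sum_normalize(am, "per_sample")
  expect_equal(unname(out$intensities[, 1]), c(0.2, 0.3, 0.5))
  # idempotent on a column already summing to 1
  out2 <- sum_normalize(out, "per_sample")
  expect_equal(out2$intensities, out$intensities)
  # columns sum to 1 within 1e-12 on random matrices
  for (s in 1:5) {
    m <- withr::with_seed(s, matrix(stats::rexp(40), 8, 5))
    norm <- sum_normalize(make_matrix(m), "per_sample")
    expect_true(all(abs(colSums(norm$intensities) - 1) < 1e-12))
  }
})

test_that("per-protein sum normalization spreads signal across conditions", {
  tab <- toy_peptides()
  out <- sum_normalize(tab, "per_protein_across_conditions")
  aaa <- out$intensity[out$peptide == "AAA"]
  expect_equal(aaa, c(0.25, 0.25, 0.5))
  expect_equal(sum(out$intensity[out$peptide == "BBB"]), 1)
  # all-zero group is flagged and left at zero
  tab0 <- peptide_table(data.frame(
    peptide = "ZZZ", protein_id = "P9", donor = "d1",
    condition = c("A", "B"), intensity = c(0, 0)))
  expect_warning(out0 <- sum_normalize(tab0,
                                       "per_protein_across_conditions"),
                 "all-zero")
  expect_equal(out0$intensity, c(0, 0))
  expect_equal(attr(out0, "flagged_groups"), "ZZZ/d1")
})

test_that("heavy-standard normalization divides by per-group standard mean", {
  tab <- peptide_table(data.frame(
    peptide = c("pep1", "std1", "pep1", "std1", "std2"),
    protein_id = c("P1", "STD", "P1", "STD", "STD"),
    donor = c("d1", "d1", "d2", "d2", "d2"),
    condition = "A",
    intensity = c(50, 10, 20, 8, 12),
    is_heavy_standard = c(FALSE, TRUE, FALSE, TRUE, TRUE)))
  out <- normalize_to_standard(tab, "STD")
  expect_equal(out$intensity[out$donor == "d1"], 5)       # 50 / 10
  expect_equal(out$intensity[out$donor == "d2"], 2)       # 20 / mean(8, 12)
  expect_false(any(out$is_heavy_standard))
  # constant standards leave output proportional to input
  tabc <- peptide_table(data.frame(
    peptide = c("pep1", "pep2", "std1"),
    protein_id = c("P1", "P2", "STD"), donor = "d1", condition = "A",
    intensity = c(30, 60, 10),
    is_heavy_standard = c(FALSE, FALSE, TRUE)))
  outc <- normalize_to_standard(tabc, "STD")
  expect_equal(outc$intensity[2] / outc$intensity[1], 2)
  # missing standard names the offending group
  tabm <- peptide_table(data.frame(
    peptide = "pep1", protein_id = "P1", donor = "d3", condition = "B",
    intensity = 5, is_heavy_standard = FALSE))
  expect_error(normalize_to_standard(tabm, "STD"), "d3/B")
})

test_that("peptide aggregation averages peptides per (protein, donor, cond)", {
  tab <- peptide_table(data.frame(
    peptide = c("a", "b", "c", "solo"),
    protein_id = c("P1", "P1", "P1", "P2"),
    donor = "d1", condition = "A",
    intensity = c(0.1, 0.2, 0.6, 0.42)))
  am <- aggregate_peptides(tab)
  expect_equal(unname(am$intensities["P1", 1]), 0.3)
  expect_equal(unname(am$intensities["P2", 1]), 0.42)  # single peptide
  expect_equal(unname(am$unique_peptides), c(3L, 1L))
  # two-point mean
  tab2 <- peptide_table(data.frame(
    peptide = c("a", "b"), protein_id = "P1", donor = "d1",
    condition = "A", intensity = c(0.2, 0.4)))
  expect_equal(unname(aggregate_peptides(tab2)$intensities[1, 1]), 0.3)
})

test_that("aggregated values are bounded by their member peptides", {
  tab <- withr::with_seed(7, peptide_table(data.frame(
    peptide = paste0("pep", 1:30),
    protein_id = rep(c("P1", "P2", "P3"), each = 10),
    donor = rep(c("d1", "d2"), 15),
    condition = rep(c("A", "B", "C"), 10),
    intensity = stats::runif(30))))
  am <- aggregate_peptides(tab)
  for (i in seq_len(nrow(tab))) {
    cell <- am$intensities[tab$protein_id[i],
                           paste(tab$donor[i], tab$condition[i], sep = "_")]
    rows <- tab$protein_id == tab$protein_id[i] &
      tab$donor == tab$donor[i] & tab$condition == tab$condition[i]
    expect_gte(cell, min(tab$intensity[rows]))
    expect_lte(cell, max(tab$intensity[rows]))
  }
})

test_that("normalization and aggregation commute with relabeling", {
  tab <- toy_peptides()
  relab <- function(x) {
    x$protein_id <- paste0("X_", x$protein_id)
    x$peptide <- paste0("x_", x$peptide)
    peptide_table(as.data.frame(x))
  }
  a <- aggregate_peptides(sum_normalize(relab(tab),
                                        "per_protein_across_conditions"))
  b <- aggregate_peptides(sum_normalize(tab,
                                        "per_protein_across_conditions"))
  rel_rows <- paste0("X_", rownames(b$intensities))
  expect_equal(unname(a$intensities[rel_rows, ]),
               unname(b$intensities))
})

test_that("unique-peptide filter keeps exactly the supported proteins", {
  ints <- matrix(1, 4, 2, dimnames = list(paste0("P", 1:4), c("s1", "s2")))
  meta <- data.frame(sample_id = c("s1", "s2"), donor = c("d1", "d2"),
                     condition = c("A", "B"))
  am <- abundance_matrix(ints, meta,
                         c(P1 = 2L, P2 = 2L, P3 = 3L, P4 = 5L))
  expect_equal(nrow(filter_by_unique_peptides(am, 2)$intensities), 4)
  expect_equal(rownames(filter_by_unique_peptides(am, 3)$intensities),
               c("P3", "P4"))
  expect_identical(filter_by_unique_peptides(am, 1)$intensities, ints)
})

test_that("complete-case filter drops proteins with any missing cell", {
  ints <- matrix(c(1, 1, 1,
                   0, 1, 1,
                   1, 0, 1), 3, 3, byrow = TRUE,
                 dimnames = list(paste0("P", 1:3), paste0("s", 1:3)))
  meta <- data.frame(sample_id = paste0("s", 1:3),
                     donor = paste0("d", 1:3), condition = c("A", "B", "C"))
  am <- abundance_matrix(ints, meta, setNames(rep(3L, 3), paste0("P", 1:3)))
  expect_equal(rownames(filter_complete_cases(am)$intensities), "P1")
  # fully observed matrix passes through
  full <- make_matrix(matrix(1, 3, 2))
  expect_identical(filter_complete_cases(full)$intensities,
                   full$intensities)
  # only the required groups matter
  expect_equal(rownames(filter_complete_cases(am, "C")$intensities),
               paste0("P", 1:3))
  expect_error(filter_complete_cases(am, "nope"), "unknown")
})

test_that("peptide and abundance tables round-trip through TSV", {
  dir <- withr::local_tempdir()
  tab <- toy_peptides()
  write_peptides(tab, file.path(dir, "pep.tsv"))
  back <- read_peptides(file.path(dir, "pep.tsv"))
  expect_equal(as.data.frame(back), as.data.frame(tab))
  res <- generate_abundance(20, 3, c("A", "B"), 0.2, 1, 0.3, 0.1, seed = 4)
  write_abundance(res$matrix, file.path(dir, "ab"))
  back2 <- read_abundance(file.path(dir, "ab"))
  expect_equal(back2$intensities, res$matrix$intensities)
  expect_equal(back2$sample_meta, res$matrix$sample_meta)
  expect_equal(back2$unique_peptides, res$matrix$unique_peptides)
})
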