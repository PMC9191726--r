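make_qc_sce <- function(total, genes, mito) {
  n <- length(total)
  counts <- matrix(1, nrow = 2, ncol = n,
                   dimnames = list(c("g1", "g2"), sprintf("c%d", seq_len(n))))
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = Matrix::Matrix(counts, sparse = TRUE)),
    colData = S4Vectors::DataFrame(dose = 0, total_count = total,
                                   n_detected_genes = genes,
                                   mito_ratio = mito))
}

test_that("QC keeps exactly the cells meeting the >=, >=, < thresholds", {
  sce <- make_qc_sce(total = c(1.4e6, 1.5e6, 2e6),
                     genes = c(9000, 8500, 9000),
                     mito = c(0.01, 0.039, 0.04))
  kept <- qc_filter(sce)
  expect_identical(colnames(kept), "c2")  # boundary cell retained, others fail
  # idempotent, and a no-op when every cell passes
  expect_identical(colnames(qc_filter(kept)), colnames(kept))
  all_pass <- make_qc_sce(rep(2e6, 4), rep(9000, 4), rep(0.01, 4))
  expect_identical(dim(qc_filter(all_pass)), dim(all_pass))
  none <- make_qc_sce(1e5, 100, 0.5)
  expect_error(qc_filter(none), "no cells survive")
})

test_that("depth normalization equalises proportional cells and keeps zeros", {
  counts <- cbind(c1 = c(2, 4, 0, 6), c2 = c(1, 2, 0, 3), c3 = c(5, 1, 0, 2))
  rownames(counts) <- sprintf("g%d", 1:4)
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = Matrix::Matrix(counts, sparse = TRUE)),
    colData = S4Vectors::DataFrame(dose = 0, total_count = colSums(counts),
                                   n_detected_genes = colSums(counts > 0),
                                   mito_ratio = 0))
  sce <- normalize_depth(sce)
  sc <- as.matrix(SummarizedExperiment::assay(sce, "scaled"))
  expect_equal(sc[, "c1"], sc[, "c2"])        # proportional profiles collapse
  expect_true(all(sc["g3", ] == 0))           # all-zero gene stays zero
  expect_equal(unname(colSums(sc)), rep(median(colSums(counts)), 3))
})

test_that("scaled column sums equal the median depth on a random matrix", {
  set.seed(5)
  counts <- matrix(rpois(600, 5), nrow = 20,
                   dimnames = list(sprintf("g%d", 1:20), sprintf("c%d", 1:30)))
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = Matrix::Matrix(counts, sparse = TRUE)),
    colData = S4Vectors::DataFrame(dose = 0, total_count = colSums(counts),
                                   n_detected_genes = colSums(counts > 0),
                                   mito_ratio = 0))
  sc <- as.matrix(SummarizedExperiment::assay(normalize_depth(sce), "scaled"))
  expect_equal(unname(colSums(sc)), rep(median(colSums(counts)), 30),
               tolerance = 1e-12)
})

test_that("cell states are recovered from marker expression", {
  e <- simulate_expression(sim_config(seed = 1))
  sce <- normalize_depth(sim_qc(e$sce))
  states <- classify_cells(sce)
  truth <- e$truth$activated[colnames(sce)]
  expect_gte(mean((states == "activated") == truth), 0.95)
})

test_that("degenerate classification inputs fall back with a warning", {
  counts <- matrix(3, nrow = 1, ncol = 1, dimnames = list("m", "c1"))
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = Matrix::Matrix(counts, sparse = TRUE)),
    colData = S4Vectors::DataFrame(dose = 0, total_count = 3,
                                   n_detected_genes = 1, mito_ratio = 0),
    rowData = S4Vectors::DataFrame(is_marker = TRUE))
  sce <- normalize_depth(sce)
  expect_warning(st <- classify_cells(sce, markers = "m"), "degenerate")
  expect_identical(as.character(st), "inactivated")
})

test_that("differential testing finds the planted responders and no more", {
  e <- simulate_expression(sim_config(seed = 1))
  sce <- normalize_depth(sim_qc(e$sce))
  states <- classify_cells(sce)
  degs <- find_degs(sce, states)
  # BH monotone in the raw-p ranking
  ord <- order(degs$p)
  expect_true(all(diff(degs$p_adj[ord]) >= -1e-12))
  # a constant gene is never a DEG
  expect_false(any(degs$significant[degs$p == 1]))
  # recall on the planted responders
  up <- degs$gene[degs$significant & degs$direction == "up"]
  expect_gte(mean(names(e$truth$gene_class) %in% up), 0.9)
  # error with a nearly empty state
  expect_error(find_degs(sce, factor(c("activated",
                                       rep("inactivated", ncol(sce) - 1)),
                                     levels = levels(states))),
               "at least 3 cells")
})

test_that("permuted state labels keep the empirical FDR at the BH level", {
  e <- simulate_expression(small_cfg(seed = 11, n_genes = 50,
                                     n_background_genes = 150))
  sce <- normalize_depth(sim_qc(e$sce))
  sce <- sce[seq_len(200), ]   # 200 null genes after permutation
  n <- ncol(sce)
  set.seed(11)
  fdp <- replicate(200, {
    states <- factor(sample(rep(c("activated", "inactivated"),
                                c(floor(n / 2), ceiling(n / 2)))),
                     levels = c("inactivated", "activated"))
    mean(find_degs(sce, states)$significant)
  })
  expect_lte(mean(fdp), 0.05)
})

test_that("dose fold-changes equal the brute-force group-mean ratios", {
  e <- simulate_expression(small_cfg(seed = 1))
  sce <- normalize_depth(sim_qc(e$sce))
  fc <- dose_fold_changes(sce)
  expect_true(all(fc[, "0"] == 1))
  sc <- as.matrix(SummarizedExperiment::assay(sce, "scaled"))
  dose <- SummarizedExperiment::colData(sce)$dose
  for (d in c(0.1, 10)) {
    oracle <- (rowMeans(sc[, dose == d]) + 1) / (rowMeans(sc[, dose == 0]) + 1)
    expect_equal(unname(fc[, as.character(d)]), unname(oracle))
  }
  # a constant gene has fold-change 1 everywhere; a top-dose-only gene (m+1)/1
  counts <- rbind(flat = rep(4, 6), top = c(0, 0, 0, 0, 9, 9))
  colnames(counts) <- sprintf("c%d", 1:6)
  sce2 <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = Matrix::Matrix(counts, sparse = TRUE)),
    colData = S4Vectors::DataFrame(dose = rep(c(0, 1, 10), each = 2),
                                   total_count = colSums(counts),
                                   n_detected_genes = colSums(counts > 0),
                                   mito_ratio = 0))
  # use the raw counts directly (equal depths make scaling a no-op apart
  # from the zero totals; skip normalization and feed counts)
  SummarizedExperiment::assay(sce2, "scaled") <- SummarizedExperiment::assay(sce2, "counts")
  fc2 <- dose_fold_changes(sce2)
  expect_equal(unname(fc2["flat", ]), rep(1, 3))
  expect_equal(unname(fc2["top", "10"]), (9 + 1) / 1)
  expect_error(dose_fold_changes(sce2[, 3:6]), "dose 0")
})
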