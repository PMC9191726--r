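toy_peaks <- function(n, gap = 2e4, chrom = "chr1") {
  start <- seq(1e4, by = gap, length.out = n)
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, start + 499),
                         peak_id = sprintf("p%02d", seq_len(n)))
}

test_that("meta-cell aggregation conserves counts and collapses at k = 1", {
  set.seed(20)
  m <- matrix(rpois(40 * 80, 2), nrow = 40,
              dimnames = list(sprintf("p%02d", 1:40), sprintf("c%02d", 1:80)))
  id <- aggregate_cells(m, k = 1)
  expect_identical(id$counts, m)
  agg <- aggregate_cells(m, k = 8)
  expect_lte(ncol(agg$counts), ncol(m))
  for (j in seq_along(agg$groups))
    expect_equal(unname(colSums(agg$counts)[j]),
                 sum(m[, agg$groups[[j]]]))
  expect_error(aggregate_cells(m, k = 100), "exceeds")
})

test_that("the zero-penalty graphical lasso matches closed-form inversion", {
  # 3-peak toy with known covariance
  L <- matrix(c(1, 0.6, 0.3, 0, 1, 0.5, 0, 0, 1), 3)
  S <- tcrossprod(L) + diag(0.5, 3)
  gl <- graphical_lasso(S, rho = 0)
  pc_direct <- partial_correlations(solve(S))
  expect_lt(max(abs(partial_correlations(gl$theta) - pc_direct)), 1e-3)
  expect_lt(max(abs(gl$theta - solve(S))), 1e-3)
})

test_that("scores separate factor-driven from independent peaks", {
  set.seed(23)
  n <- 300
  f <- rnorm(n)
  counts <- rbind(
    p1 = rpois(n, exp(0.8 * f)),
    p2 = rpois(n, exp(0.8 * f)),
    p3 = rpois(n, exp(rnorm(n, sd = 0.8))))
  sc <- coaccess_scores(counts, toy_peaks(3), base_rho = 0.05, depth_adjust = FALSE)
  s12 <- sc$score[sc$peak_i == 1 & sc$peak_j == 2]
  s13 <- sc$score[sc$peak_i == 1 & sc$peak_j == 3]
  expect_gt(s12, 0.3)
  expect_lt(abs(s13), 0.1)
  # permuting meta-cells leaves the scores unchanged
  perm <- sample(n)
  sc_p <- coaccess_scores(counts[, perm], toy_peaks(3), base_rho = 0.05, depth_adjust = FALSE)
  expect_equal(sc_p$score, sc$score, tolerance = 1e-10)
})

test_that("differential gating uses inclusive thresholds and is monotone", {
  mk <- function(i, j, s) data.frame(peak_i = i, peak_j = j, score = s,
                                     distance = 1e4)
  st <- mk(c(1, 1, 2), c(2, 3, 3), c(0.10, 0.09, 0.5))
  un <- mk(c(1, 1), c(2, 3), c(0.05, 0.00))
  dp <- differential_pairs(st, un)
  expect_true(dp$gained[dp$peak_i == 1 & dp$peak_j == 2])    # boundary in
  expect_false(dp$gained[dp$peak_i == 1 & dp$peak_j == 3])   # 0.09 < 0.1
  expect_true(dp$gained[dp$peak_i == 2 & dp$peak_j == 3])    # absent -> 0
  # raising a stimulated score never un-gains a pair
  st2 <- st; st2$score <- st2$score + 0.2
  dp2 <- differential_pairs(st2, un)
  expect_true(all(dp2$gained[dp$gained]))
})

test_that("per-gene gained-pair counts equal a brute-force overlap scan", {
  set.seed(10)
  pk <- toy_peaks(30, gap = 5e3)
  tss <- data.frame(gene = sprintf("g%02d", 1:6), chrom = "chr1",
                    position = GenomicRanges::start(pk)[seq(1, 30, 5)] + 100,
                    strand = "+")
  pairs <- data.frame(
    peak_i = sample(1:29, 40, replace = TRUE))
  pairs$peak_j <- pairs$peak_i + sample(1:5, 40, replace = TRUE)
  pairs <- pairs[pairs$peak_j <= 30, ]
  pairs$gained <- runif(nrow(pairs)) < 0.5
  counts <- gene_pair_counts(pairs, pk, tss, flank = 1000)
  for (g in seq_len(nrow(tss))) {
    lo <- tss$position[g] - 1000; hi <- tss$position[g] + 1000
    anchors <- which(GenomicRanges::start(pk) <= hi &
                     GenomicRanges::end(pk) >= lo)
    partners <- unique(c(
      pairs$peak_j[pairs$gained & pairs$peak_i %in% anchors],
      pairs$peak_i[pairs$gained & pairs$peak_j %in% anchors]))
    expect_equal(unname(counts[g]), length(setdiff(partners, anchors)))
  }
  # no peak near the TSS means a zero count
  far <- data.frame(gene = "far", chrom = "chr1", position = 5e6, strand = "+")
  expect_equal(unname(gene_pair_counts(pairs, pk, far)), 0)
  # one anchored peak with three gained partners counts 3
  p3 <- data.frame(peak_i = c(1, 1, 1), peak_j = c(2, 3, 4), gained = TRUE)
  one <- data.frame(gene = "one", chrom = "chr1",
                    position = GenomicRanges::start(pk)[1], strand = "+")
  expect_equal(unname(gene_pair_counts(p3, pk, one)), 3)
})

test_that("rank correlation behaves at the extremes", {
  x <- setNames(1:10, letters[1:10])
  y <- setNames((1:10)^2, letters[1:10])
  expect_equal(correlate_counts(x, y), 1)
  set.seed(31)
  z <- setNames(sample(100, 10), letters[1:10])
  expect_lt(abs(correlate_counts(x, z)), 0.7)
  expect_error(correlate_counts(x[1:2], y[1:2]), "at least 3")
})

test_that("planted gained pairs are recovered from the simulated assay", {
  cfg <- small_cfg(seed = 7, n_peaks = 120, n_cells_atac = 300)
  a <- simulate_atac(cfg)
  agg <- lapply(a$counts, function(m) aggregate_cells(m, k = 10))
  sc_st <- coaccess_scores(agg$stim$counts, a$peaks)
  sc_un <- coaccess_scores(agg$unstim$counts, a$peaks)
  dp <- differential_pairs(sc_st, sc_un)
  truth <- a$truth$pairs
  tg <- paste(truth$peak_i, truth$peak_j)[truth$gained]
  called <- paste(dp$peak_i, dp$peak_j)[dp$gained]
  expect_gte(mean(called %in% tg), 0.7)
  expect_gte(mean(tg %in% called), 0.7)
})
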