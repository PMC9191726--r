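peaks_gr <- function(start, end, signal = 1, chrom = "chr1") {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end - 1),
                         signal = signal,
                         peak_id = sprintf("p%03d", seq_along(start)))
}

# O(n^2) interval-graph connected components under the gap rule
bf_stitch <- function(start, end, max_gap = 5000) {
  n <- length(start)
  adj <- outer(seq_len(n), seq_len(n), function(i, j)
    pmax(start[i], start[j]) - pmin(end[i], end[j]) <= max_gap)
  comp <- seq_len(n)
  repeat {
    new_comp <- vapply(seq_len(n), function(i) min(comp[adj[i, ]]), numeric(1))
    if (identical(new_comp, comp)) break
    comp <- new_comp
  }
  comp
}

test_that("stitching follows the 5 kb gap rule", {
  gr <- peaks_gr(c(0, 3000, 9000), c(500, 3500, 9500))
  reg <- stitch_peaks(gr, max_gap = 5000)
  expect_length(reg, 2)                    # gap 2500 merges, gap 5500 does not
  expect_equal(GenomicRanges::start(reg), c(0, 9000))
  expect_equal(reg$total_signal, c(2, 1))
  single <- stitch_peaks(peaks_gr(10, 400), max_gap = 5000)
  expect_length(single, 1)
  expect_equal(GenomicRanges::width(single), 390)
})

test_that("stitched regions cover exactly the union of input bases", {
  set.seed(66)
  start <- sort(sample.int(2e5, 200))
  gr <- peaks_gr(start, start + sample(100:900, 200, replace = TRUE))
  reg <- stitch_peaks(gr, max_gap = 5000)
  cov_in <- GenomicRanges::reduce(gr)
  expect_true(all(IRanges::overlapsAny(cov_in, reg)))
  expect_equal(sum(GenomicRanges::width(GenomicRanges::intersect(
    GenomicRanges::granges(reg), GenomicRanges::granges(gr)))),
    sum(GenomicRanges::width(cov_in)))
})

test_that("stitching equals brute-force interval-graph components on random peaks", {
  set.seed(6)
  n <- 1000
  chrom <- sample(c("chr1", "chr2"), n, replace = TRUE)
  start <- sample.int(3e6, n)
  width <- sample(150:1000, n, replace = TRUE)
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, start + width - 1),
                               signal = runif(n), peak_id = sprintf("p%04d", 1:n))
  reg <- stitch_peaks(gr, max_gap = 5000)
  n_bf <- sum(vapply(c("chr1", "chr2"), function(ch) {
    on <- chrom == ch
    length(unique(bf_stitch(start[on], start[on] + width[on])))
  }, numeric(1)))
  expect_equal(length(reg), n_bf)
  expect_equal(sum(reg$total_signal), sum(gr$signal))
})

test_that("SE classification matches the slope-1 geometry on small cases", {
  gr <- peaks_gr(c(0, 1e4, 2e4, 3e4), c(500, 10500, 20500, 30500))
  gr$total_signal <- c(1, 1, 1, 100)
  r <- classify_se_te(gr)
  expect_equal(r$enh_class, c("TE", "TE", "TE", "SE"))   # only the dominant region
  gr$total_signal <- 1:4                                  # linear ramp: no SEs
  expect_true(all(classify_se_te(gr)$enh_class == "TE"))
  gr$total_signal <- rep(2, 4)
  expect_warning(r_eq <- classify_se_te(gr), "all signals equal")
  expect_true(all(r_eq$enh_class == "TE"))
  expect_error(classify_se_te(gr[1:2]), "at least 3")
})

test_that("SE classification equals the brute-force cutoff scan and scales freely", {
  set.seed(8)
  n <- 500
  start <- seq(0, by = 1e4, length.out = n)
  gr <- peaks_gr(start, start + 500)
  gr$total_signal <- rlnorm(n, 2, 1)
  r <- classify_se_te(gr)
  # oracle: scan every cutoff for the deepest point below the diagonal
  s_sorted <- sort(gr$total_signal)
  x <- (seq_len(n) - 1) / (n - 1)
  y <- (s_sorted - min(s_sorted)) / diff(range(s_sorted))
  best <- max(which((x - y) == max(x - y)))
  se_oracle <- sort(gr$total_signal, decreasing = TRUE)[seq_len(n - best)]
  expect_setequal(gr$total_signal[r$enh_class == "SE"], se_oracle)
  # SE ranks form a suffix of the signal-sorted order
  expect_true(min(r$rank[r$enh_class == "SE"]) >
              max(r$rank[r$enh_class == "TE"]))
  # invariant to uniform signal scaling
  gr2 <- gr; gr2$total_signal <- gr$total_signal * 37
  expect_identical(classify_se_te(gr2)$enh_class, r$enh_class)
})

test_that("condition merging equals the interval union, class-wise", {
  mk <- function(start, end, cls) {
    g <- peaks_gr(start, end)
    g$enh_class <- cls
    g$total_signal <- 1
    g
  }
  a <- mk(c(0, 1000), c(500, 1500), c("SE", "TE"))
  b <- mk(c(0, 1000), c(500, 1500), c("SE", "TE"))
  m_same <- merge_conditions(list(stim = a, unstim = b))
  expect_length(m_same, 2)
  disj <- mk(c(5000, 9000), c(5500, 9500), c("SE", "TE"))
  m_disj <- merge_conditions(list(stim = a, unstim = disj))
  expect_length(m_disj, 4)
  # random overlapping sets against the reduce() union, per class
  set.seed(12)
  s1 <- sort(sample.int(5e4, 40)); s2 <- sort(sample.int(5e4, 40))
  ga <- mk(s1, s1 + 800, rep(c("SE", "TE"), 20))
  gb <- mk(s2, s2 + 800, rep(c("SE", "TE"), 20))
  m <- merge_conditions(list(stim = ga, unstim = gb))
  for (cl in c("SE", "TE")) {
    pooled <- c(ga[ga$enh_class == cl], gb[gb$enh_class == cl])
    oracle <- GenomicRanges::reduce(GenomicRanges::granges(pooled))
    got <- GenomicRanges::granges(m[m$enh_class == cl])
    expect_identical(sort(got), sort(oracle))
  }
})

test_that("gene assignment prefers SE, then signal, and honours tie-breaks", {
  tss <- data.frame(gene = c("gA", "gB"), chrom = "chr1",
                    position = c(1000, 50000), strand = "+")
  gr <- peaks_gr(c(0, 2000, 48000), c(500, 2500, 49000))
  gr$enh_class <- c("TE", "SE", "TE")
  gr$total_signal <- c(100, 5, 7)
  asg <- assign_genes(gr, tss)
  # gA's nearest regions are 1 and 2; the SE (region 2) wins despite signal
  expect_equal(asg$gene_table$enh_class[asg$gene_table$gene == "gA"], "SE")
  # equidistant TSSs resolve to the lower coordinate
  tss_eq <- data.frame(gene = c("lo", "hi"), chrom = "chr1",
                       position = c(900, 1100), strand = "+")
  one <- peaks_gr(990, 1010); one$enh_class <- "TE"; one$total_signal <- 1
  asg_eq <- assign_genes(one, tss_eq)
  expect_equal(asg_eq$gene_table$gene, "lo")
  # unknown chromosome stays unassigned with a warning
  off <- peaks_gr(0, 100, chrom = "chrX"); off$enh_class <- "TE"; off$total_signal <- 1
  expect_warning(asg_off <- assign_genes(off, tss), "unassigned")
  expect_true(is.na(asg_off$regions$assigned_gene))
})

test_that("nearest-TSS assignment matches a brute-force scan on a random layout", {
  set.seed(13)
  tss <- data.frame(gene = sprintf("g%02d", 1:20), chrom = "chr1",
                    position = sort(sample.int(1e6, 20)), strand = "+")
  start <- sort(sample.int(1e6, 50))
  gr <- peaks_gr(start, start + 500)
  gr$enh_class <- sample(c("SE", "TE"), 50, replace = TRUE)
  gr$total_signal <- runif(50)
  asg <- assign_genes(gr, tss)
  mid <- (GenomicRanges::start(gr) + GenomicRanges::end(gr)) / 2
  for (i in seq_along(gr)) {
    d <- abs(tss$position - mid[i])
    nearest <- tss$gene[which(d == min(d))][1]
    g <- asg$regions$assigned_gene[i]
    if (!is.na(g)) expect_equal(g, nearest)
  }
})

test_that("quartile categorisation partitions regions 1:1:2 under distinct FCs", {
  set.seed(9)
  n <- 1000
  start <- seq(0, by = 1e4, length.out = n)
  gr <- peaks_gr(start, start + 500)
  gr$enh_class <- "SE"
  stim <- runif(n, 1, 100)
  unstim <- runif(n, 1, 100)
  r <- fold_change_and_categorize(gr, stim, unstim)
  expect_equal(as.integer(table(r$category)[c("gained", "lost", "unchanged")]),
               c(250L, 250L, 500L))
  # categories match the brute-force quantile rule
  l2fc <- log2((stim + 1) / (unstim + 1))
  q <- quantile(l2fc, c(0.25, 0.75))
  expect_identical(r$category == "gained", l2fc > q[2])
  expect_identical(r$category == "lost", l2fc < q[1])
  # all-equal fold-changes are all unchanged (strict inequalities)
  r_eq <- fold_change_and_categorize(gr, rep(2, n), rep(1, n))
  expect_true(all(r_eq$category == "unchanged"))
  # the three categories partition each class
  expect_equal(sum(table(r$category)), n)
})
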