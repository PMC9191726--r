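test_that("a fixed seed regenerates every input bit-identically", {
  cfg <- small_cfg(seed = 42)
  e1 <- simulate_expression(cfg); e2 <- simulate_expression(cfg)
  expect_identical(
    SummarizedExperiment::assay(e1$sce, "counts"),
    SummarizedExperiment::assay(e2$sce, "counts"))
  a1 <- simulate_atac(cfg); a2 <- simulate_atac(cfg)
  expect_identical(a1$counts$stim, a2$counts$stim)
  expect_identical(a1$truth$pairs, a2$truth$pairs)
  f1 <- simulate_foci(cfg, n_cells_per_dose = 50)
  f2 <- simulate_foci(cfg, n_cells_per_dose = 50)
  expect_identical(f1$table, f2$table)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(doses = c(0, 1, 0.5)), "strictly increasing")
  expect_error(sim_config(doses = c(0.1, 1, 10)), "first dose")
  expect_error(sim_config(n_genes = 0), "positive")
  expect_error(sim_config(frac_se_genes = 1.2), "0, 1")
  expect_error(sim_config(n_peaks = 50,
                          coaccess_factors = list(n_factors = 60,
                                                  loading_scale = 0.3,
                                                  stim_gain = 3)),
               "n_factors")
  expect_error(sim_config(foci = list(a = -1, k = 12)), "non-negative")
})

test_that("activation follows the Hill dose-response", {
  cfg <- sim_config(seed = 2, n_cells_per_dose = 400, n_genes = 20,
                    n_background_genes = 20)
  e <- simulate_expression(cfg)
  dose <- SummarizedExperiment::colData(e$sce)$dose
  act <- e$truth$activated
  # p(0) = 0 exactly for N > 0
  expect_identical(unname(act[dose == 0]), rep(FALSE, 400))
  # half-maximal point: dose = Km = 0.1
  frac_km <- mean(act[dose == 0.1])
  expect_lt(abs(frac_km - 0.5), 4 * sqrt(0.25 / 400))
  # expected activated fraction is non-decreasing in dose
  expect_true(all(diff(activation_probability(cfg, cfg$doses)) >= 0))
})

test_that("SE-like genes carry a larger planted Fano gain and fold-change than TE-like", {
  cfg <- sim_config(seed = 1, n_genes = 200)
  e <- simulate_expression(cfg)
  cts <- as.matrix(SummarizedExperiment::assay(e$sce, "counts"))
  dose <- SummarizedExperiment::colData(e$sce)$dose
  top <- max(dose)
  cls <- e$truth$gene_class
  # brute-force Fano ratio from the emitted raw matrix
  ratio <- vapply(names(cls), function(g)
    bf_fano(cts[g, dose == top]) / bf_fano(cts[g, dose == 0]), numeric(1))
  expect_gt(median(ratio[cls == "se_like"], na.rm = TRUE),
            median(ratio[cls == "te_like"], na.rm = TRUE))
  # mean fold-change (top vs 0) ordering
  fc <- rowMeans(cts[names(cls), dose == top]) /
    pmax(rowMeans(cts[names(cls), dose == 0]), 0.01)
  expect_gt(median(fc[cls == "se_like"]), median(fc[cls == "te_like"]))
})

test_that("metadata totals equal the matrix column sums", {
  e <- simulate_expression(small_cfg(seed = 3))
  cd <- SummarizedExperiment::colData(e$sce)
  cts <- SummarizedExperiment::assay(e$sce, "counts")
  expect_equal(unname(cd$total_count), unname(Matrix::colSums(cts)))
  expect_equal(unname(cd$n_detected_genes), unname(Matrix::colSums(cts > 0)))
})

test_that("stitching at 5 kb reconstructs the planted enhancer architectures", {
  a <- simulate_atac(small_cfg(seed = 4))
  pk <- a$peaks
  pk$signal <- 1
  reg <- stitch_peaks(pk, max_gap = 5000)
  ov <- GenomicRanges::findOverlaps(pk, reg)
  region_of <- S4Vectors::subjectHits(ov)[order(S4Vectors::queryHits(ov))]
  for (g in names(a$truth$enhancer_members)) {
    members <- match(a$truth$enhancer_members[[g]], pk$peak_id)
    expect_length(unique(region_of[members]), 1)
  }
})

test_that("stim_gain = 1 leaves planted pair correlations unchanged", {
  cfg <- small_cfg(seed = 5,
                   coaccess_factors = list(n_factors = 40,
                                           loading_scale = 0.6, stim_gain = 1),
                   n_cells_atac = 400)
  a <- simulate_atac(cfg)
  tp <- a$truth$pairs
  expect_false(any(tp$gained))
  d <- vapply(seq_len(nrow(tp)), function(r) {
    i <- tp$peak_i[r]; j <- tp$peak_j[r]
    cor(a$counts$stim[i, ], a$counts$stim[j, ]) -
      cor(a$counts$unstim[i, ], a$counts$unstim[j, ])
  }, numeric(1))
  expect_lt(mean(abs(d)), 0.1)
  expect_lt(abs(mean(d)), 0.05)
})

test_that("large loadings drive planted pair correlations toward 1", {
  cfg <- small_cfg(seed = 6,
                   coaccess_factors = list(n_factors = 40,
                                           loading_scale = 1.6, stim_gain = 1),
                   n_cells_atac = 400)
  a <- simulate_atac(cfg)
  tp <- a$truth$pairs
  r <- vapply(seq_len(nrow(tp)), function(i)
    cor(a$counts$stim[tp$peak_i[i], ], a$counts$stim[tp$peak_j[i], ]),
    numeric(1))
  expect_gt(median(r), 0.8)
})

test_that("brute-force correlation differences recover the gained-pair listing", {
  a <- simulate_atac(sim_config(seed = 7))
  tp <- a$truth$pairs
  d <- vapply(seq_len(nrow(tp)), function(r) {
    i <- tp$peak_i[r]; j <- tp$peak_j[r]
    cor(as.numeric(a$counts$stim[i, ]), as.numeric(a$counts$stim[j, ])) -
      cor(as.numeric(a$counts$unstim[i, ]), as.numeric(a$counts$unstim[j, ]))
  }, numeric(1))
  # every planted gained pair strengthens; stable pairs straddle zero
  expect_identical(which(tp$gained), which(tp$gained & d > 0))
  expect_lt(abs(mean(d[!tp$gained])), 0.1)
})

test_that("foci counts saturate at a + k and lose dose-dependence at k = 0", {
  cfg0 <- small_cfg(seed = 8, foci = list(a = 4, k = 0))
  f0 <- simulate_foci(cfg0, n_cells_per_dose = 300)
  med <- median_response(f0$table)
  expect_true(all(med$median_foci == median(rpois(1e5, 4)) |
                  abs(med$median_foci - 4) <= 1))
  expect_lt(diff(range(med$median_foci)), 2)

  cfg <- small_cfg(seed = 9)
  f <- simulate_foci(cfg, n_cells_per_dose = 2000)
  top <- f$table$foci[f$table$dose == max(cfg$foci_doses)]
  expect_lt(abs(mean(top) - (cfg$foci$a + cfg$foci$k)),
            4 * sd(top) / sqrt(length(top)))
})
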