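#' Run the full analysis pipeline on a simulated study
#'
#' Generates every input from one seeded configuration and runs all
#' stages: foci median dose-response and Hill fit, expression QC /
#' normalization / cell classification / differential expression /
#' fold-changes, Fano profiling and dynamics clustering, enhancer
#' stitching / SE calling / merging / gene assignment / gain-loss
#' categorization, gene-level Hill categorization, motif-density scan of
#' the simulated genome, and differential co-accessibility with per-gene
#' gained-pair counts and their correlation with expression statistics.
#' All result tables are written as CSV (plus a provenance JSON) under
#' `outdir`; identical config and seed give byte-identical outputs.
#'
#' QC thresholds are scaled to the simulated library depth (the deep
#' published cutoffs would empty a 200-gene matrix); all other thresholds
#' are the published defaults.
#'
#' @param cfg a [sim_config()].
#' @param outdir output directory (created).
#' @param qc list of QC thresholds for the simulated matrices.
#' @return invisibly, a list with the main in-memory results.
#' @export
run_pipeline <- function(cfg, outdir,
                         qc = list(min_total = 100, min_genes = 20,
                                   max_mito = 0.5)) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, f) data.table::fwrite(x, file.path(outdir, f))

  ## foci dose-response
  foci <- simulate_foci(cfg)
  med <- median_response(foci$table, time = 20)
  hf <- fit_hill(med$dose, med$median_foci, with_basal = TRUE)
  act_img <- activation_from_foci(simulate_foci(cfg, bimodal = TRUE)$table)
  w(med, "foci_medians.csv")
  w(data.frame(N = hf$N, Km = hf$Km, k = hf$k, a = hf$a, rss = hf$rss),
    "foci_hill_fit.csv")
  w(act_img, "foci_activation.csv")

  ## expression
  sim <- simulate_expression(cfg)
  sce <- qc_filter(sim$sce, qc$min_total, qc$min_genes, qc$max_mito)
  sce <- normalize_depth(sce)
  states <- classify_cells(sce)
  degs <- find_degs(sce, states)
  fc <- dose_fold_changes(sce)
  w(degs, "degs.csv")
  w(data.frame(cell = colnames(sce),
               dose = SummarizedExperiment::colData(sce)$dose,
               state = as.character(states)), "cell_states.csv")
  w(data.frame(gene = rownames(fc), fc, check.names = FALSE), "fold_changes.csv")

  ## heterogeneity
  deg_up <- degs$gene[degs$significant & degs$direction == "up"]
  prof <- fano_profiles(sce, genes = intersect(deg_up, rownames(sce)))
  fr <- fano_ratio(prof)
  cl <- tryCatch(cluster_fano_dynamics(prof, k = 4), error = function(e) NULL)
  w(data.frame(gene = rownames(prof$fano), prof$fano, check.names = FALSE),
    "fano_profiles.csv")
  w(data.frame(gene = names(fr), fano_ratio = unname(fr),
               cluster = if (is.null(cl)) NA else unname(cl[names(fr)])),
    "fano_ratios.csv")

  ## enhancer calling
  atac <- simulate_atac(cfg)
  calls <- lapply(c(stim = "signal_stim", unstim = "signal_unstim"), function(s) {
    pk <- atac$peaks
    pk$signal <- GenomicRanges::mcols(pk)[[s]]
    classify_se_te(stitch_peaks(pk, max_gap = 5000))
  })
  merged <- merge_conditions(calls)
  ms <- merged_region_signals(merged, atac$peaks)
  merged <- fold_change_and_categorize(merged, ms$stim, ms$unstim)
  merged$total_signal <- ms$stim + ms$unstim
  asg <- assign_genes(merged, atac$tss)
  merged <- asg$regions
  enh_tab <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(merged)),
    start = GenomicRanges::start(merged),
    end = GenomicRanges::end(merged) + 1,
    enh_class = merged$enh_class, log2_fc = merged$log2_fc,
    category = merged$category, assigned_gene = merged$assigned_gene)
  w(enh_tab, "enhancers.csv")

  ## gene-level Hill categorization
  ghill <- gene_hill_table(fc[intersect(rownames(fc), names(sim$truth$gene_class)), ])
  w(ghill, "gene_hill.csv")

  ## motif density over merged enhancers
  genome <- simulate_genome(cfg, atac$peaks)
  seqs <- extract_region_sequences(genome, merged)
  hits <- scan_motifs(seqs, builtin_motifs())
  hits$enh_class <- rep(merged$enh_class, each = length(unique(hits$family)))
  hits$category <- rep(merged$category, each = length(unique(hits$family)))
  w(hits, "motif_hits.csv")

  ## co-accessibility
  agg <- lapply(atac$counts, function(m) aggregate_cells(m, k = 10))
  sc_st <- coaccess_scores(agg$stim$counts, atac$peaks)
  sc_un <- coaccess_scores(agg$unstim$counts, atac$peaks)
  pairs <- differential_pairs(sc_st, sc_un)
  gcount <- gene_pair_counts(pairs, atac$peaks, atac$tss)
  top <- as.character(max(cfg$doses))
  stats_fc <- setNames(fc[, top], rownames(fc))
  r_fc <- tryCatch(correlate_counts(gcount, stats_fc), error = function(e) NA)
  r_fano <- tryCatch(correlate_counts(gcount, fr), error = function(e) NA)
  w(pairs, "coaccess_pairs.csv")
  w(data.frame(gene = names(gcount), gained_pairs = unname(gcount)),
    "gene_pair_counts.csv")
  w(data.frame(statistic = c("rna_fold_change", "fano_ratio"),
               spearman_r = c(r_fc, r_fano)), "coaccess_correlations.csv")

  write_provenance(outdir, cfg, cfg$seed)
  invisible(list(foci_fit = hf, states = states, degs = degs,
                 fano_ratio = fr, enhancers = merged, gene_hill = ghill,
                 pairs = pairs, gene_pair_counts = gcount,
                 correlations = c(rna_fold_change = r_fc, fano_ratio = r_fano)))
}

#' Per-condition signal of merged regions
#'
#' Sums the per-peak bulk signal of each condition over the peaks falling
#' in each merged region.
#'
#' @param merged merged `GRanges` (see [merge_conditions()]).
#' @param peaks the peak `GRanges` with `signal_stim` / `signal_unstim`.
#' @return list `stim`, `unstim` of per-region signals.
#' @export
merged_region_signals <- function(merged, peaks) {
  ov <- GenomicRanges::findOverlaps(merged, peaks)
  st <- un <- numeric(length(merged))
  agg <- tapply(peaks$signal_stim[S4Vectors::subjectHits(ov)],
                S4Vectors::queryHits(ov), sum)
  st[as.integer(names(agg))] <- agg
  agg <- tapply(peaks$signal_unstim[S4Vectors::subjectHits(ov)],
                S4Vectors::queryHits(ov), sum)
  un[as.integer(names(agg))] <- agg
  list(stim = st, unstim = un)
}

#' Extract region sequences from contigs
#'
#' @param genome named character vector or `DNAStringSet` of contigs.
#' @param regions a `GRanges` (0-based half-open internally).
#' @return named character vector of region sequences.
#' @export
extract_region_sequences <- function(genome, regions) {
  if (is(genome, "XStringSet")) genome <- as.character(genome)
  chrom <- as.character(GenomicRanges::seqnames(regions))
  out <- vapply(seq_along(regions), function(i) {
    contig <- genome[[chrom[i]]]
    substr(contig, GenomicRanges::start(regions)[i] + 1,
           min(nchar(contig), GenomicRanges::end(regions)[i] + 1))
  }, character(1))
  names(out) <- sprintf("region%04d", seq_along(regions))
  out
}
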