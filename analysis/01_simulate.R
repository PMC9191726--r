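#!/usr/bin/env Rscript
# Generate the synthetic study: dose-resolved single-cell expression,
# per-condition single-cell ATAC with planted co-accessibility, a foci
# imaging titration, and the planted ground truth. Writes standard-format
# inputs under results/data/ that the later stages re-read or re-derive.

library(sehet)

cfg <- sim_config(seed = 1)
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

expr <- simulate_expression(cfg)
write_mtx(SummarizedExperiment::assay(expr$sce, "counts"),
          file.path(out, "expression"))
write.csv(as.data.frame(SummarizedExperiment::colData(expr$sce)),
          file.path(out, "cell_metadata.csv"))

atac <- simulate_atac(cfg)
for (cond in names(atac$counts))
  write_mtx(atac$counts[[cond]], file.path(out, paste0("atac_", cond)))
# score column carries the normalized signal itself (the signals here are
# depth-normalized tag counts, not fractions of 1)
for (cond in c("stim", "unstim")) {
  bed <- GenomicRanges::granges(atac$peaks)
  bed$name <- atac$peaks$peak_id
  bed$score <- round(GenomicRanges::mcols(atac$peaks)[[paste0("signal_", cond)]], 3)
  write_bed(bed, file.path(out, paste0("peaks_", cond, ".bed")))
}
write.csv(atac$tss, file.path(out, "tss.csv"), row.names = FALSE)

foci <- simulate_foci(cfg)
write_foci(foci$table, file.path(out, "foci.csv"))

jsonlite::write_json(
  list(gene_class = as.list(expr$truth$gene_class),
       activation_probability = expr$truth$activation_probability,
       gained_pairs = atac$truth$pairs[atac$truth$pairs$gained, ]),
  file.path(out, "truth.json"), auto_unbox = TRUE, digits = NA)
write_provenance(out, cfg, cfg$seed)

message("simulated study written to ", out,
        ": ", ncol(expr$sce), " cells x ", nrow(expr$sce), " genes, ",
        length(atac$peaks), " ATAC peaks x ", ncol(atac$counts$stim),
        " cells/condition, ", nrow(foci$table), " imaged cells")
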