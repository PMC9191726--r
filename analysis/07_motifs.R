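#!/usr/bin/env Rscript
# Motif density over called enhancers: scan the (synthetic) genome
# sequence of every merged region for the NF-kB, PU.1 and TATA families,
# compare densities between SE and TE and across gain/loss categories
# with undersampled tests, and count TATA hits in promoter windows.

library(sehet)

cfg <- sim_config(seed = 1)
out <- "results"
enh <- read.csv(file.path(out, "enhancers.csv"))
tss <- read.csv(file.path(out, "data", "tss.csv"))
atac <- simulate_atac(cfg)
genome <- simulate_genome(cfg, atac$peaks)
names(genome) <- sort(unique(as.character(GenomicRanges::seqnames(atac$peaks))))

regions <- GenomicRanges::GRanges(enh$chrom,
                                  IRanges::IRanges(enh$start, enh$end - 1))
seqs <- extract_region_sequences(genome, regions)
motifs <- builtin_motifs()
hits <- scan_motifs(seqs, motifs)
n_fam <- length(unique(hits$family))
hits$enh_class <- rep(enh$enh_class, each = n_fam)
hits$category <- rep(enh$category, each = n_fam)
write.csv(hits, file.path(out, "motif_hits.csv"), row.names = FALSE)

# the simulated genome plants no motifs, so these densities are the
# background hit rate of the scanner: the SE/TE comparison should be null
for (fam in c("NFkB", "PU1")) {
  sub <- hits[hits$family == fam, ]
  cmp <- density_compare(sub$density, sub$enh_class, seed = 1)
  message(sprintf(
    "%s density per 10^4 bp (background, no planted motifs): SE median %.2f, TE median %.2f (p = %.2g)",
    fam, cmp$medians["SE"], cmp$medians["TE"], cmp$p))
}

tata <- promoter_tata(genome, tss)
write.csv(tata, file.path(out, "promoter_tata.csv"), row.names = FALSE)
message(sprintf("TATA hits in promoter windows: mean %.2f per gene",
                mean(tata$count)))
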