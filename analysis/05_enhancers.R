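#!/usr/bin/env Rscript
# Enhancer calling: stitch ATAC peaks within 5 kb per condition, rank and
# split super- from typical enhancers at the slope-1 cutoff, merge the
# calls across conditions, categorise accessibility gain/loss by class
# quartiles, and assign each region to its nearest TSS (SE beats TE).

library(sehet)

out <- "results"
peaks_stim <- read_bed(file.path(out, "data", "peaks_stim.bed"))
peaks_unstim <- read_bed(file.path(out, "data", "peaks_unstim.bed"))
tss <- read.csv(file.path(out, "data", "tss.csv"))

calls <- lapply(list(stim = peaks_stim, unstim = peaks_unstim), function(pk) {
  pk$signal <- pk$score                 # score carries the signal
  classify_se_te(stitch_peaks(pk, max_gap = 5000))
})
merged <- merge_conditions(calls)

sig <- function(pk) {
  ov <- GenomicRanges::findOverlaps(merged, pk)
  out <- numeric(length(merged))
  s <- tapply(pk$score[S4Vectors::subjectHits(ov)],
              S4Vectors::queryHits(ov), sum)
  out[as.integer(names(s))] <- s
  out
}
s_st <- sig(peaks_stim); s_un <- sig(peaks_unstim)
merged <- fold_change_and_categorize(merged, s_st, s_un)
merged$total_signal <- s_st + s_un
merged <- assign_genes(merged, tss)$regions

write.csv(data.frame(
  chrom = as.character(GenomicRanges::seqnames(merged)),
  start = GenomicRanges::start(merged),
  end = GenomicRanges::end(merged) + 1,
  enh_class = merged$enh_class, log2_fc = round(merged$log2_fc, 4),
  category = merged$category, assigned_gene = merged$assigned_gene),
  file.path(out, "enhancers.csv"), row.names = FALSE)

tab <- table(merged$enh_class, merged$category)
message("merged enhancer regions by class and category:")
print(tab)
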