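#!/usr/bin/env Rscript
# Transcriptional heterogeneity: per-gene per-dose Fano factors of the
# up-regulated DEGs, top-vs-zero-dose ratios, Ward clustering of the
# heterogeneity dynamics, and an undersampled comparison of SE-like
# versus TE-like genes.

library(sehet)

cfg <- sim_config(seed = 1)
out <- "results"

expr <- simulate_expression(cfg)
sce <- normalize_depth(qc_filter(expr$sce, 100, 20, 0.5))
degs <- read.csv(file.path(out, "degs.csv"))
up <- degs$gene[degs$significant & degs$direction == "up"]

prof <- fano_profiles(sce, genes = intersect(up, rownames(sce)))
fr <- fano_ratio(prof)
cvr <- fano_ratio(prof, what = "cv")
cl <- cluster_fano_dynamics(prof, k = 4)

write.csv(data.frame(gene = rownames(prof$fano), prof$fano,
                     check.names = FALSE),
          file.path(out, "fano_profiles.csv"), row.names = FALSE)
write.csv(data.frame(gene = names(fr), fano_ratio = unname(fr),
                     cv_ratio = unname(cvr),
                     cluster = unname(cl[names(fr)])),
          file.path(out, "fano_ratios.csv"), row.names = FALSE)

cls <- expr$truth$gene_class
se <- fr[intersect(names(fr), names(cls)[cls == "se_like"])]
te <- fr[intersect(names(fr), names(cls)[cls == "te_like"])]
cmp <- compare_groups_undersampled(list(se = se[is.finite(se)],
                                        te = te[is.finite(te)]),
                                   test = "welch", seed = 1)
message(sprintf(
  "Fano ratio (top vs 0): SE-like median %.2f, TE-like median %.2f (undersampled Welch p = %.2g, n = %d/group); Spearman(Fano ratio, CV ratio) = %.2f",
  median(se, na.rm = TRUE), median(te, na.rm = TRUE), cmp$p, cmp$n_per_group,
  cor(fr, cvr, method = "spearman", use = "complete.obs")))
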