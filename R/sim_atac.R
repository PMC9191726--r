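#' Simulate single-cell ATAC fragment counts with planted co-accessibility
#'
#' Peaks are organised into per-gene architectures: one promoter peak at the
#' TSS and an enhancer cluster 8-30 kb away whose internal gaps are below
#' 5 kb (so stitching at the 5 kb rule reconstructs the planted enhancer)
#' while distinct architectures are separated by much more than 5 kb.
#' SE-like genes get larger, stronger clusters. Per-peak bulk signal is
#' drawn per condition with a per-gene gained / lost / unchanged
#' accessibility category. Fragment counts are Poisson emissions of latent
#' factors: each factor links two member peaks of one gene; factors of
#' "gained" promoter-enhancer pairs have their loadings multiplied by
#' `stim_gain` in the stimulated condition only, which is the planted
#' ground truth the differential co-accessibility stage should recover.
#'
#' @param cfg a [sim_config()].
#' @return list of class `sim_atac`:
#'   \describe{
#'     \item{peaks}{`GRanges` with `peak_id`, `gene`, `role`
#'       (promoter/enhancer), `signal_stim`, `signal_unstim`.}
#'     \item{counts}{list of peaks x cells sparse count matrices
#'       (`stim`, `unstim`).}
#'     \item{tss}{data.frame `gene`, `chrom`, `position`, `strand`.}
#'     \item{truth}{planted pairs (`peak_i`, `peak_j`, `gene`, `gained`),
#'       enhancer membership, per-gene accessibility category and class.}
#'   }
#' @export
simulate_atac <- function(cfg) {
  validate_sim_config(cfg)
  cf <- cfg$coaccess_factors
  set.seed(child_seed(cfg$seed, "atac_layout"))
  cls <- gene_classes(cfg)

  ## ---- layout -------------------------------------------------------
  cursor <- rep(10000, cfg$n_chromosomes)
  peaks <- list(); tss <- list(); members <- list()
  gene_cat <- character(); gene_used <- character()
  n_assigned <- 0L
  for (g in names(cls)) {
    n_enh <- if (cls[g] == "se_like") sample(4:6, 1) else sample(1:2, 1)
    if (n_assigned + n_enh + 1 > cfg$n_peaks) break
    chr <- ((length(gene_used)) %% cfg$n_chromosomes) + 1L
    strand <- if (length(gene_used) %% 2 == 0) "+" else "-"
    t_pos <- cursor[chr] + 3000
    p_list <- data.frame(chrom = paste0("chr", chr),
                         start = t_pos - 200, end = t_pos + 300,
                         gene = g, role = "promoter")
    pos <- t_pos + round(runif(1, 8000, 30000))
    for (i in seq_len(n_enh)) {
      w <- round(runif(1, 300, 800))
      p_list <- rbind(p_list, data.frame(chrom = paste0("chr", chr),
                                         start = pos, end = pos + w,
                                         gene = g, role = "enhancer"))
      pos <- pos + w + round(runif(1, 500, 3000))
    }
    cursor[chr] <- pos + 20000 + round(runif(1, 30000, 80000))
    peaks[[g]] <- p_list
    tss[[g]] <- data.frame(gene = g, chrom = paste0("chr", chr),
                           position = t_pos, strand = strand)
    gene_used <- c(gene_used, g)
    n_assigned <- n_assigned + nrow(p_list)
    # accessibility category of the architecture
    pr <- if (cls[g] == "se_like") c(.5, .2, .3) else c(.2, .2, .6)
    gene_cat[g] <- sample(c("gained", "lost", "unchanged"), 1, prob = pr)
  }
  pk <- do.call(rbind, peaks)
  pk$peak_id <- sprintf("peak%03d", seq_len(nrow(pk)))
  rownames(pk) <- pk$peak_id

  ## ---- bulk signal per condition -----------------------------------
  base <- rlnorm(nrow(pk), log(5), 0.4)
  base[pk$role == "enhancer" & cls[pk$gene] == "se_like"] <-
    base[pk$role == "enhancer" & cls[pk$gene] == "se_like"] * 6
  cond_fc <- c(gained = 2, lost = 0.5, unchanged = 1)[gene_cat[pk$gene]]
  noise <- function(n) rlnorm(n, 0, 0.15)
  sig_un <- base * noise(nrow(pk))
  sig_st <- base * cond_fc * noise(nrow(pk))

  ## ---- latent factors ----------------------------------------------
  # one factor per peak group: SE-like genes get a gained hub factor over
  # the promoter and first three enhancers (a clique of co-accessible
  # pairs, emulating a forming contact hub) plus a stable enhancer pair;
  # TE-like genes a single promoter-enhancer factor, gained for a subset.
  # Each peak loads on at most one factor, keeping the log-normal
  # emission tails well-behaved.
  fac <- list()
  for (g in gene_used) {
    idx <- which(pk$gene == g)
    prom <- idx[pk$role[idx] == "promoter"]
    enh <- idx[pk$role[idx] == "enhancer"]
    if (cls[g] == "se_like") {
      fac[[length(fac) + 1]] <- list(members = c(prom, head(enh, 3)),
                                     gene = g, gained = TRUE)
      if (length(enh) >= 5)
        fac[[length(fac) + 1]] <- list(members = enh[4:5], gene = g,
                                       gained = FALSE)
    } else {
      fac[[length(fac) + 1]] <- list(members = c(prom, enh[1]), gene = g,
                                     gained = rbinom(1, 1, 0.35) == 1)
    }
    if (length(fac) >= cf$n_factors) break
  }
  fac <- head(fac, cf$n_factors)
  pairs <- do.call(rbind, lapply(fac, function(f) {
    cmb <- t(combn(sort(f$members), 2))
    data.frame(peak_i = cmb[, 1], peak_j = cmb[, 2], gene = f$gene,
               gained = f$gained && cf$stim_gain != 1)
  }))

  ## ---- count emission ----------------------------------------------
  set.seed(child_seed(cfg$seed, "atac_counts"))
  emit <- function(stim) {
    n_cells <- cfg$n_cells_atac
    L <- matrix(0, nrow(pk), length(fac))
    for (f in seq_along(fac)) {
      lo <- cf$loading_scale * if (stim && fac[[f]]$gained) cf$stim_gain else 1
      L[fac[[f]]$members, f] <- lo
    }
    Z <- matrix(rnorm(n_cells * length(fac)), n_cells, length(fac))
    eta <- tcrossprod(L, Z)                       # peaks x cells
    lam <- 1.5 * exp(eta - 0.5 * rowSums(L^2))    # mean-preserving log-normal
    m <- matrix(rpois(length(lam), lam), nrow(pk), n_cells,
                dimnames = list(pk$peak_id,
                                sprintf("%s%04d", if (stim) "stim" else "ctrl",
                                        seq_len(n_cells))))
    Matrix::Matrix(m, sparse = TRUE)
  }
  counts <- list(unstim = emit(FALSE), stim = emit(TRUE))

  gr <- GenomicRanges::GRanges(
    pk$chrom, IRanges::IRanges(pk$start, pk$end - 1L),
    peak_id = pk$peak_id, gene = pk$gene, role = pk$role,
    signal_stim = sig_st, signal_unstim = sig_un)
  names(gr) <- pk$peak_id

  truth <- list(
    pairs = pairs,
    enhancer_members = split(pk$peak_id[pk$role == "enhancer"],
                             pk$gene[pk$role == "enhancer"]),
    gene_category = gene_cat,
    gene_class = cls[gene_used])

  structure(list(peaks = gr, counts = counts,
                 tss = do.call(rbind, tss), truth = truth),
            class = "sim_atac")
}

#' Simulate random genome sequences covering a peak set
#'
#' Uniform-random ACGT contigs long enough to contain every peak (plus a
#' margin), for exercising the motif-scanning stage. No motifs are planted.
#'
#' @param cfg a [sim_config()] (supplies the seed).
#' @param peaks a `GRanges`; contig lengths are taken from its maxima.
#' @param margin extra bases beyond the last peak.
#' @return a [Biostrings::DNAStringSet], one sequence per chromosome.
#' @export
simulate_genome <- function(cfg, peaks, margin = 1000) {
  set.seed(child_seed(cfg$seed, "genome"))
  ends <- tapply(GenomicRanges::end(peaks),
                 as.character(GenomicRanges::seqnames(peaks)), max)
  seqs <- vapply(ends + margin, function(len)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
  Biostrings::DNAStringSet(seqs)
}
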