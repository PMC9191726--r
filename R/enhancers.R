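#' Stitch peaks into enhancer regions
#'
#' Peaks whose gap (next start minus previous end, half-open coordinates)
#' is at most `max_gap` are merged per chromosome; the stitched region's
#' signal is the sum of its members' signals. The output covers exactly
#' the union of the input bases.
#'
#' @param peaks a `GRanges` with a numeric `signal` metadata column (a
#'   `peak_id` column is carried through if present).
#' @param max_gap maximum gap in bp (default 5000, the ATAC stitching rule).
#' @return a `GRanges` of stitched regions with `total_signal`, `n_peaks`
#'   and a `members` CharacterList/IntegerList of member peaks.
#' @export
stitch_peaks <- function(peaks, max_gap = 5000) {
  if (any(GenomicRanges::width(peaks) < 1))
    stop("malformed interval at line ",
         which(GenomicRanges::width(peaks) < 1)[1])
  if (is.null(peaks$signal)) stop("peaks must carry a 'signal' column")
  reg <- GenomicRanges::reduce(peaks, min.gapwidth = max_gap + 1L,
                               with.revmap = TRUE)
  rm_ <- reg$revmap
  reg$total_signal <- vapply(rm_, function(i) sum(peaks$signal[i]), numeric(1))
  reg$n_peaks <- lengths(rm_)
  if (!is.null(peaks$peak_id))
    reg$members <- S4Vectors::endoapply(rm_, function(i) i) # indices into input
  reg
}

#' Classify stitched regions into super- and typical enhancers
#'
#' The ROSE rank-signal geometry: regions are sorted by total signal
#' ascending and rank and signal are rescaled to \[0, 1\], giving a convex
#' curve that sags below the diagonal. The cutoff is the point where the
#' tangent of the curve has slope 1, found as the point maximising
#' (scaled rank - scaled signal), i.e. the deepest point below the
#' diagonal; ties are resolved toward the high-signal end. Regions
#' strictly above the cutoff point are super-enhancers, so SE ranks
#' always form a suffix of the signal-sorted order (a linear ramp, which
#' never dips below the diagonal, yields no SEs). If all signals are
#' equal every region is a typical enhancer (with a warning). Invariant
#' to uniform scaling of the signals.
#'
#' @param regions a `GRanges` with `total_signal` (from [stitch_peaks()]).
#' @return the input with `rank` (1 = weakest) and `enh_class`
#'   (`"SE"`/`"TE"`) columns; the cutoff rank is in attribute `se_cutoff`.
#' @export
classify_se_te <- function(regions) {
  n <- length(regions)
  if (n < 3) stop("need at least 3 regions to classify")
  s <- regions$total_signal
  ord <- order(s, GenomicRanges::start(regions)) # stable for equal signals
  s_sorted <- s[ord]
  if (diff(range(s_sorted)) == 0) {
    warning("all signals equal; classifying every region TE")
    regions$rank <- order(ord)
    regions$enh_class <- "TE"
    return(regions)
  }
  x <- (seq_len(n) - 1) / (n - 1)
  y <- (s_sorted - s_sorted[1]) / (s_sorted[n] - s_sorted[1])
  score <- x - y                       # depth below the diagonal
  cutoff <- max(which(score == max(score)))
  cls_sorted <- rep("TE", n)
  cls_sorted[seq_len(n) > cutoff] <- "SE"
  rank <- integer(n); rank[ord] <- seq_len(n)
  regions$rank <- rank
  regions$enh_class <- cls_sorted[rank]
  attr(regions, "se_cutoff") <- cutoff
  regions
}

#' Merge enhancer regions across conditions
#'
#' Coordinate union (overlapping or bookended intervals merge) computed
#' separately for the SE and TE sets of each condition; the source
#' condition(s) of every merged region are retained.
#'
#' @param regions_by_condition named list of `GRanges`, each with
#'   `enh_class` (from [classify_se_te()]).
#' @return a `GRanges` of merged regions with `enh_class` and `conditions`.
#' @export
merge_conditions <- function(regions_by_condition) {
  stopifnot(length(regions_by_condition) >= 1,
            !is.null(names(regions_by_condition)))
  out <- list()
  for (cl in c("SE", "TE")) {
    pieces <- lapply(names(regions_by_condition), function(cond) {
      r <- regions_by_condition[[cond]]
      r <- r[r$enh_class == cl]
      if (length(r)) {
        GenomicRanges::mcols(r) <- NULL
        r$condition <- cond
      }
      r
    })
    pooled <- suppressWarnings(do.call(c, pieces))
    if (length(pooled) == 0) next
    merged <- GenomicRanges::reduce(pooled, with.revmap = TRUE)
    merged$enh_class <- cl
    merged$conditions <- S4Vectors::endoapply(
      merged$revmap, function(i) unique(match(pooled$condition[i],
                                              names(regions_by_condition))))
    merged$revmap <- NULL
    out[[cl]] <- merged
  }
  suppressWarnings(do.call(c, unname(out)))
}

#' Assign enhancer regions to genes by nearest TSS
#'
#' Each region is assigned the TSS nearest to its midpoint (equidistant
#' TSSs: the lower coordinate wins). Each gene then keeps exactly one
#' enhancer: SE beats TE, and within a class the highest total signal wins
#' (ties: lower start coordinate). Regions on chromosomes absent from the
#' TSS table stay unassigned, with a warning.
#'
#' @param regions a `GRanges` with `enh_class` and `total_signal`.
#' @param tss data.frame `gene`, `chrom`, `position`, `strand`.
#' @return list: `regions` (input plus `assigned_gene`, `NA` where the
#'   gene kept another enhancer or no TSS exists) and `gene_table`
#'   (one row per gene with its kept region index and class).
#' @export
assign_genes <- function(regions, tss) {
  stopifnot(all(c("gene", "chrom", "position") %in% names(tss)))
  chroms <- as.character(GenomicRanges::seqnames(regions))
  mid <- (GenomicRanges::start(regions) + GenomicRanges::end(regions)) / 2
  nearest_gene <- rep(NA_character_, length(regions))
  for (i in seq_along(regions)) {
    cand <- tss[tss$chrom == chroms[i], ]
    if (nrow(cand) == 0) next
    d <- abs(cand$position - mid[i])
    best <- which(d == min(d))
    if (length(best) > 1) best <- best[which.min(cand$position[best])]
    nearest_gene[i] <- cand$gene[best]
  }
  if (anyNA(nearest_gene) && any(!chroms %in% tss$chrom))
    warning("region(s) on chromosomes absent from the TSS table left unassigned")
  # one enhancer per gene: SE > TE, then signal, then lower start
  keep <- rep(FALSE, length(regions))
  for (g in unique(nearest_gene[!is.na(nearest_gene)])) {
    idx <- which(nearest_gene == g)
    pri <- order(regions$enh_class[idx] != "SE",      # SE first
                 -regions$total_signal[idx],
                 GenomicRanges::start(regions)[idx])
    keep[idx[pri[1]]] <- TRUE
  }
  assigned <- ifelse(keep, nearest_gene, NA_character_)
  regions$assigned_gene <- assigned
  gene_table <- data.frame(
    gene = assigned[keep],
    region = which(keep),
    enh_class = regions$enh_class[keep],
    total_signal = regions$total_signal[keep], row.names = NULL)
  list(regions = regions, gene_table = gene_table)
}

#' Accessibility fold-change and gained/lost/unchanged categories
#'
#' `log2((signal_stim + c) / (signal_unstim + c))` per merged region; then,
#' separately within each enhancer class, regions strictly above the upper
#' quartile of the fold-change are `gained` and strictly below the lower
#' quartile `lost`; the rest are `unchanged`. With all fold-changes equal
#' everything is unchanged (strict inequalities).
#'
#' @param regions a `GRanges` with `enh_class`.
#' @param signal_stim,signal_unstim per-region signals (same order).
#' @param pseudocount additive constant `c` (default 1 normalized unit).
#' @param probs lower/upper quantiles (default quartiles).
#' @return the regions with `log2_fc` and `category` columns.
#' @export
fold_change_and_categorize <- function(regions, signal_stim, signal_unstim,
                                       pseudocount = 1, probs = c(0.25, 0.75)) {
  stopifnot(length(signal_stim) == length(regions),
            length(signal_unstim) == length(regions))
  l2fc <- log2((signal_stim + pseudocount) / (signal_unstim + pseudocount))
  category <- rep("unchanged", length(regions))
  for (cl in unique(regions$enh_class)) {
    idx <- which(regions$enh_class == cl)
    if (length(idx) == 0) { warning("empty class ", cl, " skipped"); next }
    q <- quantile(l2fc[idx], probs)
    category[idx[l2fc[idx] > q[2]]] <- "gained"
    category[idx[l2fc[idx] < q[1]]] <- "lost"
  }
  regions$log2_fc <- l2fc
  regions$category <- category
  regions
}
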