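#' Quality-control filter on cells
#'
#' Retains exactly the cells meeting all three criteria: total count at
#' least `min_total`, detected genes at least `min_genes`, and
#' mitochondrial count ratio strictly below `max_mito` (the >=, >=, <
#' semantics of the published thresholds). Defaults are the deep
#' full-length single-cell RNA-seq cutoffs (1.5 million counts, 8500
#' genes, 4% mitochondrial); pass scaled values for small simulated
#' matrices. Idempotent.
#'
#' @param sce a `SingleCellExperiment` with colData `total_count`,
#'   `n_detected_genes`, `mito_ratio`.
#' @param min_total,min_genes,max_mito thresholds.
#' @return the filtered `SingleCellExperiment`.
#' @export
qc_filter <- function(sce, min_total = 1.5e6, min_genes = 8500, max_mito = 0.04) {
  cd <- SummarizedExperiment::colData(sce)
  stopifnot(all(c("total_count", "n_detected_genes", "mito_ratio") %in% names(cd)))
  keep <- cd$total_count >= min_total & cd$n_detected_genes >= min_genes &
    cd$mito_ratio < max_mito
  if (!any(keep)) stop("no cells survive QC filtering")
  sce[, keep]
}

#' Depth normalization
#'
#' Scales each cell's counts to the median sequencing depth and stores the
#' result as assay `scaled` (linear scale: used for fold-changes and Fano
#' factors) together with its `log1p` transform as assay `lognorm` (used
#' for classification and rank tests).
#'
#' @param sce a `SingleCellExperiment` with assay `counts`.
#' @return the `SingleCellExperiment` with assays `scaled` and `lognorm`
#'   added.
#' @export
normalize_depth <- function(sce) {
  cts <- SummarizedExperiment::assay(sce, "counts")
  depth <- Matrix::colSums(cts)
  if (any(depth == 0)) stop("zero-depth cell(s): ",
                            paste(head(colnames(sce)[depth == 0]), collapse = ", "))
  sf <- median(depth) / depth
  scaled <- cts %*% Matrix::Diagonal(x = sf)
  dimnames(scaled) <- dimnames(cts)
  SummarizedExperiment::assay(sce, "scaled") <- scaled
  SummarizedExperiment::assay(sce, "lognorm") <- log1p(scaled)
  sce
}

#' Classify cells as activated or inactivated from marker expression
#'
#' A two-component Gaussian mixture is fitted to the mean log-normalized
#' expression of the marker genes; the component with the higher mean is
#' the activated state. Degenerate inputs (a single cell, or all cells
#' identical) yield all-inactivated with a warning.
#'
#' @param sce a normalized `SingleCellExperiment` (see [normalize_depth()]).
#' @param markers character vector of marker gene ids; defaults to the
#'   rowData `is_marker` flag.
#' @return factor of per-cell states, levels `c("inactivated", "activated")`.
#' @export
classify_cells <- function(sce, markers = NULL) {
  if (is.null(markers))
    markers <- rownames(sce)[SummarizedExperiment::rowData(sce)$is_marker]
  markers <- intersect(markers, rownames(sce))
  if (length(markers) < 1) stop("no marker genes present in the matrix")
  x <- Matrix::colMeans(SummarizedExperiment::assay(sce, "lognorm")[markers, , drop = FALSE])
  lv <- c("inactivated", "activated")
  if (length(x) < 2 || sd(x) == 0) {
    warning("degenerate marker expression; classifying all cells inactivated")
    return(factor(rep("inactivated", length(x)), levels = lv))
  }
  fit <- Mclust(x, G = 2, modelNames = c("E", "V"), verbose = FALSE)
  if (is.null(fit)) {
    warning("mixture fit failed; classifying all cells inactivated")
    return(factor(rep("inactivated", length(x)), levels = lv))
  }
  act_comp <- which.max(fit$parameters$mean)
  factor(ifelse(fit$classification == act_comp, "activated", "inactivated"),
         levels = lv)
}

#' Differentially expressed genes between activated and inactivated cells
#'
#' Per-gene Wilcoxon rank-sum test on log-normalized expression with
#' Benjamini-Hochberg adjustment; genes with adjusted p below `alpha` and
#' absolute log2 fold-change of at least `min_log2fc` are flagged
#' significant (the adjusted-p cut is deliberately lenient to keep
#' heterogeneous genes; the fold-change floor is the usual
#' marker-detection convention and suppresses depth-composition
#' artifacts). The log2 fold-change compares state means of linear
#' depth-scaled expression with a pseudocount of 1.
#'
#' @param sce a normalized `SingleCellExperiment`.
#' @param states per-cell factor from [classify_cells()].
#' @param alpha adjusted-p cutoff for the `significant` flag.
#' @param min_log2fc absolute log2 fold-change floor for the flag.
#' @return data.frame `gene`, `log2_fc`, `p`, `p_adj`, `direction`,
#'   `significant`, ordered as the matrix rows.
#' @export
find_degs <- function(sce, states, alpha = 0.05, min_log2fc = 0.25) {
  stopifnot(length(states) == ncol(sce))
  states <- factor(states, levels = c("inactivated", "activated"))
  if (any(table(states) < 3)) stop("each state needs at least 3 cells")
  ln <- as.matrix(SummarizedExperiment::assay(sce, "lognorm"))
  sc <- as.matrix(SummarizedExperiment::assay(sce, "scaled"))
  act <- states == "activated"
  p <- vapply(seq_len(nrow(ln)), function(i) {
    x <- ln[i, act]; y <- ln[i, !act]
    if (all(x == x[1]) && all(y == y[1]) && x[1] == y[1]) return(1)
    suppressWarnings(wilcox.test(x, y)$p.value)
  }, numeric(1))
  p[is.na(p)] <- 1
  p_adj <- p.adjust(p, method = "BH")
  l2fc <- log2((rowMeans(sc[, act, drop = FALSE]) + 1) /
               (rowMeans(sc[, !act, drop = FALSE]) + 1))
  data.frame(gene = rownames(sce), log2_fc = l2fc, p = p, p_adj = p_adj,
             direction = ifelse(l2fc >= 0, "up", "down"),
             significant = p_adj < alpha & abs(l2fc) >= min_log2fc,
             row.names = NULL)
}

#' Per-gene fold-change of mean expression versus dose 0
#'
#' Mean linear depth-scaled expression per dose divided by the mean at dose
#' 0, with a pseudocount of 1 applied to both means. A gene constant across
#' doses has fold-change 1 everywhere.
#'
#' @param sce a normalized `SingleCellExperiment` with colData `dose`.
#' @param assay_name assay averaged (default the linear `scaled` values).
#' @return matrix genes x doses of fold-changes (dose-0 column included,
#'   identically 1).
#' @export
dose_fold_changes <- function(sce, assay_name = "scaled") {
  dose <- SummarizedExperiment::colData(sce)$dose
  if (!any(dose == 0)) stop("dose 0 group missing")
  doses <- sort(unique(dose))
  m <- SummarizedExperiment::assay(sce, assay_name)
  means <- vapply(doses, function(d) Matrix::rowMeans(m[, dose == d, drop = FALSE]),
                  numeric(nrow(m)))
  fc <- (means + 1) / (means[, 1] + 1)
  dimnames(fc) <- list(rownames(sce), as.character(doses))
  fc
}
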