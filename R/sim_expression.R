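#' Simulate a dose-resolved single-cell expression experiment
#'
#' Cells at each dose are activated with the Hill probability
#' `dose^N / (Km^N + dose^N)`; gene counts are negative-binomial with
#' gene-class- and state-dependent mean and dispersion. SE-like genes are
#' almost silent when inactive and burst widely when active (low NB size),
#' so their planted Fano-factor gain between the top dose and dose 0
#' exceeds the TE-like genes'. Per-gene active-state means and dispersions
#' are log-normally jittered around the class values, giving genes of
#' similar induction a range of heterogeneity as in real data. The matrix
#' additionally carries a block of unresponsive background genes (so that
#' library depth is not dominated by the responders, as in a real
#' transcriptome), three dedicated strongly-and-reliably induced marker
#' genes (NF-kB-target-like) used for cell-state classification, and a few
#' mitochondrial-like genes for QC.
#'
#' @param cfg a [sim_config()].
#' @return list of class `sim_expression` with elements
#'   \describe{
#'     \item{sce}{a [SingleCellExperiment::SingleCellExperiment] with assay
#'       `counts`, colData `dose`, `total_count`, `n_detected_genes`,
#'       `mito_ratio` and rowData `gene_id`, `class`, `is_marker`, `is_mito`.}
#'     \item{truth}{planted ground truth: per-cell activation state,
#'       per-gene class and generating parameters, activation
#'       probabilities, and exact per-dose Fano factors of each gene's
#'       generating mixture (raw-count scale).}
#'   }
#' @export
simulate_expression <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(child_seed(cfg$seed, "expression"))
  cls <- gene_classes(cfg)
  genes <- names(cls)

  # per-gene generating parameters: class values with log-normal jitter
  jit <- cfg$burst_jitter
  gp <- data.frame(
    gene = genes, class = unname(cls),
    mean_off = NA_real_, mean_on = NA_real_, dispersion = NA_real_)
  for (cl in c("se_like", "te_like")) {
    bp <- cfg$burst_params[[cl]]
    idx <- which(gp$class == cl)
    gp$mean_off[idx] <- bp$mean_off
    gp$mean_on[idx] <- bp$mean_on * rlnorm(length(idx), 0, jit$mean_on_sd)
    gp$dispersion[idx] <- bp$dispersion * rlnorm(length(idx), 0, jit$dispersion_sd)
  }

  markers <- c("marker_NFKBIA", "marker_CD83", "marker_TNFAIP3")
  mp <- cfg$marker_params
  bg <- if (cfg$n_background_genes > 0)
    sprintf("bg%03d", seq_len(cfg$n_background_genes)) else character()
  mito <- if (cfg$n_mito_genes > 0)
    sprintf("MT-%02d", seq_len(cfg$n_mito_genes)) else character()
  all_genes <- c(genes, markers, bg, mito)

  dose <- rep(cfg$doses, each = cfg$n_cells_per_dose)
  n_cells <- length(dose)
  cells <- sprintf("cell%04d", seq_len(n_cells))
  p_act <- activation_probability(cfg, dose)
  activated <- rbinom(n_cells, 1, p_act) == 1

  counts <- matrix(0L, nrow = length(all_genes), ncol = n_cells,
                   dimnames = list(all_genes, cells))
  for (g in seq_along(genes)) {
    mu <- ifelse(activated, gp$mean_on[g], gp$mean_off[g])
    counts[g, ] <- rnbinom(n_cells, mu = mu, size = gp$dispersion[g])
  }
  for (m in markers) {
    mu <- ifelse(activated, mp$mean_on, mp$mean_off)
    counts[m, ] <- rnbinom(n_cells, mu = mu, size = mp$dispersion)
  }
  for (b in bg)
    counts[b, ] <- rnbinom(n_cells, mu = 30, size = 10)
  for (m in mito)
    counts[m, ] <- rnbinom(n_cells, mu = 2, size = 10)

  total <- colSums(counts)
  col_dat <- S4Vectors::DataFrame(
    dose = dose,
    total_count = total,
    n_detected_genes = colSums(counts > 0),
    mito_ratio = if (length(mito)) colSums(counts[mito, , drop = FALSE]) / pmax(total, 1) else 0,
    row.names = cells)
  row_dat <- S4Vectors::DataFrame(
    gene_id = all_genes,
    class = c(unname(cls), rep("marker", length(markers)),
              rep("background", length(bg)), rep("mito", length(mito))),
    is_marker = all_genes %in% markers,
    is_mito = all_genes %in% mito,
    row.names = all_genes)

  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = Matrix::Matrix(counts, sparse = TRUE)),
    colData = col_dat, rowData = row_dat)

  truth <- list(
    activated = setNames(activated, cells),
    activation_probability = setNames(activation_probability(cfg, cfg$doses),
                                      as.character(cfg$doses)),
    gene_class = cls,
    gene_params = gp,
    markers = markers,
    true_fano = planted_fano(cfg, gp),
    activation_hill = cfg$activation_hill)

  structure(list(sce = sce, truth = truth), class = "sim_expression")
}

# exact Fano factor of each gene's generating two-state NB mixture, per
# dose (raw-count scale): genes x doses matrix
planted_fano <- function(cfg, gene_params) {
  p <- activation_probability(cfg, cfg$doses)
  m <- t(vapply(seq_len(nrow(gene_params)), function(g) {
    m0 <- gene_params$mean_off[g]; m1 <- gene_params$mean_on[g]
    th <- gene_params$dispersion[g]
    mu <- (1 - p) * m0 + p * m1
    v <- (1 - p) * (m0 + m0^2 / th) + p * (m1 + m1^2 / th) +
      p * (1 - p) * (m1 - m0)^2
    ifelse(mu > 0, v / mu, NA_real_)
  }, numeric(length(p))))
  dimnames(m) <- list(gene_params$gene, as.character(cfg$doses))
  m
}
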