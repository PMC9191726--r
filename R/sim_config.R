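#' Configuration of the synthetic study
#'
#' Bundles every knob of the synthetic-data generators. Defaults emulate the
#' study design the pipeline targets: five anti-IgM doses (0, 0.01, 0.1, 1
#' and 10 ug/mL) with ~90 cells per dose for expression, a cell-activation
#' Hill response with `N = 4` and `Km = 0.1` ug/mL, negative-binomial burst
#' statistics that give SE-like genes a larger heterogeneity gain than
#' TE-like genes, latent-factor-driven peak co-accessibility that
#' strengthens upon stimulation, and a 14-point imaging titration for foci
#' (dense around the EC50 so that the Hill coefficient is identifiable from
#' integer-valued per-dose medians).
#'
#' @param n_cells_per_dose cells per dose in the expression simulation.
#' @param doses strictly increasing doses (ug/mL), first must be 0.
#' @param foci_doses dose ladder for the foci simulation (ug/mL).
#' @param n_genes,n_peaks,n_chromosomes problem sizes.
#' @param frac_se_genes fraction of genes given SE-like burst statistics.
#' @param activation_hill list `(N, Km)` of the cell-activation response.
#' @param burst_params list with elements `se_like` and `te_like`, each a
#'   list `(mean_off, mean_on, dispersion)` of negative-binomial
#'   (mean, size) parameters for the inactive / active cell state.
#' @param coaccess_factors list `(n_factors, loading_scale, stim_gain)`
#'   controlling the latent factors that drive peak co-accessibility;
#'   `stim_gain` multiplies the loadings of planted gained pairs in the
#'   stimulated condition only.
#' @param burst_jitter list `(mean_on_sd, dispersion_sd)`: log-normal
#'   standard deviations of the per-gene jitter around the class burst
#'   parameters.
#' @param marker_params burst parameters of the three dedicated marker
#'   genes (reliably induced, low dispersion).
#' @param n_background_genes unresponsive background genes added so that
#'   library depth is not dominated by responders.
#' @param foci list `(a, k)`: basal foci count and amplitude.
#' @param n_cells_atac cells per condition in the ATAC simulation.
#' @param n_mito_genes genes flagged as mitochondrial-like.
#' @param seed master seed; fully determines all generator output.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_cells_per_dose = 90,
                       doses = c(0, 0.01, 0.1, 1, 10),
                       foci_doses = c(0, 0.01, 0.02, 0.04, 0.06, 0.08, 0.1,
                                      0.12, 0.15, 0.2, 0.3, 0.5, 1, 10),
                       n_genes = 200,
                       n_peaks = 200,
                       n_chromosomes = 2,
                       frac_se_genes = 0.25,
                       activation_hill = list(N = 4, Km = 0.1),
                       burst_params = list(
                         se_like = list(mean_off = 1, mean_on = 30, dispersion = 0.5),
                         te_like = list(mean_off = 5, mean_on = 15, dispersion = 5)),
                       burst_jitter = list(mean_on_sd = 0.25, dispersion_sd = 0.7),
                       marker_params = list(mean_off = 2, mean_on = 25, dispersion = 8),
                       n_background_genes = 600,
                       coaccess_factors = list(n_factors = 120,
                                               loading_scale = 0.3,
                                               stim_gain = 3),
                       foci = list(a = 1, k = 12),
                       n_cells_atac = 500,
                       n_mito_genes = 5,
                       seed = 1) {
  cfg <- list(
    n_cells_per_dose = as.integer(n_cells_per_dose), doses = doses,
    foci_doses = foci_doses, n_genes = as.integer(n_genes),
    n_peaks = as.integer(n_peaks), n_chromosomes = as.integer(n_chromosomes),
    frac_se_genes = frac_se_genes, activation_hill = activation_hill,
    burst_params = burst_params, coaccess_factors = coaccess_factors,
    burst_jitter = burst_jitter, marker_params = marker_params,
    n_background_genes = as.integer(n_background_genes),
    foci = foci, n_cells_atac = as.integer(n_cells_atac),
    n_mito_genes = as.integer(n_mito_genes), seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (length(doses) < 2 || any(diff(doses) <= 0))
      stop("configuration error: doses must be strictly increasing")
    if (doses[1] != 0)
      stop("configuration error: first dose must be 0")
    if (length(foci_doses) < 2 || any(diff(foci_doses) <= 0) || foci_doses[1] != 0)
      stop("configuration error: foci_doses must be strictly increasing from 0")
    if (n_cells_per_dose < 1 || n_genes < 1 || n_peaks < 1 ||
        n_chromosomes < 1 || n_cells_atac < 1)
      stop("configuration error: sizes must be positive")
    if (frac_se_genes < 0 || frac_se_genes > 1)
      stop("configuration error: frac_se_genes must lie in [0, 1]")
    if (activation_hill$N <= 0 || activation_hill$Km <= 0)
      stop("configuration error: activation Hill parameters must be positive")
    if (foci$a < 0 || foci$k < 0)
      stop("configuration error: foci a and k must be non-negative")
    if (coaccess_factors$n_factors >= n_peaks)
      stop("configuration error: n_factors must be smaller than n_peaks")
    for (cl in c("se_like", "te_like")) {
      bp <- burst_params[[cl]]
      if (bp$mean_off < 0 || bp$mean_on < 0 || bp$dispersion <= 0)
        stop("configuration error: invalid burst_params for ", cl)
    }
  })
  invisible(cfg)
}

#' Per-cell activation probability at a dose
#'
#' The Hill response `dose^N / (Km^N + dose^N)` of the activation model in a
#' config; 0 at dose 0 and 1/2 at `dose == Km`.
#'
#' @param cfg a [sim_config()].
#' @param dose numeric vector of doses.
#' @return activation probabilities.
#' @export
activation_probability <- function(cfg, dose) {
  hill_curve(dose, cfg$activation_hill$N, cfg$activation_hill$Km)
}

# shared SE-like / TE-like gene-class assignment (own seed stream so the
# expression and ATAC generators agree)
gene_classes <- function(cfg) {
  set.seed(child_seed(cfg$seed, "gene_class"))
  n_se <- round(cfg$frac_se_genes * cfg$n_genes)
  cls <- rep("te_like", cfg$n_genes)
  cls[sample.int(cfg$n_genes, n_se)] <- "se_like"
  names(cls) <- sprintf("gene%03d", seq_len(cfg$n_genes))
  cls
}
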