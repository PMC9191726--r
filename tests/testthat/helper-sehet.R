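# reduced-size study configuration for fast unit tests
small_cfg <- function(seed = 1, ...) {
  args <- list(seed = seed, n_cells_per_dose = 40, n_genes = 60,
               n_background_genes = 150, n_peaks = 60, n_cells_atac = 120,
               coaccess_factors = list(n_factors = 40, loading_scale = 0.3,
                                       stim_gain = 3))
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

# QC thresholds matched to the simulated library depth
sim_qc <- function(sce) qc_filter(sce, min_total = 100, min_genes = 20,
                                  max_mito = 0.5)

# brute-force Fano factor (independent of the package implementation)
bf_fano <- function(x) if (mean(x) == 0) NA_real_ else var(x) / mean(x)
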