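#' Simulate per-cell nuclear foci counts across a dose titration
#'
#' By default each cell's foci count is Poisson with the smooth Hill mean
#' `a + k * dose^N / (Km^N + dose^N)` (the generating model the median
#' dose-response fit should recover). With `bimodal = TRUE` the generator
#' instead draws a per-cell activation state from the Hill probability and
#' emits `Poisson(a)` foci for inactive and `Poisson(a + k)` for active
#' cells, reproducing the bimodal per-dose foci distributions seen in
#' imaging; in that mode the truth records each cell's state.
#'
#' @param cfg a [sim_config()]; uses `foci_doses`, `foci$a`, `foci$k` and
#'   `activation_hill`.
#' @param n_cells_per_dose cells imaged per dose (default 500).
#' @param time_min imaging time point in minutes (annotation only).
#' @param bimodal draw two-population foci counts instead of the smooth
#'   Poisson model.
#' @return list of class `sim_foci`: `table` (data.frame `cell_id`, `dose`,
#'   `time_min`, `foci`) and `truth` (generating parameters, per-dose
#'   activation probabilities, and per-cell states when `bimodal`).
#' @export
simulate_foci <- function(cfg, n_cells_per_dose = 500, time_min = 20,
                          bimodal = FALSE) {
  validate_sim_config(cfg)
  if (cfg$foci$a < 0 || cfg$foci$k < 0)
    stop("configuration error: negative foci parameters")
  set.seed(child_seed(cfg$seed, "foci"))
  doses <- cfg$foci_doses
  dose <- rep(doses, each = n_cells_per_dose)
  n <- length(dose)
  a <- cfg$foci$a; k <- cfg$foci$k
  p <- activation_probability(cfg, dose)
  if (bimodal) {
    act <- rbinom(n, 1, p) == 1
    foci <- rpois(n, a + k * act)
  } else {
    act <- NULL
    foci <- rpois(n, a + k * p)
  }
  tab <- data.frame(
    cell_id = sprintf("foci%05d", seq_len(n)),
    dose = dose, time_min = time_min, foci = foci,
    stringsAsFactors = FALSE)
  truth <- list(
    a = a, k = k,
    N = cfg$activation_hill$N, Km = cfg$activation_hill$Km,
    bimodal = bimodal,
    activation_probability = setNames(activation_probability(cfg, doses),
                                      as.character(doses)),
    activated = if (bimodal) setNames(act, tab$cell_id))
  structure(list(table = tab, truth = truth), class = "sim_foci")
}
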