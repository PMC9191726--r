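#' Fit a basal-free Hill curve to a gene's dose fold-changes
#'
#' The dose-response of mean-expression fold-change versus dose 0 is fitted
#' on the natural scale with the basal term removed
#' (`k * d^N / (Km^N + d^N)`), the model used for switch-likeness
#' categorization. Only genes induced beyond `min_induction` (top-dose
#' fold-change minus 1) are fitted; others — and flat responses, whose `N`
#' is unidentifiable — are returned flagged instead of fitted.
#'
#' @param fold_changes numeric vector of fold-changes, one per dose
#'   (dose 0 included as-is).
#' @param doses numeric vector of doses.
#' @param min_induction induction filter on `fc[top] - 1` (default 0.2).
#' @param ... passed to [fit_hill()].
#' @return a `hill_fit`, or a list of class `hill_skip` with a `reason`
#'   (`"low_induction"` or `"flat"`).
#' @export
fit_gene_hill <- function(fold_changes, doses, min_induction = 0.2, ...) {
  stopifnot(length(fold_changes) == length(doses))
  if (length(doses) < 4) stop("need fold-changes over at least 4 doses")
  top <- which.max(doses)
  if (!is.finite(fold_changes[top]) ||
      (fold_changes[top] - 1) <= min_induction)
    return(structure(list(reason = "low_induction"), class = "hill_skip"))
  if (diff(range(fold_changes)) < 1e-10)
    return(structure(list(reason = "flat"), class = "hill_skip"))
  fit_hill(doses, fold_changes, with_basal = FALSE, ...)
}

#' Fit and categorize a panel of genes
#'
#' Applies [fit_gene_hill()] to each row of a fold-change matrix and
#' [categorize_hill()] to the resulting coefficients. Skipped genes are
#' categorized `"excluded"`.
#'
#' @param fc_matrix genes x doses fold-change matrix (as from
#'   [dose_fold_changes()]).
#' @param doses numeric doses matching the columns.
#' @param min_induction induction filter, see [fit_gene_hill()].
#' @return data.frame `gene`, `N`, `Km`, `k`, `rss`, `category`.
#' @export
gene_hill_table <- function(fc_matrix, doses = as.numeric(colnames(fc_matrix)),
                            min_induction = 0.2) {
  rows <- lapply(rownames(fc_matrix), function(g) {
    f <- fit_gene_hill(fc_matrix[g, ], doses, min_induction)
    if (inherits(f, "hill_skip"))
      data.frame(gene = g, N = NA_real_, Km = NA_real_, k = NA_real_,
                 rss = NA_real_, category = "excluded")
    else
      data.frame(gene = g, N = f$N, Km = f$Km, k = f$k, rss = f$rss,
                 category = categorize_hill(f$N))
  })
  do.call(rbind, rows)
}
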