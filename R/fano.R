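#' Fano factor of a sample
#'
#' Variance over mean, the deviation-from-Poisson heterogeneity index (1
#' for Poisson counts). Undefined (mean 0) samples return `NA`, never 0.
#'
#' @param x numeric vector (at least 2 values).
#' @return the Fano factor, or `NA` when the mean is 0.
#' @export
fano_factor <- function(x) {
  if (length(x) < 2) stop("Fano factor needs at least 2 observations")
  m <- mean(x)
  if (m == 0) return(NA_real_)
  var(x) / m
}

#' Per-gene, per-dose Fano factor and CV profiles
#'
#' Computes variance/mean (Fano) and sd/mean (CV) of expression for each
#' gene within each dose group. Values are `NA` where the group mean is 0.
#' Operates on the linear depth-scaled assay by default so that the
#' Poisson reference (Fano = 1) is meaningful.
#'
#' @param sce a normalized `SingleCellExperiment` with colData `dose`.
#' @param genes optional subset of gene ids.
#' @param assay_name assay to profile.
#' @return list of class `fano_profiles` with matrices `fano` and `cv`
#'   (genes x doses) and the dose vector.
#' @export
fano_profiles <- function(sce, genes = NULL, assay_name = "scaled") {
  dose <- SummarizedExperiment::colData(sce)$dose
  doses <- sort(unique(dose))
  if (any(table(dose) < 2)) stop("every dose group needs at least 2 cells")
  m <- SummarizedExperiment::assay(sce, assay_name)
  if (!is.null(genes)) m <- m[genes, , drop = FALSE]
  m <- as.matrix(m)
  fano <- cv <- matrix(NA_real_, nrow(m), length(doses),
                       dimnames = list(rownames(m), as.character(doses)))
  for (j in seq_along(doses)) {
    sub <- m[, dose == doses[j], drop = FALSE]
    mu <- rowMeans(sub)
    v <- apply(sub, 1, var)
    ok <- mu > 0
    fano[ok, j] <- v[ok] / mu[ok]
    cv[ok, j] <- sqrt(v[ok]) / mu[ok]
  }
  structure(list(fano = fano, cv = cv, doses = doses), class = "fano_profiles")
}

#' Fano (or CV) ratio between two doses
#'
#' Per-gene ratio of the heterogeneity index at the top dose versus the
#' reference dose (undefined values propagate as `NA`).
#'
#' @param profiles a [fano_profiles()] result.
#' @param top_dose,ref_dose doses to compare (defaults: highest vs 0).
#' @param what `"fano"` or `"cv"`.
#' @return named numeric vector of per-gene ratios.
#' @export
fano_ratio <- function(profiles, top_dose = NULL, ref_dose = 0, what = "fano") {
  m <- profiles[[what]]
  if (is.null(top_dose)) top_dose <- max(profiles$doses)
  i <- match(as.character(top_dose), colnames(m))
  j <- match(as.character(ref_dose), colnames(m))
  if (is.na(i) || is.na(j)) stop("requested dose not profiled")
  m[, i] / m[, j]
}

#' Cluster heterogeneity dynamics across doses
#'
#' Each gene's Fano profile is scaled across doses — by default centred on
#' its own mean (`scale = "center"`), which removes the gene's
#' heterogeneity level but keeps the amplitude of its change profile, so
#' that genes with a flat profile remain mutually close; `scale = "z"`
#' additionally divides by the per-gene standard deviation (which
#' amplifies near-constant profiles into noise). Genes are then
#' agglomerated by Ward linkage on squared Euclidean distances (the
#' `ward.D2` variant) and the tree is cut at `k` branches. Genes with
#' undefined (`NA`) entries are excluded with a warning.
#'
#' @param profiles a [fano_profiles()] result (or a genes x doses matrix).
#' @param k number of clusters.
#' @param scale per-gene scaling, `"center"` (default) or `"z"`.
#' @return integer vector of cluster ids named by gene (excluded genes
#'   absent), with the `hclust` tree in attribute `tree`.
#' @export
cluster_fano_dynamics <- function(profiles, k = 4, scale = c("center", "z")) {
  scale <- match.arg(scale)
  m <- if (inherits(profiles, "fano_profiles")) profiles$fano else profiles
  ok <- complete.cases(m)
  if (!all(ok)) {
    warning(sum(!ok), " gene(s) with undefined Fano entries excluded from clustering")
    m <- m[ok, , drop = FALSE]
  }
  if (nrow(m) < k) stop("need at least k genes with fully defined profiles")
  z <- t(apply(m, 1, function(x) {
    if (scale == "center") return(x - mean(x))
    s <- sd(x)
    if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }))
  tree <- hclust(dist(z), method = "ward.D2")
  cl <- cutree(tree, k = k)
  names(cl) <- rownames(m)
  attr(cl, "tree") <- tree
  cl
}

#' Group comparison with undersampling
#'
#' Every group is subsampled without replacement to the smallest group's
#' size before running a one-way ANOVA (`test = "anova"`) or Welch test
#' (`test = "welch"`; for two groups this is Welch's t-test), equalising
#' power across unbalanced groups. With equal group sizes the subsample is
#' a permutation and the result equals the plain test.
#'
#' @param values numeric vector, or a list of numeric vectors (one per group).
#' @param groups grouping factor (ignored when `values` is a list).
#' @param test `"anova"` or `"welch"`.
#' @param seed integer seed controlling the subsample.
#' @return list with `p`, `n_per_group`, `test`.
#' @export
compare_groups_undersampled <- function(values, groups = NULL,
                                        test = c("anova", "welch"), seed = 1) {
  test <- match.arg(test)
  gl <- if (is.list(values)) values else split(values, groups)
  if (length(gl) < 2) stop("need at least 2 groups")
  n_min <- min(lengths(gl))
  if (n_min < 2) stop("smallest group has fewer than 2 values")
  set.seed(seed)
  sub <- lapply(gl, function(x) sample(x, n_min))
  y <- unlist(sub, use.names = FALSE)
  g <- factor(rep(seq_along(sub), each = n_min))
  p <- oneway.test(y ~ g, var.equal = (test == "anova"))$p.value
  list(p = p, n_per_group = n_min, test = test)
}
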