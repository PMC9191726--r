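#' Aggregate single cells into meta-cells
#'
#' Sparse per-cell ATAC counts are densified before covariance estimation:
#' cells are embedded by TF-IDF of the binarized matrix followed by a
#' truncated SVD, each cell's `k`-nearest-neighbour group (itself
#' included) is summed into a meta-cell, and groups overlapping an already
#' accepted group by more than `jaccard_max` are dropped. With `k = 1`
#' meta-cells are the cells themselves.
#'
#' @param counts peaks x cells matrix (sparse or dense).
#' @param k neighbourhood size (>= 1, <= number of cells).
#' @param n_dims SVD components used for the embedding.
#' @param jaccard_max overlap cap for accepting a group.
#' @return list: `counts` (peaks x meta-cells), `groups` (list of member
#'   cell indices per meta-cell).
#' @export
aggregate_cells <- function(counts, k = 10, n_dims = 15, jaccard_max = 0.9) {
  n_cells <- ncol(counts)
  if (k > n_cells) stop("k exceeds the number of cells")
  if (k < 1) stop("k must be >= 1")
  if (k == 1)
    return(list(counts = counts, groups = as.list(seq_len(n_cells))))
  m <- as.matrix(counts)
  bin <- m > 0
  tf <- t(t(bin) / pmax(colSums(bin), 1))
  idf <- log1p(n_cells / pmax(rowSums(bin), 1))
  x <- t(tf * idf)                                   # cells x peaks
  n_dims <- min(n_dims, dim(x) - 1)
  sv <- svd(scale(x, scale = FALSE), nu = n_dims, nv = 0)
  emb <- sv$u %*% diag(sv$d[seq_len(n_dims)], n_dims)
  nn <- t(apply(as.matrix(dist(emb)), 1, function(d) order(d)[seq_len(k)]))
  groups <- list()
  for (i in seq_len(n_cells)) {
    g <- sort(nn[i, ])
    dup <- any(vapply(groups, function(h)
      length(intersect(g, h)) / length(union(g, h)) > jaccard_max, logical(1)))
    if (!dup) groups[[length(groups) + 1]] <- g
  }
  agg <- vapply(groups, function(g) rowSums(m[, g, drop = FALSE]),
                numeric(nrow(m)))
  dimnames(agg) <- list(rownames(counts),
                        sprintf("meta%04d", seq_along(groups)))
  list(counts = agg, groups = groups)
}

#' Distance-penalized graphical lasso by coordinate descent
#'
#' Estimates a sparse precision matrix from a covariance `S` under an
#' element-wise L1 penalty matrix `rho` (block coordinate descent over
#' columns, each column solved by lasso coordinate descent). With
#' `rho = 0` the estimate converges to `solve(S)`.
#'
#' @param S covariance (or correlation) matrix.
#' @param rho penalty matrix (or scalar), same shape as `S`.
#' @param tol convergence tolerance on the average absolute change of the
#'   working covariance, relative to the mean absolute off-diagonal of `S`.
#' @param max_iter maximum full sweeps.
#' @return list `theta` (precision), `w` (estimated covariance),
#'   `iterations`.
#' @export
graphical_lasso <- function(S, rho, tol = 1e-4, max_iter = 200) {
  p <- nrow(S)
  if (length(rho) == 1) rho <- matrix(rho, p, p)
  W <- S
  diag(W) <- diag(S) + diag(rho)
  B <- matrix(0, p, p)   # column j holds beta for column j's lasso problem
  s_off <- mean(abs(S[upper.tri(S)]))
  if (!is.finite(s_off) || s_off == 0) s_off <- mean(abs(diag(S)))
  it <- 0
  repeat {
    it <- it + 1
    delta <- 0
    for (j in seq_len(p)) {
      idx <- setdiff(seq_len(p), j)
      W11 <- W[idx, idx, drop = FALSE]
      s12 <- S[idx, j]
      r12 <- rho[idx, j]
      beta <- B[idx, j]
      # lasso coordinate descent: min 1/2 b'W11 b - s12'b + sum r|b|
      for (ii in seq_len(100)) {
        b_old <- beta
        for (u in seq_along(idx)) {
          resid <- s12[u] - sum(W11[u, ] * beta) + W11[u, u] * beta[u]
          beta[u] <- sign(resid) * max(abs(resid) - r12[u], 0) / W11[u, u]
        }
        if (max(abs(beta - b_old)) < tol * s_off / 10) break
      }
      w12 <- W11 %*% beta
      delta <- delta + mean(abs(W[idx, j] - w12))
      W[idx, j] <- w12
      W[j, idx] <- w12
      B[idx, j] <- beta
    }
    if (delta / p < tol * s_off || it >= max_iter) break
  }
  theta <- matrix(0, p, p)
  for (j in seq_len(p)) {
    idx <- setdiff(seq_len(p), j)
    theta[j, j] <- 1 / (W[j, j] - sum(W[idx, j] * B[idx, j]))
    theta[idx, j] <- -B[idx, j] * theta[j, j]
  }
  theta <- (theta + t(theta)) / 2
  list(theta = theta, w = W, iterations = it)
}

#' Partial correlations from a precision matrix
#'
#' `-theta_ij / sqrt(theta_ii * theta_jj)`, clipped to `[-1, 1]`; the
#' score scale of the co-accessibility stage.
#'
#' @param theta precision (inverse covariance) matrix.
#' @return matrix of partial correlations with unit diagonal.
#' @export
partial_correlations <- function(theta) {
  d <- sqrt(abs(diag(theta)))
  pc <- -theta / tcrossprod(d)
  diag(pc) <- 1
  pmin(pmax(pc, -1), 1)
}

#' Co-accessibility scores between peaks
#'
#' The Cicero-style core: overlapping genomic windows are analysed
#' separately; within each window the meta-cell counts are standardized,
#' their correlation matrix shrunk toward the identity, and a graphical
#' lasso with a distance-increasing penalty
#' `rho_ij = base_rho * (d_ij / s)^dist_exponent` (capped at `rho_max`) is
#' solved. Scores are the resulting partial correlations; pairs seen in
#' several windows get the mean of their window scores.
#'
#' @param counts peaks x meta-cells matrix (see [aggregate_cells()]).
#' @param peaks `GRanges` describing the rows of `counts`.
#' @param window,stride window width and stride in bp (defaults 500 kb /
#'   250 kb).
#' @param base_rho penalty at distance `s`.
#' @param dist_exponent distance-penalty exponent.
#' @param s distance scale in bp; `NULL` calibrates it per run to the
#'   median within-window inter-peak distance.
#' @param rho_max penalty cap.
#' @param shrink identity-shrinkage weight applied to the correlation
#'   matrix before inversion.
#' @param depth_adjust project the global accessibility axis (log total
#'   counts per meta-cell) out of every peak vector before covariance
#'   estimation; recommended for genome-wide matrices, disable for small
#'   targeted panels.
#' @return data.frame `peak_i`, `peak_j` (row indices, i < j), `score`,
#'   `distance`.
#' @export
coaccess_scores <- function(counts, peaks, window = 5e5, stride = 2.5e5,
                            base_rho = 0.3, dist_exponent = 0.75, s = NULL,
                            rho_max = 2, shrink = 0.05, depth_adjust = TRUE) {
  stopifnot(nrow(counts) == length(peaks))
  mid <- (GenomicRanges::start(peaks) + GenomicRanges::end(peaks)) / 2
  chrom <- as.character(GenomicRanges::seqnames(peaks))
  m <- as.matrix(counts)
  if (ncol(m) < 3) stop("need at least 3 meta-cells")
  # k-NN aggregation leaves a global composition factor that correlates
  # every peak pair; project it out of each peak vector before covariance
  # (disable for small targeted panels where total accessibility is signal)
  z <- NULL
  if (depth_adjust) {
    z <- scale(log1p(colSums(m)))[, 1]
    if (sd(z) == 0 || !all(is.finite(z))) z <- NULL
  }
  acc <- new.env(parent = emptyenv())
  add_score <- function(i, j, sc, d) {
    key <- paste(i, j)
    cur <- acc[[key]]
    acc[[key]] <- if (is.null(cur)) c(sc, 1, d) else c(cur[1] + sc, cur[2] + 1, d)
  }
  for (ch in unique(chrom)) {
    on_ch <- which(chrom == ch)
    if (length(on_ch) < 2) next
    lo <- min(mid[on_ch]); hi <- max(mid[on_ch])
    starts <- seq(floor(lo / stride) * stride - window + stride, hi, by = stride)
    if (is.null(s)) {
      dm <- mid[on_ch]
      n_s <- min(length(dm), 200)
      dsub <- dm[seq(1, length(dm), length.out = n_s)]
      pd <- abs(outer(dsub, dsub, "-"))
      pd <- pd[pd > 0 & pd <= window]
      s_run <- max(median(pd), 1)
    } else s_run <- s
    for (ws in starts) {
      in_w <- on_ch[mid[on_ch] >= ws & mid[on_ch] < ws + window]
      if (length(in_w) < 2) next
      x <- m[in_w, , drop = FALSE]
      keep <- apply(x, 1, sd) > 0
      in_w <- in_w[keep]
      if (length(in_w) < 2) next
      x <- scale(t(m[in_w, , drop = FALSE]))       # meta-cells x peaks
      if (!is.null(z)) x <- x - z %*% crossprod(z, x) / sum(z^2)
      S <- cor(x)
      S <- (1 - shrink) * S + shrink * diag(ncol(S))
      d_ij <- abs(outer(mid[in_w], mid[in_w], "-"))
      rho <- pmin(base_rho * (d_ij / s_run)^dist_exponent, rho_max)
      diag(rho) <- 0
      gl <- graphical_lasso(S, rho)
      pc <- partial_correlations(gl$theta)
      for (a in seq_along(in_w)) for (b in seq_along(in_w)) {
        if (a >= b) next
        add_score(in_w[a], in_w[b], pc[a, b], d_ij[a, b])
      }
    }
  }
  keys <- ls(acc)
  if (length(keys) == 0)
    return(data.frame(peak_i = integer(), peak_j = integer(),
                      score = numeric(), distance = numeric()))
  ij <- do.call(rbind, strsplit(keys, " "))
  vals <- t(vapply(keys, function(k) acc[[k]], numeric(3)))
  out <- data.frame(peak_i = as.integer(ij[, 1]), peak_j = as.integer(ij[, 2]),
                    score = vals[, 1] / vals[, 2], distance = vals[, 3])
  out[order(out$peak_i, out$peak_j), ]
}

#' Differential (gained) co-accessible pairs between conditions
#'
#' A pair is gained when its stimulated score is at least `score_min` and
#' the stimulated-minus-unstimulated difference is at least `delta_min`
#' (both boundaries inclusive). Pairs absent from one condition score 0
#' there.
#'
#' @param scores_stim,scores_unstim data.frames from [coaccess_scores()]
#'   over the same peak universe.
#' @param score_min stimulated-score threshold (default 0.1).
#' @param delta_min difference threshold (default 0.05).
#' @return data.frame `peak_i`, `peak_j`, `score_stim`, `score_unstim`,
#'   `delta`, `gained`.
#' @export
differential_pairs <- function(scores_stim, scores_unstim,
                               score_min = 0.1, delta_min = 0.05) {
  key_s <- paste(scores_stim$peak_i, scores_stim$peak_j)
  key_u <- paste(scores_unstim$peak_i, scores_unstim$peak_j)
  keys <- union(key_s, key_u)
  ij <- do.call(rbind, strsplit(keys, " "))
  st <- scores_stim$score[match(keys, key_s)]
  un <- scores_unstim$score[match(keys, key_u)]
  st[is.na(st)] <- 0
  un[is.na(un)] <- 0
  out <- data.frame(peak_i = as.integer(ij[, 1]), peak_j = as.integer(ij[, 2]),
                    score_stim = st, score_unstim = un, delta = st - un)
  out$gained <- out$score_stim >= score_min & out$delta >= delta_min
  out[order(out$peak_i, out$peak_j), ]
}

#' Count gained co-accessible partner regions per gene
#'
#' For each gene, the peaks overlapping the window TSS +/- `flank` are its
#' promoter-proximal anchors; the count is the number of distinct partner
#' peaks joined to an anchor by a gained pair.
#'
#' @param pairs data.frame from [differential_pairs()].
#' @param peaks `GRanges` describing the peak indices in `pairs`.
#' @param tss data.frame `gene`, `chrom`, `position` (0-based).
#' @param flank window half-width in bp (default 1000).
#' @return named integer vector: gained-partner count per gene.
#' @export
gene_pair_counts <- function(pairs, peaks, tss, flank = 1000) {
  gained <- pairs[pairs$gained, , drop = FALSE]
  chrom <- as.character(GenomicRanges::seqnames(peaks))
  counts <- setNames(integer(nrow(tss)), tss$gene)
  for (i in seq_len(nrow(tss))) {
    win_lo <- tss$position[i] - flank
    win_hi <- tss$position[i] + flank
    anchors <- which(chrom == tss$chrom[i] &
                     GenomicRanges::start(peaks) <= win_hi &
                     GenomicRanges::end(peaks) >= win_lo)
    if (length(anchors) == 0) next
    partners <- c(gained$peak_j[gained$peak_i %in% anchors],
                  gained$peak_i[gained$peak_j %in% anchors])
    counts[i] <- length(unique(setdiff(partners, anchors)))
  }
  counts
}

#' Spearman correlation between gained-pair counts and a gene statistic
#'
#' Rank correlation with average ranks for ties, the outlier-robust
#' convention used throughout the analysis.
#'
#' @param counts named numeric vector (e.g. from [gene_pair_counts()]).
#' @param statistic named numeric vector (e.g. RNA fold-changes or Fano
#'   ratios); matched to `counts` by name.
#' @return the Spearman correlation coefficient.
#' @export
correlate_counts <- function(counts, statistic) {
  common <- intersect(names(counts), names(statistic))
  common <- common[is.finite(statistic[common])]
  if (length(common) < 3) stop("need at least 3 paired observations")
  cor(counts[common], statistic[common], method = "spearman")
}
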