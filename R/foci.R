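#' Per-dose median foci response
#'
#' Medians of the per-cell foci counts at one imaging time point, the
#' summary that is fed to the Hill fit. Even-count medians are the mean of
#' the two central order statistics.
#'
#' @param table a foci table (`cell_id`, `dose`, `time_min`, `foci`) as
#'   produced by [simulate_foci()] or [read_foci()].
#' @param time imaging time point (minutes) to extract.
#' @return data.frame with `dose` and `median_foci`, sorted by dose.
#' @export
median_response <- function(table, time = 20) {
  stopifnot(all(c("dose", "time_min", "foci") %in% names(table)))
  tab <- table[table$time_min == time, ]
  doses <- sort(unique(tab$dose))
  if (length(doses) < 2)
    stop("need at least two distinct doses at time ", time)
  med <- vapply(doses, function(d) {
    x <- tab$foci[tab$dose == d]
    if (length(x) == 0) stop("empty dose group at dose ", d)
    median(x)
  }, numeric(1))
  data.frame(dose = doses, median_foci = med)
}

#' Predict per-dose activation fractions from foci counts
#'
#' Binary activation labels are derived from the pooled foci counts by a
#' two-component Poisson mixture fitted with EM (label = posterior > 0.5);
#' a logistic regression of label on foci count is then fitted and the mean
#' predicted activation probability per dose is reported. If the mixture
#' components fail to separate (means within 0.5 counts) a warning is
#' raised and labels fall back to thresholding at the overall median.
#'
#' @param table a foci table.
#' @param time imaging time point (minutes).
#' @return data.frame `dose`, `activation` (mean predicted probability),
#'   with the fitted mixture means in attribute `mixture_means`.
#' @export
activation_from_foci <- function(table, time = 20) {
  tab <- table[table$time_min == time, ]
  doses <- sort(unique(tab$dose))
  top <- max(doses)
  if (!any(tab$dose == 0) || !any(tab$dose == top))
    stop("foci required at both dose 0 and the top dose")
  mix <- poisson_mixture(tab$foci)
  if (abs(diff(mix$lambda)) < 0.5) {
    warning("mixture components failed to separate; falling back to the overall median threshold")
    label <- as.integer(tab$foci > median(tab$foci))
  } else {
    label <- as.integer(mix$posterior > 0.5)
  }
  fit <- suppressWarnings(glm(label ~ foci, data = cbind(tab, label = label),
                              family = binomial()))
  prob <- predict(fit, type = "response")
  out <- data.frame(
    dose = doses,
    activation = vapply(doses, function(d) mean(prob[tab$dose == d]), numeric(1)))
  attr(out, "mixture_means") <- mix$lambda
  out
}

# two-component Poisson mixture via EM; component 2 has the larger mean
poisson_mixture <- function(x, max_iter = 500, tol = 1e-8) {
  lam <- unname(quantile(x, c(0.25, 0.75))) + c(0, 0.5)
  if (diff(lam) < 1e-6) lam <- lam + c(-0.25, 0.25)
  lam <- pmax(lam, 1e-3)
  pi1 <- 0.5
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    d1 <- pi1 * stats::dpois(x, lam[1])
    d2 <- (1 - pi1) * stats::dpois(x, lam[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    g2 <- d2 / tot
    pi1 <- mean(1 - g2)
    lam[1] <- sum((1 - g2) * x) / max(sum(1 - g2), 1e-12)
    lam[2] <- sum(g2 * x) / max(sum(g2), 1e-12)
    ll <- sum(log(tot))
    if (is.finite(ll) && abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  if (lam[1] > lam[2]) { # larger mean = "activated" component
    lam <- rev(lam); g2 <- 1 - g2
  }
  list(lambda = lam, posterior = g2)
}
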