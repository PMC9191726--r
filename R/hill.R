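#' Hill dose-response curve
#'
#' `a + k * d^N / (Km^N + d^N)`, the four-parameter model used both for
#' nuclear foci counts and for gene-expression fold-changes (where the basal
#' term `a` is removed). `N` is the Hill coefficient (cooperativity), `Km`
#' the half-maximal dose in the dose units, `k` the response amplitude and
#' `a` the basal response. The curve value at dose 0 is `a` for any `N > 0`.
#'
#' @param dose numeric vector of non-negative doses.
#' @param N Hill coefficient (> 0).
#' @param Km half-maximal dose (> 0).
#' @param k amplitude (>= 0).
#' @param a basal term (>= 0).
#' @return numeric vector of responses.
#' @export
hill_curve <- function(dose, N, Km, k = 1, a = 0) {
  h <- ifelse(dose <= 0, 0, dose^N / (Km^N + dose^N))
  a + k * h
}

#' Least-squares Hill fit by multi-start optimization
#'
#' Fits the Hill model to a dose-response by minimising the residual sum of
#' squares. A log-spaced `(N, Km)` grid is scanned with the amplitude and
#' basal terms solved analytically (linear least squares, clamped at 0) at
#' each node; the best nodes then seed Nelder-Mead and bounded
#' quasi-Newton (L-BFGS-B) refinements and the lowest-RSS solution of the
#' whole basket is returned. `N` is constrained to `n_bounds` during
#' optimization to avoid overflow; the bounds are recorded in the fit.
#'
#' @param dose numeric vector of doses (may include 0).
#' @param response numeric vector, same length as `dose`.
#' @param with_basal fit the basal term `a` (`TRUE`) or fix `a = 0`.
#' @param n_bounds length-2 bounds on `N` during optimization.
#' @param grid_size nodes per axis of the `(N, Km)` start grid.
#' @param n_starts number of best grid nodes refined by the optimizer basket.
#' @return an object of class `hill_fit`: list with `N`, `Km`, `k`, `a`,
#'   `rss`, `n_points`, `with_basal`, `n_bounds`.
#' @export
fit_hill <- function(dose, response, with_basal = TRUE,
                     n_bounds = c(0.05, 20), grid_size = 8, n_starts = 5) {
  stopifnot(length(dose) == length(response))
  keep <- is.finite(dose) & is.finite(response)
  dose <- dose[keep]; response <- response[keep]
  n_par <- if (with_basal) 4L else 3L
  if (length(dose) < n_par)
    stop("under-determined fit: ", length(dose), " points for ", n_par,
         " free parameters")
  if (all(response == 0)) stop("degenerate fit: all-zero response")
  dpos <- dose[dose > 0]
  if (length(dpos) < 2) stop("need at least two positive doses")

  km_lo <- min(dpos) / 10
  km_hi <- max(dpos) * 10
  n_grid <- exp(seq(log(0.25), log(16), length.out = grid_size))
  km_grid <- exp(seq(log(km_lo), log(km_hi), length.out = grid_size))

  solve_ak <- function(N, Km) {
    h <- hill_curve(dose, N, Km)
    if (with_basal) {
      b <- tryCatch(stats::coef(stats::lm.fit(cbind(1, h), response)),
                    error = function(e) c(0, 0))
      b[!is.finite(b)] <- 0
      a <- max(b[1], 0)
      k <- max(b[2], 0)
      # re-solve k with a clamped if needed
      if (b[1] < 0) k <- max(sum(h * response) / max(sum(h^2), 1e-300), 0)
    } else {
      a <- 0
      k <- max(sum(h * response) / max(sum(h^2), 1e-300), 0)
    }
    c(a = a, k = k)
  }
  rss_at <- function(N, Km, k, a) sum((response - hill_curve(dose, N, Km, k, a))^2)

  # parameter vector: (log N, log Km, k, a?)
  obj <- function(p) {
    N <- exp(p[1]); Km <- exp(p[2]); k <- p[3]
    a <- if (with_basal) p[4] else 0
    if (!is.finite(N) || !is.finite(Km) || N < n_bounds[1] || N > n_bounds[2] ||
        k < 0 || a < 0) return(1e300)
    rss_at(N, Km, k, a)
  }

  starts <- expand.grid(N = n_grid, Km = km_grid)
  starts$rss <- vapply(seq_len(nrow(starts)), function(i) {
    ak <- solve_ak(starts$N[i], starts$Km[i])
    rss_at(starts$N[i], starts$Km[i], ak["k"], ak["a"])
  }, numeric(1))

  lower <- c(log(n_bounds[1]), log(km_lo / 10), 0, if (with_basal) 0)
  upper <- c(log(n_bounds[2]), log(km_hi * 10), Inf, if (with_basal) Inf)
  best <- NULL
  for (i in order(starts$rss)[seq_len(min(n_starts, nrow(starts)))]) {
    ak <- solve_ak(starts$N[i], starts$Km[i])
    p0 <- c(log(starts$N[i]), log(starts$Km[i]), ak["k"], if (with_basal) ak["a"])
    for (m in c("Nelder-Mead", "L-BFGS-B")) {
      o <- tryCatch(
        if (m == "L-BFGS-B")
          optim(p0, obj, method = m, lower = lower, upper = upper,
                control = list(maxit = 500, factr = 1e4))
        else
          optim(p0, obj, method = m,
                control = list(maxit = 2000, reltol = 1e-14)),
        error = function(e) NULL)
      if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
    }
  }
  # final Nelder-Mead polish from the incumbent
  o <- tryCatch(optim(best$par, obj, method = "Nelder-Mead",
                      control = list(maxit = 4000, reltol = 1e-15)),
                error = function(e) NULL)
  if (!is.null(o) && o$value < best$value) best <- o

  p <- best$par
  structure(list(
    N = exp(p[1]), Km = exp(p[2]), k = unname(p[3]),
    a = if (with_basal) unname(p[4]) else 0,
    rss = best$value, n_points = length(dose),
    with_basal = with_basal, n_bounds = n_bounds
  ), class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("Hill fit: N = %.4g, Km = %.4g, k = %.4g, a = %.4g (rss %.4g, %d points)\n",
              x$N, x$Km, x$k, x$a, x$rss, x$n_points))
  invisible(x)
}

#' @export
predict.hill_fit <- function(object, dose, ...) {
  hill_curve(dose, object$N, object$Km, object$k, object$a)
}

#' Categorize a Hill coefficient by switch-likeness
#'
#' Fits with `N > 9` or `N < 0.3` are excluded as overfitted / unfit; the
#' remainder are binned as high (`5 <= N`), medium (`1 < N < 5`) or low
#' (`N <= 1`). Boundary semantics follow the plotted group definitions
#' (`N = 1` is low, `N = 5` is high); all boundaries are configurable.
#'
#' @param N numeric Hill coefficient(s), or a `hill_fit`.
#' @param exclude_above,exclude_below exclusion bounds.
#' @param high_min,med_min bin edges: high is `N >= high_min`, medium is
#'   `med_min < N < high_min`, low is `N <= med_min`.
#' @return character vector in `{"high","med","low","excluded"}`.
#' @export
categorize_hill <- function(N, exclude_above = 9, exclude_below = 0.3,
                            high_min = 5, med_min = 1) {
  if (inherits(N, "hill_fit")) N <- N$N
  out <- character(length(N))
  out[!is.finite(N) | N > exclude_above | N < exclude_below] <- "excluded"
  todo <- out == ""
  out[todo & N >= high_min] <- "high"
  out[todo & N > med_min & N < high_min] <- "med"
  out[out == ""] <- "low"
  out
}
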