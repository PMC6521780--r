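## Self-contained local false discovery rate engine for a family of a few
## hundred pathway statistics. The observed statistics z (by default the
## natural-log pathway odds ratios) are modelled as a two-group mixture
##   f(z) = p0 f0(z) + (1 - p0) f1(z),
## and the local FDR of a case is the Bayes posterior probability that it
## is null, fdr(z) = p0 f0(z) / f(z). With only ~200 statistics the usual
## large-family defaults misbehave, so four heuristics are applied:
##   1. outlier statistics (beyond 5 robust SDs of the median) are removed
##      from all fitting and assigned fdr = 0;
##   2. the histogram uses 25 equal-width bins;
##   3. the empirical null N(mean, sd^2) and p0 are estimated by central
##      matching: a quadratic fit to log f over the central window of bins;
##   4. the mixture density f is a natural-spline Poisson regression of bin
##      counts on bin midpoints with 4 effective degrees of freedom.

#' Flag outlier statistics
#'
#' A case is an outlier when it lies more than `k` scaled median absolute
#' deviations from the median (MAD scaled by 1.4826 to be consistent with
#' the normal SD). Outliers are excluded from mixture fitting and assigned
#' local FDR 0.
#'
#' @param z numeric vector of statistics (length >= 50).
#' @param k robust-SD multiple; default 5.
#' @return Logical vector, TRUE = outlier.
#' @export
flag_outliers <- function(z, k = 5) {
  if (length(z) < 50) stopf("need at least 50 statistics, got %d", length(z))
  m <- stats::median(z)
  s <- stats::mad(z)
  if (s == 0) stopf("MAD of statistics is zero; outlier rule undefined")
  abs(z - m) > k * s
}

#' Fit the two-group mixture and empirical null
#'
#' Implements the heuristic recipe described above. Raises a misfit error
#' when the quadratic fitted to log f has no central peak (nonnegative
#' curvature); callers running many fits should catch this and record the
#' run as a (rare) algorithm failure.
#'
#' @param z statistics on the analysis scale (>= 50 non-outlier values).
#' @param breaks number of equal-width histogram bins (default 25).
#' @param df effective degrees of freedom of the spline density (default 4).
#' @param outlier_k outlier rule multiple passed to [flag_outliers()].
#' @param central_frac central-matching window: bins whose fitted density
#'   is at least this fraction of the modal density (default 0.3).
#' @return An object of class `locfdr_fit`: list with `z`, `p0`,
#'   `null_mean`, `null_sd`, `fdr` (per input case, clipped to \[0,1\],
#'   outliers = 0), `outlier` flags, and `diagnostics` (bin edges/counts,
#'   fitted counts, central window, density model).
#' @export
fit_locfdr <- function(z, breaks = 25L, df = 4L, outlier_k = 5,
                       central_frac = 0.3) {
  out <- flag_outliers(z, k = outlier_k)
  zz <- z[!out]
  if (length(zz) < 50)
    stopf("need at least 50 non-outlier statistics, got %d", length(zz))
  edges <- seq(min(zz), max(zz), length.out = breaks + 1)
  width <- diff(edges[1:2])
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  counts <- tabulate(pmin(pmax(findInterval(zz, edges), 1L), breaks),
                     nbins = breaks)
  n <- length(zz)

  # Poisson regression of bin counts on a natural-spline basis of the
  # midpoints; glm.fit with an explicit basis keeps the thousands of fits
  # in the Monte-Carlo harness cheap.
  basis <- splines::ns(mids, df = df)
  fit <- stats::glm.fit(cbind(1, basis), counts, family = stats::poisson())
  if (!fit$converged || anyNA(fit$coefficients))
    stopf("locfdr misfit: density regression did not converge")
  beta <- fit$coefficients
  fitted_counts <- as.numeric(fit$fitted.values)

  # density evaluator; outside the bin-midpoint support f is held at its
  # boundary value (flat extrapolation)
  f_at <- function(x) {
    xc <- pmin(pmax(x, mids[1]), mids[breaks])
    mu <- exp(drop(cbind(1, stats::predict(basis, xc)) %*% beta))
    mu / (n * width)
  }

  # central window: the contiguous run of bins around the mode whose
  # fitted density stays above `central_frac` of the modal density — the
  # region where the null component dominates (for a normal null,
  # central_frac = 0.3 reaches about +/- 1.55 null SDs); at least 5 bins
  # so the quadratic is determined
  pk <- which.max(fitted_counts)
  lo <- pk
  while (lo > 1 && fitted_counts[lo - 1] >= central_frac * fitted_counts[pk])
    lo <- lo - 1
  hi <- pk
  while (hi < breaks &&
         fitted_counts[hi + 1] >= central_frac * fitted_counts[pk])
    hi <- hi + 1
  if (hi - lo + 1 < 5) {
    lo <- max(1, pk - 2)
    hi <- min(breaks, pk + 2)
  }
  win <- lo:hi
  # central matching reads the quadratic off the smoothed log density
  # (not the raw counts): with ~200-case families the central bins hold
  # too few counts for a stable curvature estimate on their own
  log_dens <- log(fitted_counts[win] / (n * width))
  b <- stats::.lm.fit(cbind(1, mids[win], mids[win]^2),
                      log_dens)$coefficients
  if (anyNA(b) || b[3] >= 0)
    stopf("locfdr misfit: log mixture density has no central peak")

  null_sd <- sqrt(-1 / (2 * b[3]))
  null_mean <- b[2] * null_sd^2
  # height of the matched quadratic at its vertex determines p0:
  # log(p0 * dnorm(mu; mu, sd)) = b0 + b1*mu + b2*mu^2
  p0 <- exp(b[1] + b[2] * null_mean + b[3] * null_mean^2) *
    null_sd * sqrt(2 * pi)
  p0 <- min(p0, 1)

  fdr <- numeric(length(z))
  fdr[!out] <- pmin(1, p0 * stats::dnorm(zz, null_mean, null_sd) / f_at(zz))
  fdr[out] <- 0

  structure(list(z = z, p0 = p0, null_mean = null_mean, null_sd = null_sd,
                 fdr = fdr, outlier = out,
                 f = f_at,
                 diagnostics = list(bin_edges = edges, bin_counts = counts,
                                    fitted_counts = fitted_counts,
                                    central_window = win,
                                    n_used = n, bin_width = width)),
            class = "locfdr_fit")
}

#' Evaluate local FDR at new statistic values
#'
#' @param fit a `locfdr_fit`.
#' @param z_new statistics on the same scale as the fit.
#' @return Local FDR values in \[0, 1\]. Values outside the histogram
#'   support use the flat boundary extrapolation of f.
#' @export
locfdr_values <- function(fit, z_new) {
  pmin(1, fit$p0 * stats::dnorm(z_new, fit$null_mean, fit$null_sd) /
         fit$f(z_new))
}

#' @export
print.locfdr_fit <- function(x, ...) {
  cat(sprintf(
    "locfdr fit: %d cases (%d outliers), p0 = %.3f, null = N(%.3f, %.3f^2)\n",
    length(x$z), sum(x$outlier), x$p0, x$null_mean, x$null_sd))
  invisible(x)
}

#' Dump fit diagnostics as JSON
#'
#' The model fit should always be inspected in small families; this writes
#' the histogram, fitted curve and null parameters for external review.
#'
#' @param fit a `locfdr_fit`.
#' @param path output JSON file.
#' @export
locfdr_diagnostics_json <- function(fit, path) {
  d <- fit$diagnostics
  jsonlite::write_json(
    list(p0 = fit$p0, null_mean = fit$null_mean, null_sd = fit$null_sd,
         n_outliers = sum(fit$outlier), bin_edges = d$bin_edges,
         bin_counts = d$bin_counts, fitted_counts = d$fitted_counts,
         central_window = range(d$central_window)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
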