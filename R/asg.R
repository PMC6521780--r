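## Dichotomizing the Hellinger-distance distribution into alternatively
## spliced genes (ASGs) vs. not. Because the distances are univariate,
## 2-means clustering reduces to choosing a single threshold: the optimal
## 2-partition of sorted values is always a contiguous split, so the exact
## global optimum is found by scanning all n-1 splits with cumulative sums.
## This is deterministic — no random initialization exists by construction.

#' Exact 1-D 2-means threshold
#'
#' Finds the split of the sorted values minimizing total within-cluster sum
#' of squares over all n-1 contiguous splits (the global 2-means optimum in
#' one dimension). The threshold is the midpoint between the two clusters'
#' boundary values.
#'
#' @param distances numeric vector (>= 10 values, not all identical).
#' @return `list(threshold=, centers=)` with `centers` sorted ascending.
#' @export
two_means_threshold <- function(distances) {
  x <- distances[!is.na(distances)]
  n <- length(x)
  if (n < 10) stopf("need at least 10 non-missing distances, got %d", n)
  if (max(x) == min(x)) stopf("distances have zero variance")
  x <- sort(x)
  cs <- cumsum(x)
  cs2 <- cumsum(x^2)
  j <- seq_len(n - 1)
  wss_left <- cs2[j] - cs[j]^2 / j
  wss_right <- (cs2[n] - cs2[j]) - (cs[n] - cs[j])^2 / (n - j)
  best <- which.min(wss_left + wss_right)
  list(threshold = (x[best] + x[best + 1]) / 2,
       centers = c(cs[best] / best, (cs[n] - cs[best]) / (n - best)))
}

#' Classify genes as alternatively spliced
#'
#' Applies [two_means_threshold()] to a subject's Hellinger profile; the
#' cluster with the larger center is the ASG class, so a gene is ASG iff
#' its distance is at or above the threshold. Genes with missing distances
#' are excluded from both the threshold fit and the background rate.
#'
#' @param profile a `hellinger_profile` (or a bare numeric vector of
#'   distances, in which case genes are named by position).
#' @return An object of class `asg_calls`: list with `calls` (named logical,
#'   TRUE = ASG, classified genes only), `threshold`, `centers`, `pi_all`
#'   (background ASG rate) and `n_classified`.
#' @export
classify_asg <- function(profile) {
  if (is.numeric(profile)) {
    d <- profile
    gene <- if (is.null(names(profile))) as.character(seq_along(profile))
            else names(profile)
  } else {
    d <- profile$distance
    gene <- profile$gene_id
  }
  keep <- !is.na(d)
  fit <- two_means_threshold(d[keep])
  calls <- d[keep] >= fit$threshold
  names(calls) <- gene[keep]
  structure(list(calls = calls,
                 values = stats::setNames(d[keep], gene[keep]),
                 threshold = fit$threshold,
                 centers = fit$centers,
                 pi_all = mean(calls),
                 n_classified = sum(keep)),
            class = "asg_calls")
}

#' @export
print.asg_calls <- function(x, ...) {
  cat(sprintf(
    "ASG call set: %d genes classified, threshold %.4f, pi_all %.4f\n",
    x$n_classified, x$threshold, x$pi_all))
  invisible(x)
}
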