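## Per-gene quantification of alternative splicing between the two paired
## samples. A gene's "relative isoform usage" in a sample is the vector of
## each isoform's share of the gene's total expression there; the Hellinger
## distance between the two samples' usage vectors,
##   H_g = sqrt( 1/2 * sum_k (sqrt p_Ak - sqrt p_Bk)^2 ),
## lies in [0,1]: 0 = identical usage, 1 = disjoint isoform support. H_g is
## invariant to library size, so TPM normalization cannot change it; TPM is
## still applied (and kept) because downstream expression-based feature
## modes need library-comparable abundances.

#' Transcripts-per-million normalization of both samples
#'
#' Rescales each sample column so that its total abundance equals 1e6.
#'
#' @param table a [paired_isoforms] table with at least one positive
#'   abundance per sample.
#' @return The rescaled table.
#' @export
tpm_normalize <- function(table) {
  tot_a <- sum(table$abundance_A)
  tot_b <- sum(table$abundance_B)
  if (tot_a <= 0 || tot_b <= 0)
    stopf("cannot TPM-normalize a sample with zero total abundance")
  table$abundance_A <- table$abundance_A * (1e6 / tot_a)
  table$abundance_B <- table$abundance_B * (1e6 / tot_b)
  table
}

#' Filter genes by isoform count
#'
#' Standard practice in alternative-splicing analytics: only genes with at
#' least `min_isoforms` and at most `max_isoforms` annotated isoforms are
#' retained (defaults 2 and 30). A single-isoform gene cannot be
#' alternatively spliced; genes with very many isoforms yield unstable
#' usage estimates.
#'
#' @param table a [paired_isoforms] table.
#' @param min_isoforms,max_isoforms inclusive bounds on isoforms per gene.
#' @return The filtered table; counts of removed genes are logged.
#' @export
filter_isoform_counts <- function(table, min_isoforms = 2L,
                                  max_isoforms = 30L) {
  k <- table(table$gene_id)
  bad <- names(k)[k < min_isoforms | k > max_isoforms]
  if (length(bad) > 0) {
    n1pas_log(sprintf("removed %d gene(s) outside [%d, %d] isoforms",
                      length(bad), min_isoforms, max_isoforms))
    table <- table[!(table$gene_id %in% bad), , drop = FALSE]
  }
  table
}

#' Relative isoform usage of one gene in both samples
#'
#' Divides each isoform's abundance by the gene total within the sample.
#' If either sample's gene total is zero the usage (and hence the distance)
#' is undefined and `NULL` is returned — the gene is recorded as missing,
#' not an error.
#'
#' @param abundance_A,abundance_B nonnegative abundance vectors over the
#'   same isoforms (length >= 2).
#' @return `list(proportions_A=, proportions_B=)` or `NULL` when undefined.
#' @export
isoform_usage <- function(abundance_A, abundance_B) {
  if (length(abundance_A) != length(abundance_B))
    stopf("samples disagree on the number of isoforms")
  ta <- sum(abundance_A); tb <- sum(abundance_B)
  if (ta == 0 || tb == 0) return(NULL)
  list(proportions_A = abundance_A / ta, proportions_B = abundance_B / tb)
}

#' Hellinger distance between two probability vectors
#'
#' @param p,q nonnegative vectors of equal length, each summing to 1.
#' @return A distance in \[0, 1\].
#' @export
hellinger_distance <- function(p, q) {
  if (length(p) != length(q))
    stopf("usage vectors must have equal length")
  d <- sqrt(0.5 * sum((sqrt(p) - sqrt(q))^2))
  min(d, 1)  # guard tiny floating overshoot at disjoint support
}

#' Per-gene Hellinger distance profile for one subject
#'
#' Computes one distance per retained gene; genes unexpressed in at least
#' one sample get `NA` (`missing_rule = "either"`, the default, because a
#' zero gene total leaves the usage vector undefined). The alternative
#' `"both"` rule marks a gene missing only when both samples are
#' unexpressed and records distance 1 for one-sided expression (complete
#' loss or gain of isoform usage); it is provided for auditing.
#'
#' @param table a normalized, filtered [paired_isoforms] table.
#' @param missing_rule `"either"` or `"both"`; see Details.
#' @return An object of class `hellinger_profile`: a data frame with
#'   columns `gene_id`, `n_isoforms`, `distance` (NA = missing), plus
#'   attributes `n_genes_total` and `n_genes_missing`.
#' @export
distance_profile <- function(table, missing_rule = c("either", "both")) {
  missing_rule <- match.arg(missing_rule)
  if (nrow(table) == 0)
    stopf("no genes left after filtering")
  idx <- split(seq_len(nrow(table)), table$gene_id)
  gene_id <- names(idx)
  k <- lengths(idx)
  d <- vapply(idx, function(i) {
    a <- table$abundance_A[i]; b <- table$abundance_B[i]
    u <- isoform_usage(a, b)
    if (is.null(u)) {
      if (missing_rule == "both" && (sum(a) > 0 || sum(b) > 0)) return(1)
      return(NA_real_)
    }
    hellinger_distance(u$proportions_A, u$proportions_B)
  }, 0)
  hellinger_profile(gene_id, d, n_isoforms = unname(k))
}

#' @rdname distance_profile
#' @param gene_id gene identifiers.
#' @param distance distances in \[0,1\], `NA` = missing.
#' @param n_isoforms optional isoform counts per gene.
#' @export
hellinger_profile <- function(gene_id, distance, n_isoforms = NA_integer_) {
  gene_id <- as.character(gene_id)
  if (anyDuplicated(gene_id)) stopf("duplicate gene_id in profile")
  ok <- is.na(distance) | (distance >= 0 & distance <= 1)
  if (!all(ok)) stopf("Hellinger distances must lie in [0, 1]")
  structure(
    data.frame(gene_id = gene_id, n_isoforms = as.integer(n_isoforms),
               distance = as.numeric(distance), stringsAsFactors = FALSE),
    n_genes_total = length(gene_id),
    n_genes_missing = sum(is.na(distance)),
    class = c("hellinger_profile", "data.frame"))
}
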