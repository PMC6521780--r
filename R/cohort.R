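## Cohort-level validation of single-subject calls. The N x P binary call
## matrix (1 = pathway enriched for that patient: OR > 1 and locFDR < 0.20)
## is compared with nulls built by independently shuffling each patient's
## row: row sums (each patient's number of calls) are preserved while the
## correspondence between patients and pathway identities is destroyed.
## Empirical p-values use add-one smoothing, (1 + #exceedances)/(B + 1),
## so the floor at B = 2000 is ~0.0005 and zero is never reported.

#' Assemble a binary call matrix from enrichment profiles
#'
#' @param profiles named list of `enrichment_profile` objects (names =
#'   patient ids; falls back to each profile's `patient_id`).
#' @return A binary patients x pathways matrix; a pathway unscored for a
#'   patient counts as not-enriched (0).
#' @export
call_matrix <- function(profiles) {
  ids <- names(profiles)
  if (is.null(ids)) ids <- vapply(profiles, function(p) p$patient_id, "")
  pathways <- sort(unique(unlist(
    lapply(profiles, function(p) p$records$pathway_id))))
  m <- matrix(0L, nrow = length(profiles), ncol = length(pathways),
              dimnames = list(ids, pathways))
  for (i in seq_along(profiles)) {
    rec <- profiles[[i]]$records
    m[i, rec$pathway_id[rec$enriched]] <- 1L
  }
  m
}

#' Pathway capture rate
#'
#' The proportion of patients for whom the pathway was called enriched:
#' the column mean of the binary call matrix.
#'
#' @param matrix binary call matrix (patients x pathways).
#' @param pathway_id a column name.
#' @return A proportion in \[0, 1\].
#' @export
capture_rate <- function(matrix, pathway_id) {
  if (!pathway_id %in% colnames(matrix))
    stopf("unknown pathway '%s'", pathway_id)
  mean(matrix[, pathway_id])
}

#' Shuffle each patient's calls across pathways
#'
#' Independently permutes every row, preserving each patient's number of
#' enriched calls while decoupling pathway identities.
#'
#' @param matrix binary call matrix.
#' @param seed optional integer seed.
#' @return The shuffled matrix.
#' @export
shuffle_rows <- function(matrix, seed = NULL) {
  with_seed(seed, {
    t(apply(matrix, 1, sample))
  })
}

#' Empirical p-value for one pathway's capture rate
#'
#' Per replicate the rows are shuffled and one column is selected at random
#' as the synthetic null pathway; the p-value is the smoothed proportion of
#' null capture rates strictly exceeding the observed one.
#'
#' @param matrix binary call matrix.
#' @param pathway_id target pathway column.
#' @param B number of null replicates, default 2000.
#' @param seed optional integer seed.
#' @return List with `observed_rate`, `null_rates` (length B) and
#'   `empirical_p`.
#' @export
empirical_p_single <- function(matrix, pathway_id, B = 2000L, seed = NULL) {
  obs <- capture_rate(matrix, pathway_id)
  with_seed(seed, {
    null_rates <- vapply(seq_len(B), function(i) {
      shuf <- t(apply(matrix, 1, sample))
      mean(shuf[, sample.int(ncol(matrix), 1L)])
    }, 0)
    list(observed_rate = obs, null_rates = null_rates,
         empirical_p = (1 + sum(null_rates > obs)) / (B + 1))
  })
}

#' Empirical p-value for capturing at least one of k pathways
#'
#' Mirrors the cancer-pathway assessment: the observed rate is the fraction
#' of patients with at least one enriched call among the named pathways;
#' each null replicate shuffles the rows and draws `k` columns at random
#' without replacement.
#'
#' @param matrix binary call matrix.
#' @param pathway_ids target pathway columns (k = length, typically 9).
#' @param B number of null replicates, default 2000.
#' @param seed optional integer seed.
#' @return List with `observed_rate`, `null_rates` and `empirical_p`.
#' @export
empirical_p_any_of_k <- function(matrix, pathway_ids, B = 2000L,
                                 seed = NULL) {
  k <- length(pathway_ids)
  if (k > ncol(matrix))
    stopf("k = %d exceeds the %d available pathways", k, ncol(matrix))
  if (!all(pathway_ids %in% colnames(matrix)))
    stopf("unknown pathway in pathway_ids")
  obs <- mean(rowSums(matrix[, pathway_ids, drop = FALSE]) >= 1)
  with_seed(seed, {
    null_rates <- vapply(seq_len(B), function(i) {
      shuf <- t(apply(matrix, 1, sample))
      cols <- sample.int(ncol(matrix), k)
      mean(rowSums(shuf[, cols, drop = FALSE]) >= 1)
    }, 0)
    list(observed_rate = obs, null_rates = null_rates,
         empirical_p = (1 + sum(null_rates > obs)) / (B + 1))
  })
}

#' Cohort validation summary for a set of target pathways
#'
#' For each target pathway reports the capture rate, its empirical p-value,
#' and the median rank of the pathway across patients (rank by ascending
#' locFDR, ties broken by descending OR — the ordering of the profile
#' records). Small pathways carry more variable odds ratios; no correction
#' is applied for this, and a caveat is logged.
#'
#' @param profiles named list of `enrichment_profile` objects.
#' @param target_ids pathway ids to assess.
#' @param B,seed forwarded to [empirical_p_single()].
#' @return Data frame with one row per target.
#' @export
validate_cohort <- function(profiles, target_ids, B = 2000L, seed = NULL) {
  m <- call_matrix(profiles)
  n1pas_log("caveat: smaller pathways have more variable odds ratios; ",
            "capture rates are not adjusted for pathway size")
  seeds <- if (is.null(seed)) rep(list(NULL), length(target_ids))
           else as.list(seed + seq_along(target_ids) - 1L)
  rows <- lapply(seq_along(target_ids), function(i) {
    id <- target_ids[i]
    res <- empirical_p_single(m, id, B = B, seed = seeds[[i]])
    ranks <- vapply(profiles, function(p) {
      r <- match(id, p$records$pathway_id)
      if (is.na(r)) NA_real_ else as.numeric(r)
    }, 0)
    data.frame(pathway_id = id,
               n_scored_median = stats::median(
                 vapply(profiles, function(p) p$n_scored, 0L)),
               capture_rate = res$observed_rate,
               empirical_p = res$empirical_p,
               median_rank = stats::median(ranks, na.rm = TRUE))
  })
  do.call(rbind, rows)
}
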