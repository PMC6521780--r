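## Pathway-level enrichment of ASGs. For each gene set the classified genes
## are cross-tabulated as (ASG vs not) x (in pathway vs background) and the
## enrichment effect size is the cross-product odds ratio
##   OR = (a/b) / (c/d),
## a = ASGs in pathway, b = non-ASGs in pathway, c = ASGs in background,
## d = non-ASGs in background. The subject's ~200 pathway ORs form an
## empirical distribution to which the locFDR engine is fitted; a pathway
## is called enriched when OR > 1 and locFDR < 0.20.

#' Filter a gene-set collection by annotated size
#'
#' Retains sets whose annotated size (before intersection with any
#' expressed-gene universe) lies in `[min_size, max_size]`; defaults 15 and
#' 500 keep pathways interpretable and their odds ratios stable.
#'
#' @param collection a `gene_set_collection`.
#' @param min_size,max_size inclusive annotated-size bounds.
#' @return The filtered collection; errors if nothing survives.
#' @export
filter_gene_sets <- function(collection, min_size = 15L, max_size = 500L) {
  sizes <- vapply(collection, function(s) length(s$genes), 0L)
  keep <- sizes >= min_size & sizes <= max_size
  if (!any(keep))
    stopf("no gene set with annotated size in [%d, %d]", min_size, max_size)
  if (any(!keep))
    n1pas_log(sprintf("removed %d gene set(s) outside [%d, %d] genes",
                      sum(!keep), min_size, max_size))
  gene_set_collection(unclass(collection)[keep])
}

# Core 2x2 arithmetic on a logical call vector restricted to one pathway.
# a,b,c,d as documented above; any zero cell triggers the Haldane-Anscombe
# +0.5 correction (flagged), which keeps the OR finite for mixture fitting.
or_from_counts <- function(a, b, c, d) {
  corrected <- (a == 0 || b == 0 || c == 0 || d == 0)
  if (corrected) { a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5 }
  list(odds_ratio = (a / b) / (c / d), corrected = corrected)
}

#' Odds ratio of ASG over-representation in one pathway
#'
#' @param calls an `asg_calls` object from [classify_asg()].
#' @param pathway_genes character vector of the pathway's annotated genes.
#' @param min_expressed minimum classified (expressed-in-both-samples)
#'   genes the pathway must contain to be scored; default 15.
#' @return A one-row data frame with counts `a`,`b`,`c`,`d`, `odds_ratio`,
#'   `corrected` and `n_expressed`, or `NULL` when the pathway has fewer
#'   than `min_expressed` classified genes (skipped, not an error).
#' @export
pathway_odds_ratio <- function(calls, pathway_genes, min_expressed = 15L) {
  in_path <- names(calls$calls) %in% pathway_genes
  n_exp <- sum(in_path)
  if (n_exp < min_expressed) return(NULL)
  a <- sum(calls$calls[in_path])
  b <- n_exp - a
  total_asg <- sum(calls$calls)
  c <- total_asg - a
  d <- (calls$n_classified - n_exp) - c
  or <- or_from_counts(a, b, c, d)
  data.frame(a = a, b = b, c = c, d = d, odds_ratio = or$odds_ratio,
             corrected = or$corrected, n_expressed = n_exp)
}

#' Score every eligible pathway for one subject
#'
#' @param calls an `asg_calls` object.
#' @param collection a size-filtered `gene_set_collection`.
#' @param min_expressed expressed-gene rule per pathway (default 15).
#' @param min_scoreable minimum number of scored pathways needed for a
#'   meaningful locFDR family (default 50).
#' @return Data frame with one row per scored pathway (`pathway_id` plus
#'   the [pathway_odds_ratio()] columns); skipped pathways and reasons in
#'   attribute `skipped`.
#' @export
score_pathways <- function(calls, collection, min_expressed = 15L,
                           min_scoreable = 50L) {
  rows <- lapply(names(collection), function(id) {
    rec <- pathway_odds_ratio(calls, collection[[id]]$genes,
                              min_expressed = min_expressed)
    if (is.null(rec)) return(NULL)
    cbind(pathway_id = id, rec)
  })
  skipped <- names(collection)[vapply(rows, is.null, TRUE)]
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) < min_scoreable)
    stopf("only %d scoreable pathway(s); need at least %d for locFDR",
          length(rows), min_scoreable)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Run the full single-subject pipeline
#'
#' Composes TPM normalization, the 2-30 isoform filter, the Hellinger
#' profile, 2-means ASG classification, the 15-500 gene-set size filter,
#' per-pathway odds ratios, the locFDR fit over the OR family, and the
#' enrichment rule (OR > 1 and locFDR below `fdr_threshold`). Deterministic
#' given its inputs. A locFDR misfit propagates as an error of class
#' `n1pas_misfit` so cohort drivers can record it as an algorithm failure.
#'
#' @param table a [paired_isoforms] table (raw abundances are fine; TPM is
#'   applied internally).
#' @param collection a `gene_set_collection` (unfiltered is fine).
#' @param patient_id label stored in the profile.
#' @param fdr_threshold enrichment locFDR threshold, default 0.20.
#' @param or_scale scale on which the mixture is fitted: `"raw"` (the odds
#'   ratios themselves, the default — this is the scale on which the
#'   two-group mixture is described and it reproduces the method's
#'   published operating characteristics) or `"log"` (natural-log odds
#'   ratios, whose null is more nearly symmetric).
#' @param missing_rule forwarded to [distance_profile()].
#' @return An object of class `enrichment_profile`: list with `patient_id`,
#'   `records` (sorted by locFDR then descending OR), `n_scored`, `pi_all`,
#'   `threshold`, `locfdr_fit`, and `skipped`.
#' @export
run_n1pas <- function(table, collection, patient_id = "subject",
                      fdr_threshold = 0.20,
                      or_scale = c("raw", "log"),
                      missing_rule = "either") {
  or_scale <- match.arg(or_scale)
  table <- tpm_normalize(table)
  table <- filter_isoform_counts(table)
  profile <- distance_profile(table, missing_rule = missing_rule)
  calls <- classify_asg(profile)
  collection <- filter_gene_sets(collection)
  records <- score_pathways(calls, collection)
  finish_profile(records, calls, patient_id = patient_id,
                 fdr_threshold = fdr_threshold, or_scale = or_scale)
}

# Shared tail of the pipeline: locFDR over the OR family + enrichment rule.
finish_profile <- function(records, calls, patient_id = "subject",
                           fdr_threshold = 0.20, or_scale = "raw") {
  skipped <- attr(records, "skipped")
  z <- if (or_scale == "log") log(records$odds_ratio) else records$odds_ratio
  fit <- tryCatch(fit_locfdr(z), error = function(e) {
    e2 <- simpleError(conditionMessage(e))
    class(e2) <- c("n1pas_misfit", class(e2))
    stop(e2)
  })
  records$locfdr <- fit$fdr
  records$enriched <- records$odds_ratio > 1 & records$locfdr < fdr_threshold
  ord <- order(records$locfdr, -records$odds_ratio)
  records <- records[ord, , drop = FALSE]
  rownames(records) <- NULL
  structure(list(patient_id = patient_id, records = records,
                 n_scored = nrow(records), pi_all = calls$pi_all,
                 threshold = calls$threshold, locfdr_fit = fit,
                 skipped = skipped),
            class = "enrichment_profile")
}

#' @export
print.enrichment_profile <- function(x, ...) {
  cat(sprintf(
    "N1PAS profile for '%s': %d pathways scored, %d enriched (pi_all %.3f)\n",
    x$patient_id, x$n_scored, sum(x$records$enriched), x$pi_all))
  print(utils::head(x$records[, c("pathway_id", "n_expressed", "a",
                                  "odds_ratio", "locfdr", "enriched")]))
  invisible(x)
}
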