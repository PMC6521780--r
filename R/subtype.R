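## Survival-subtyping pipeline. Per-patient pathway odds ratios are
## aggregated into an N x P matrix, filtered to pathways enriched in at
## least one patient, and each remaining pathway is assessed one at a time:
## patients are split into two groups by partitioning around medoids (PAM,
## k = 2) on that pathway's OR column, Kaplan-Meier curves are compared by
## the log-rank test, and the log-rank p-value is referred to an empirical
## null built by shuffling each patient's ORs across pathways. The
## empirical p-values are BH-adjusted; pathways at FDR_BH < 0.20 are
## survival-relevant.

#' Assemble the cohort odds-ratio matrix
#'
#' Pathways scored in at least one patient are retained; a patient missing
#' a retained pathway gets the neutral value OR = 1, recorded in the
#' `imputed` attribute (a logical matrix of the same shape).
#'
#' @param profiles named list of `enrichment_profile` objects (>= 2).
#' @return Numeric patients x pathways matrix with attribute `imputed`.
#' @export
assemble_or_matrix <- function(profiles) {
  if (length(profiles) < 2) stopf("need at least 2 patients")
  ids <- names(profiles)
  if (is.null(ids)) ids <- vapply(profiles, function(p) p$patient_id, "")
  pathways <- sort(unique(unlist(
    lapply(profiles, function(p) p$records$pathway_id))))
  if (length(pathways) == 0) stopf("no pathway scored in any patient")
  m <- matrix(1, nrow = length(profiles), ncol = length(pathways),
              dimnames = list(ids, pathways))
  imputed <- matrix(TRUE, nrow = length(profiles), ncol = length(pathways),
                    dimnames = dimnames(m))
  for (i in seq_along(profiles)) {
    rec <- profiles[[i]]$records
    m[i, rec$pathway_id] <- rec$odds_ratio
    imputed[i, rec$pathway_id] <- FALSE
  }
  if (any(imputed))
    n1pas_log(sprintf("imputed OR = 1 for %d patient-pathway pair(s)",
                      sum(imputed)))
  attr(m, "imputed") <- imputed
  m
}

#' Keep only pathways enriched in at least one patient
#'
#' @param matrix OR matrix from [assemble_or_matrix()].
#' @param profiles the same profiles the matrix was built from.
#' @return The column-filtered matrix (P' columns).
#' @export
filter_significant <- function(matrix, profiles) {
  hit <- unique(unlist(lapply(profiles, function(p)
    p$records$pathway_id[p$records$enriched])))
  keep <- colnames(matrix) %in% hit
  if (!any(keep)) stopf("no pathway enriched in any patient")
  matrix[, keep, drop = FALSE]
}

#' Split patients into two groups by PAM
#'
#' Partitioning around medoids with k = 2 (deterministic BUILD + SWAP) on a
#' per-patient feature vector or matrix, Euclidean distance. For the
#' multivariate alternative feature modes set `standardize = TRUE` to
#' z-scale each feature across patients first.
#'
#' @param values numeric vector (one value per patient) or matrix
#'   (patients x features).
#' @param standardize z-scale columns before clustering (default FALSE).
#' @param seed accepted for API symmetry with stochastic stages; PAM with
#'   deterministic BUILD + SWAP never consumes randomness, so it is unused.
#' @return List with `labels` (integer 1/2 per patient; group 1 has the
#'   lower medoid in 1-D) and `medoids`.
#' @export
cluster_two <- function(values, standardize = FALSE, seed = NULL) {
  x <- if (is.matrix(values)) values else matrix(values, ncol = 1)
  if (nrow(x) < 4) stopf("need at least 4 patients to cluster")
  if (all(apply(x, 2, function(col) max(col) == min(col))))
    stopf("zero variance: cannot split patients")
  if (standardize) {
    x <- apply(x, 2, function(col) {
      s <- stats::sd(col)
      if (s == 0) rep(0, length(col)) else (col - mean(col)) / s
    })
  }
  fit <- cluster::pam(x, k = 2, metric = "euclidean", keep.diss = FALSE,
                      keep.data = FALSE)
  labels <- fit$clustering
  medoids <- fit$medoids
  if (!is.matrix(values) && medoids[1, 1] > medoids[2, 1]) {
    labels <- 3L - labels          # group 1 = lower-OR medoid in 1-D
    medoids <- medoids[2:1, , drop = FALSE]
  }
  if (!is.null(rownames(x))) names(labels) <- rownames(x)
  list(labels = labels, medoids = medoids)
}

#' Kaplan-Meier curves and two-sample log-rank test
#'
#' @param labels two-group assignment per patient (named by patient id, or
#'   aligned with `survival$patient_id`).
#' @param survival a `survival_table` covering the labelled patients.
#' @return List with `fit` (a [survival::survfit] object), `chisq` and
#'   `logrank_p` (1 df).
#' @export
km_logrank <- function(labels, survival) {
  if (!is.null(names(labels))) {
    idx <- match(names(labels), survival$patient_id)
    if (anyNA(idx)) stopf("labelled patient missing from survival table")
    survival <- survival[idx, , drop = FALSE]
  } else if (length(labels) != nrow(survival)) {
    stopf("labels and survival table disagree on patients")
  }
  if (length(unique(labels)) != 2 || min(table(labels)) == 0)
    stopf("both groups must be non-empty")
  if (sum(survival$event) == 0) stopf("no events observed")
  df <- data.frame(time = survival$time, event = survival$event,
                   group = factor(labels))
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  list(fit = survival::survfit(survival::Surv(time, event) ~ group,
                               data = df),
       chisq = sd$chisq,
       logrank_p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

# Restricted-mean survival time of each group, used to orient the
# Better/Worse labels automatically (the group with the higher RMST over
# the common follow-up window is "Better").
group_rmst <- function(labels, survival) {
  if (!is.null(names(labels))) {
    survival <- survival[match(names(labels), survival$patient_id), ,
                         drop = FALSE]
  }
  tau <- max(survival$time)
  vapply(sort(unique(labels)), function(g) {
    s <- survival[labels == g, , drop = FALSE]
    f <- survival::survfit(survival::Surv(time, event) ~ 1, data = s)
    t_all <- c(0, pmin(f$time, tau), tau)
    surv <- c(1, f$surv, utils::tail(f$surv, 1))
    sum(diff(t_all) * surv[-length(surv)])
  }, 0)
}

#' Empirical null for one pathway's survival separation
#'
#' Per replicate each patient's odds ratios are independently shuffled
#' across the P' pathways, the target column is re-clustered and the
#' log-rank p-value recomputed; the empirical p-value is the smoothed
#' fraction of null p-values at or below the observed one. Replicates
#' where clustering degenerates (zero variance) are redrawn, with a count.
#'
#' @param matrix filtered OR matrix (patients x P').
#' @param survival a `survival_table`.
#' @param pathway_id target column.
#' @param B replicates, default 2000.
#' @param seed optional integer seed.
#' @return List with `observed_p`, `null_p` (length B), `empirical_p`,
#'   `n_redrawn`.
#' @export
empirical_null_survival <- function(matrix, survival, pathway_id,
                                    B = 2000L, seed = NULL) {
  obs <- km_logrank(stats::setNames(
    cluster_two(matrix[, pathway_id])$labels, rownames(matrix)),
    survival)$logrank_p
  with_seed(seed, {
    n_redrawn <- 0L
    null_p <- vapply(seq_len(B), function(i) {
      repeat {
        shuf <- t(apply(matrix, 1, sample))
        col <- shuf[, match(pathway_id, colnames(matrix))]
        p <- tryCatch({
          lab <- stats::setNames(cluster_two(col)$labels, rownames(matrix))
          km_logrank(lab, survival)$logrank_p
        }, error = function(e) NA_real_)
        if (!is.na(p)) return(p)
        n_redrawn <<- n_redrawn + 1L
      }
    }, 0)
    if (n_redrawn > 0)
      n1pas_log(sprintf("redrew %d degenerate null replicate(s)", n_redrawn))
    list(observed_p = obs, null_p = null_p,
         empirical_p = (1 + sum(null_p <= obs)) / (B + 1),
         n_redrawn = n_redrawn)
  })
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin wrapper over [stats::p.adjust()] with input validation; pathways at
#' `fdr_bh < 0.20` are flagged survival-relevant downstream.
#'
#' @param pvals p-values in (0, 1\].
#' @return Adjusted values (monotone, capped at 1).
#' @export
bh_adjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals <= 0 | pvals > 1))
    stopf("p-values must lie in (0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Odds-ratio decision threshold between two patient groups
#'
#' The clinical cutoff: midpoint between the lower group's maximum and the
#' upper group's minimum. Defined only when the groups' 1-D value ranges do
#' not overlap or touch; otherwise `NA` with a warning.
#'
#' @param values per-patient values (e.g. one pathway's ORs).
#' @param labels two-group assignment aligned with `values`.
#' @return The midpoint, or `NA`.
#' @export
decision_threshold <- function(values, labels) {
  g <- sort(unique(labels))
  if (length(g) != 2) stopf("need exactly two groups")
  v1 <- values[labels == g[1]]; v2 <- values[labels == g[2]]
  if (mean(v1) > mean(v2)) { tmp <- v1; v1 <- v2; v2 <- tmp }
  if (max(v1) >= min(v2)) {
    warning("group value ranges overlap; decision threshold undefined",
            call. = FALSE)
    return(NA_real_)
  }
  (max(v1) + min(v2)) / 2
}

#' Jaccard agreement between two subtype assignments
#'
#' @param labels_1,labels_2 named label vectors over the same patients.
#' @param subtype the label value whose member sets are compared.
#' @return |intersection| / |union| of the two member sets.
#' @export
jaccard_agreement <- function(labels_1, labels_2, subtype) {
  g1 <- names(labels_1)[labels_1 == subtype]
  g2 <- names(labels_2)[labels_2 == subtype]
  u <- union(g1, g2)
  if (length(u) == 0) stopf("both subtype member sets are empty")
  length(intersect(g1, g2)) / length(u)
}

#' Per-pathway feature matrices for the alternative clustering inputs
#'
#' Besides the N1PAS odds ratio (`n1pas_or`, one feature), patients can be
#' clustered on the pathway's raw tumour isoform TPMs (`tumor_expr`), the
#' tumour-minus-normal isoform TPMs (`diff_expr`), or the pathway genes'
#' Hellinger distances (`gene_hellinger`, missing distances imputed with
#' the patient's mean distance across all genes).
#'
#' @param mode one of `"n1pas_or"`, `"tumor_expr"`, `"diff_expr"`,
#'   `"gene_hellinger"`.
#' @param pathway_id target pathway.
#' @param or_matrix OR matrix (needed for `n1pas_or`).
#' @param tables named list of TPM-normalized [paired_isoforms] tables per
#'   patient (expression modes).
#' @param profiles named list of `hellinger_profile` objects per patient
#'   (`gene_hellinger` mode).
#' @param collection the `gene_set_collection` defining pathway membership.
#' @return Patients x features numeric matrix.
#' @export
build_feature_matrix <- function(mode = c("n1pas_or", "tumor_expr",
                                          "diff_expr", "gene_hellinger"),
                                 pathway_id, or_matrix = NULL,
                                 tables = NULL, profiles = NULL,
                                 collection = NULL) {
  mode <- match.arg(mode)
  if (mode == "n1pas_or") {
    if (is.null(or_matrix)) stopf("n1pas_or mode needs or_matrix")
    return(or_matrix[, pathway_id, drop = FALSE])
  }
  genes <- collection[[pathway_id]]$genes
  if (is.null(genes)) stopf("unknown pathway '%s'", pathway_id)
  if (mode %in% c("tumor_expr", "diff_expr")) {
    if (is.null(tables)) stopf("%s mode needs per-patient tables", mode)
    iso_ids <- sort(unique(unlist(lapply(tables, function(tb)
      tb$isoform_id[tb$gene_id %in% genes]))))
    if (length(iso_ids) == 0) stopf("pathway has no isoforms in this mode")
    m <- vapply(tables, function(tb) {
      i <- match(iso_ids, tb$isoform_id)
      val <- if (mode == "tumor_expr") tb$abundance_B[i]
             else tb$abundance_B[i] - tb$abundance_A[i]
      ifelse(is.na(val), 0, val)
    }, numeric(length(iso_ids)))
    m <- matrix(m, ncol = length(iso_ids), byrow = TRUE,
                dimnames = list(names(tables), iso_ids))
    return(m)
  }
  # gene_hellinger
  if (is.null(profiles)) stopf("gene_hellinger mode needs profiles")
  gene_ids <- sort(unique(unlist(lapply(profiles, function(p)
    p$gene_id[p$gene_id %in% genes]))))
  if (length(gene_ids) == 0) stopf("pathway has no measured genes")
  m <- vapply(profiles, function(p) {
    d <- p$distance[match(gene_ids, p$gene_id)]
    d[is.na(d)] <- mean(p$distance, na.rm = TRUE)
    d
  }, numeric(length(gene_ids)))
  matrix(m, ncol = length(gene_ids), byrow = TRUE,
         dimnames = list(names(profiles), gene_ids))
}

#' Run the whole survival-subtyping pipeline
#'
#' @param profiles named list of `enrichment_profile` objects.
#' @param survival a `survival_table` covering the patients.
#' @param B empirical-null replicates per pathway (default 2000).
#' @param seed optional integer seed.
#' @param fdr_threshold survival-relevance threshold on FDR_BH (0.20).
#' @return Data frame of class `subtype_result` ranked by empirical
#'   p-value: pathway, log-rank p, empirical p, `fdr_bh`,
#'   `survival_relevant`, group sizes, Better/Worse orientation, decision
#'   threshold; per-pathway labels in attribute `labels`.
#' @export
subtype_pathways <- function(profiles, survival, B = 2000L, seed = NULL,
                             fdr_threshold = 0.20) {
  m <- assemble_or_matrix(profiles)
  m <- filter_significant(m, profiles)
  ids <- colnames(m)
  seeds <- if (is.null(seed)) rep(list(NULL), length(ids))
           else as.list(seed + seq_along(ids) - 1L)
  labels_list <- list()
  rows <- lapply(seq_along(ids), function(j) {
    id <- ids[j]
    cl <- cluster_two(m[, id])
    labels <- stats::setNames(cl$labels, rownames(m))
    rm <- group_rmst(labels, survival)
    better <- which.max(rm)
    named <- ifelse(labels == better, "Better", "Worse")
    labels_list[[id]] <<- stats::setNames(named, names(labels))
    lr <- km_logrank(labels, survival)
    emp <- empirical_null_survival(m, survival, id, B = B,
                                   seed = seeds[[j]])
    data.frame(pathway_id = id,
               logrank_p = lr$logrank_p,
               empirical_p = emp$empirical_p,
               n_better = sum(named == "Better"),
               n_worse = sum(named == "Worse"),
               or_threshold = suppressWarnings(
                 decision_threshold(m[, id], labels)))
  })
  out <- do.call(rbind, rows)
  out$fdr_bh <- bh_adjust(out$empirical_p)
  out$survival_relevant <- out$fdr_bh < fdr_threshold
  out <- out[order(out$empirical_p, out$logrank_p), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "labels") <- labels_list
  class(out) <- c("subtype_result", "data.frame")
  out
}
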