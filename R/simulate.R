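## Monte-Carlo harness for operating characteristics. A patient is
## represented by their pool of per-gene Hellinger distances. Each
## replicate (a) permutes gene labels so distances no longer aggregate
## meaningfully into pathways, (b) picks a "specified" pathway with
## expressed size in [G, G + 5], (c) plants an ASG excess pi above the
## patient's background pi_all by reassigning m = round(G * (pi + pi_all))
## of its gene labels values drawn from the patient's ASG pool (the rest
## from the non-ASG pool), then (d) reruns the full classification +
## enrichment + locFDR machinery over all pathways. pi = 0 replicates give
## false-positive rates; pi > 0 replicates give power as the detection rate
## of the specified pathway. locFDR misfits are recorded as failures and
## excluded from summaries.

#' Permute gene labels of a Hellinger profile
#'
#' Shuffles the assignment of distances to gene ids, preserving the
#' multiset of values (and hence the 2-means threshold and pi_all).
#'
#' @param profile a `hellinger_profile`.
#' @param seed optional integer seed.
#' @return The permuted profile.
#' @export
permute_gene_labels <- function(profile, seed = NULL) {
  with_seed(seed, {
    perm <- sample.int(nrow(profile))
    profile$distance <- profile$distance[perm]
    profile$n_isoforms <- profile$n_isoforms[perm]
    profile
  })
}

#' Select the specified pathway for one replicate
#'
#' Uniform choice among pathways whose expressed size (genes with a
#' non-missing distance in the profile) lies in `[G, G + size_window]`.
#'
#' @param collection a `gene_set_collection`.
#' @param profile a `hellinger_profile` defining expressed genes.
#' @param G nominal pathway size from the simulation grid.
#' @param size_window how many genes larger than `G` a pathway may be
#'   (default 5).
#' @param seed optional integer seed.
#' @return A pathway id.
#' @export
select_specified_pathway <- function(collection, profile, G,
                                     size_window = 5L, seed = NULL) {
  expressed <- profile$gene_id[!is.na(profile$distance)]
  sizes <- vapply(collection, function(s) sum(s$genes %in% expressed), 0L)
  eligible <- names(collection)[sizes >= G & sizes <= G + size_window]
  if (length(eligible) == 0)
    stopf("no pathway with expressed size in [%d, %d]", G, G + size_window)
  with_seed(seed, eligible[sample.int(length(eligible), 1L)])
}

#' Plant an ASG excess inside one pathway
#'
#' Reassigns `m = round(G * (pi + pi_all))` randomly chosen expressed genes
#' of the pathway distances sampled (with replacement) from the patient's
#' ASG value pool, and the remaining pathway genes values from the non-ASG
#' pool; genes outside the pathway are untouched.
#'
#' @param profile a (typically label-permuted) `hellinger_profile`.
#' @param calls the patient's `asg_calls` (defines the two value pools and
#'   pi_all).
#' @param pathway_genes the specified pathway's genes.
#' @param pi ASG excess over background; `pi + pi_all` must be <= 1.
#' @param G nominal pathway size; defaults to the expressed size.
#' @param seed optional integer seed.
#' @return The modified profile.
#' @export
induce_enrichment <- function(profile, calls, pathway_genes, pi,
                              G = NULL, seed = NULL) {
  if (pi + calls$pi_all > 1)
    stopf("pi + pi_all = %.3f exceeds 1", pi + calls$pi_all)
  pool_values <- profile_pool_values(calls)
  if (length(pool_values$asg) == 0) stopf("empty ASG pool")
  idx <- which(profile$gene_id %in% pathway_genes & !is.na(profile$distance))
  if (is.null(G)) G <- length(idx)
  m <- min(round(G * (pi + calls$pi_all)), length(idx))
  with_seed(seed, {
    chosen <- if (m > 0) sample(idx, m) else integer(0)
    rest <- setdiff(idx, chosen)
    profile$distance[chosen] <- sample(pool_values$asg, m, replace = TRUE)
    profile$distance[rest] <- sample(pool_values$non_asg, length(rest),
                                     replace = TRUE)
    profile
  })
}

# The two value pools implied by a classification.
profile_pool_values <- function(calls) {
  list(asg = unname(calls$values[calls$calls]),
       non_asg = unname(calls$values[!calls$calls]))
}

#' Precompute per-patient simulation state
#'
#' Classifies the patient's pool once (giving pi_all and the ASG/non-ASG
#' value pools) and indexes pathway membership against the expressed
#' genes, so each replicate only permutes, plants, reclassifies and
#' rescoring stays cheap.
#'
#' @param profile the patient's `hellinger_profile` (the distance pool).
#' @param collection a size-filtered `gene_set_collection`.
#' @param min_expressed expressed-gene rule for scoring (default 15).
#' @return An object of class `n1pas_sim_prep`.
#' @export
prepare_simulation <- function(profile, collection, min_expressed = 15L) {
  d <- profile$distance
  keep <- !is.na(d)
  d <- d[keep]
  genes <- profile$gene_id[keep]
  calls <- classify_asg(d)
  memb <- lapply(collection, function(s) which(genes %in% s$genes))
  sizes <- lengths(memb)
  scoreable <- sizes >= min_expressed
  structure(list(values = d, genes = genes,
                 pi_all = calls$pi_all,
                 asg_pool = d[d >= calls$threshold],
                 non_asg_pool = d[d < calls$threshold],
                 memb = memb[scoreable],
                 sizes = sizes[scoreable],
                 pathway_ids = names(collection)[scoreable]),
            class = "n1pas_sim_prep")
}

#' Run one simulation replicate
#'
#' @param prep an `n1pas_sim_prep` from [prepare_simulation()].
#' @param G nominal pathway size, one of the simulation grid values.
#' @param pi ASG excess over background (0 for false-positive runs).
#' @param size_window eligibility window above `G` (default 5).
#' @param fdr_threshold enrichment rule threshold (default 0.20).
#' @param or_scale analysis scale of the mixture fit, as in [run_n1pas()].
#' @return A one-row data frame: `specified_pathway`, `detected`,
#'   `n_detected`, `n_scored`, `failed`. Uses the current RNG stream; seed
#'   at the harness level.
#' @export
run_replicate <- function(prep, G, pi, size_window = 5L,
                          fdr_threshold = 0.20,
                          or_scale = c("raw", "log")) {
  or_scale <- match.arg(or_scale)
  eligible <- which(prep$sizes >= G & prep$sizes <= G + size_window)
  if (length(eligible) == 0)
    stopf("no pathway with expressed size in [%d, %d]", G, G + size_window)
  target <- eligible[sample.int(length(eligible), 1L)]

  h <- sample(prep$values)                      # permute gene labels
  idx <- prep$memb[[target]]
  # plant against the pathway's actual expressed size G* (in [G, G+5]) so
  # the induced ASG proportion is pi + pi_all regardless of which eligible
  # pathway was drawn
  m <- min(round(length(idx) * (pi + prep$pi_all)), length(idx))
  chosen <- if (m > 0) idx[sample.int(length(idx), m)] else integer(0)
  rest <- setdiff(idx, chosen)
  h[chosen] <- sample(prep$asg_pool, m, replace = TRUE)
  h[rest] <- sample(prep$non_asg_pool, length(rest), replace = TRUE)

  fit2 <- two_means_threshold(h)
  calls <- h >= fit2$threshold
  total_asg <- sum(calls)
  n_total <- length(calls)

  a <- vapply(prep$memb, function(ix) sum(calls[ix]), 0L)
  n_exp <- prep$sizes
  b <- n_exp - a
  cc <- total_asg - a
  d <- (n_total - n_exp) - cc
  zero <- a == 0L | b == 0L | cc == 0L | d == 0L
  or <- ifelse(zero,
               ((a + 0.5) / (b + 0.5)) / ((cc + 0.5) / (d + 0.5)),
               (a / b) / (cc / d))

  res <- tryCatch({
    fit <- fit_locfdr(if (or_scale == "log") log(or) else or)
    enriched <- or > 1 & fit$fdr < fdr_threshold
    data.frame(specified_pathway = prep$pathway_ids[target],
               detected = enriched[target],
               n_detected = sum(enriched),
               n_scored = length(or), failed = FALSE)
  }, error = function(e) {
    data.frame(specified_pathway = prep$pathway_ids[target],
               detected = NA, n_detected = NA_integer_,
               n_scored = length(or), failed = TRUE)
  })
  rownames(res) <- NULL
  res
}

#' Run the Monte-Carlo grid for one patient
#'
#' @param profile the patient's `hellinger_profile` distance pool.
#' @param collection a `gene_set_collection` (size-filtered internally).
#' @param G_values nominal pathway sizes (default `c(15, 30, 50, 100)`).
#' @param pi_values ASG excesses (default `c(0, 0.05, 0.10, 0.15, 0.20)`).
#' @param replicates replicates per (G, pi) cell (default 100).
#' @param seed optional integer seed for the whole grid.
#' @param size_window,fdr_threshold,or_scale forwarded to
#'   [run_replicate()].
#' @return Long data frame: `G`, `pi`, `replicate` plus the
#'   [run_replicate()] columns.
#' @export
run_simulation <- function(profile, collection,
                           G_values = c(15L, 30L, 50L, 100L),
                           pi_values = c(0, 0.05, 0.10, 0.15, 0.20),
                           replicates = 100L, seed = NULL,
                           size_window = 5L, fdr_threshold = 0.20,
                           or_scale = c("raw", "log")) {
  or_scale <- match.arg(or_scale)
  prep <- prepare_simulation(profile, filter_gene_sets(collection))
  with_seed(seed, {
    grid <- expand.grid(G = G_values, pi = pi_values)
    out <- lapply(seq_len(nrow(grid)), function(g) {
      rows <- lapply(seq_len(replicates), function(r) {
        cbind(G = grid$G[g], pi = grid$pi[g], replicate = r,
              run_replicate(prep, grid$G[g], grid$pi[g],
                            size_window = size_window,
                            fdr_threshold = fdr_threshold,
                            or_scale = or_scale))
      })
      do.call(rbind, rows)
    })
    do.call(rbind, out)
  })
}

#' Summarize simulation results across patients
#'
#' Per (G, pi) cell and per patient, failures are dropped, the
#' false-positive rate is the mean of `n_detected / n_scored` (pi = 0
#' rows) and power is the mean of `detected` (pi > 0 rows). Patient means
#' are then averaged with a normal-approximation 95% confidence interval
#' using the across-patient standard error.
#'
#' @param results long data frame with a `patient` column plus
#'   [run_simulation()] columns.
#' @return Data frame: `G`, `pi`, `n_patients`, `mean_rate`, `se`,
#'   `ci_lower`, `ci_upper`, `failure_rate`, `measure` ("false_positive"
#'   or "power").
#' @export
summarize_simulation <- function(results) {
  cells <- split(results, interaction(results$G, results$pi, drop = TRUE))
  rows <- lapply(cells, function(cell) {
    per_patient <- vapply(split(cell, cell$patient), function(p) {
      ok <- !p$failed
      if (p$pi[1] == 0) mean(p$n_detected[ok] / p$n_scored[ok])
      else mean(p$detected[ok])
    }, 0)
    n <- length(per_patient)
    m <- mean(per_patient)
    se <- if (n >= 2) stats::sd(per_patient) / sqrt(n) else NA_real_
    data.frame(G = cell$G[1], pi = cell$pi[1], n_patients = n,
               mean_rate = m, se = se,
               ci_lower = m - 1.96 * se, ci_upper = m + 1.96 * se,
               failure_rate = mean(cell$failed),
               measure = if (cell$pi[1] == 0) "false_positive" else "power")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$G, out$pi), , drop = FALSE]
}

#' Multi-patient operating-characteristics study
#'
#' Generates a cohort of synthetic patients (Hellinger-distance pools) and
#' one shared synthetic gene-set collection, then runs the Monte-Carlo grid
#' for every patient. The collection is validated against the requested
#' `G_values` first: a draw whose sizes leave some arm with no eligible
#' pathway is redrawn from the seed stream (eligibility depends only on
#' set sizes, so this cannot bias the measured rates); the number of
#' redraws is logged.
#'
#' @param n_patients number of synthetic patients (default 20).
#' @param spec a [generator_spec()].
#' @param G_values,pi_values,replicates,size_window,fdr_threshold,or_scale
#'   forwarded to [run_simulation()].
#' @param seed integer seed for the whole study.
#' @return Long data frame with a `patient` column plus the
#'   [run_simulation()] columns; summarize with [summarize_simulation()].
#' @export
operating_characteristics <- function(n_patients = 20L,
                                      spec = generator_spec(),
                                      G_values = c(15L, 30L, 50L, 100L),
                                      pi_values = c(0, 0.05, 0.10, 0.15,
                                                    0.20),
                                      replicates = 100L, seed = NULL,
                                      size_window = 5L,
                                      fdr_threshold = 0.20,
                                      or_scale = c("raw", "log")) {
  or_scale <- match.arg(or_scale)
  base <- if (is.null(seed)) 0L else as.integer(seed)
  collection <- NULL
  for (try in 0:50) {
    cand <- filter_gene_sets(gen_gene_sets(spec, seed = base + try))
    sizes <- vapply(cand, function(s) length(s$genes), 0L)
    ok <- all(vapply(G_values, function(G)
      any(sizes >= G & sizes <= G + size_window), TRUE))
    if (ok) { collection <- cand; break }
  }
  if (is.null(collection))
    stopf("could not draw a collection covering all G arms")
  if (try > 0)
    n1pas_log(sprintf("redrew the gene-set collection %d time(s) to cover ",
                      try), "every pathway-size arm")
  out <- lapply(seq_len(n_patients), function(i) {
    pool <- gen_distance_pools(spec, seed = base + 1000L + i)
    res <- run_simulation(pool$profile, collection, G_values = G_values,
                          pi_values = pi_values, replicates = replicates,
                          seed = base + 2000L + i,
                          size_window = size_window,
                          fdr_threshold = fdr_threshold,
                          or_scale = or_scale)
    cbind(patient = sprintf("sim%03d", i), res)
  })
  do.call(rbind, out)
}
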