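test_that("OR matrix assembly imputes unscored pathways at 1", {
  profs <- list(
    p1 = make_profile_stub("p1", c("A", "B"), c(2, 0.5), c(TRUE, FALSE)),
    p2 = make_profile_stub("p2", c("A", "C"), c(1.5, 3), c(FALSE, TRUE)),
    p3 = make_profile_stub("p3", c("A", "B", "C"), c(1, 1, 1),
                           c(FALSE, FALSE, FALSE)))
  suppressMessages(m <- assemble_or_matrix(profs))
  expect_equal(dim(m), c(3, 3))
  expect_equal(m["p1", "C"], 1)
  expect_true(attr(m, "imputed")["p1", "C"])
  expect_false(attr(m, "imputed")["p1", "A"])
  # filter to pathways enriched in >= 1 patient drops B
  mf <- filter_significant(m, profs)
  expect_setequal(colnames(mf), c("A", "C"))
  expect_error(assemble_or_matrix(profs[1]), "at least 2")
})

test_that("PAM with k = 2 splits clearly separated 1-D values", {
  cl <- cluster_two(c(1, 1, 1, 5, 5))
  expect_equal(cl$labels, c(1, 1, 1, 2, 2))
  expect_error(cluster_two(rep(2, 6)), "zero variance")
  expect_error(cluster_two(c(1, 5)), "at least 4")
  # symmetric two-group data splits into the two groups
  cl2 <- cluster_two(c(0.1, 0.2, 0.15, 3.1, 3.2, 3.15))
  expect_equal(cl2$labels, c(1, 1, 1, 2, 2, 2))
})

test_that("log-rank matches the hypergeometric-increment oracle", {
  t1 <- c(1, 2, 3, 4, 5, 6)
  ev <- rep(1L, 6)
  gr <- rep(1:2, each = 3)
  sv <- survival_table(sprintf("p%d", 1:6), t1, ev)
  res <- km_logrank(stats::setNames(gr, sv$patient_id), sv)
  expect_equal(res$chisq, logrank_chisq_oracle(t1, ev, gr),
               tolerance = 1e-9)
  # random censored data sets, same agreement
  set.seed(701)
  for (i in 1:20) {
    n <- sample(10:40, 1)
    tm <- round(rexp(n, 0.1), 3) + 0.001
    e <- rbinom(n, 1, 0.7)
    if (sum(e) == 0) e[1] <- 1L
    g <- sample(1:2, n, replace = TRUE)
    if (length(unique(g)) < 2) g[1:2] <- 1:2
    sv <- survival_table(sprintf("p%d", 1:n), tm, e)
    res <- km_logrank(stats::setNames(g, sv$patient_id), sv)
    expect_equal(res$chisq, logrank_chisq_oracle(tm, e, g),
                 tolerance = 1e-8)
  }
})

test_that("log-rank degenerate inputs behave as specified", {
  # identical survival in both groups: statistic 0, p = 1
  sv <- survival_table(sprintf("p%d", 1:4), c(1, 2, 1, 2), c(1, 1, 1, 1))
  res <- km_logrank(stats::setNames(c(1, 1, 2, 2), sv$patient_id), sv)
  expect_equal(res$chisq, 0, tolerance = 1e-12)
  expect_equal(res$logrank_p, 1)
  # KM curves are nonincreasing step functions bounded by 1
  expect_true(all(res$fit$surv <= 1))
  surv_by <- split(res$fit$surv, rep(seq_along(res$fit$strata),
                                     res$fit$strata))
  for (sb in surv_by) expect_true(!is.unsorted(rev(sb)))
  # no events at all is an error
  sv0 <- survival_table(sprintf("p%d", 1:4), c(1, 2, 3, 4), rep(0L, 4))
  expect_error(km_logrank(stats::setNames(c(1, 1, 2, 2), sv0$patient_id),
                          sv0), "no events")
})

test_that("BH adjustment reproduces the step-up arithmetic", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 0)), "p-values")
  # monotone in input ranks, bounded by 1
  set.seed(702)
  p <- runif(30)
  adj <- bh_adjust(p)
  expect_true(all(adj <= 1))
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
})

test_that("decision thresholds are midpoints of separable groups", {
  expect_equal(decision_threshold(c(0.8, 0.9, 1.4, 1.6),
                                  c(1, 1, 2, 2)), 1.15)
  expect_equal(decision_threshold(c(1, 3), c(1, 2)), 2)
  expect_warning(thr <- decision_threshold(c(1, 2, 2, 3), c(1, 1, 2, 2)),
                 "overlap")
  expect_true(is.na(thr))
})

test_that("Jaccard agreement follows set arithmetic", {
  l1 <- stats::setNames(rep("W", 3), c("p1", "p2", "p3"))
  l2 <- stats::setNames(rep("W", 3), c("p2", "p3", "p4"))
  expect_equal(jaccard_agreement(l1, l2, "W"), 0.5)
  expect_equal(jaccard_agreement(l1, l1, "W"), 1)
  l3 <- stats::setNames(rep("W", 2), c("p8", "p9"))
  expect_equal(jaccard_agreement(l1, l3, "W"), 0)
  expect_error(jaccard_agreement(l1, l2, "B"), "empty")
})

test_that("alternative feature modes extract the documented features", {
  spec <- generator_spec(n_genes = 60, n_pathways = 3,
                         pathway_size_range = c(5, 10), zero_rate = 0.1)
  tables <- list(); hprofs <- list()
  for (i in 1:4) {
    g <- gen_paired_isoforms(spec, seed = 720 + i)
    tables[[sprintf("pt%d", i)]] <- tpm_normalize(g$table)
    hprofs[[sprintf("pt%d", i)]] <- distance_profile(
      filter_isoform_counts(tables[[i]]))
  }
  gs <- gen_gene_sets(spec, seed = 725)
  id <- names(gs)[1]
  mt <- build_feature_matrix("tumor_expr", id, tables = tables,
                             collection = gs)
  expect_equal(nrow(mt), 4)
  md <- build_feature_matrix("diff_expr", id, tables = tables,
                             collection = gs)
  expect_equal(dim(md), dim(mt))
  # difference mode really is tumor minus normal
  tb1 <- tables[[1]]
  iso <- colnames(mt)[1]
  i1 <- match(iso, tb1$isoform_id)
  expect_equal(md[1, iso], tb1$abundance_B[i1] - tb1$abundance_A[i1])
  mh <- build_feature_matrix("gene_hellinger", id, profiles = hprofs,
                             collection = gs)
  expect_equal(nrow(mh), 4)
  # missing distances imputed with the patient's mean distance
  p1 <- hprofs[[1]]
  miss_genes <- intersect(p1$gene_id[is.na(p1$distance)], colnames(mh))
  if (length(miss_genes) > 0)
    expect_equal(unname(mh[1, miss_genes[1]]),
                 mean(p1$distance, na.rm = TRUE))
})

test_that("a planted survival-relevant pathway is recovered", {
  # OR split carries a hazard ratio of 4 at N = 50, ~60% events; the
  # pipeline should flag the planted pathway in most seeds
  hits <- 0
  for (s in 1:10) {
    set.seed(730 + s)
    n <- 50
    ids <- sprintf("pt%02d", 1:n)
    worse <- rep(c(TRUE, FALSE), length.out = n)
    profs <- lapply(seq_len(n), function(i) {
      or <- exp(rnorm(12, 0, 0.25))
      or[1] <- if (worse[i]) runif(1, 0.4, 0.7) else runif(1, 1.8, 2.6)
      make_profile_stub(ids[i], sprintf("P%02d", 1:12), or,
                        c(TRUE, runif(11) < 0.08))
    })
    names(profs) <- ids
    sv <- gen_survival(stats::setNames(worse, ids),
                       generator_spec(hazard_ratio = 4, censor_rate = 0.4),
                       seed = 760 + s)
    suppressMessages(
      res <- subtype_pathways(profs, sv, B = 99, seed = 790 + s))
    if (res$survival_relevant[res$pathway_id == "P01"]) hits <- hits + 1
  }
  expect_gte(hits, 8)
})

test_that("the pipeline stays quiet when survival is independent of ORs", {
  # null calibration: features carry no survival signal, so few pathways
  # should pass the FDR_BH < 0.20 gate
  fracs <- vapply(1:5, function(s) {
    set.seed(800 + s)
    n <- 40
    ids <- sprintf("pt%02d", 1:n)
    profs <- lapply(seq_len(n), function(i)
      make_profile_stub(ids[i], sprintf("P%02d", 1:10),
                        exp(rnorm(10, 0, 0.3)), runif(10) < 0.15))
    names(profs) <- ids
    sv <- gen_survival(stats::setNames(rep(FALSE, n), ids),
                       generator_spec(censor_rate = 0.3), seed = 830 + s)
    suppressMessages(
      res <- subtype_pathways(profs, sv, B = 99, seed = 860 + s))
    mean(res$survival_relevant)
  }, 0)
  expect_lte(mean(fracs), 0.25)
})
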