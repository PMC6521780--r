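test_that("gene-set size filter keeps 15-500 annotated genes inclusive", {
  mk <- function(n) list(description = "d", genes = sprintf("g%03d", 1:n))
  coll <- gene_set_collection(list(p14 = mk(14), p15 = mk(15),
                                   p500 = mk(500), p501 = mk(501)))
  expect_message(out <- filter_gene_sets(coll), "removed 2")
  expect_setequal(names(out), c("p15", "p500"))
  expect_error(filter_gene_sets(gene_set_collection(list(p1 = mk(5)))),
               "no gene set")
})

test_that("pathway odds ratio reproduces the cross-product arithmetic", {
  genes <- sprintf("g%04d", 1:1020)
  in_path <- genes[1:20]
  calls <- make_calls(stats::setNames(
    c(rep(TRUE, 10), rep(FALSE, 10),          # a = 10, b = 10
      rep(TRUE, 150), rep(FALSE, 850)),       # c = 150, d = 850
    genes))
  rec <- pathway_odds_ratio(calls, in_path)
  expect_equal(rec$a, 10); expect_equal(rec$d, 850)
  expect_equal(rec$odds_ratio, (10 / 10) / (150 / 850), tolerance = 1e-12)
  expect_equal(rec$odds_ratio, 5.6667, tolerance = 1e-4)
  expect_false(rec$corrected)

  # zero cell: Haldane-Anscombe correction on all four cells
  calls0 <- make_calls(stats::setNames(
    c(rep(FALSE, 20), rep(TRUE, 150), rep(FALSE, 850)), genes))
  rec0 <- pathway_odds_ratio(calls0, in_path)
  expect_true(rec0$corrected)
  expect_equal(rec0$odds_ratio, (0.5 / 20.5) / (150.5 / 850.5),
               tolerance = 1e-12)
  expect_equal(rec0$odds_ratio, 0.1378, tolerance = 1e-3)

  # pathway proportion equal to background proportion gives OR = 1
  calls1 <- make_calls(stats::setNames(
    c(rep(TRUE, 5), rep(FALSE, 15), rep(TRUE, 250), rep(FALSE, 750)),
    genes))
  expect_equal(pathway_odds_ratio(calls1, in_path)$odds_ratio, 1)

  # fewer than 15 expressed genes: skipped
  expect_null(pathway_odds_ratio(calls, genes[1:10]))
})

test_that("odds ratios match an independent contingency-table oracle", {
  set.seed(501)
  genes <- sprintf("g%04d", 1:400)
  for (i in 1:1000) {
    asg <- stats::setNames(runif(400) < runif(1, 0.1, 0.5), genes)
    path <- sample(genes, sample(15:80, 1))
    rec <- pathway_odds_ratio(make_calls(asg), path)
    if (rec$corrected) next
    expect_equal(rec$odds_ratio, or_table_oracle(asg, genes %in% path),
                 tolerance = 1e-12)
  }
})

test_that("the 2x2 tables conserve totals and are label-equivariant", {
  set.seed(502)
  genes <- sprintf("g%04d", 1:500)
  for (i in 1:50) {
    asg <- stats::setNames(runif(500) < 0.3, genes)
    path <- sample(genes, 40)
    rec <- pathway_odds_ratio(make_calls(asg), path)
    expect_equal(rec$a + rec$b + rec$c + rec$d, 500)
    expect_equal(rec$a + rec$c, sum(asg))
    expect_equal(rec$a + rec$b, rec$n_expressed)
    if (!rec$corrected) {
      flipped <- pathway_odds_ratio(make_calls(!asg), path)
      if (!flipped$corrected)
        expect_equal(flipped$odds_ratio, 1 / rec$odds_ratio,
                     tolerance = 1e-12)
    }
  }
})

test_that("score_pathways scores each eligible pathway exactly once", {
  spec <- generator_spec(n_genes = 800, n_pathways = 60,
                         pathway_size_range = c(15, 100))
  pool <- gen_distance_pools(spec, seed = 9)
  gs <- gen_gene_sets(spec, seed = 10)
  calls <- classify_asg(pool$profile)
  recs <- score_pathways(calls, gs)
  expect_equal(nrow(recs), 60)
  expect_true(all(recs$a + recs$c == sum(calls$calls)))
  # removing one pathway removes exactly its record
  gs2 <- gene_set_collection(unclass(gs)[-5])
  recs2 <- score_pathways(calls, gs2)
  expect_setequal(setdiff(recs$pathway_id, recs2$pathway_id),
                  names(gs)[5])
  # a family too small for locFDR is refused
  tiny <- gene_set_collection(unclass(gs)[1:10])
  expect_error(score_pathways(calls, tiny), "at least 50")
})

test_that("the single-subject pipeline is deterministic end to end", {
  spec <- generator_spec(n_genes = 1500, n_pathways = 80,
                         pathway_size_range = c(15, 150))
  gen <- gen_paired_isoforms(spec, seed = 11)
  gs <- gen_gene_sets(spec, seed = 12)
  suppressMessages({
    p1 <- run_n1pas(gen$table, gs, patient_id = "s1")
    p2 <- run_n1pas(gen$table, gs, patient_id = "s1")
  })
  expect_identical(p1$records, p2$records)
  expect_equal(p1$n_scored, nrow(p1$records))
  expect_true(all(p1$records$locfdr >= 0 & p1$records$locfdr <= 1))
  expect_true(all(p1$records$enriched ==
                    (p1$records$odds_ratio > 1 & p1$records$locfdr < 0.2)))
  # records are ordered by locfdr, ties by descending OR
  expect_true(!is.unsorted(p1$records$locfdr))
})

test_that("planted ASG labels are recovered end to end", {
  spec <- generator_spec(n_genes = 1500, n_pathways = 80,
                         pathway_size_range = c(15, 150))
  gen <- gen_paired_isoforms(spec, seed = 13)
  suppressMessages({
    tb <- filter_isoform_counts(tpm_normalize(gen$table))
  })
  prof <- distance_profile(tb)
  calls <- classify_asg(prof)
  truth <- gen$truth[names(calls$calls)]
  keep <- !is.na(truth)
  sens <- mean(calls$calls[keep][truth[keep]])
  spec_ <- mean(!calls$calls[keep][!truth[keep]])
  expect_gte((sens + spec_) / 2, 0.85)
  # genes zeroed in one sample surface as missing distances
  zeroed <- names(gen$truth)[is.na(gen$truth)]
  zd <- prof$distance[prof$gene_id %in% zeroed]
  expect_true(all(is.na(zd)))
})
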