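sim_spec <- generator_spec(n_genes = 1200, n_pathways = 80,
                           pathway_size_range = c(15, 120))

test_that("label permutation preserves the multiset of distances", {
  pool <- gen_distance_pools(sim_spec, seed = 901)
  perm <- permute_gene_labels(pool$profile, seed = 902)
  expect_equal(sort(perm$distance), sort(pool$profile$distance))
  expect_identical(perm$gene_id, pool$profile$gene_id)
  expect_identical(permute_gene_labels(pool$profile, seed = 5),
                   permute_gene_labels(pool$profile, seed = 5))
  # threshold and pi_all depend only on the values, so they are unchanged
  expect_equal(classify_asg(perm)$pi_all, classify_asg(pool$profile)$pi_all)
})

test_that("specified-pathway eligibility uses the [G, G+5] window", {
  genes <- sprintf("g%05d", 1:100)
  prof <- hellinger_profile(genes, runif(100))
  coll <- gene_set_collection(list(
    s15 = list(description = "", genes = genes[1:15]),
    s18 = list(description = "", genes = genes[1:18]),
    s21 = list(description = "", genes = genes[1:21])))
  picks <- vapply(1:40, function(i)
    select_specified_pathway(coll, prof, G = 15, seed = i), "")
  expect_true(all(picks %in% c("s15", "s18")))
  expect_setequal(unique(picks), c("s15", "s18"))
  expect_equal(select_specified_pathway(coll, prof, G = 21, seed = 1),
               "s21")
  expect_error(select_specified_pathway(coll, prof, G = 50), "no pathway")
})

test_that("induced enrichment hits the targeted ASG proportion", {
  pool <- gen_distance_pools(sim_spec, seed = 903)
  calls <- classify_asg(pool$profile)
  perm <- permute_gene_labels(pool$profile, seed = 904)
  genes <- pool$profile$gene_id[1:100]
  # the m arithmetic: nominal G with pi + pi_all
  got <- induce_enrichment(perm, calls, genes, pi = 0.20, G = 100,
                           seed = 905)
  thr <- calls$threshold
  planted_frac <- mean(got$distance[got$gene_id %in% genes] >= thr)
  expect_equal(round(100 * (0.20 + calls$pi_all)),
               sum(got$distance[got$gene_id %in% genes] >= thr))
  expect_lt(abs(planted_frac - (0.20 + calls$pi_all)), 0.05)
  # pi = 0 keeps the pathway at the background rate
  got0 <- induce_enrichment(perm, calls, genes, pi = 0, G = 100,
                            seed = 906)
  frac0 <- mean(got0$distance[got0$gene_id %in% genes] >= thr)
  expect_lt(abs(frac0 - calls$pi_all), 0.06)
  # genes outside the pathway are untouched
  outside <- !(got$gene_id %in% genes)
  expect_equal(got$distance[outside], perm$distance[outside])
  expect_error(induce_enrichment(perm, calls, genes, pi = 0.9), "exceeds 1")
})

test_that("m is G times (pi + pi_all), rounded", {
  # construct a classification with pi_all exactly 0.19
  vals <- c(rep(0.1, 810), rep(0.9, 190))
  names(vals) <- sprintf("g%05d", 1:1000)
  calls <- classify_asg(vals)
  expect_equal(calls$pi_all, 0.19)
  prof <- hellinger_profile(names(vals), vals)
  genes <- names(vals)[1:100]
  got <- induce_enrichment(prof, calls, genes, pi = 0.20, G = 100,
                           seed = 907)
  expect_equal(sum(got$distance[got$gene_id %in% genes] >= calls$threshold),
               39)  # round(100 * 0.39)
})

test_that("replicates run the full machinery and record detection", {
  pool <- gen_distance_pools(sim_spec, seed = 908)
  suppressMessages(
    prep <- prepare_simulation(pool$profile, filter_gene_sets(gen_gene_sets(
      sim_spec, seed = 909))))
  set.seed(910)
  rec <- run_replicate(prep, G = 30, pi = 0.20)
  expect_true(rec$specified_pathway %in% prep$pathway_ids)
  expect_true(rec$n_scored >= 50)
  set.seed(911)
  null_rec <- run_replicate(prep, G = 30, pi = 0)
  expect_true(null_rec$n_detected <= null_rec$n_scored)
})

test_that("false positives stay under the nominal level at pi = 0", {
  pool <- gen_distance_pools(sim_spec, seed = 912)
  gs <- gen_gene_sets(sim_spec, seed = 913)
  suppressMessages(
    res <- run_simulation(pool$profile, gs, G_values = 30L, pi_values = 0,
                          replicates = 60, seed = 914))
  ok <- !res$failed
  expect_lt(mean(res$n_detected[ok] / res$n_scored[ok]), 0.20)
})

test_that("power increases with pi and varies less for larger pathways", {
  pool <- gen_distance_pools(sim_spec, seed = 915)
  gs <- gen_gene_sets(sim_spec, seed = 916)
  # monotone power in pi at fixed G, averaged over 20 seeds
  power_at <- function(pi, G, seeds) {
    vapply(seeds, function(s) {
      suppressMessages(
        r <- run_simulation(pool$profile, gs, G_values = G, pi_values = pi,
                            replicates = 10, seed = s))
      mean(r$detected[!r$failed])
    }, 0)
  }
  seeds <- 1000 + 1:20
  p_by_pi <- vapply(c(0.05, 0.10, 0.15, 0.20), function(pi)
    mean(power_at(pi, 30L, seeds)), 0)
  expect_true(all(diff(p_by_pi) >= -0.02))
  # across-seed SD of power at pi = 0.10 shrinks from G = 15 to G = 100
  sd15 <- sd(power_at(0.10, 15L, seeds))
  sd100 <- sd(power_at(0.10, 100L, seeds))
  expect_gt(sd15, sd100)
})

test_that("summaries aggregate patient means with normal CIs", {
  df <- data.frame(patient = rep(c("a", "b"), each = 4),
                   G = 30L, pi = 0,
                   replicate = rep(1:4, 2),
                   specified_pathway = "P",
                   detected = FALSE,
                   n_detected = c(4, 4, 4, 4, 6, 6, 6, 6),
                   n_scored = 100, failed = FALSE)
  s <- summarize_simulation(df)
  expect_equal(s$mean_rate, 0.05)
  expect_equal(s$se, 0.01)
  expect_equal(s$ci_lower, 0.05 - 1.96 * 0.01)
  expect_equal(s$measure, "false_positive")
  # identical per-patient rates give a zero-width interval
  df0 <- df; df0$n_detected <- 5
  s0 <- summarize_simulation(df0)
  expect_equal(s0$se, 0)
  expect_equal(s0$ci_lower, s0$ci_upper)
})
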