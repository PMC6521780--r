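# Independent oracles used across tests. These deliberately take different
# computational routes from the package implementation.

# Hellinger distance via the Bhattacharyya-coefficient identity
# H = sqrt(1 - sum_k sqrt(p_k q_k)).
hellinger_bc <- function(p, q) {
  sqrt(max(0, 1 - sum(sqrt(p * q))))
}

# Exhaustive 1-D 2-means: every contiguous split of the sorted values,
# within-cluster SS computed naively.
brute_force_split <- function(x) {
  x <- sort(x)
  n <- length(x)
  wss <- vapply(seq_len(n - 1), function(j) {
    lo <- x[1:j]; hi <- x[(j + 1):n]
    sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
  }, 0)
  j <- which.min(wss)
  list(threshold = (x[j] + x[j + 1]) / 2, wss = min(wss),
       centers = c(mean(x[1:j]), mean(x[(j + 1):n])))
}

# Two-sample log-rank chi-square from the hypergeometric-increment formula,
# accumulated event time by event time.
logrank_chisq_oracle <- function(time, event, group) {
  g1 <- sort(unique(group))[1]
  o1 <- e1 <- v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1)
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (o1 - e1)^2 / v
}

# Cross-product odds ratio from a 2x2 table assembled with base table().
or_table_oracle <- function(asg, in_pathway) {
  tab <- table(factor(asg, levels = c(TRUE, FALSE)),
               factor(in_pathway, levels = c(TRUE, FALSE)))
  (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
}

# Minimal asg_calls object for enrichment arithmetic tests.
make_calls <- function(calls) {
  structure(list(calls = calls,
                 values = stats::setNames(ifelse(calls, 0.8, 0.1),
                                          names(calls)),
                 threshold = 0.5, centers = c(0.1, 0.8),
                 pi_all = mean(calls), n_classified = length(calls)),
            class = "asg_calls")
}

# Minimal enrichment_profile stub for cohort/subtyping tests.
make_profile_stub <- function(patient_id, pathway_id, odds_ratio, enriched,
                              locfdr = ifelse(enriched, 0.05, 0.6)) {
  rec <- data.frame(pathway_id = pathway_id, odds_ratio = odds_ratio,
                    locfdr = locfdr, enriched = enriched,
                    n_expressed = 20L, a = 5L,
                    stringsAsFactors = FALSE)
  structure(list(patient_id = patient_id, records = rec,
                 n_scored = nrow(rec), pi_all = 0.2, threshold = 0.4),
            class = "enrichment_profile")
}
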