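## Synthetic-data generators emulating the statistical structure the method
## assumes: a bimodal per-gene Hellinger-distance distribution with a
## controllable background ASG rate, gene-set collections with realistic
## size spread over a few-thousand-gene universe, paired isoform tables
## with planted ASGs, and right-censored survival tied to a group label.
## Defaults mirror the cohort the method targets: 4,000 genes, background
## ASG weight 0.19, 206 gene sets sized 15-500.

#' Default generator settings
#'
#' @param n_genes universe size (default 4000).
#' @param isoform_range inclusive range of isoforms per gene (2-10).
#' @param w background ASG mixture weight (default 0.19; must be <= 0.9 —
#'   2-means on a near-unimodal sample is degenerate).
#' @param null_beta,asg_beta shape parameters of the Beta components for
#'   non-ASG and ASG Hellinger distances. The defaults Beta(1.5, 8) and
#'   Beta(6, 3) give a cleanly bimodal histogram that exact 2-means
#'   separates with >= 90% accuracy.
#' @param n_pathways number of gene sets (default 206).
#' @param pathway_size_range inclusive annotated-size range (15-500).
#' @param zero_rate fraction of genes zeroed in one sample to exercise the
#'   missingness rule (default 0.02).
#' @param baseline_hazard,hazard_ratio,censor_rate survival generator
#'   settings: exponential event hazard for the Better group, its multiple
#'   for the Worse group, and the target censoring fraction.
#' @return A list of class `generator_spec`.
#' @export
generator_spec <- function(n_genes = 4000L, isoform_range = c(2L, 10L),
                           w = 0.19,
                           null_beta = c(1.5, 8), asg_beta = c(6, 3),
                           n_pathways = 206L,
                           pathway_size_range = c(15L, 500L),
                           zero_rate = 0.02,
                           baseline_hazard = 0.05, hazard_ratio = 4,
                           censor_rate = 0.4) {
  if (w <= 0 || w > 0.9)
    stopf("background weight w must lie in (0, 0.9]")
  if (any(c(null_beta, asg_beta) <= 0))
    stopf("Beta shape parameters must be positive")
  structure(list(n_genes = as.integer(n_genes),
                 isoform_range = as.integer(isoform_range), w = w,
                 null_beta = null_beta, asg_beta = asg_beta,
                 n_pathways = as.integer(n_pathways),
                 pathway_size_range = as.integer(pathway_size_range),
                 zero_rate = zero_rate,
                 baseline_hazard = baseline_hazard,
                 hazard_ratio = hazard_ratio, censor_rate = censor_rate),
            class = "generator_spec")
}

synthetic_gene_ids <- function(n) sprintf("g%05d", seq_len(n))

#' Generate a synthetic Hellinger-distance pool
#'
#' Each gene's distance is drawn from the ASG component Beta(a1, b1) with
#' probability `w`, else from the null component Beta(a0, b0). The truth
#' labels are returned alongside for parameter-recovery checks.
#'
#' @param spec a [generator_spec()].
#' @param seed optional integer seed.
#' @return List with `profile` (a `hellinger_profile`, no missing values)
#'   and `truth` (logical, TRUE = ASG).
#' @export
gen_distance_pools <- function(spec = generator_spec(), seed = NULL) {
  with_seed(seed, {
    n <- spec$n_genes
    truth <- stats::runif(n) < spec$w
    d <- numeric(n)
    d[truth] <- stats::rbeta(sum(truth), spec$asg_beta[1], spec$asg_beta[2])
    d[!truth] <- stats::rbeta(sum(!truth), spec$null_beta[1],
                              spec$null_beta[2])
    list(profile = hellinger_profile(synthetic_gene_ids(n), d),
         truth = truth)
  })
}

#' Generate a synthetic gene-set collection
#'
#' Set sizes are log-uniform over the configured range (matching the
#' right-skewed size spread of curated pathway databases); members are
#' sampled uniformly from the gene universe, overlaps allowed.
#'
#' @param spec a [generator_spec()].
#' @param seed optional integer seed.
#' @return A `gene_set_collection` with `spec$n_pathways` sets.
#' @export
gen_gene_sets <- function(spec = generator_spec(), seed = NULL) {
  if (spec$pathway_size_range[2] > spec$n_genes)
    stopf("largest pathway size %d exceeds the %d-gene universe",
          spec$pathway_size_range[2], spec$n_genes)
  with_seed(seed, {
    universe <- synthetic_gene_ids(spec$n_genes)
    r <- spec$pathway_size_range
    sizes <- round(exp(stats::runif(spec$n_pathways, log(r[1]), log(r[2]))))
    sizes <- pmin(pmax(sizes, r[1]), r[2])
    sets <- lapply(seq_len(spec$n_pathways), function(i)
      list(description = sprintf("synthetic pathway %03d", i),
           genes = sample(universe, sizes[i])))
    names(sets) <- sprintf("SP%03d", seq_len(spec$n_pathways))
    gene_set_collection(sets)
  })
}

#' Generate a paired isoform expression table with planted ASGs
#'
#' Per gene: K ~ uniform over the isoform range; sample-A usage is
#' Dirichlet(1.5); with probability `w` the gene is an ASG and sample-B
#' usage is an independent Dirichlet(0.5) draw (expected Hellinger distance
#' around 0.6), otherwise sample-B usage is a high-concentration Dirichlet
#' resample around sample A (concentration 60, expected distance around
#' 0.1). Gene totals are log-normal(meanlog 5, sdlog 1.5) per sample and
#' split across isoforms by usage; a small fraction of genes is zeroed in
#' one sample to exercise the missingness rule.
#'
#' @param spec a [generator_spec()].
#' @param seed optional integer seed.
#' @return List with `table` (a [paired_isoforms]) and `truth` (named
#'   logical per gene, TRUE = ASG; zeroed genes are NA).
#' @export
gen_paired_isoforms <- function(spec = generator_spec(), seed = NULL) {
  with_seed(seed, {
    n <- spec$n_genes
    genes <- synthetic_gene_ids(n)
    k <- sample(spec$isoform_range[1]:spec$isoform_range[2], n,
                replace = TRUE)
    truth <- stats::runif(n) < spec$w
    zeroed <- stats::runif(n) < spec$zero_rate
    total_iso <- sum(k)
    iso_id <- character(total_iso)
    gene_of <- character(total_iso)
    ab_a <- numeric(total_iso)
    ab_b <- numeric(total_iso)
    pos <- 0L
    for (i in seq_len(n)) {
      ki <- k[i]
      p_a <- rdirichlet1(rep(1.5, ki))
      p_b <- if (truth[i]) rdirichlet1(rep(0.5, ki))
             else rdirichlet1(60 * p_a + 1e-3)
      tot <- stats::rlnorm(2, meanlog = 5, sdlog = 1.5)
      a <- p_a * tot[1]
      b <- p_b * tot[2]
      if (zeroed[i]) {
        if (stats::runif(1) < 0.5) a <- rep(0, ki) else b <- rep(0, ki)
      }
      j <- pos + seq_len(ki)
      iso_id[j] <- sprintf("%s.i%02d", genes[i], seq_len(ki))
      gene_of[j] <- genes[i]
      ab_a[j] <- a
      ab_b[j] <- b
      pos <- pos + ki
    }
    truth_out <- ifelse(zeroed, NA, truth)
    names(truth_out) <- genes
    list(table = paired_isoforms(iso_id, gene_of, ab_a, ab_b,
                                 sample_labels = c("normal", "tumor")),
         truth = truth_out)
  })
}

#' Generate right-censored survival times tied to a group label
#'
#' Event times are exponential with hazard `baseline_hazard`, multiplied by
#' `hazard_ratio` for patients labelled `"Worse"` (or `TRUE`). Censoring is
#' independent uniform on (0, tau) with tau solved numerically so the
#' expected censoring fraction matches `censor_rate`.
#'
#' @param labels per-patient group: `"Better"`/`"Worse"`, or logical with
#'   TRUE = Worse. Names become patient ids.
#' @param spec a [generator_spec()].
#' @param seed optional integer seed.
#' @return A `survival_table`.
#' @export
gen_survival <- function(labels, spec = generator_spec(), seed = NULL) {
  worse <- if (is.logical(labels)) labels else labels == "Worse"
  ids <- names(labels)
  if (is.null(ids)) ids <- sprintf("p%03d", seq_along(labels))
  if (spec$censor_rate < 0 || spec$censor_rate >= 1)
    stopf("censor_rate must lie in [0, 1)")
  with_seed(seed, {
    haz <- spec$baseline_hazard * ifelse(worse, spec$hazard_ratio, 1)
    t_event <- stats::rexp(length(haz), rate = haz)
    if (spec$censor_rate == 0) {
      return(survival_table(ids, t_event, rep(1L, length(ids))))
    }
    # P(C < T), C ~ U(0,tau), T ~ Exp(h): (1 - (1-exp(-h tau))/(h tau))
    mean_censor <- function(tau) {
      mean(1 - (1 - exp(-haz * tau)) / (haz * tau))
    }
    tau <- stats::uniroot(function(x) mean_censor(x) - spec$censor_rate,
                          lower = 1e-6, upper = 1e6, tol = 1e-8)$root
    c_time <- stats::runif(length(haz), 0, tau)
    survival_table(ids, pmin(t_event, c_time),
                   as.integer(t_event <= c_time))
  })
}
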