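# n1pas

Single-subject pathway enrichment of alternatively spliced genes from
paired RNA-Seq isoform expression.

## The problem

Most RNA-Seq analytics compare gene-level expression across cohorts and
ignore alternative splicing, even though a tumour frequently dysregulates
the splicing machinery itself. When one patient contributes a *pair* of
samples — tumour and adjacent normal, before and during therapy — the
shift in each gene's isoform mix is measurable for that patient alone, and
pathway annotations let those gene-level shifts aggregate into an
interpretable, mechanism-level readout. `n1pas` turns one patient's paired
isoform table into a profile of pathways enriched with alternatively
spliced genes (ASGs), with an odds-ratio effect size and a local
false-discovery-rate (locFDR) significance per pathway. It is aimed at
statistical genomicists and translational researchers working on N-of-1
transcriptomics.

## The method

For gene *g* with *K_g* isoforms, the relative isoform usage in sample A
is `p_gA = (x_gA1, …, x_gAK) / Σ_k x_gAk`, and the dissimilarity between
the two samples' usage vectors is the Hellinger distance

    H_g = sqrt( 1/2 · Σ_k ( sqrt(p_gAk) − sqrt(p_gBk) )² )  ∈ [0, 1].

The pipeline then:

1. **Classifies ASGs** by exact one-dimensional 2-means on the H_g
   distribution (a deterministic threshold; the high cluster is ASG). The
   ASG fraction across all genes is the patient's background rate π_all.
2. **Scores each pathway** with the cross-product odds ratio
   `OR = (a/b)/(c/d)` of the 2×2 table (ASG vs not) × (in pathway vs
   background), with the Haldane–Anscombe +0.5 correction when a cell is
   zero. Pathways need 15–500 annotated genes and ≥ 15 expressed genes.
3. **Fits a two-group mixture** to the subject's ~200 pathway ORs and
   reports `fdr(z) = p0·f0(z)/f(z)`, the posterior probability a pathway
   is null, using an empirical null estimated by central matching. A
   pathway is *enriched* when `OR > 1` and `locFDR < 0.20`.

Cohort layers on top of the single-subject core: capture-rate validation
against row-shuffled permutation nulls, a survival-subtyping pipeline
(per-pathway PAM clustering into two subtypes, Kaplan–Meier + log-rank,
empirical p-values, Benjamini–Hochberg FDR), and a Monte-Carlo harness
for false-positive rates and power. Synthetic-data generators emulate
the paired-isoform structure so everything runs without downloads.

## Worked example

```r
library(n1pas)
spec    <- generator_spec()                    # 4,000 genes, w = 0.19
gen     <- gen_paired_isoforms(spec, seed = 4) # paired table + truth
gs      <- gen_gene_sets(spec, seed = 5)       # 206 sets, 15-500 genes
profile <- run_n1pas(gen$table, gs, patient_id = "demo")
profile
#> N1PAS profile for 'demo': 206 pathways scored, 13 enriched (pi_all 0.166)
#>   pathway_id n_expressed  a odds_ratio       locfdr enriched
#> 1      SP010          22  9   3.503529 0.0000000000     TRUE
#> 2      SP133          16  6   3.025077 0.0000000000     TRUE
#> 3      SP180          20  7   2.716518 0.0001962635     TRUE
#> 4      SP126          16  5   2.287481 0.0160701823     TRUE
#> 5      SP013          46 14   2.218358 0.0277082899     TRUE
#> 6      SP184          80 24   2.191310 0.0339626491     TRUE
```

Reading the output: 16.6% of this patient's genes were classified ASG
(π_all); pathway `SP010` has 22 expressed genes of which 9 are ASG —
3.5 times the odds of the background — and its locFDR ≈ 0 marks it
confidently non-null. `profile$locfdr_fit` carries the mixture
diagnostics (null mean/SD, p0, histogram), which are worth inspecting for
any new data set.

A command-line front end with one subcommand per experiment (`score`,
`validate`, `subtype`, `simulate`, `synth`) is installed at
`system.file("scripts/n1pas.R", package = "n1pas")`.

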