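## Readers/writers for the external formats: paired isoform expression with
## an isoform->gene mapping, GMT gene sets, survival tables, and the
## per-patient enrichment profile. All files are UTF-8, tab-separated with a
## header row; lines starting with '#' are ignored.

read_tsv_file <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    fileEncoding = "UTF-8")
}

#' Construct a paired isoform expression table
#'
#' The central input container: one row per isoform with its host gene and
#' the nonnegative abundance in each of the two paired samples (sample A is
#' conventionally the baseline/normal, sample B the tumour/treated sample).
#'
#' @param isoform_id character vector, unique isoform identifiers.
#' @param gene_id character vector, host gene of each isoform.
#' @param abundance_A,abundance_B nonnegative finite abundances (e.g. RSEM
#'   estimates or TPM) for the two samples.
#' @param sample_labels length-2 character vector naming the samples.
#' @return An object of class `paired_isoforms`: a data frame with columns
#'   `isoform_id`, `gene_id`, `abundance_A`, `abundance_B` and a
#'   `sample_labels` attribute.
#' @export
paired_isoforms <- function(isoform_id, gene_id, abundance_A, abundance_B,
                            sample_labels = c("A", "B")) {
  isoform_id <- as.character(isoform_id)
  gene_id <- as.character(gene_id)
  if (anyDuplicated(isoform_id))
    stopf("duplicate isoform_id values (e.g. '%s')",
          isoform_id[duplicated(isoform_id)][1])
  if (length(gene_id) != length(isoform_id) || anyNA(gene_id) ||
      any(gene_id == ""))
    stopf("every isoform needs a gene_id")
  ab <- cbind(abundance_A, abundance_B)
  if (!is.numeric(ab) || anyNA(ab) || any(!is.finite(ab)))
    stopf("abundances must be finite numbers")
  if (any(ab < 0))
    stopf("negative abundance encountered")
  if (length(sample_labels) != 2)
    stopf("sample_labels must have length 2")
  out <- data.frame(isoform_id = isoform_id, gene_id = gene_id,
                    abundance_A = as.numeric(abundance_A),
                    abundance_B = as.numeric(abundance_B),
                    stringsAsFactors = FALSE)
  structure(out, sample_labels = as.character(sample_labels),
            class = c("paired_isoforms", "data.frame"))
}

#' Read a paired isoform expression table with its gene mapping
#'
#' Expects a tab-separated file whose first column is the isoform identifier
#' and whose next two numeric columns are the paired-sample abundances (the
#' column names become the sample labels), plus a two-column mapping file
#' `isoform_id`, `gene_id`. Isoforms without a mapping are dropped with a
#' logged count.
#'
#' @param path expression table file.
#' @param mapping_path isoform-to-gene mapping file.
#' @return A [paired_isoforms] table.
#' @export
read_isoform_table <- function(path, mapping_path) {
  expr <- read_tsv_file(path)
  if (ncol(expr) < 3)
    stopf("expression table needs an isoform column and two abundance columns")
  iso <- as.character(expr[[1]])
  a <- expr[[2]]; b <- expr[[3]]
  if (!is.numeric(a) || !is.numeric(b) || anyNA(a) || anyNA(b))
    stopf("abundance columns must be numeric with no missing values")
  if (any(a < 0) || any(b < 0))
    stopf("negative abundance in expression table")
  map <- read_tsv_file(mapping_path)
  if (ncol(map) < 2)
    stopf("mapping file needs isoform_id and gene_id columns")
  gene <- as.character(map[[2]])[match(iso, as.character(map[[1]]))]
  keep <- !is.na(gene)
  if (!any(keep))
    stopf("no isoform in the expression table has a gene mapping")
  n_drop <- sum(!keep)
  if (n_drop > 0)
    n1pas_log(sprintf("dropped %d unmapped isoform(s) of %d", n_drop,
                      length(iso)))
  paired_isoforms(iso[keep], gene[keep], a[keep], b[keep],
                  sample_labels = names(expr)[2:3])
}

#' Read a GMT gene-set collection
#'
#' Standard Broad GMT dialect: one set per line,
#' `set_id TAB description TAB gene1 TAB gene2 ...`. Duplicate genes within a
#' set are deduplicated; a duplicated set id is an error.
#'
#' @param path GMT file.
#' @return A named list of class `gene_set_collection`; each element is a
#'   list with `description` and `genes` (character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  sets <- list()
  for (ln in lines) {
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stopf("GMT line with fewer than 3 fields: '%s'",
            substr(ln, 1, 50))
    id <- fields[1]
    if (id %in% names(sets))
      stopf("duplicate gene-set id '%s'", id)
    genes <- unique(fields[-(1:2)])
    genes <- genes[nzchar(genes)]
    sets[[id]] <- list(description = fields[2], genes = genes)
  }
  gene_set_collection(sets)
}

#' @rdname read_gmt
#' @param sets named list of `list(description=, genes=)` entries.
#' @export
gene_set_collection <- function(sets) {
  if (length(sets) > 0) {
    if (is.null(names(sets)) || anyDuplicated(names(sets)))
      stopf("gene-set ids must be unique and non-empty")
    n_genes <- vapply(sets, function(s) length(s$genes), 0L)
    if (any(n_genes == 0))
      stopf("empty gene set: '%s'", names(sets)[n_genes == 0][1])
  }
  structure(sets, class = "gene_set_collection")
}

#' Write a gene-set collection in GMT format
#' @param collection a `gene_set_collection`.
#' @param path output file.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection), function(id) {
    s <- collection[[id]]
    paste(c(id, s$description, s$genes), collapse = "\t")
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a right-censored survival table
#'
#' Tab-separated with columns `patient_id`, `time`, `event`
#' (0 = censored, 1 = death). Times must be strictly positive and patient
#' ids unique.
#'
#' @param path survival file.
#' @return A data frame of class `survival_table`.
#' @export
read_survival <- function(path) {
  df <- read_tsv_file(path)
  need <- c("patient_id", "time", "event")
  if (!all(need %in% names(df)))
    stopf("survival table needs columns: %s", paste(need, collapse = ", "))
  survival_table(as.character(df$patient_id), df$time, df$event)
}

#' @rdname read_survival
#' @param patient_id,time,event vectors forming the table.
#' @export
survival_table <- function(patient_id, time, event) {
  patient_id <- as.character(patient_id)
  if (anyDuplicated(patient_id))
    stopf("duplicate patient_id in survival table")
  if (!is.numeric(time) || anyNA(time) || any(time <= 0))
    stopf("survival times must be positive numbers")
  if (!all(event %in% c(0, 1)))
    stopf("event indicator must be 0 (censored) or 1 (death)")
  structure(data.frame(patient_id = patient_id, time = as.numeric(time),
                       event = as.integer(event), stringsAsFactors = FALSE),
            class = c("survival_table", "data.frame"))
}

#' Write or re-read a single-subject enrichment profile
#'
#' The tabular form of a scored profile: columns `pathway_id`,
#' `n_genes_expressed`, `n_asg_in_pathway`, `odds_ratio`, `locfdr`,
#' `enriched`. Values round-trip at full double precision, well beyond 6
#' significant digits.
#'
#' @param profile an `enrichment_profile` from [run_n1pas()].
#' @param path output file.
#' @export
write_enrichment_profile <- function(profile, path) {
  df <- profile$records[, c("pathway_id", "n_expressed", "a", "odds_ratio",
                            "locfdr", "enriched")]
  names(df) <- c("pathway_id", "n_genes_expressed", "n_asg_in_pathway",
                 "odds_ratio", "locfdr", "enriched")
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_enrichment_profile
#' @export
read_enrichment_profile <- function(path) {
  df <- read_tsv_file(path)
  df$enriched <- as.logical(df$enriched)
  df
}
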