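cohort_fixture <- function() {
  load_cohort(phenostrat_example("cohort_monogenic.tsv"))
}

cnv_fixture <- function() {
  load_cnv(phenostrat_example("cnv_records.tsv"))
}

pathway_fixture <- function() {
  load_pathways(phenostrat_example("gene_pathways.tsv"))
}

flags_fixture <- function() {
  load_phenotype_flags(phenostrat_example("gene_phenotype_flags.tsv"))
}

# default-pipeline assignment on the packaged cohort
fixture_assignment <- function(linkage = "complete", k = 3) {
  coh <- cohort_fixture()
  z <- zscore(coh, na_policy = "zero")
  cut_clusters(hca(euclidean_distances(z), linkage = linkage), k,
               composite_severity(z))
}

# write a small cohort file from a data.frame of character columns
write_cohort_file <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, na = "", row.names = FALSE)
  path
}

# minimal valid cohort data.frame with given scores matrix (NA = blank)
tiny_cohort_df <- function(scores, genes = NULL) {
  n <- nrow(scores)
  if (is.null(genes)) genes <- rep("GENE1", n)
  df <- data.frame(patient_id = sprintf("P%d", seq_len(n)),
                   birth_year = 2015L, sex = "M", gene = genes,
                   diagnosis = "test", stringsAsFactors = FALSE)
  sc <- as.data.frame(scores)
  names(sc) <- domain_names()[seq_len(ncol(scores))]
  for (d in setdiff(domain_names(), names(sc))) sc[[d]] <- NA_integer_
  cbind(df, sc[domain_names()])
}
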