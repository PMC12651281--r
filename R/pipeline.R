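#' Pipeline configuration
#'
#' @param na_policy Missing-data policy, `"zero"` or `"drop"` (the clustering
#'   stage always operates on the NA-free `"zero"` encoding; `na_policy`
#'   governs the correlation stage and is recorded in the outputs).
#' @param linkage `"complete"` or `"ward"`.
#' @param k Number of clusters to cut.
#' @param by Contingency rows: `"gene"` or `"pathway"`.
#' @param seed Seed recorded in outputs (the analysis itself is
#'   deterministic; the seed matters only when the input cohort is simulated).
#' @param digits Decimal digits used when serializing floating-point results,
#'   so re-runs are byte-identical.
#' @return List of class `phenostrat_config`.
#' @export
pipeline_config <- function(na_policy = c("zero", "drop"),
                            linkage = c("complete", "ward"),
                            k = 3, by = c("gene", "pathway"),
                            seed = 1L, digits = 10L) {
  cfg <- list(na_policy = match.arg(na_policy), linkage = match.arg(linkage),
              k = as.integer(k), by = match.arg(by), seed = as.integer(seed),
              digits = as.integer(digits))
  class(cfg) <- "phenostrat_config"
  cfg
}

write_matrix_tsv <- function(m, path, rowname_col) {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- rowname_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, na = "NA",
                     row.names = FALSE, fileEncoding = "UTF-8")
}

#' Run the full stratification pipeline
#'
#' End-to-end analysis from a scored cohort file: ingest and validate,
#' Z-normalize, cluster patients (Euclidean distance, configured linkage),
#' cut into k severity-ranked groups, profile clusters, test the
#' gene-by-cluster (or pathway-by-cluster) association, compute the domain
#' correlation architecture, and profile CNV records when supplied. All
#' results are written as plain-text artifacts plus one machine-readable
#' summary JSON stamped with the configuration and package version.
#'
#' @param cohort_file Path to the scored cohort table (see [load_cohort()]).
#' @param cnv_file Optional path to a CNV table (see [load_cnv()]).
#' @param pathway_file Optional gene-to-pathway TSV (see [load_pathways()]);
#'   required when `config$by == "pathway"`, otherwise used only for the
#'   per-cluster pathway composition overlay.
#' @param config A [pipeline_config()].
#' @param outdir Output directory (created if missing). Files written:
#'   `zmatrix.tsv`, `dendrogram.nwk`, `assignments.tsv`,
#'   `cluster_profiles.tsv`, `chisq.json`, `corr.tsv`, `corr_pvals.tsv`,
#'   `cnv_profile.json` (when a CNV file is given) and `summary.json`.
#' @param truth Optional named ground-truth cluster labels (from
#'   [generate_cohort()]); when given, the summary reports the Adjusted Rand
#'   Index of the recovered assignment.
#' @return Invisibly, a list with all in-memory results (`cohort`, `z`,
#'   `dend`, `assignment`, `profiles`, `chisq`, `correlations`, `cnv`,
#'   `summary`).
#' @examples
#' \donttest{
#' res <- run_pipeline(phenostrat_example("cohort_monogenic.tsv"),
#'                     cnv_file = phenostrat_example("cnv_records.tsv"),
#'                     outdir = tempfile("phenostrat_"))
#' res$summary$chisq$df   # 34
#' }
#' @export
run_pipeline <- function(cohort_file, cnv_file = NULL, pathway_file = NULL,
                         config = pipeline_config(), outdir, truth = NULL) {
  stopifnot(inherits(config, "phenostrat_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  cohort <- stage("ingest", load_cohort(cohort_file))
  if (nrow(cohort$scores) == 0L) {
    stop("pipeline stage 'ingest' failed: cohort file contains no patients",
         call. = FALSE)
  }
  annot <- if (!is.null(pathway_file)) stage("ingest", load_pathways(pathway_file))
  if (config$by == "pathway" && is.null(annot)) {
    stop("pipeline stage 'ingest' failed: by = \"pathway\" needs a pathway file",
         call. = FALSE)
  }

  z <- stage("normalize", zscore(cohort, na_policy = "zero"))
  sev <- composite_severity(z)
  dend <- stage("cluster", hca(euclidean_distances(z), linkage = config$linkage))
  assignment <- stage("cluster", cut_clusters(dend, config$k, sev))
  profiles <- stage("cluster", cluster_profile(cohort, assignment))
  tab <- stage("associate",
               contingency(cohort, assignment, by = config$by, annot = annot))
  chisq <- stage("associate", suppressWarnings(chisquare(tab)))
  corr <- stage("correlate",
                domain_correlations(cohort, na_policy = config$na_policy))
  dom_order <- stage("correlate",
                     suppressWarnings(as.character(order_heatmap(corr))))
  cnv <- if (!is.null(cnv_file)) {
    stage("cnv_profile", cnv_summary(load_cnv(cnv_file)))
  }
  pw <- if (!is.null(annot)) {
    stage("associate", pathway_summary(assignment, annot, cohort))
  }

  dg <- config$digits
  write_matrix_tsv(round(z$values, dg), file.path(outdir, "zmatrix.tsv"),
                   "patient_id")
  hca_newick(dend, file.path(outdir, "dendrogram.nwk"))
  utils::write.table(
    data.frame(patient_id = names(assignment),
               cluster = as.integer(assignment),
               composite_severity = round(sev[names(assignment)], dg)),
    file.path(outdir, "assignments.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(profiles, file.path(outdir, "cluster_profiles.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(statistic = round(chisq$statistic, dg), df = chisq$df,
         p_value = round(chisq$p_value, dg), by = config$by,
         table = as.data.frame(as.table(chisq$observed),
                               stringsAsFactors = FALSE)),
    file.path(outdir, "chisq.json"), auto_unbox = TRUE, digits = NA)
  write_matrix_tsv(round(corr$r, dg), file.path(outdir, "corr.tsv"), "domain")
  write_matrix_tsv(round(corr$p, dg), file.path(outdir, "corr_pvals.tsv"),
                   "domain")
  if (!is.null(cnv)) {
    jsonlite::write_json(
      list(n_records = cnv$n_records, n_patients = cnv$n_patients,
           min_mb = cnv$min_mb, max_mb = cnv$max_mb,
           category_counts = as.list(cnv$category_counts),
           class_counts_record = as.list(cnv$class_counts_record),
           origin_counts = as.list(cnv$origin_counts)),
      file.path(outdir, "cnv_profile.json"), auto_unbox = TRUE, digits = NA)
  }

  summary <- list(
    package = "phenostrat",
    version = as.character(utils::packageVersion("phenostrat")),
    config = unclass(config),
    n_patients = nrow(cohort$scores),
    n_genes = length(unique(cohort$meta$gene)),
    cluster_sizes = as.integer(table(as.integer(assignment))),
    median_composite_by_cluster =
      round(as.numeric(tapply(sev[names(assignment)], as.integer(assignment),
                              stats::median)), dg),
    chisq = list(statistic = round(chisq$statistic, dg), df = chisq$df,
                 p_value = round(chisq$p_value, dg)),
    heatmap_domain_order = dom_order,
    max_r_neuro_motor_mental_id = {
      sub <- corr$r[c("neuro", "motor", "mental", "id"),
                    c("neuro", "motor", "mental", "id")]
      round(max(sub[upper.tri(sub)], na.rm = TRUE), dg)
    },
    pathway_modal = if (!is.null(pw)) as.list(pw$modal),
    cnv = if (!is.null(cnv)) list(min_mb = cnv$min_mb, max_mb = cnv$max_mb,
                                  n_patients = cnv$n_patients),
    ari_vs_truth = if (!is.null(truth))
      round(ari(truth, stats::setNames(as.integer(assignment),
                                       names(assignment))), dg)
  )
  summary <- summary[!vapply(summary, is.null, TRUE)]
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(cohort = cohort, z = z, dend = dend,
                 assignment = assignment, profiles = profiles, chisq = chisq,
                 correlations = corr, cnv = cnv, pathways = pw,
                 summary = summary))
}
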