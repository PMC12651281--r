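#' Gene-by-cluster (or pathway-by-cluster) contingency table
#'
#' Cross-tabulates patients by gene symbol (or pathway category) and cluster
#' label. Rows and columns that happen to be empty are retained, so the table
#' shape reflects the full label sets.
#'
#' @param cohort A `phenostrat_cohort`.
#' @param assign Cluster labels from [cut_clusters()], named by patient id and
#'   covering the cohort.
#' @param by `"gene"` (default) or `"pathway"`.
#' @param annot Named character vector gene -> pathway category (from
#'   [load_pathways()]); required when `by = "pathway"`. Cohort genes missing
#'   from the annotation map to `"other"`.
#' @return Integer matrix of patient counts; rows = genes (sorted) or pathway
#'   categories, columns = cluster labels `1..k`.
#' @examples
#' coh <- load_cohort(phenostrat_example("cohort_monogenic.tsv"))
#' z <- zscore(coh)
#' cl <- cut_clusters(hca(euclidean_distances(z)), 3, composite_severity(z))
#' dim(contingency(coh, cl))   # 18 x 3
#' @export
contingency <- function(cohort, assign, by = c("gene", "pathway"),
                        annot = NULL) {
  stopifnot(inherits(cohort, "phenostrat_cohort"))
  by <- match.arg(by)
  ids <- rownames(cohort$scores)
  if (!all(ids %in% names(assign))) {
    stop("unassigned patient(s): ",
         paste(setdiff(ids, names(assign)), collapse = ", "))
  }
  lab <- as.integer(assign[ids])
  k <- if (!is.null(attr(assign, "k"))) attr(assign, "k") else max(lab)
  row_var <- if (by == "gene") {
    cohort$meta$gene
  } else {
    if (is.null(annot)) stop("by = \"pathway\" requires a pathway annotation")
    cat_ <- unname(annot[cohort$meta$gene])
    cat_[is.na(cat_)] <- "other"
    cat_
  }
  tab <- table(factor(row_var, levels = sort(unique(row_var))),
               factor(lab, levels = seq_len(k)))
  out <- matrix(as.integer(tab), nrow(tab), ncol(tab),
                dimnames = list(rownames(tab), colnames(tab)))
  out
}

#' Pearson's chi-squared test of a contingency table
#'
#' Pearson statistic sum (O - E)^2 / E without continuity correction; p-value
#' from the upper tail of the chi-squared distribution with
#' df = (rows - 1)(cols - 1). Rows or columns with zero total (expected count
#' zero everywhere) are dropped before computation, with a warning, since the
#' statistic is undefined there. A warning is also emitted when any expected
#' count is below 5 -- routine for sparse gene-by-cluster tables -- but the
#' statistic is still returned.
#'
#' @param tab Matrix of non-negative counts, at least 2 x 2 after dropping
#'   empty rows/columns.
#' @return Object of class `phenostrat_chisq`: list with `statistic`, `df`,
#'   `p_value`, `observed`, `expected`, `n`.
#' @export
chisquare <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("contingency table must hold non-negative integer counts")
  }
  if (sum(tab) == 0) stop("contingency table is empty")
  rz <- rowSums(tab) == 0
  cz <- colSums(tab) == 0
  if (any(rz) || any(cz)) {
    warning("dropping ", sum(rz), " empty row(s) and ", sum(cz),
            " empty column(s) before the chi-squared test")
    tab <- tab[!rz, !cz, drop = FALSE]
  }
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    stop("need at least 2 non-empty rows and 2 non-empty columns")
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  if (any(ct$expected < 5)) {
    warning("some expected counts are below 5; the chi-squared approximation ",
            "is rough on sparse tables")
  }
  structure(list(statistic = unname(ct$statistic),
                 df = unname(ct$parameter),
                 p_value = unname(ct$p.value),
                 observed = tab,
                 expected = ct$expected,
                 n = sum(tab)),
            class = "phenostrat_chisq")
}

#' @export
print.phenostrat_chisq <- function(x, ...) {
  cat(sprintf("Pearson chi-squared: X2 = %.3f, df = %d, p = %.4g (n = %d)\n",
              x$statistic, x$df, x$p_value, x$n))
  invisible(x)
}

overlap_categories <- function() {
  cats <- c("neurological", "motor", "intellectual_disability", "dysmorphism")
  subsets <- list()
  for (m in 1:15) {           # non-empty subsets of 4 categories
    members <- cats[as.logical(bitwAnd(m, c(1L, 2L, 4L, 8L)))]
    subsets[[paste(members, collapse = "+")]] <- members
  }
  subsets
}

#' Exact-subset overlap partition of genes across phenotype categories
#'
#' Partitions genes into the 15 non-empty regions of the 4-set Venn diagram
#' over neurological features, motor development issues, intellectual
#' disability and dysmorphism: a gene lands in the region matching exactly its
#' set of raised flags. Regions are therefore disjoint and their union is the
#' set of genes with at least one flag; genes with no flag are omitted.
#'
#' @param flags data.frame from [load_phenotype_flags()]: `gene` plus four
#'   logical columns named after the categories.
#' @return Named list over all 15 subset keys (e.g.
#'   `"neurological+motor+intellectual_disability"`), each a character vector
#'   of gene symbols (possibly empty).
#' @export
phenotype_overlap <- function(flags) {
  cats <- c("neurological", "motor", "intellectual_disability", "dysmorphism")
  if (!all(c("gene", cats) %in% names(flags))) {
    stop("flags must have columns: gene, ", paste(cats, collapse = ", "))
  }
  subsets <- overlap_categories()
  key_of <- vapply(seq_len(nrow(flags)), function(i) {
    members <- cats[unlist(flags[i, cats], use.names = FALSE)]
    if (!length(members)) NA_character_ else paste(members, collapse = "+")
  }, "")
  out <- lapply(names(subsets), function(k) flags$gene[!is.na(key_of) & key_of == k])
  names(out) <- names(subsets)
  out
}

#' Per-cluster pathway composition
#'
#' Counts patients per (cluster, pathway category) and reports each cluster's
#' modal category -- the post hoc biological annotation overlay on a
#' phenotype-driven clustering.
#'
#' @param assign Cluster labels from [cut_clusters()].
#' @param annot Named character vector gene -> pathway category.
#' @param cohort A `phenostrat_cohort`.
#' @return List with `counts` (clusters x categories integer matrix) and
#'   `modal` (named character; NA for an empty cluster).
#' @export
pathway_summary <- function(assign, annot, cohort) {
  stopifnot(inherits(cohort, "phenostrat_cohort"))
  ids <- rownames(cohort$scores)
  if (!all(ids %in% names(assign))) stop("assignment does not cover the cohort")
  lab <- as.integer(assign[ids])
  k <- if (!is.null(attr(assign, "k"))) attr(assign, "k") else max(lab)
  cat_ <- unname(annot[cohort$meta$gene])
  cat_[is.na(cat_)] <- "other"
  levels_ <- c("transcription_rna_processing", "ion_channel_metabolic",
               "myelination_structural_signaling", "other")
  tab <- table(factor(lab, levels = seq_len(k)),
               factor(cat_, levels = levels_))
  counts <- matrix(as.integer(tab), nrow(tab), ncol(tab),
                   dimnames = dimnames(tab))
  modal <- apply(counts, 1, function(r) {
    if (sum(r) == 0) NA_character_ else colnames(counts)[which.max(r)]
  })
  list(counts = counts, modal = modal)
}
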