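#' Path to a packaged example data file
#'
#' @param file Name of a file under `extdata/`; with no argument, lists the
#'   available files. Packaged fixtures: `cohort_monogenic.tsv` (the monogenic
#'   cohort scored on the 15-domain rubric), `cnv_records.tsv` (the CNV
#'   cohort), `gene_pathways.tsv` (gene to pathway-category map) and
#'   `gene_phenotype_flags.tsv` (curated gene-level phenotype flags).
#' @return File path (or vector of file names).
#' @export
phenostrat_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "phenostrat")))
  }
  path <- system.file("extdata", file, package = "phenostrat", mustWork = TRUE)
  path
}

read_delim_auto <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("file is empty: ", path)
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    colClasses = "character", check.names = FALSE,
                    strip.white = TRUE, fill = FALSE,
                    na.strings = NULL, fileEncoding = "UTF-8")
}

#' Load a scored cohort table
#'
#' Reads a delimited cohort file (TSV or CSV; one row per patient) holding
#' patient metadata and the 15 ordinal domain scores, validates it against the
#' scoring rubric, and returns a cohort object. Blank score cells are treated
#' as NA ("NA/Normal": the feature is absent, normal, or was not assessed).
#'
#' @param path Path to a UTF-8 delimited file with header columns
#'   `patient_id`, `birth_year`, `sex`, `gene`, `diagnosis` plus the 15
#'   domains of [domain_names()]. `birth_year` and `diagnosis` are optional.
#' @param rubric A [scoring_rubric()]; defines the expected domain columns.
#' @return An object of class `phenostrat_cohort`: a list with
#'   \describe{
#'     \item{meta}{data.frame of `patient_id`, `birth_year`, `sex`, `gene`,
#'       `diagnosis`, `family_id` (the id prefix before the first dot, so
#'       sibling rows like `ID6.1`/`ID6.2` share a family).}
#'     \item{scores}{integer matrix (patients x 15 domains), values in 1..4
#'       or NA, rownames = patient ids.}
#'     \item{domains}{domain order used.}
#'   }
#' @section Errors: an unknown column is a schema error; a score outside 1..4
#'   (or non-integer) is a validation error naming the offending cell;
#'   duplicated patient ids are an error.
#' @examples
#' coh <- load_cohort(phenostrat_example("cohort_monogenic.tsv"))
#' nrow(coh$meta)                   # 29 patients
#' length(unique(coh$meta$gene))    # 18 genes
#' @export
load_cohort <- function(path, rubric = scoring_rubric()) {
  d <- read_delim_auto(path)
  domains <- names(rubric)
  required <- c("patient_id", "sex", "gene", domains)
  optional <- c("birth_year", "diagnosis")
  missing_cols <- setdiff(required, names(d))
  if (length(missing_cols)) {
    stop("cohort file is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  unknown <- setdiff(names(d), c(required, optional))
  if (length(unknown)) {
    stop("unknown column(s) in cohort file (not a rubric domain): ",
         paste(unknown, collapse = ", "))
  }
  if (anyDuplicated(d$patient_id)) {
    stop("duplicate patient_id: ",
         paste(unique(d$patient_id[duplicated(d$patient_id)]), collapse = ", "))
  }
  if (any(d$gene == "")) {
    stop("empty gene symbol for patient(s): ",
         paste(d$patient_id[d$gene == ""], collapse = ", "))
  }
  bad_sex <- !d$sex %in% c("M", "F")
  if (any(bad_sex)) {
    stop("sex must be M or F; offending patient(s): ",
         paste(d$patient_id[bad_sex], collapse = ", "))
  }

  scores <- matrix(NA_integer_, nrow(d), length(domains),
                   dimnames = list(d$patient_id, domains))
  for (dom in domains) {
    v <- d[[dom]]
    blank <- is.na(v) | v == ""
    num <- suppressWarnings(as.numeric(v))
    bad <- !blank & (is.na(num) | num %% 1 != 0 | num < 1 | num > 4)
    if (any(bad)) {
      stop("invalid score in domain '", dom, "' (must be 1..4 or blank): ",
           paste(sprintf("patient %s = '%s'", d$patient_id[bad], v[bad]),
                 collapse = "; "))
    }
    scores[!blank, dom] <- as.integer(num[!blank])
  }

  meta <- data.frame(
    patient_id = d$patient_id,
    birth_year = if ("birth_year" %in% names(d))
      suppressWarnings(as.integer(d$birth_year)) else NA_integer_,
    sex = d$sex,
    gene = d$gene,
    diagnosis = if ("diagnosis" %in% names(d)) d$diagnosis else NA_character_,
    family_id = sub("\\..*$", "", d$patient_id),
    stringsAsFactors = FALSE
  )
  structure(list(meta = meta, scores = scores, domains = domains),
            class = "phenostrat_cohort")
}

#' Write a cohort back to a delimited file
#'
#' Inverse of [load_cohort()]: writes the metadata and score matrix as TSV,
#' with NA scores as blank cells, so that reloading reproduces the score
#' matrix cell for cell.
#'
#' @param cohort A `phenostrat_cohort`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "phenostrat_cohort"))
  sc <- cohort$scores
  out <- cbind(cohort$meta[c("patient_id", "birth_year", "sex", "gene",
                             "diagnosis")],
               as.data.frame(sc))
  utils::write.table(out, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
print.phenostrat_cohort <- function(x, ...) {
  cat("phenostrat cohort:", nrow(x$scores), "patients,",
      length(unique(x$meta$gene)), "genes,", ncol(x$scores), "domains\n")
  cat("missing (NA/Normal) cells:",
      sum(is.na(x$scores)), "of", length(x$scores), "\n")
  invisible(x)
}

#' Per-domain score distribution report
#'
#' Pure report: counts of each score level and NA rate per domain; the cohort
#' is not modified.
#'
#' @param cohort A `phenostrat_cohort`.
#' @param rubric Rubric defining the domains (defaults to the cohort's own).
#' @return data.frame with one row per domain: counts `n1`..`n4`, `n_na`, and
#'   `na_rate`.
#' @export
validate_scores <- function(cohort, rubric = scoring_rubric()) {
  stopifnot(inherits(cohort, "phenostrat_cohort"))
  sc <- cohort$scores
  rows <- lapply(colnames(sc), function(dom) {
    v <- sc[, dom]
    data.frame(domain = dom,
               n1 = sum(v == 1, na.rm = TRUE), n2 = sum(v == 2, na.rm = TRUE),
               n3 = sum(v == 3, na.rm = TRUE), n4 = sum(v == 4, na.rm = TRUE),
               n_na = sum(is.na(v)),
               na_rate = if (length(v)) mean(is.na(v)) else NA_real_)
  })
  do.call(rbind, rows)
}

#' Load a CNV record table
#'
#' Reads a delimited table of copy-number variants, one row per dup/del call
#' (a patient may own several rows). Coordinates may carry thousands
#' separators (commas), which are stripped; alternatively a single `location`
#' column of the form `start_end` is accepted in place of `start`/`end`.
#'
#' @param path Path to a UTF-8 TSV/CSV with columns `patient_id`, `type`
#'   (`dup`/`del`), `chr`, `band`, and either `start` + `end` or `location`;
#'   optional `birth_year`, `sex`, `length_mb` (ignored; lengths are
#'   recomputed), `class` (`P`, `LP`, `VUS`; blank or other = `unknown`) and
#'   `origin` (`de_novo`, `paternal`, `maternal`, `uncertain`).
#' @return data.frame of class `phenostrat_cnv` with columns `patient_id`,
#'   `birth_year`, `sex`, `cnv_type`, `chromosome`, `band`, `start`, `end`,
#'   `class`, `origin`, `length_bp`, `length_mb`. Coordinates are 1-based
#'   inclusive; `length_bp = end - start` (the +-1 bp convention difference is
#'   below the 0.1 Mb reporting precision).
#' @examples
#' cnv <- load_cnv(phenostrat_example("cnv_records.tsv"))
#' nrow(cnv)                          # 13 records
#' length(unique(cnv$patient_id))     # 10 patients
#' @export
load_cnv <- function(path) {
  d <- read_delim_auto(path)
  need <- c("patient_id", "type", "chr")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols)) {
    stop("CNV file is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  parse_coord <- function(v, what) {
    num <- suppressWarnings(as.numeric(gsub("[ ,]", "", v)))
    bad <- which(is.na(num) | num < 0)
    if (length(bad)) {
      stop("unparseable ", what, " coordinate at row(s): ",
           paste(bad, collapse = ", "))
    }
    num
  }
  if (all(c("start", "end") %in% names(d))) {
    start <- parse_coord(d$start, "start")
    end <- parse_coord(d$end, "end")
  } else if ("location" %in% names(d)) {
    parts <- strsplit(d$location, "_", fixed = TRUE)
    if (any(lengths(parts) != 2L)) {
      stop("location must be 'start_end'; offending row(s): ",
           paste(which(lengths(parts) != 2L), collapse = ", "))
    }
    start <- parse_coord(vapply(parts, `[`, "", 1L), "start")
    end <- parse_coord(vapply(parts, `[`, "", 2L), "end")
  } else {
    stop("CNV file needs either 'start' and 'end' columns or a 'location' column")
  }
  if (any(end <= start)) {
    stop("end must be greater than start; offending row(s): ",
         paste(which(end <= start), collapse = ", "))
  }
  bad_type <- !d$type %in% c("dup", "del")
  if (any(bad_type)) {
    stop("type must be dup or del; offending row(s): ",
         paste(which(bad_type), collapse = ", "))
  }
  valid_chr <- c(as.character(1:22), "X", "Y")
  if (any(!d$chr %in% valid_chr)) {
    stop("invalid chromosome: ",
         paste(unique(d$chr[!d$chr %in% valid_chr]), collapse = ", "))
  }
  cls <- if ("class" %in% names(d)) d$class else rep("", nrow(d))
  cls[!cls %in% c("P", "LP", "VUS")] <- "unknown"
  org <- if ("origin" %in% names(d)) d$origin else rep("uncertain", nrow(d))
  org[!org %in% c("de_novo", "paternal", "maternal")] <- "uncertain"

  out <- data.frame(
    patient_id = d$patient_id,
    birth_year = if ("birth_year" %in% names(d))
      suppressWarnings(as.integer(d$birth_year)) else NA_integer_,
    sex = if ("sex" %in% names(d)) d$sex else NA_character_,
    cnv_type = d$type,
    chromosome = d$chr,
    band = if ("band" %in% names(d)) d$band else NA_character_,
    start = start,
    end = end,
    class = cls,
    origin = org,
    stringsAsFactors = FALSE
  )
  out$length_bp <- out$end - out$start
  out$length_mb <- round(out$length_bp / 1e6, 1)
  class(out) <- c("phenostrat_cnv", "data.frame")
  out
}

#' Load a gene-to-pathway annotation table
#'
#' @param path Two-column TSV/CSV `gene`, `pathway_category`. Recognised
#'   categories: `transcription_rna_processing`, `ion_channel_metabolic`,
#'   `myelination_structural_signaling`; anything else maps to `other`.
#' @return Named character vector: gene symbol -> pathway category.
#' @export
load_pathways <- function(path) {
  d <- read_delim_auto(path)
  if (!all(c("gene", "pathway_category") %in% names(d))) {
    stop("pathway file needs columns 'gene' and 'pathway_category'")
  }
  known <- c("transcription_rna_processing", "ion_channel_metabolic",
             "myelination_structural_signaling")
  cat_ <- ifelse(d$pathway_category %in% known, d$pathway_category, "other")
  stats::setNames(cat_, d$gene)
}

#' Load curated gene-level phenotype flags
#'
#' Reads a table of per-gene boolean flags over the four major clinical
#' phenotype categories (neurological features, motor development issues,
#' intellectual disability, dysmorphism) used by [phenotype_overlap()]. The
#' packaged fixture is a curated mapping: most flags follow mechanically from
#' the cohort's per-gene clinical summaries (seizures/hypotonia/spasticity =
#' neurological; any delay or loss of ambulation = motor; any ID level =
#' intellectual disability; facial or skeletal anomalies = dysmorphism), and
#' genes whose published overlap placement conflicts with that rule were
#' assigned to a single category by editorial judgement. The mapping is data,
#' not code: edit the TSV to change it.
#'
#' @param path TSV/CSV with columns `gene`, `neurological`, `motor`,
#'   `intellectual_disability`, `dysmorphism` (0/1).
#' @return data.frame with a `gene` column and four logical flag columns.
#' @export
load_phenotype_flags <- function(path) {
  d <- read_delim_auto(path)
  cats <- c("neurological", "motor", "intellectual_disability", "dysmorphism")
  if (!all(c("gene", cats) %in% names(d))) {
    stop("flags file needs columns: gene, ", paste(cats, collapse = ", "))
  }
  for (cc in cats) d[[cc]] <- as.integer(d[[cc]]) > 0L
  d[c("gene", cats)]
}
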