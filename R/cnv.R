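#' CNV interval lengths
#'
#' Length in base pairs and megabases of each record. Coordinates are 1-based
#' inclusive and length is `end - start`; at the 0.1 Mb reporting precision
#' this is indistinguishable from the `+1` convention.
#'
#' @param records A `phenostrat_cnv` data.frame (from [load_cnv()]) or any
#'   data.frame with numeric `start` and `end` columns.
#' @return data.frame with `length_bp` and `length_mb` (rounded to 0.1 Mb),
#'   one row per record.
#' @examples
#' cnv_length(data.frame(start = 151478865, end = 170590912))  # 19.1 Mb
#' @export
cnv_length <- function(records) {
  if (!all(c("start", "end") %in% names(records))) {
    stop("records need 'start' and 'end' columns")
  }
  start <- as.numeric(records$start)
  end <- as.numeric(records$end)
  if (any(end <= start)) {
    stop("end must be greater than start; offending row(s): ",
         paste(which(end <= start), collapse = ", "))
  }
  bp <- end - start
  data.frame(length_bp = bp, length_mb = round(bp / 1e6, 1))
}

#' Classify patients by the kinds of CNV they carry
#'
#' @param records A `phenostrat_cnv` data.frame; must be non-empty.
#' @return Named character vector over distinct patients:
#'   `"dup_only"`, `"del_only"` or `"both"`. The result does not depend on
#'   record order (patients are reported in sorted id order).
#' @export
classify_patients <- function(records) {
  if (nrow(records) == 0L) stop("no CNV records")
  ids <- sort(unique(records$patient_id))
  out <- vapply(ids, function(p) {
    types <- unique(records$cnv_type[records$patient_id == p])
    if (all(types == "dup")) "dup_only"
    else if (all(types == "del")) "del_only"
    else "both"
  }, "")
  out
}

cnv_class_rank <- c(P = 3L, LP = 2L, VUS = 1L, unknown = 0L)

#' Cohort-level CNV profile
#'
#' Summarizes a CNV record set: per-record lengths, per-patient dup/del
#' category, cohort size range, class counts (per record, and per patient
#' taking each patient's most severe class, P > LP > VUS > unknown) and
#' origin counts per patient (origin is a property of the event carrier, so a
#' patient with two records of one rearrangement counts once).
#'
#' @param records A `phenostrat_cnv` data.frame; must be non-empty.
#' @return Object of class `phenostrat_cnv_profile`: list with `n_records`,
#'   `n_patients`, `lengths` (per-record data.frame), `min_mb`, `max_mb`,
#'   `patient_category` and `category_counts`, `class_counts_record`,
#'   `class_counts_patient`, `origin_counts` (per patient).
#' @examples
#' prof <- cnv_summary(load_cnv(phenostrat_example("cnv_records.tsv")))
#' c(prof$min_mb, prof$max_mb)   # 1.3 19.1
#' @export
cnv_summary <- function(records) {
  if (nrow(records) == 0L) stop("no CNV records")
  len <- cnv_length(records)
  cat_ <- classify_patients(records)
  ids <- names(cat_)

  class_levels <- c("P", "LP", "VUS", "unknown")
  per_patient_class <- vapply(ids, function(p) {
    cls <- records$class[records$patient_id == p]
    cls[which.max(cnv_class_rank[cls])]
  }, "")
  per_patient_origin <- vapply(ids, function(p) {
    org <- unique(records$origin[records$patient_id == p])
    if (length(org) > 1L) org <- setdiff(org, "uncertain")[1]  # first informative
    org[1]
  }, "")
  origin_levels <- c("de_novo", "paternal", "maternal", "uncertain")

  structure(list(
    n_records = nrow(records),
    n_patients = length(ids),
    lengths = cbind(data.frame(patient_id = records$patient_id,
                               cnv_type = records$cnv_type), len),
    min_mb = min(len$length_mb),
    max_mb = max(len$length_mb),
    patient_category = cat_,
    category_counts = table(factor(cat_, levels = c("dup_only", "del_only",
                                                    "both"))),
    class_counts_record = table(factor(records$class, levels = class_levels)),
    class_counts_patient = table(factor(per_patient_class,
                                        levels = class_levels)),
    origin_counts = table(factor(per_patient_origin, levels = origin_levels))
  ), class = "phenostrat_cnv_profile")
}

#' @export
print.phenostrat_cnv_profile <- function(x, ...) {
  cat("CNV profile:", x$n_records, "records in", x$n_patients, "patients\n")
  cat(sprintf("size range: %.1f - %.1f Mb\n", x$min_mb, x$max_mb))
  cat("patient categories:",
      paste(names(x$category_counts), x$category_counts, sep = "=",
            collapse = ", "), "\n")
  invisible(x)
}
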