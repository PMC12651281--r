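#' The 15 clinical scoring domains, in canonical order
#'
#' Column order used throughout the package for score matrices, Z-matrices
#' and correlation matrices.
#'
#' @return Character vector of the 15 domain names.
#' @export
domain_names <- function() {
  c("onset", "perinatal", "vision", "neuro", "seizure", "eeg", "mri",
    "mental", "motor", "id", "dysmorph", "skeletal", "anomalies",
    "family", "syndrome")
}

#' Ordinal clinical severity scoring rubric
#'
#' Builds the 15-domain semi-quantitative scoring rubric used to grade
#' clinical severity in intellectual-disability cohorts. Each domain is rated
#' on an ordinal 1--4 scale (1 = mild or late-onset manifestation, 4 = severe,
#' neonatal-onset or multisystemic manifestation), with a blank/NA level
#' meaning the feature is absent, normal, or was not assessed.
#'
#' @return An object of class `phenostrat_rubric`: a list with one element per
#'   domain, each a list with `name`, `criteria` (named character vector over
#'   levels `"1"`..`"4"`) and `na_label`.
#' @examples
#' r <- scoring_rubric()
#' length(r)          # 15
#' r$onset$criteria[["4"]]
#' @export
scoring_rubric <- function() {
  crit <- list(
    onset = c("onset at 2-3 years or later, mild presentation",
              "onset 12-24 months, walking or speech delay",
              "onset 4-12 months, early motor delay",
              "neonatal to 3 months, severe multisystem onset"),
    perinatal = c("unremarkable pregnancy and delivery",
                  "mild to moderate perinatal risk factors",
                  "significant perinatal abnormality",
                  "major perinatal complication"),
    vision = c("minor or transient visual issues",
               "mild ocular anomaly such as strabismus",
               "persistent nystagmus or abnormal eye movements",
               "severe visual loss or optic atrophy"),
    neuro = c("subtle neurological signs",
              "mild hypertonia or clumsiness",
              "focal spasticity or dystonia",
              "severe spastic tetraplegia or marked hypotonia"),
    seizure = c("none or doubtful seizure events",
                "febrile or late-onset seizures, controlled",
                "non-febrile recurrent seizures before 12 months",
                "neonatal-onset, frequent or intractable seizures"),
    eeg = c("near-normal EEG",
            "mild nonspecific slowing",
            "clear focal or generalized epileptiform discharges",
            "severe EEG pattern such as hypsarrhythmia or burst-suppression"),
    mri = c("subtle or equivocal MRI findings",
            "mild nonspecific lesions",
            "moderate abnormality such as delayed myelination",
            "severe structural malformation"),
    mental = c("mild behavioural symptoms",
               "suggestive attention or coordination problems",
               "formal ASD/ADHD diagnosis with functional impact",
               "severe behavioural disturbance"),
    motor = c("mild motor delay or clumsiness",
              "moderate delay, walks with partial support",
              "severe delay, cannot walk unaided",
              "loss of ambulation or never walked"),
    id = c("borderline intellectual functioning or learning difficulty",
           "mild intellectual disability",
           "moderate intellectual disability",
           "severe or profound intellectual disability"),
    dysmorph = c("very mild or doubtful dysmorphic features",
                 "mild atypical features",
                 "clear facial or systemic dysmorphism",
                 "syndromic multisystemic dysmorphism"),
    skeletal = c("very mild or suspected skeletal involvement",
                 "mild deformity",
                 "moderate localized deformity or contracture",
                 "severe or multiple skeletal deformities"),
    anomalies = c("minor non-significant anomaly",
                  "mild recurrent condition",
                  "significant single-organ anomaly",
                  "multi-organ involvement"),
    family = c("negative family history",
               "suspected distantly affected relative",
               "first-degree relative affected",
               "multiple relatives affected, clear inheritance"),
    syndrome = c("no syndromic features",
                 "focal phenotype only",
                 "suspected syndrome",
                 "confirmed clinical syndrome")
  )
  stopifnot(identical(names(crit), domain_names()))
  rubric <- lapply(names(crit), function(d) {
    list(name = d,
         criteria = stats::setNames(crit[[d]], as.character(1:4)),
         na_label = "NA/Normal")
  })
  names(rubric) <- names(crit)
  class(rubric) <- "phenostrat_rubric"
  rubric
}

#' @export
print.phenostrat_rubric <- function(x, ...) {
  cat("Clinical severity scoring rubric:", length(x), "ordinal domains (1-4)\n")
  cat(paste(names(x), collapse = ", "), "\n")
  invisible(x)
}
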