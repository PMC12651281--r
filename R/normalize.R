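#' Numeric score matrix under a missing-data policy
#'
#' Converts the ordinal score matrix to numeric form. Under `na_policy =
#' "zero"`, NA ("NA/Normal", i.e. feature absent or normal) is encoded as 0,
#' placing all patients on an effective 0--4 severity scale; under `"drop"`,
#' NAs are kept and downstream operations use pairwise/observed-only handling.
#'
#' @param cohort A `phenostrat_cohort`.
#' @param na_policy `"zero"` (default) or `"drop"`.
#' @return Numeric matrix patients x domains.
#' @export
score_matrix <- function(cohort, na_policy = c("zero", "drop")) {
  stopifnot(inherits(cohort, "phenostrat_cohort"))
  na_policy <- match.arg(na_policy)
  x <- cohort$scores
  storage.mode(x) <- "double"
  if (na_policy == "zero") x[is.na(x)] <- 0
  x
}

#' Z-score standardization of the score matrix
#'
#' Standardizes each domain column to Z = (X - mu) / sigma so domains are
#' comparable (mean 0, SD 1). sigma is the sample standard deviation
#' (n - 1 divisor), computed over observed values. A zero-variance domain is
#' mapped to an all-zero column rather than dividing by zero.
#'
#' @param cohort A `phenostrat_cohort`, or a numeric patients x domains matrix.
#' @param na_policy Missing-data policy applied before standardization; see
#'   [score_matrix()]. With `"drop"`, cells that were NA stay NA in Z.
#' @return An object of class `phenostrat_zmatrix`: list with `values`
#'   (patients x domains), `mu`, `sigma` (per-domain), and `na_policy`.
#' @examples
#' z <- zscore(load_cohort(phenostrat_example("cohort_monogenic.tsv")))
#' round(colMeans(z$values), 12)   # all zero
#' @export
zscore <- function(cohort, na_policy = c("zero", "drop")) {
  na_policy <- match.arg(na_policy)
  x <- if (inherits(cohort, "phenostrat_cohort")) {
    score_matrix(cohort, na_policy)
  } else {
    as.matrix(cohort)
  }
  if (nrow(x) < 2L) {
    stop("zscore needs at least 2 patients (sample SD is undefined for n = 1)")
  }
  mu <- colMeans(x, na.rm = TRUE)
  sigma <- apply(x, 2, stats::sd, na.rm = TRUE)
  z <- sweep(x, 2, mu, "-")
  ok <- !is.na(sigma) & sigma > 0
  z[, ok] <- sweep(z[, ok, drop = FALSE], 2, sigma[ok], "/")
  # zero-variance domains: observed cells become 0, NAs stay NA
  cz <- z[, !ok, drop = FALSE]
  cz[!is.na(cz)] <- 0
  z[, !ok] <- cz
  structure(list(values = z, mu = mu, sigma = sigma, na_policy = na_policy),
            class = "phenostrat_zmatrix")
}

#' @export
print.phenostrat_zmatrix <- function(x, ...) {
  cat("Z-matrix:", nrow(x$values), "patients x", ncol(x$values),
      "domains (na_policy =", x$na_policy, ")\n")
  invisible(x)
}

#' Per-patient composite severity
#'
#' Aggregates each patient's profile into a single unitless severity value:
#' the unweighted arithmetic mean of the patient's domain Z-values (over
#' observed domains when the Z-matrix carries NAs). Used to rank clusters from
#' most to least severe.
#'
#' @param z A `phenostrat_zmatrix` (or numeric matrix of Z-values).
#' @return Named numeric vector, one value per patient.
#' @export
composite_severity <- function(z) {
  v <- if (inherits(z, "phenostrat_zmatrix")) z$values else as.matrix(z)
  rowMeans(v, na.rm = TRUE)
}
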