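#' Pairwise Pearson correlations between clinical domains
#'
#' Correlates every pair of the 15 domain score columns. Under
#' `na_policy = "zero"` the complete NA-as-0 matrix is used (the result is
#' then identical whether computed from raw scores or Z-values, since Pearson
#' R is invariant to per-column affine rescaling); under `"drop"`,
#' pairwise-complete observations are used and the effective n varies by pair.
#' Two-sided p-values come from the t transform
#' t = R * sqrt((n - 2) / (1 - R^2)) with n the effective pair count.
#' Zero-variance domains give undefined correlations, reported as NA; pairs
#' with fewer than 3 complete observations are NA with a warning. A
#' Benjamini-Hochberg adjusted p-value matrix is also returned for
#' transparency (the primary report is the unadjusted p).
#'
#' @param cohort A `phenostrat_cohort` or numeric matrix (columns = domains).
#' @param na_policy `"zero"` (default) or `"drop"`.
#' @return Object of class `phenostrat_corr`: list with matrices `r`, `p`,
#'   `p_adj`, `n` (effective pair counts) and the `na_policy` used. Diagonal:
#'   r = 1, p = NA by convention.
#' @examples
#' co <- domain_correlations(load_cohort(phenostrat_example("cohort_monogenic.tsv")))
#' co$r["motor", "id"]
#' @export
domain_correlations <- function(cohort, na_policy = c("zero", "drop")) {
  na_policy <- match.arg(na_policy)
  x <- if (inherits(cohort, "phenostrat_cohort")) {
    score_matrix(cohort, na_policy)
  } else {
    as.matrix(cohort)
  }
  obs <- !is.na(x)
  n_eff <- crossprod(obs)          # pairwise-complete counts
  r <- suppressWarnings(stats::cor(x, use = "pairwise.complete.obs",
                                   method = "pearson"))
  low_n <- n_eff < 3 & row(n_eff) != col(n_eff)
  if (any(low_n & !is.na(r))) {
    warning("pair(s) with fewer than 3 complete observations reported as NA")
  }
  r[low_n] <- NA_real_

  df <- n_eff - 2
  tval <- r * sqrt(df / pmax(1 - r^2, 0))
  p <- 2 * stats::pt(-abs(tval), df)
  p[!is.na(r) & abs(r) >= 1 - 1e-15] <- 0   # perfect correlation
  p[is.na(r)] <- NA_real_
  diag(p) <- NA_real_
  diag(r)[!is.na(diag(r))] <- 1

  # BH adjustment over the upper-triangle tests, mirrored back
  ut <- upper.tri(p)
  p_adj <- p
  p_adj[ut] <- stats::p.adjust(p[ut], method = "BH")
  p_adj[lower.tri(p_adj)] <- t(p_adj)[lower.tri(p_adj)]

  structure(list(r = r, p = p, p_adj = p_adj, n = n_eff,
                 na_policy = na_policy),
            class = "phenostrat_corr")
}

#' @export
print.phenostrat_corr <- function(x, ...) {
  cat("domain correlation matrix:", nrow(x$r), "domains (na_policy =",
      x$na_policy, ")\n")
  off <- x$r[upper.tri(x$r)]
  cat(sprintf("R range: [%.2f, %.2f]; %d pair(s) with p < 0.05\n",
              min(off, na.rm = TRUE), max(off, na.rm = TRUE),
              sum(x$p[upper.tri(x$p)] < 0.05, na.rm = TRUE)))
  invisible(x)
}

#' Heatmap ordering of domains by clustering the correlation structure
#'
#' Hierarchically clusters domains on the distance 1 - R (sign-sensitive, so
#' positively and negatively correlated blocks separate) and returns the leaf
#' order, to be applied symmetrically to rows and columns of a heatmap.
#' NA correlations are imputed as 0 (distance 1) for ordering only, with a
#' warning.
#'
#' @param corr A `phenostrat_corr` (or square correlation matrix).
#' @param linkage Linkage passed to [hca()].
#' @return Character vector of domain names in leaf order; the tree is
#'   attached as attribute `"tree"`.
#' @export
order_heatmap <- function(corr, linkage = "complete") {
  r <- if (inherits(corr, "phenostrat_corr")) corr$r else as.matrix(corr)
  if (anyNA(r)) {
    warning("NA correlations imputed as 0 for heatmap ordering only")
    r[is.na(r)] <- 0
  }
  d <- 1 - r
  diag(d) <- 0
  d[d < 0] <- 0                     # guard against 1 - (1 + eps)
  tree <- hca(d, linkage = linkage)
  structure(tree$labels[tree$order], tree = tree)
}
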