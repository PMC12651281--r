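#' Default per-cluster domain mean profiles
#'
#' Builds a k x 15 matrix of ground-truth domain means on the effective 0--4
#' severity scale: cluster centers are evenly spaced from severe to mild
#' (`separation` score units apart before clipping) and a fixed per-domain
#' offset pattern makes profiles domain-specific (high onset/neuro/motor/ID
#' loading, lower systemic/skeletal loading), mimicking the structure of a
#' severity-stratified monogenic cohort.
#'
#' @param k Number of clusters.
#' @param separation Score-unit gap between adjacent cluster centers.
#' @return k x 15 numeric matrix, rows = clusters (1 = most severe), columns
#'   = [domain_names()], values clipped to `[0, 4]`.
#' @export
default_domain_profiles <- function(k = 3, separation = 1.5) {
  offsets <- c(onset = 0.3, perinatal = -0.8, vision = -0.6, neuro = 0.4,
               seizure = -0.2, eeg = -0.3, mri = 0, mental = -0.2,
               motor = 0.5, id = 0.5, dysmorph = -0.8, skeletal = -1,
               anomalies = -1.2, family = -0.5, syndrome = -0.8)
  centers <- 3.5 - separation * (seq_len(k) - 1)
  m <- outer(centers, offsets, "+")
  m <- pmin(pmax(m, 0), 4)
  dimnames(m) <- list(NULL, domain_names())
  m
}

#' Synthetic-cohort generator configuration
#'
#' Defines the statistical structure the analysis assumes: latent phenotype
#' clusters with cluster-specific ordinal domain profiles, domain-level
#' missingness, and gene labels tied to clusters at a controllable strength.
#' Defaults emulate the packaged monogenic cohort: 29 patients in 3 latent
#' clusters with weights proportional to the observed severe/intermediate/mild
#' split (9/8/12), 18 gene symbols partitioned into three cluster-typical
#' blocks, and moderate ordinal noise.
#'
#' @param n_patients Cohort size.
#' @param k_clusters Number of latent clusters.
#' @param cluster_weights Probability simplex of length `k_clusters`.
#' @param domain_means k x 15 matrix of domain means on the 0--4 scale.
#' @param domain_sd Gaussian noise SD (score units) before rounding.
#' @param na_prob Per-domain probability of masking a score to NA, on top of
#'   the structural rule that a rounded score of 0 is emitted as NA
#'   (absent/normal feature). Scalar or length-15 vector, each in `[0, 1)`.
#' @param genes Character vector of gene symbols.
#' @param gene_emission k x length(genes) matrix; row c is the gene
#'   distribution of cluster c (rows sum to 1). Default: genes split into k
#'   contiguous blocks, uniform within the cluster's own block.
#' @param association_strength s in `[0, 1]`: each patient's gene is drawn
#'   from `(1 - s) * uniform + s * emission[cluster, ]`; 0 makes genes
#'   independent of cluster, 1 makes emission deterministic per cluster.
#' @param seed Optional integer seed; identical configs with identical seeds
#'   reproduce identical cohorts.
#' @return Object of class `phenostrat_simconfig` (validated list).
#' @export
sim_config <- function(n_patients = 29, k_clusters = 3,
                       cluster_weights = c(9, 8, 12) / 29,
                       domain_means = default_domain_profiles(k_clusters),
                       domain_sd = 0.5, na_prob = 0.1,
                       genes = sprintf("GENE%02d", 1:18),
                       gene_emission = NULL,
                       association_strength = 0.9, seed = NULL) {
  if (n_patients < 1) stop("n_patients must be positive")
  if (k_clusters < 1) stop("k_clusters must be positive")
  if (length(cluster_weights) != k_clusters || any(cluster_weights < 0) ||
      abs(sum(cluster_weights) - 1) > 1e-8) {
    stop("cluster_weights must be a length-k simplex (non-negative, sum 1)")
  }
  domain_means <- as.matrix(domain_means)
  if (nrow(domain_means) != k_clusters || ncol(domain_means) != 15 ||
      any(domain_means < 0) || any(domain_means > 4)) {
    stop("domain_means must be k x 15 with values in [0, 4]")
  }
  if (domain_sd < 0) stop("domain_sd must be non-negative")
  if (length(na_prob) == 1L) na_prob <- rep(na_prob, 15)
  if (length(na_prob) != 15 || any(na_prob < 0) || any(na_prob >= 1)) {
    stop("na_prob must be in [0, 1) per domain")
  }
  if (is.null(gene_emission)) {
    # contiguous gene blocks per cluster, uniform within block
    blocks <- split(seq_along(genes),
                    cut(seq_along(genes), k_clusters, labels = FALSE))
    gene_emission <- matrix(0, k_clusters, length(genes))
    for (c_ in seq_len(k_clusters)) {
      gene_emission[c_, blocks[[c_]]] <- 1 / length(blocks[[c_]])
    }
  }
  gene_emission <- as.matrix(gene_emission)
  if (nrow(gene_emission) != k_clusters ||
      ncol(gene_emission) != length(genes) ||
      any(gene_emission < 0) ||
      any(abs(rowSums(gene_emission) - 1) > 1e-8)) {
    stop("gene_emission rows must be probability simplexes over the genes")
  }
  if (association_strength < 0 || association_strength > 1) {
    stop("association_strength must be in [0, 1]")
  }
  structure(list(n_patients = as.integer(n_patients),
                 k_clusters = as.integer(k_clusters),
                 cluster_weights = cluster_weights,
                 domain_means = domain_means, domain_sd = domain_sd,
                 na_prob = na_prob, genes = genes,
                 gene_emission = gene_emission,
                 association_strength = association_strength, seed = seed),
            class = "phenostrat_simconfig")
}

#' Generate a synthetic cohort with known ground truth
#'
#' For each patient: draw the latent cluster from the weights; per domain,
#' draw Normal(mean = cluster profile, sd = `domain_sd`), round and clip to
#' 0..4, and emit 0 as NA (the feature is absent); mask further cells to NA at
#' `na_prob`; draw the gene from the mixture
#' `(1 - s) * uniform + s * emission[cluster, ]`.
#'
#' @param config A [sim_config()].
#' @return List with
#'   \describe{
#'     \item{cohort}{a `phenostrat_cohort` (patient ids `S001`, ...).}
#'     \item{truth}{list: `cluster` (named integer), `gene` (named character),
#'       `scores_premask` (rounded/clipped 0--4 integer matrix before NA
#'       masking), `gene_cluster_table` (true gene x cluster draw counts).}
#'   }
#' @examples
#' sim <- generate_cohort(sim_config(seed = 1))
#' table(sim$truth$cluster)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "phenostrat_simconfig"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_patients
  k <- config$k_clusters
  ids <- sprintf("S%03d", seq_len(n))

  cl <- sample.int(k, n, replace = TRUE, prob = config$cluster_weights)
  mu <- config$domain_means[cl, , drop = FALSE]
  raw <- matrix(stats::rnorm(n * 15, mean = mu, sd = config$domain_sd), n, 15)
  sc <- pmin(pmax(round(raw), 0), 4)
  storage.mode(sc) <- "integer"
  dimnames(sc) <- list(ids, domain_names())
  premask <- sc

  scores <- sc
  scores[scores == 0L] <- NA_integer_          # structural: absent feature
  mask <- matrix(stats::runif(n * 15), n, 15) <
    matrix(config$na_prob, n, 15, byrow = TRUE)
  scores[mask] <- NA_integer_

  unif <- rep(1 / length(config$genes), length(config$genes))
  s <- config$association_strength
  gene <- vapply(seq_len(n), function(i) {
    p <- (1 - s) * unif + s * config$gene_emission[cl[i], ]
    sample(config$genes, 1L, prob = p)
  }, "")

  meta <- data.frame(
    patient_id = ids,
    birth_year = sample(2002:2021, n, replace = TRUE),
    sex = sample(c("M", "F"), n, replace = TRUE, prob = c(0.62, 0.38)),
    gene = gene,
    diagnosis = "synthetic",
    family_id = ids,
    stringsAsFactors = FALSE
  )
  cohort <- structure(list(meta = meta, scores = scores,
                           domains = domain_names()),
                      class = "phenostrat_cohort")
  truth <- list(cluster = stats::setNames(cl, ids),
                gene = stats::setNames(gene, ids),
                scores_premask = premask,
                gene_cluster_table = table(factor(gene, levels = config$genes),
                                           factor(cl, levels = seq_len(k))))
  list(cohort = cohort, truth = truth)
}

#' Adjusted Rand Index between two partitions
#'
#' Chance-corrected agreement, used to score cluster recovery against the
#' generator's ground truth. Thin wrapper over
#' [mclust::adjustedRandIndex()].
#'
#' @param a,b Two label vectors of equal length (matched by name when both are
#'   named).
#' @return ARI in `[-1, 1]`; 1 = identical partitions.
#' @export
ari <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) b <- b[names(a)]
  mclust::adjustedRandIndex(a, b)
}

#' Monte-Carlo rejection rate of the gene-by-cluster chi-squared test
#'
#' For each grid point (cohort size x association strength), repeatedly
#' generates a synthetic cohort, runs the full analysis pipeline
#' (Z-normalization, Euclidean HCA, k-cut, gene-by-cluster Pearson
#' chi-squared) and records the rejection frequency at level `alpha`. At
#' `association_strength = 0` the gene labels are independent of any
#' score-derived partition, so the rejection rate estimates the test's type-I
#' error under the pipeline's actual operating conditions.
#'
#' @param n_patients Vector of cohort sizes.
#' @param association_strength Vector of mixture strengths in `[0, 1]`.
#' @param n_reps Replicates per grid point (0 gives an empty table).
#' @param alpha Significance level.
#' @param k Number of clusters cut from the dendrogram.
#' @param linkage Linkage for [hca()].
#' @param base_config A [sim_config()] supplying all other generator settings.
#' @param seed Optional seed set once before the sweep.
#' @return data.frame with one row per grid point: `n_patients`,
#'   `association_strength`, `n_reps`, `n_valid` (replicates where the test
#'   was computable) and `rejection_rate`.
#' @export
power_curve <- function(n_patients = 200, association_strength = c(0, 0.5, 1),
                        n_reps = 100, alpha = 0.05, k = 3,
                        linkage = "complete", base_config = sim_config(),
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  grid <- expand.grid(n_patients = n_patients,
                      association_strength = association_strength)
  if (n_reps < 1) {
    return(cbind(grid[0, ], n_reps = integer(), n_valid = integer(),
                 rejection_rate = numeric()))
  }
  out <- lapply(seq_len(nrow(grid)), function(g) {
    n <- grid$n_patients[g]
    s <- grid$association_strength[g]
    pvals <- vapply(seq_len(n_reps), function(r) {
      cfg <- sim_config(n_patients = n, k_clusters = base_config$k_clusters,
                        cluster_weights = base_config$cluster_weights,
                        domain_means = base_config$domain_means,
                        domain_sd = base_config$domain_sd,
                        na_prob = base_config$na_prob,
                        genes = base_config$genes,
                        gene_emission = base_config$gene_emission,
                        association_strength = s, seed = NULL)
      sim <- generate_cohort(cfg)
      z <- zscore(sim$cohort, na_policy = "zero")
      cls <- cut_clusters(hca(euclidean_distances(z), linkage = linkage),
                          k, composite_severity(z))
      tryCatch(
        suppressWarnings(
          chisquare(contingency(sim$cohort, cls))$p_value),
        error = function(e) NA_real_)
    }, numeric(1))
    data.frame(n_patients = n, association_strength = s, n_reps = n_reps,
               n_valid = sum(!is.na(pvals)),
               rejection_rate = mean(pvals < alpha, na.rm = TRUE))
  })
  do.call(rbind, out)
}
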