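#' Euclidean distance matrix between patient Z-profiles
#'
#' d(i, j) = sqrt(sum_d (Z_id - Z_jd)^2) over the 15 domains.
#'
#' @param z A `phenostrat_zmatrix` or numeric matrix (rows = patients). Must
#'   be NA-free: apply a missing-data policy upstream (`na_policy = "zero"`).
#' @return Symmetric n x n numeric matrix with zero diagonal, dimnames from
#'   patient ids.
#' @export
euclidean_distances <- function(z) {
  v <- if (inherits(z, "phenostrat_zmatrix")) z$values else as.matrix(z)
  if (anyNA(v)) {
    stop("Z-matrix contains NA; use na_policy = \"zero\" (or impute) before ",
         "computing distances")
  }
  as.matrix(stats::dist(v, method = "euclidean"))
}

as_dist_matrix <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || !isSymmetric(unname(d), tol = 1e-10)) {
    stop("distance matrix must be square and symmetric")
  }
  if (any(d < 0) || any(abs(diag(d)) > 1e-10)) {
    stop("distance matrix must be non-negative with zero diagonal")
  }
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("obs", seq_len(nrow(d)))
  }
  d
}

# leaf order without branch crossings, from an hclust-style merge matrix
leaf_order <- function(merge) {
  n <- nrow(merge) + 1L
  out <- vector("list", n - 1L)
  for (s in seq_len(n - 1L)) {
    left <- if (merge[s, 1L] < 0) -merge[s, 1L] else out[[merge[s, 1L]]]
    right <- if (merge[s, 2L] < 0) -merge[s, 2L] else out[[merge[s, 2L]]]
    out[[s]] <- c(left, right)
  }
  out[[n - 1L]]
}

#' Agglomerative hierarchical clustering with a deterministic tie-break
#'
#' Bottom-up agglomeration on a pre-computed distance matrix with complete
#' linkage (merge cost = maximum inter-cluster pairwise distance) or Ward
#' linkage (merge cost = increase in within-cluster sum of squares;
#' Lance-Williams update on squared Euclidean distances, heights reported on
#' the original distance scale). When several cluster pairs share the minimal
#' merge cost -- which happens systematically when patients have identical
#' score profiles -- the pair whose (smallest-original-index, second-index)
#' identifier is lexicographically smallest is merged, making the merge
#' sequence deterministic and independent of input order.
#'
#' @param d Symmetric distance matrix (e.g. from [euclidean_distances()]) or a
#'   `dist` object.
#' @param linkage `"complete"` (default) or `"ward"`.
#' @return An object of classes `phenostrat_hca` and `hclust` (compatible with
#'   [stats::cutree()], [stats::as.dendrogram()], `plot()`), with elements
#'   `merge`, `height`, `order`, `labels`, `method`, `dist.method`.
#' @examples
#' d <- euclidean_distances(matrix(c(0, 1, 10), ncol = 1))
#' h <- hca(d)
#' h$height   # 1, 10
#' @export
hca <- function(d, linkage = c("complete", "ward")) {
  linkage <- match.arg(linkage)
  D <- as_dist_matrix(d)
  n <- nrow(D)
  if (n < 2L) stop("hca needs at least 2 observations")
  labels <- rownames(D)

  work <- if (linkage == "ward") D^2 else D
  diag(work) <- Inf
  size <- rep(1, n)
  rep_idx <- seq_len(n)        # smallest original member index per cluster
  node <- -seq_len(n)          # hclust merge coding of the cluster in slot i
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (s in seq_len(n - 1L)) {
    m <- min(work)
    cand <- which(work == m, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    a <- pmin(rep_idx[cand[, 1L]], rep_idx[cand[, 2L]])
    b <- pmax(rep_idx[cand[, 1L]], rep_idx[cand[, 2L]])
    pick <- order(a, b)[1L]
    i <- cand[pick, 1L]
    j <- cand[pick, 2L]
    if (rep_idx[i] > rep_idx[j]) { k <- i; i <- j; j <- k }

    height[s] <- if (linkage == "ward") sqrt(m) else m
    pair <- c(node[i], node[j])
    # hclust row convention: singletons before internal nodes, ascending
    pair <- pair[order(pair >= 0, abs(pair))]
    merge[s, ] <- pair

    others <- which(is.finite(work[i, ]) | is.finite(work[j, ]))
    others <- setdiff(others, c(i, j))
    if (length(others)) {
      dik <- work[i, others]
      djk <- work[j, others]
      upd <- if (linkage == "complete") {
        pmax(dik, djk)
      } else {
        ( (size[i] + size[others]) * dik +
          (size[j] + size[others]) * djk -
          size[others] * m ) / (size[i] + size[j] + size[others])
      }
      work[i, others] <- upd
      work[others, i] <- upd
    }
    work[j, ] <- Inf
    work[, j] <- Inf
    work[i, i] <- Inf
    size[i] <- size[i] + size[j]
    node[i] <- s
  }

  structure(list(merge = merge, height = height, order = leaf_order(merge),
                 labels = labels, method = linkage,
                 call = match.call(), dist.method = "euclidean"),
            class = c("phenostrat_hca", "hclust"))
}

#' Cut a dendrogram into k severity-ranked clusters
#'
#' Cuts the merge tree at the height yielding exactly `k` groups and, when a
#' composite-severity vector is supplied, renumbers the groups by descending
#' median composite severity so cluster 1 is always the most severe. Ties in
#' the median are broken by the original (cutree) label order.
#'
#' @param dend An `hclust`-like tree from [hca()].
#' @param k Number of clusters, `1 <= k <= n`.
#' @param severity Optional named numeric from [composite_severity()]; names
#'   must cover the tree's labels.
#' @return Object of class `phenostrat_clusters`: named integer vector of
#'   labels in `1..k`, with attributes `k` and `linkage`.
#' @export
cut_clusters <- function(dend, k, severity = NULL) {
  stopifnot(inherits(dend, "hclust"))
  n <- length(dend$labels)
  if (k < 1 || k > n) stop("k must be between 1 and n = ", n)
  raw <- stats::cutree(dend, k = k)
  if (!is.null(severity)) {
    if (!all(names(raw) %in% names(severity))) {
      stop("severity vector does not cover all patients in the tree")
    }
    med <- tapply(severity[names(raw)], raw, stats::median)
    ranking <- order(-med, as.integer(names(med)))
    relabel <- integer(k)
    relabel[as.integer(names(med))[ranking]] <- seq_len(k)
    raw <- stats::setNames(relabel[raw], names(raw))
  }
  structure(raw, k = as.integer(k), linkage = dend$method,
            class = "phenostrat_clusters")
}

#' @export
print.phenostrat_clusters <- function(x, ...) {
  cat("cluster assignment: k =", attr(x, "k"),
      "(", attr(x, "linkage"), "linkage ), sizes:",
      paste(table(unclass(x)), collapse = "/"), "\n")
  invisible(x)
}

#' Per-cluster per-domain score distributions
#'
#' Summarizes the raw ordinal scores (NA kept as NA) within each cluster:
#' median, quartiles and NA count per (cluster, domain) pair. This is the
#' tabular counterpart of a box-plot panel stratified by cluster.
#'
#' @param cohort A `phenostrat_cohort`.
#' @param assign Cluster labels from [cut_clusters()] (named by patient), or
#'   any named vector covering the cohort.
#' @return data.frame with columns `cluster`, `domain`, `n`, `n_na`, `q1`,
#'   `median`, `q3`.
#' @export
cluster_profile <- function(cohort, assign) {
  stopifnot(inherits(cohort, "phenostrat_cohort"))
  ids <- rownames(cohort$scores)
  if (!all(ids %in% names(assign))) {
    stop("assignment does not cover every patient in the cohort")
  }
  lab <- as.integer(assign[ids])
  rows <- list()
  for (cl in sort(unique(lab))) {
    sub <- cohort$scores[lab == cl, , drop = FALSE]
    for (dom in colnames(sub)) {
      v <- sub[, dom]
      q <- stats::quantile(v, c(.25, .5, .75), na.rm = TRUE, names = FALSE,
                           type = 7)
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = cl, domain = dom, n = length(v), n_na = sum(is.na(v)),
        q1 = q[1], median = q[2], q3 = q[3])
    }
  }
  do.call(rbind, rows)
}

#' Export a dendrogram as Newick text
#'
#' Leaves are patient ids; branch lengths derive from merge heights.
#'
#' @param dend An `hclust`-like tree from [hca()].
#' @param path Optional file to write to.
#' @return Newick string (invisibly if `path` is given).
#' @export
hca_newick <- function(dend, path = NULL) {
  stopifnot(inherits(dend, "hclust"))
  phy <- ape::as.phylo(dend)
  txt <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
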