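# Naive agglomerative oracle: complete linkage recomputed from the original
# distance matrix at every step (no Lance-Williams recursion), same
# lexicographic tie-break as hca(). Exhaustive O(n^3) scan.
naive_complete_heights <- function(D) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  heights <- numeric(n - 1)
  for (s in seq_len(n - 1)) {
    best <- NULL
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i >= j) next
        h <- max(D[clusters[[i]], clusters[[j]]])
        key <- c(h, min(clusters[[i]], clusters[[j]]),
                 max(min(clusters[[i]]), min(clusters[[j]])))
        if (is.null(best) || h < best$key[1] - 1e-12 ||
            (abs(h - best$key[1]) <= 1e-12 &&
             (key[2] < best$key[2] ||
              (key[2] == best$key[2] && key[3] < best$key[3])))) {
          best <- list(key = key, i = i, j = j)
        }
      }
    }
    heights[s] <- best$key[1]
    clusters[[best$i]] <- c(clusters[[best$i]], clusters[[best$j]])
    clusters[[best$j]] <- NULL
  }
  heights
}

# definitional Pearson chi-square from raw sums
brute_chisq <- function(tab) {
  n <- sum(tab)
  E <- outer(rowSums(tab), colSums(tab)) / n
  sum((tab - E)^2 / E)
}

# definitional Pearson R from raw sums
brute_pearson <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
}
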