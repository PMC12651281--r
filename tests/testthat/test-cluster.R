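test_that("euclidean distances match a double-loop recomputation", {
  set.seed(11)
  m <- matrix(rnorm(6 * 4), 6, 4)
  D <- euclidean_distances(m)
  ref <- matrix(0, 6, 6)
  for (i in 1:6) for (j in 1:6) ref[i, j] <- sqrt(sum((m[i, ] - m[j, ])^2))
  expect_equal(unname(D), ref, tolerance = 1e-12)
  expect_equal(euclidean_distances(rbind(c(0, 0), c(3, 4)))[1, 2], 5)
  expect_equal(euclidean_distances(rbind(c(1, 2), c(1, 2)))[1, 2], 0)
  expect_error(euclidean_distances(matrix(c(1, NA, 2, 3), 2)), "na_policy")
})

test_that("hca reproduces hand-derived merges on 1-D points", {
  h <- hca(euclidean_distances(matrix(c(0, 1, 10), ncol = 1)))
  expect_equal(h$height, c(1, 10))
  expect_equal(h$merge[1, ], c(-1, -2))

  h2 <- hca(euclidean_distances(matrix(c(0, 4), ncol = 1)))
  expect_equal(h2$height, 4)
})

test_that("hca complete-linkage heights equal the naive oracle on random instances", {
  set.seed(21)
  for (rep in 1:100) {
    n <- sample(4:10, 1)
    m <- matrix(rnorm(n * 3), n, 3)
    D <- euclidean_distances(m)
    expect_equal(hca(D, "complete")$height, naive_complete_heights(D),
                 tolerance = 1e-10)
  }
})

test_that("hca agrees with stats::hclust on tie-free data for both linkages", {
  set.seed(33)
  for (rep in 1:20) {
    n <- sample(5:20, 1)
    m <- matrix(rnorm(n * 4), n, 4)
    D <- euclidean_distances(m)
    expect_equal(hca(D, "complete")$height,
                 hclust(as.dist(D), "complete")$height, tolerance = 1e-10)
    expect_equal(hca(D, "ward")$height,
                 hclust(as.dist(D), "ward.D2")$height, tolerance = 1e-10)
    expect_equal(cutree(hca(D, "complete"), 3),
                 cutree(hclust(as.dist(D), "complete"), 3))
  }
})

test_that("merge heights are monotone non-decreasing", {
  set.seed(5)
  for (linkage in c("complete", "ward")) {
    D <- euclidean_distances(matrix(rnorm(15 * 4), 15, 4))
    expect_true(all(diff(hca(D, linkage)$height) >= -1e-12))
  }
  # also under exact ties (duplicated rows)
  m <- rbind(c(0, 0), c(0, 0), c(1, 0), c(1, 0), c(5, 5))
  expect_true(all(diff(hca(euclidean_distances(m))$height) >= 0))
})

test_that("permuting patient order changes no height and no final grouping", {
  coh <- cohort_fixture()
  z <- zscore(coh)
  base_tree <- hca(euclidean_distances(z))
  base <- cut_clusters(base_tree, 3, composite_severity(z))
  set.seed(9)
  for (rep in 1:5) {
    perm <- sample(nrow(z$values))
    zp <- z$values[perm, ]
    tree <- hca(euclidean_distances(zp))
    expect_equal(sort(tree$height), sort(base_tree$height), tolerance = 1e-10)
    cl <- cut_clusters(tree, 3, composite_severity(z)[rownames(zp)])
    expect_equal(as.integer(cl[names(base)]), as.integer(base))
  }
})

test_that("hca rejects malformed distance input", {
  bad <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(hca(bad), "symmetric")
  expect_error(hca(matrix(0, 1, 1)), "at least 2")
})

test_that("cut_clusters covers the edge cuts and severity-ranks labels", {
  z <- zscore(cohort_fixture())
  tree <- hca(euclidean_distances(z))
  sev <- composite_severity(z)
  n <- nrow(z$values)

  all_one <- cut_clusters(tree, 1, sev)
  expect_true(all(all_one == 1))
  singletons <- cut_clusters(tree, n, sev)
  expect_equal(sort(unique(as.integer(singletons))), 1:n)
  expect_error(cut_clusters(tree, n + 1, sev), "between 1 and")

  k3 <- cut_clusters(tree, 3, sev)
  med <- tapply(sev[names(k3)], as.integer(k3), median)
  expect_true(all(diff(med) < 0))   # cluster 1 most severe, strictly ordered
})

test_that("patients with identical score rows always co-cluster", {
  coh <- cohort_fixture()
  z <- zscore(coh)
  cl <- cut_clusters(hca(euclidean_distances(z)), 3, composite_severity(z))
  fam <- cl[c("ID1.1", "ID1.2", "ID2.1", "ID2.2", "ID2.3")]
  expect_equal(length(unique(as.integer(fam))), 1)   # NKX6-2 families together
})

test_that("cluster_profile summarizes per-cluster domain distributions", {
  coh <- cohort_fixture()
  cl <- fixture_assignment()
  prof <- cluster_profile(coh, cl)
  expect_equal(nrow(prof), 3 * 15)

  # single cluster equals the whole-cohort distribution
  one <- setNames(rep(1L, 29), rownames(coh$scores))
  p1 <- cluster_profile(coh, one)
  expect_equal(p1$median[p1$domain == "motor"],
               median(coh$scores[, "motor"], na.rm = TRUE))

  # severe cluster's median motor score >= mild cluster's
  motor <- prof[prof$domain == "motor", ]
  expect_gte(motor$median[motor$cluster == 1], motor$median[motor$cluster == 3])

  expect_error(cluster_profile(coh, one[-1]), "cover")
})

test_that("cluster_profile recovers generator cluster means on synthetic data", {
  means <- default_domain_profiles(3, separation = 2)
  sim <- generate_cohort(sim_config(n_patients = 120, domain_means = means,
                                    cluster_weights = rep(1, 3) / 3,
                                    domain_sd = 0.3, na_prob = 0, seed = 17))
  prof <- cluster_profile(sim$cohort,
                          structure(sim$truth$cluster, k = 3L))
  for (cl in 1:3) {
    sub <- prof[prof$cluster == cl, ]
    med <- setNames(sub$median, sub$domain)
    mu <- means[cl, names(med)]
    # medians are conditional on the feature being present (score >= 1), so
    # only domains whose true mean is well inside the observable range are
    # comparable to the generator mean
    obs <- !is.na(med) & mu >= 1
    expect_true(all(abs(med[obs] - mu[obs]) <= 0.5))
  }
})

test_that("dendrogram exports as Newick with patient leaves", {
  tree <- hca(euclidean_distances(zscore(cohort_fixture())))
  txt <- hca_newick(tree)
  expect_match(txt, "^\\(")
  expect_match(txt, "ID1\\.1")
  phy <- ape::read.tree(text = txt)
  expect_setequal(phy$tip.label, tree$labels)
})
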