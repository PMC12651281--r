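test_that("gene contingency table has full shape with the fixture cohort", {
  coh <- cohort_fixture()
  cl <- fixture_assignment()
  tab <- contingency(coh, cl)
  expect_equal(dim(tab), c(18, 3))
  expect_equal(sum(tab), 29)
  gene_counts <- table(coh$meta$gene)
  expect_equal(unname(rowSums(tab)), as.integer(gene_counts[rownames(tab)]))

  # single-cluster assignment: one column holding the per-gene counts
  one <- structure(setNames(rep(1L, 29), rownames(coh$scores)), k = 1L)
  t1 <- contingency(coh, one)
  expect_equal(ncol(t1), 1)
  expect_equal(unname(t1[, 1]), as.integer(gene_counts[rownames(t1)]))

  expect_error(contingency(coh, one[-3]), "unassigned")
})

test_that("contingency cells match the generator's gene-cluster draws", {
  sim <- generate_cohort(sim_config(n_patients = 80, seed = 23))
  truth_cl <- structure(sim$truth$cluster, k = 3L)
  tab <- contingency(sim$cohort, truth_cl)
  ref <- sim$truth$gene_cluster_table
  present <- rownames(ref)[rowSums(ref) > 0]
  expect_true(all(tab[present, ] == ref[present, ]))
  expect_identical(rownames(tab), rownames(ref))
})

test_that("pathway contingency groups genes into categories", {
  coh <- cohort_fixture()
  cl <- fixture_assignment()
  tab <- contingency(coh, cl, by = "pathway", annot = pathway_fixture())
  expect_equal(sum(tab), 29)
  expect_equal(nrow(tab), 3)   # all three categories present in this cohort
  expect_error(contingency(coh, cl, by = "pathway"), "annotation")
})

test_that("chisquare matches closed forms on 2x2 tables", {
  r <- chisquare(rbind(c(10, 0), c(0, 10)))
  expect_equal(r$statistic, 20)           # n(ad-bc)^2 / row x col products
  expect_equal(r$df, 1)
  expect_equal(r$p_value, pchisq(20, 1, lower.tail = FALSE))

  flat <- suppressWarnings(chisquare(rbind(c(5, 5), c(5, 5))))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)
})

test_that("chisquare equals brute-force sum((O-E)^2/E) on random tables", {
  set.seed(41)
  for (rep in 1:100) {
    nr <- sample(2:6, 1); nc <- sample(2:4, 1)
    tab <- matrix(rpois(nr * nc, 4) + 1, nr, nc)  # +1 avoids empty rows/cols
    r <- suppressWarnings(chisquare(tab))
    expect_equal(r$statistic, brute_chisq(tab), tolerance = 1e-9)
    expect_equal(r$df, (nr - 1) * (nc - 1))
    expect_equal(r$p_value,
                 pchisq(brute_chisq(tab), (nr - 1) * (nc - 1),
                        lower.tail = FALSE), tolerance = 1e-9)
  }
})

test_that("chisquare statistic is invariant to row/column permutations", {
  set.seed(43)
  tab <- matrix(rpois(15, 5) + 1, 5, 3)
  base <- suppressWarnings(chisquare(tab))$statistic
  for (rep in 1:10) {
    p <- tab[sample(5), sample(3)]
    expect_equal(suppressWarnings(chisquare(p))$statistic, base,
                 tolerance = 1e-12)
  }
})

test_that("chisquare drops empty rows/columns with a warning and validates input", {
  tab <- rbind(c(6, 2), c(0, 0), c(3, 7))
  w <- capture_warnings(r <- chisquare(tab))
  expect_true(any(grepl("empty row", w)))
  expect_equal(r$df, 1)            # 2 non-empty rows remain
  expect_error(chisquare(matrix(0, 2, 2)), "empty")
  expect_error(chisquare(rbind(c(1, -1), c(2, 2))), "non-negative")
  expect_error(suppressWarnings(chisquare(rbind(c(3, 0), c(2, 0)))),
               "non-empty")
})

test_that("expected counts below 5 trigger a warning but still return the statistic", {
  tab <- rbind(c(2, 0, 1), c(0, 2, 1), c(1, 1, 0))
  expect_warning(chisquare(tab), "below 5")
})

test_that("phenotype overlap partitions the curated flags as published", {
  part <- phenotype_overlap(flags_fixture())
  expect_length(part, 15)

  expect_length(part[["dysmorphism"]], 0)        # no dysmorphism-only gene
  nmi <- part[["neurological+motor+intellectual_disability"]]
  expect_true(all(c("IQSEC2", "SCN2A", "ADSL", "PLP1", "NKX6-2", "ATP1A3")
                  %in% nmi))
  expect_setequal(part[["motor+intellectual_disability+dysmorphism"]],
                  c("ACTG1", "SMAD6"))
  expect_true(all(c("NIPBL", "TCF4") %in%
                  part[["neurological+intellectual_disability+dysmorphism"]]))

  # regions are disjoint and cover every flagged gene
  all_genes <- unlist(part)
  expect_false(any(duplicated(all_genes)))
  flags <- flags_fixture()
  flagged <- flags$gene[rowSums(flags[, -1]) > 0]
  expect_setequal(all_genes, flagged)
})

test_that("phenotype overlap of all-false flags is empty", {
  f <- data.frame(gene = c("A", "B"), neurological = FALSE, motor = FALSE,
                  intellectual_disability = FALSE, dysmorphism = FALSE)
  expect_length(unlist(phenotype_overlap(f)), 0)
})

test_that("pathway summary reports per-cluster composition and modal category", {
  coh <- cohort_fixture()
  annot <- pathway_fixture()
  # force a cluster holding only transcription-pathway patients
  ids <- rownames(coh$scores)
  lab <- setNames(rep(2L, 29), ids)
  lab[coh$meta$gene %in% c("TCF4", "HNRNPU", "NIPBL")] <- 1L
  ps <- pathway_summary(structure(lab, k = 2L), annot, coh)
  expect_equal(unname(ps$modal[1]), "transcription_rna_processing")
  expect_equal(sum(ps$counts), 29)

  # empty cluster: zero row, NA modal
  ps3 <- pathway_summary(structure(lab, k = 3L), annot, coh)
  expect_equal(sum(ps3$counts[3, ]), 0)
  expect_true(is.na(ps3$modal[3]))
})

test_that("modal pathway matches generator truth under strong association", {
  # genes named after pathway blocks; emission deterministic per cluster
  genes <- sprintf("GENE%02d", 1:18)
  annot <- setNames(rep(c("transcription_rna_processing",
                          "ion_channel_metabolic",
                          "myelination_structural_signaling"), each = 6),
                    genes)
  hits <- 0L
  set.seed(57)
  for (rep in 1:20) {
    sim <- generate_cohort(sim_config(n_patients = 90, genes = genes,
                                      cluster_weights = rep(1, 3) / 3,
                                      association_strength = 1, seed = NULL))
    ps <- pathway_summary(structure(sim$truth$cluster, k = 3L), annot,
                          sim$cohort)
    want <- c("transcription_rna_processing", "ion_channel_metabolic",
              "myelination_structural_signaling")
    hits <- hits + as.integer(identical(unname(ps$modal), want))
  }
  expect_gte(hits / 20, 0.95)
})
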