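test_that("ternary Jaccard distance follows the equal-nonzero-state convention", {
  expect_equal(jaccard_distance(c(1, 0, -1, 1), c(1, 1, -1, 0)), 0.5)
  expect_equal(jaccard_distance(c(1, 0, -1), c(1, 0, -1)), 0)
  expect_equal(jaccard_distance(c(1, 1), c(-1, -1)), 1)     # disjoint states
  expect_equal(jaccard_distance(c(0, 0), c(0, 0)), 0)       # all-zero: identical
  # binarized variant treats hyper and hypo alike
  expect_equal(jaccard_distance(c(1, 1), c(-1, -1), binarize = TRUE), 0)
  expect_error(jaccard_distance(c(1, 0), c(1, 0, 1)), "equal length")
})

test_that("pairwise distance matrix agrees with the scalar definition", {
  set.seed(13)
  tern <- matrix(sample(c(-1L, 0L, 1L), 20 * 6, TRUE, prob = c(0.2, 0.6, 0.2)),
                 20, 6, dimnames = list(NULL, paste0("t", 1:6)))
  D <- as.matrix(methdriver:::ternary_jaccard_dist(tern))
  for (i in 1:5) for (j in (i + 1):6) {
    expect_equal(D[i, j], jaccard_distance(tern[, i], tern[, j]))
  }
  expect_true(all(D >= 0 & D <= 1))
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))
})

test_that("UPGMA clustering recovers planted blocks and is column-order invariant", {
  tern <- block_ternary(n_per_block = 6, loci_per_block = 5, noise = 6)
  truth <- rep(1:3, each = 6)
  names(truth) <- colnames(tern)
  cl <- hierarchical_cluster(tern, k = 3)
  expect_true(same_partition(cl$labels[names(truth)], truth))

  # shuffling tumor columns changes nothing (canonical sort rule)
  set.seed(1)
  cl2 <- hierarchical_cluster(tern[, sample(ncol(tern))], k = 3)
  expect_identical(cl2$labels, cl$labels)

  # k = n: every tumor its own cluster
  cl_n <- hierarchical_cluster(tern, k = ncol(tern))
  expect_equal(length(unique(cl_n$labels)), ncol(tern))

  # duplicate columns co-cluster for k < n
  tern_dup <- tern
  tern_dup[, "T002"] <- tern_dup[, "T001"]
  cl_d <- hierarchical_cluster(tern_dup, k = 5)
  expect_equal(cl_d$labels[["T001"]], cl_d$labels[["T002"]])

  expect_error(hierarchical_cluster(tern, k = 100), "exceeds")
  # merge heights non-decreasing along the agglomeration
  expect_true(all(diff(cl$hclust$height) >= -1e-12))
})

test_that("dendrogram exports as Newick", {
  cl <- hierarchical_cluster(block_ternary(), k = 3)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_dendrogram_newick(cl, path)
  tree <- ape::read.tree(path)
  expect_setequal(tree$tip.label, colnames(block_ternary()))
})

test_that("subtype-specificity p matches the exact tail and flags enrichment only", {
  # frequencies mirroring a basal-like hypomethylation call: 14/22 altered in
  # the subtype vs 17/66 elsewhere (31/88 overall)
  expect_equal(hypergeom_upper(14, 31, 22, 88), sum_hyper_upper(14, 31, 22, 88),
               tolerance = 1e-12)
  expect_equal(hypergeom_upper(14, 31, 22, 88), 1.70e-3, tolerance = 0.05)

  tumors <- sprintf("t%02d", 1:40)
  subtypes <- setNames(rep(c("A", "B"), each = 20), tumors)
  tern <- matrix(0L, 2, 40, dimnames = list(c("l1", "l2"), tumors))
  tern["l1", 1:12] <- 1L                      # all altered tumors inside A
  tern["l2", c(1:5, 21:25)] <- -1L            # 5/20 in each: no enrichment
  drv <- data.frame(locus_id = c("l1", "l2"), gene_id = c("g1", "g2"),
                    direction = c("hyper", "hypo"), state = c(1L, -1L))
  res <- subtype_specific_test(tern, drv, subtypes)
  calls <- res$calls
  expect_true(calls$specific[calls$locus_id == "l1" & calls$subtype == "A"])
  expect_false(any(calls$specific[calls$locus_id == "l2"]))
  # equal frequency: k/n = K/N, p >= 0.5 and never specific
  l2A <- calls[calls$locus_id == "l2" & calls$subtype == "A", ]
  expect_gte(l2A$p, 0.5)
  expect_identical(res$specific_genes$A, "g1")
  expect_length(res$specific_genes$B, 0)

  # unlabeled tumors are excluded with a message
  subtypes_na <- subtypes
  subtypes_na[1:2] <- NA
  expect_message(subtype_specific_test(tern, drv, subtypes_na), "unlabeled")
  expect_error(subtype_specific_test(tern, drv, setNames(rep("A", 40), tumors)),
               ">= 2 subtype")
})
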