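test_that("beta formula matches direct arithmetic and clamps negatives", {
  expect_equal(compute_beta(100, 100), 100 / 300)
  expect_equal(compute_beta(-5, 10), 0)     # numerator clamped at 0
  expect_equal(compute_beta(0, 0), 0)       # 0 / 100
  expect_error(compute_beta(Inf, 1), "finite")
  expect_error(compute_beta(1, NA), "finite")

  # always in [0, 1): numerator <= |M| < |U| + |M| + 100
  set.seed(5)
  M <- rnorm(500, 0, 5000); U <- rnorm(500, 0, 5000)
  b <- compute_beta(M, U)
  expect_true(all(b >= 0 & b < 1))
})

test_that("detection-p filter drops loci failing in strictly more than 10% of samples", {
  dp <- matrix(0.01, 3, 10,
               dimnames = list(c("keep_all", "keep_boundary", "drop"), NULL))
  dp["keep_boundary", 1] <- 0.5          # 1/10 failing: exactly 10%, retained
  dp["drop", 1:2] <- 0.5                 # 2/10 failing: dropped
  expect_identical(filter_unreliable_loci(dp), c("keep_all", "keep_boundary"))
  expect_identical(filter_unreliable_loci(dp * 0 + 0.01), rownames(dp))
})

test_that("sex-chromosome exclusion keeps autosomes only", {
  ann <- data.frame(locus_id = c("l1", "l2", "l3", "l4"),
                    gene_id = paste0("g", 1:4),
                    chromosome = c("1", "X", "7", "Y"))
  expect_identical(exclude_sex_chromosomes(ann$locus_id, ann), c("l1", "l3"))
  expect_identical(exclude_sex_chromosomes(c("l1", "l3"), ann), c("l1", "l3"))
  expect_warning(exclude_sex_chromosomes(c("l2", "l4"), ann), "nothing retained")
  expect_error(exclude_sex_chromosomes("nope", ann), "missing from annotation")
})

test_that("differential expression handles degenerate and extreme genes", {
  set.seed(2)
  expr <- matrix(rnorm(50 * 10), 50, 10,
                 dimnames = list(paste0("g", 1:50), paste0("s", 1:10)))
  expr["g1", ] <- 3                                    # constant gene
  expr["g2", ] <- c(rep(0, 5), rep(5, 5)) + rnorm(10, 0, 1e-3)
  de <- differential_expression(expr, paste0("s", 1:5), paste0("s", 6:10))
  expect_equal(de$p[de$gene_id == "g1"], 1)            # zero variance -> p = 1
  expect_false(de$de[de$gene_id == "g1"])
  expect_true(de$q[de$gene_id == "g2"] < 0.05)
  expect_equal(de$direction[de$gene_id == "g2"], -1)   # groupA below groupB

  # symmetric under group swap up to direction sign
  de2 <- differential_expression(expr, paste0("s", 6:10), paste0("s", 1:5))
  expect_equal(de2$p, de$p)
  expect_equal(de2$direction[de$gene_id != "g1"], -de$direction[de$gene_id != "g1"])

  expect_error(differential_expression(expr, "s1", paste0("s", 6:10)), ">= 2")
  expect_error(differential_expression(expr, paste0("s", 1:5), paste0("s", 5:9)),
               "disjoint")
})

test_that("row-wise Welch t agrees with stats::t.test", {
  set.seed(3)
  expr <- matrix(rnorm(20 * 12, 5), 20, 12,
                 dimnames = list(paste0("g", 1:20), paste0("s", 1:12)))
  de <- differential_expression(expr, paste0("s", 1:5), paste0("s", 6:12))
  for (g in c("g1", "g7", "g20")) {
    ref <- t.test(expr[g, 1:5], expr[g, 6:12])
    expect_equal(de$p[de$gene_id == g], ref$p.value, tolerance = 1e-12)
    expect_equal(de$stat[de$gene_id == g], unname(ref$statistic), tolerance = 1e-12)
  }
  # pooled-variance variant against var.equal = TRUE
  de_s <- differential_expression(expr, paste0("s", 1:5), paste0("s", 6:12),
                                  var_equal = TRUE)
  ref <- t.test(expr["g3", 1:5], expr["g3", 6:12], var.equal = TRUE)
  expect_equal(de_s$p[de_s$gene_id == "g3"], ref$p.value, tolerance = 1e-12)
})

test_that("t-test p-values are calibrated under the null", {
  set.seed(41)
  expr <- matrix(rnorm(2000 * 20), 2000, 20,
                 dimnames = list(paste0("g", 1:2000), paste0("s", 1:20)))
  de <- differential_expression(expr, paste0("s", 1:10), paste0("s", 11:20))
  expect_equal(mean(de$p < 0.05), 0.05, tolerance = 0.02 / 0.05)
  expect_false(any(de$de))  # BH on a global null finds ~nothing
  # BH q monotone non-decreasing in p rank
  expect_true(all(diff(de$q[order(de$p)]) >= -1e-12))
})
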