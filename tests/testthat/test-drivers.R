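make_annotation <- function(loci, genes = NULL) {
  data.frame(locus_id = loci,
             gene_id = if (is.null(genes)) paste0("gene_", loci) else genes,
             chromosome = "1", stringsAsFactors = FALSE)
}

test_that("frequency filter uses an inclusive 10% boundary and drops both-direction genes", {
  tern <- matrix(0L, 3, 100,
                 dimnames = list(c("lA", "lB", "lC"), sprintf("t%03d", 1:100)))
  tern["lA", 1:10] <- 1L    # exactly 10%: retained
  tern["lB", 1:9] <- 1L     # 9%: not a candidate
  tern["lC", 1:15] <- -1L
  ann <- make_annotation(c("lA", "lB", "lC"))
  cand <- frequency_filter(tern, ann)
  expect_setequal(cand$locus_id, c("lA", "lC"))
  expect_equal(cand$n_altered[cand$locus_id == "lA"], 10)
  expect_equal(cand$n_zero[cand$locus_id == "lA"], 90)

  # same GENE hyper at one locus (15%) and hypo at another (12%): both dropped
  tern2 <- matrix(0L, 3, 100,
                  dimnames = list(c("l1", "l2", "l3"), sprintf("t%03d", 1:100)))
  tern2["l1", 1:15] <- 1L
  tern2["l2", 1:12] <- -1L
  tern2["l3", 1:20] <- 1L
  ann2 <- make_annotation(c("l1", "l2", "l3"), c("gX", "gX", "gY"))
  cand2 <- frequency_filter(tern2, ann2)
  expect_identical(cand2$locus_id, "l3")
})

test_that("cis test passes only concordant, significant candidates", {
  set.seed(8)
  tern <- matrix(0L, 2, 30, dimnames = list(c("l1", "l2"), sprintf("t%02d", 1:30)))
  tern[, 1:10] <- 1L
  ann <- make_annotation(c("l1", "l2"), c("g1", "g2"))
  expr <- matrix(rnorm(2 * 30, 5, 0.1), 2, 30,
                 dimnames = list(c("g1", "g2"), colnames(tern)))
  expr["g1", 1:10] <- expr["g1", 1:10] - 2   # hyper, expression down: concordant
  expr["g2", 1:10] <- expr["g2", 1:10] + 2   # hyper, expression UP: discordant
  cand <- frequency_filter(tern, ann)
  res <- cis_test(cand, tern, expr)
  expect_true(res$cis_pass[res$gene_id == "g1"])
  expect_false(res$cis_pass[res$gene_id == "g2"])
  expect_lt(res$cis_q[res$gene_id == "g2"], 0.05)   # significant but discordant

  # gene missing from expression or groups too small -> skipped, not tested
  expr1 <- expr["g1", , drop = FALSE]
  res2 <- cis_test(cand, tern, expr1)
  expect_identical(res2$skip_reason[res2$gene_id == "g2"],
                   "gene_absent_from_expression")
  expect_false(res2$cis_pass[res2$gene_id == "g2"])
})

test_that("cis test is calibrated on null candidates", {
  set.seed(19)
  n_cand <- 200; n_tumor <- 40
  tern <- matrix(0L, n_cand, n_tumor,
                 dimnames = list(sprintf("l%03d", 1:n_cand), sprintf("t%02d", 1:n_tumor)))
  for (i in 1:n_cand) tern[i, sample(n_tumor, 12)] <- 1L
  ann <- make_annotation(rownames(tern), sprintf("g%03d", 1:n_cand))
  expr <- matrix(rnorm(n_cand * n_tumor, 5), n_cand, n_tumor,
                 dimnames = list(ann$gene_id, colnames(tern)))
  res <- cis_test(frequency_filter(tern, ann), tern, expr)
  expect_lt(mean(res$cis_pass), 0.05)
})

test_that("downstream genes recover a planted program and exclude the candidate's own gene", {
  set.seed(31)
  n_genes <- 500; nA <- 15; nB <- 20
  samples <- sprintf("t%02d", 1:(nA + nB))
  expr <- matrix(rnorm(n_genes * (nA + nB), 5), n_genes, nA + nB,
                 dimnames = list(sprintf("g%03d", 1:n_genes), samples))
  planted <- sprintf("g%03d", 101:140)
  expr[planted, 1:nA] <- expr[planted, 1:nA] + 2   # 2 sd shift in altered group
  expr["g001", 1:nA] <- expr["g001", 1:nA] + 3     # own gene strongly DE

  tern <- matrix(0L, 1, nA + nB, dimnames = list("l1", samples))
  tern[1, 1:nA] <- 1L
  cand <- data.frame(locus_id = "l1", gene_id = "g001", direction = "hyper",
                     state = 1L, n_altered = nA, n_zero = nB)
  ds <- downstream_genes(cand, tern, expr)
  expect_gte(length(intersect(ds$genes, planted)) / length(planted), 0.9)
  expect_false("g001" %in% ds$genes)               # self-exclusion

  # fully null expression: essentially nothing
  expr0 <- matrix(rnorm(n_genes * (nA + nB), 5), n_genes, nA + nB,
                  dimnames = dimnames(expr))
  expect_lte(downstream_genes(cand, tern, expr0)$count, 2)
})

test_that("BH discovery counts per replicate match p.adjust", {
  set.seed(12)
  pmat <- matrix(runif(200 * 25)^2, 200, 25,
                 dimnames = list(sprintf("g%03d", 1:200), NULL))
  counts <- methdriver:::bh_discovery_counts(pmat, 0.05)
  ref <- apply(pmat, 2, function(p) sum(p.adjust(p, "BH") <= 0.05))
  expect_equal(unname(counts), unname(ref))
  # excluding one gene removes it from the BH family
  counts2 <- methdriver:::bh_discovery_counts(pmat, 0.05, exclude_row = "g001")
  ref2 <- apply(pmat[-1, ], 2, function(p) sum(p.adjust(p, "BH") <= 0.05))
  expect_equal(unname(counts2), unname(ref2))
})

test_that("permutation p uses the add-one estimator and a plain-fraction option", {
  set.seed(4)
  n1 <- 5; n2 <- 6; B <- 120
  expr <- matrix(rnorm(80 * 20, 5), 80, 20,
                 dimnames = list(sprintf("g%02d", 1:80), sprintf("t%02d", 1:20)))
  cand <- data.frame(locus_id = "l1", gene_id = "g01", direction = "hyper",
                     state = 1L, n_altered = n1, n_zero = n2)
  pmat <- methdriver:::perm_p_matrix(expr, n1, n2, B, seed = 9)
  counts <- methdriver:::bh_discovery_counts(pmat, 0.05, exclude_row = "g01")

  # observed count of 0: every replicate count >= 0, so add-one p is exactly 1
  pt0 <- permutation_test(cand, expr, 0, B, seed = 9, pmat = pmat)
  expect_equal(pt0$p, 1)

  # pick an observed value with a known exceed count r and check (r+1)/(B+1)
  obs <- max(counts)            # r = number of replicates at the max
  r <- sum(counts >= obs)
  pt <- permutation_test(cand, expr, obs, B, seed = 9, pmat = pmat)
  expect_equal(pt$p, (r + 1) / (B + 1))
  pt_lit <- permutation_test(cand, expr, obs, B, seed = 9, pmat = pmat,
                             estimator = "literal")
  expect_equal(pt_lit$p, r / B)

  # impossible observed count: literal estimator hits 0, add-one stays positive
  pt_hi <- permutation_test(cand, expr, max(counts) + 1, B, seed = 9, pmat = pmat)
  expect_equal(pt_hi$p, 1 / (B + 1))
  expect_error(permutation_test(cand, expr, 1, 50, seed = 9), "B >= 100")
})

test_that("permutation replicates are deterministic given sizes and seed", {
  set.seed(6)
  expr <- matrix(rnorm(60 * 18, 5), 60, 18,
                 dimnames = list(sprintf("g%02d", 1:60), sprintf("t%02d", 1:18)))
  p1 <- methdriver:::perm_p_matrix(expr, 5, 7, 150, seed = 33)
  p2 <- methdriver:::perm_p_matrix(expr, 5, 7, 150, seed = 33)
  expect_identical(p1, p2)
  # and the replicate Welch p-values agree with the direct row-wise test
  set.seed(33)
  draw <- sample.int(18, 12)
  direct <- methdriver:::row_t_test(expr, draw[1:5], draw[6:12])
  expect_equal(unname(p1[, 1]), unname(direct$p), tolerance = 1e-10)
  expect_error(methdriver:::perm_p_matrix(expr, 10, 9, 100, 1), "exceed")
})

test_that("pathway enrichment matches exact enumeration and handles edge cases", {
  bg <- sprintf("g%02d", 1:20)
  pw <- list(hit = bg[1:5], other = bg[6:15])
  # downstream = exactly the 5-gene pathway: p = 1 / C(20,5)
  en <- pathway_enrichment(bg[1:5], pw, bg, q_cut = 1e-3)
  p_hit <- en$table$p[en$table$pathway == "hit"]
  expect_equal(p_hit, 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(p_hit, enum_hyper_upper(5, 5, 5, 20), tolerance = 1e-12)
  expect_true(en$pass)

  # no overlap: full upper tail, p = 1
  en0 <- pathway_enrichment(bg[16:20], list(hit = bg[1:5]), bg)
  expect_equal(en0$table$p, 1)
  # downstream = background: k = K for every pathway, p = 1
  enb <- pathway_enrichment(bg, pw, bg)
  expect_true(all(enb$table$p == 1))
  expect_error(pathway_enrichment("g1", pw, character(0)), "background")
})

test_that("shared hypergeometric tail matches enumeration for N <= 25", {
  set.seed(77)
  for (rep in 1:10) {
    N <- sample(8:25, 1); K <- sample(1:(N - 1), 1)
    n <- sample(1:min(6, N), 1); k <- sample(0:min(n, K), 1)
    expect_equal(hypergeom_upper(k, K, n, N), enum_hyper_upper(k, K, n, N),
                 tolerance = 1e-10)
  }
})

test_that("driver cascade is nested and the all-zero matrix yields nothing", {
  b <- simulate_bundle(small_sim_config(seed = 2))
  ac <- small_analysis_config(seed = 2)
  tumors <- b$samples$sample_id[b$samples$group == "tumor"][1:20]
  tern_zero <- matrix(0L, 10, 20,
                      dimnames = list(b$annotation$locus_id[1:10], tumors))
  res0 <- call_drivers(tern_zero, b$expr[, tumors], b$annotation, b$pathways, ac)
  expect_equal(unname(res0$counts), c(0L, 0L, 0L, 0L))

  res <- run_pipeline(b, ac)
  calls <- res$drivers$calls
  expect_true(all(calls$locus_id[calls$is_driver] %in% calls$locus_id[calls$perm_pass]))
  expect_true(all(calls$perm_pass <= calls$cis_pass))  # logical nesting
  expect_true(all(calls$is_driver <= calls$perm_pass))
  cnt <- res$drivers$counts
  expect_true(all(diff(cnt) <= 0))
  # downstream sets never contain the candidate's own gene
  for (key in names(res$drivers$downstream)) {
    gene <- calls$gene_id[paste(calls$locus_id, calls$direction, sep = "|") == key]
    expect_false(gene %in% res$drivers$downstream[[key]])
  }
})
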