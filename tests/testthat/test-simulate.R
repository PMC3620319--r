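test_that("the generator is deterministic and internally consistent", {
  cfg <- small_sim_config(seed = 21)
  b1 <- simulate_bundle(cfg)
  b2 <- simulate_bundle(cfg)
  expect_identical(b1$beta, b2$beta)
  expect_identical(b1$expr, b2$expr)
  expect_identical(b1$truth, b2$truth)

  expect_true(all(b1$beta > 0 & b1$beta < 1))
  expect_identical(rownames(b1$beta), b1$annotation$locus_id)
  expect_identical(colnames(b1$beta), b1$samples$sample_id)
  expect_true(all(colnames(b1$expr) == colnames(b1$beta)))

  tr <- b1$truth
  expect_length(intersect(tr$locus_id[tr$role == "driver"],
                          tr$locus_id[tr$role == "passenger"]), 0)
  for (j in which(tr$role == "driver")) {
    expect_false(tr$gene_id[j] %in% tr$downstream[[j]])       # self-excluded
    pw <- b1$pathways[[tr$target_pathway[j]]]
    expect_true(all(tr$downstream[[j]] %in% pw))              # program in pathway
    # subtype concentration of altered samples >= 80%
    st <- setNames(b1$samples$subtype, b1$samples$sample_id)
    frac_in <- mean(st[tr$altered_samples[[j]]] == tr$subtype[j])
    expect_gte(frac_in, 0.8)
  }
  # every driver gene is a direct neighbor of some cancer gene
  drv_genes <- tr$gene_id[tr$role == "driver"]
  nb <- neighbors_of_set(b1$network, b1$cancer_genes)
  expect_true(all(drv_genes %in% nb))
})

test_that("bundles round-trip through their on-disk formats", {
  b <- simulate_bundle(small_sim_config(seed = 5))
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  rb <- read_bundle(dir)
  expect_equal(rb$beta, b$beta, tolerance = 1e-9)
  expect_equal(rb$expr, b$expr, tolerance = 1e-9)
  expect_identical(rb$annotation, b$annotation)
  expect_identical(rb$samples, b$samples)
  expect_identical(rb$pathways, b$pathways)
  expect_identical(rb$network$edges, b$network$edges)
  expect_setequal(rb$cancer_genes, b$cancer_genes)
  truth <- jsonlite::read_json(file.path(dir, "synthetic_truth.json"))
  expect_length(truth$planted, nrow(b$truth))
})

test_that("infeasible generator settings are rejected", {
  expect_error(simulation_config(downstream_size = 60, pathway_size = 50),
               "downstream program")
  expect_error(simulation_config(n_drivers = 300, n_passengers = 300, n_loci = 500),
               "exceed")
  expect_error(simulation_config(n_genes = 100), "too small")
  expect_error(simulation_config(n_normal = 1), ">= 2")
})

test_that("recovery scoring arithmetic is correct at the boundaries", {
  b <- simulate_bundle(small_sim_config(seed = 9))
  tr <- b$truth[b$truth$role == "driver", ]
  perfect <- list(calls = data.frame(locus_id = tr$locus_id, gene_id = tr$gene_id,
                                     direction = tr$direction, is_driver = TRUE))
  sc <- score_recovery(perfect, b)
  expect_equal(sc$locus$precision, 1)
  expect_equal(sc$locus$recall, 1)

  none <- list(calls = data.frame(locus_id = character(0), gene_id = character(0),
                                  direction = character(0), is_driver = logical(0)))
  sc0 <- score_recovery(none, b)
  expect_true(is.na(sc0$locus$precision))   # not applicable
  expect_equal(sc0$locus$recall, 0)

  # direction must match for a locus-level true positive
  wrong_dir <- perfect
  wrong_dir$calls$direction <- ifelse(tr$direction == "hyper", "hypo", "hyper")
  expect_equal(score_recovery(wrong_dir, b)$locus$recall, 0)
})

test_that("beta-mode methylation stays in range and still carries planted shifts", {
  b <- simulate_bundle(small_sim_config(seed = 30, beta_mode = "beta"))
  expect_true(all(b$beta > 0 & b$beta < 1))
  tr <- b$truth[1, ]
  normals <- b$samples$sample_id[b$samples$group == "normal"]
  delta <- mean(b$beta[tr$locus_id, unlist(tr$altered_samples)]) -
    mean(b$beta[tr$locus_id, normals])
  expect_equal(sign(delta), tr$state)
  expect_gt(abs(delta), 0.15)
})
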