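#' Upper-tail hypergeometric probability P(X >= k)
#'
#' Shared tail implementation for pathway enrichment, cancer-gene enrichment,
#' PPI-neighbor enrichment, overlap significance and the subtype test.
#' Drawing `n` items from a universe of `N` containing `K` successes,
#' returns the probability of observing at least `k` successes.
#'
#' @param k Observed overlap.
#' @param K Successes in the universe.
#' @param n Draw size.
#' @param N Universe size.
#' @return P(X >= k), exactly 1 when k <= 0.
#' @export
hypergeom_upper <- function(k, K, n, N) {
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Candidate methylation-altered loci from the ternary matrix
#'
#' A locus is a candidate in a direction (hyper = +1, hypo = -1) when the
#' fraction of tumors carrying that state is at least `min_fraction`
#' (inclusive boundary). Genes with both a hyper and a hypo candidate are
#' then excluded entirely: a both-direction gene cannot be assigned a single
#' driver direction.
#'
#' @param ternary Loci x tumors matrix of states in \{-1, 0, +1\}.
#' @param annotation Data frame with locus_id, gene_id (chromosome ignored).
#' @param min_fraction Minimum altered-tumor fraction (default 0.10).
#' @return Data frame: locus_id, gene_id, direction ("hyper"/"hypo"),
#'   state (+1/-1), n_altered, n_zero.
#' @export
frequency_filter <- function(ternary, annotation, min_fraction = 0.10) {
  if (nrow(ternary) == 0L || ncol(ternary) == 0L) stop("ternary matrix is empty")
  n_tumors <- ncol(ternary)
  gene <- annotation$gene_id[match(rownames(ternary), annotation$locus_id)]
  if (anyNA(gene)) {
    stop(sprintf("loci missing from annotation: %s",
                 paste(utils::head(rownames(ternary)[is.na(gene)], 5L), collapse = ", ")))
  }
  n_hyper <- rowSums(ternary == 1L)
  n_hypo <- rowSums(ternary == -1L)
  n_zero <- rowSums(ternary == 0L)
  build <- function(dir, state, n_alt) {
    keep <- n_alt / n_tumors >= min_fraction
    data.frame(locus_id = rownames(ternary)[keep], gene_id = gene[keep],
               direction = rep(dir, sum(keep)), state = rep(state, sum(keep)),
               n_altered = n_alt[keep], n_zero = n_zero[keep],
               stringsAsFactors = FALSE)
  }
  cand <- rbind(build("hyper", 1L, n_hyper), build("hypo", -1L, n_hypo))
  if (nrow(cand) > 0L) {
    both <- intersect(cand$gene_id[cand$direction == "hyper"],
                      cand$gene_id[cand$direction == "hypo"])
    cand <- cand[!(cand$gene_id %in% both), , drop = FALSE]
  }
  rownames(cand) <- NULL
  cand
}

# comparison groups for one candidate: tumors carrying the candidate state
# vs tumors with state 0; opposite-state tumors are excluded from both
candidate_groups <- function(candidate, ternary) {
  states <- ternary[candidate$locus_id, ]
  list(altered = colnames(ternary)[states == candidate$state],
       zero = colnames(ternary)[states == 0L])
}

#' Condition 1: cis effect of a methylation alteration on its own gene
#'
#' For each candidate locus, tests the candidate gene's expression in altered
#' vs no-alteration tumors (two-sample t-test), BH-adjusted across all
#' candidates tested. A candidate passes when cis_q < `q_cut` AND the effect
#' direction is concordant: hypermethylation must lower and hypomethylation
#' must raise the gene's own expression in the altered group.
#'
#' Candidates whose gene is missing from the expression matrix, or whose
#' groups fall below `min_group`, are skipped (NA statistics, recorded
#' reason) and excluded from the BH family.
#'
#' @param candidates Output of [frequency_filter()].
#' @param ternary Ternary alteration matrix.
#' @param expr Genes x tumor-samples expression matrix.
#' @param q_cut FDR threshold (default 0.05).
#' @param min_group Minimum group size (default 3).
#' @param var_equal Pooled-variance t instead of Welch.
#' @return `candidates` with columns cis_p, cis_q, cis_concordant, cis_pass,
#'   skip_reason appended.
#' @export
cis_test <- function(candidates, ternary, expr, q_cut = 0.05, min_group = 3L,
                     var_equal = FALSE) {
  n <- nrow(candidates)
  cis_p <- rep(NA_real_, n); concord <- rep(NA, n)
  skip <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    cand <- candidates[i, ]
    if (!(cand$gene_id %in% rownames(expr))) {
      skip[i] <- "gene_absent_from_expression"; next
    }
    grp <- candidate_groups(cand, ternary)
    grp$altered <- intersect(grp$altered, colnames(expr))
    grp$zero <- intersect(grp$zero, colnames(expr))
    if (length(grp$altered) < min_group || length(grp$zero) < min_group) {
      skip[i] <- "group_below_minimum"; next
    }
    tt <- row_t_test(expr[cand$gene_id, , drop = FALSE],
                     match(grp$altered, colnames(expr)),
                     match(grp$zero, colnames(expr)), var_equal = var_equal)
    cis_p[i] <- tt$p
    # hyper -> expression lower in altered; hypo -> higher
    concord[i] <- if (cand$direction == "hyper") tt$direction < 0 else tt$direction > 0
  }
  cis_q <- rep(NA_real_, n)
  tested <- !is.na(cis_p)
  cis_q[tested] <- stats::p.adjust(cis_p[tested], method = "BH")
  candidates$cis_p <- cis_p
  candidates$cis_q <- cis_q
  candidates$cis_concordant <- concord
  candidates$cis_pass <- !is.na(cis_q) & cis_q < q_cut & concord
  candidates$skip_reason <- skip
  candidates
}

#' Condition 2 statistic: downstream genes of a candidate alteration
#'
#' Downstream genes are the genes differentially expressed (BH q < `q_cut`)
#' between tumors carrying the candidate alteration and tumors with no
#' alteration at the locus, over the whole expression matrix, excluding the
#' candidate's own gene.
#'
#' @inheritParams cis_test
#' @param candidate One row of the candidate table.
#' @return List with `genes` (character vector) and `count`.
#' @export
downstream_genes <- function(candidate, ternary, expr, q_cut = 0.05,
                             var_equal = FALSE) {
  grp <- candidate_groups(candidate, ternary)
  de <- differential_expression(expr,
                                intersect(grp$altered, colnames(expr)),
                                intersect(grp$zero, colnames(expr)),
                                q_cut = q_cut, var_equal = var_equal)
  genes <- setdiff(de$gene_id[de$de], candidate$gene_id)
  list(genes = genes, count = length(genes))
}

# Welch/Student p-values for B random disjoint group splits of the tumor
# columns, vectorized over replicates with two matrix products. Returns a
# genes x B matrix of two-sided p-values.
perm_p_matrix <- function(expr, n1, n2, B, seed, var_equal = FALSE) {
  ns <- ncol(expr)
  if (n1 + n2 > ns) stop("permutation groups exceed the number of tumor samples")
  set.seed(seed)
  IA <- matrix(0, ns, B); IB <- matrix(0, ns, B)
  for (j in seq_len(B)) {
    draw <- sample.int(ns, n1 + n2)
    IA[draw[seq_len(n1)], j] <- 1
    IB[draw[(n1 + 1L):(n1 + n2)], j] <- 1
  }
  X2 <- expr^2
  mA <- (expr %*% IA) / n1; mB <- (expr %*% IB) / n2
  vA <- ((X2 %*% IA) - n1 * mA^2) / (n1 - 1)
  vB <- ((X2 %*% IB) - n2 * mB^2) / (n2 - 1)
  vA[vA < 0] <- 0; vB[vB < 0] <- 0   # numerical guard
  if (var_equal) {
    sp2 <- ((n1 - 1) * vA + (n2 - 1) * vB) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- matrix(n1 + n2 - 2, nrow(expr), B)
  } else {
    se2 <- vA / n1 + vB / n2
    df <- se2^2 / (vA^2 / (n1^2 * (n1 - 1)) + vB^2 / (n2^2 * (n2 - 1)))
  }
  stat <- abs(mA - mB) / sqrt(se2)
  p <- 2 * stats::pt(stat, df, lower.tail = FALSE)
  p[!is.finite(stat) | se2 == 0] <- 1
  dimnames(p) <- list(rownames(expr), NULL)
  p
}

# number of BH discoveries at q_cut per column of a p-value matrix,
# optionally removing one row (the candidate's own gene) from the family
bh_discovery_counts <- function(pmat, q_cut, exclude_row = NULL) {
  if (!is.null(exclude_row)) {
    pmat <- pmat[setdiff(rownames(pmat), exclude_row), , drop = FALSE]
  }
  m <- nrow(pmat)
  thresh <- seq_len(m) / m * q_cut
  sorted <- apply(pmat, 2L, sort, method = "quick")
  ok <- sorted <= thresh
  apply(ok, 2L, function(v) { w <- which(v); if (length(w)) max(w) else 0L })
}

#' Condition 2 test: permutation null for the downstream-DE count
#'
#' Each replicate draws two disjoint random tumor groups of the candidate's
#' group sizes, recomputes the DE-gene count at the same threshold with the
#' candidate's own gene removed from the family, and the empirical p-value
#' of the observed count is (r + 1)/(B + 1), where r is the number of
#' replicate counts at least as large as the observed one (`estimator =
#' "literal"` gives the plain fraction r/B instead).
#'
#' @param candidate One candidate row (needs n_altered, n_zero, gene_id).
#' @param expr Genes x tumor-samples expression matrix.
#' @param observed_count Observed downstream-DE count from [downstream_genes()].
#' @param B Number of replicates (>= 100).
#' @param seed Seed for the replicate draws.
#' @param q_cut DE threshold used inside each replicate (default 0.05).
#' @param estimator "add_one" (default) or "literal".
#' @param var_equal Pooled-variance t instead of Welch.
#' @param pmat Optional precomputed replicate p-value matrix (the shared
#'   null cache); computed from (expr, sizes, B, seed) when NULL.
#' @return List of class `permutation_null`: n_altered, n_zero, B, replicate
#'   `counts`, empirical `p`.
#' @export
permutation_test <- function(candidate, expr, observed_count, B, seed,
                             q_cut = 0.05, estimator = c("add_one", "literal"),
                             var_equal = FALSE, pmat = NULL) {
  estimator <- match.arg(estimator)
  if (B < 100L) stop("permutation test requires B >= 100")
  if (is.null(pmat)) {
    pmat <- perm_p_matrix(expr, candidate$n_altered, candidate$n_zero, B, seed,
                          var_equal = var_equal)
  }
  counts <- bh_discovery_counts(pmat, q_cut, exclude_row = candidate$gene_id)
  r <- sum(counts >= observed_count)
  p <- if (estimator == "add_one") (r + 1) / (B + 1) else r / B
  structure(list(n_altered = candidate$n_altered, n_zero = candidate$n_zero,
                 B = B, counts = counts, exceed = r, p = p),
            class = "permutation_null")
}

#' Condition 3: pathway enrichment of a downstream gene set
#'
#' Upper-tail hypergeometric test of the overlap between the downstream set
#' and each pathway, over the background of all genes in the expression
#' matrix (pathways are intersected with that background first). BH across
#' the pathways tested for this candidate; the condition passes when at
#' least one pathway reaches q < `q_cut`.
#'
#' @param downstream Character vector of downstream gene ids.
#' @param pathways Named list of pathway gene sets.
#' @param background Character vector: the gene universe (all genes measured).
#' @param q_cut FDR threshold (default 1e-4).
#' @return List with `table` (pathway, overlap k, pathway size K, p, q) and
#'   `pass`.
#' @export
pathway_enrichment <- function(downstream, pathways, background, q_cut = 1e-4) {
  if (length(background) == 0L) stop("enrichment background is empty")
  downstream <- intersect(downstream, background)
  sets <- lapply(pathways, intersect, background)
  sets <- sets[vapply(sets, length, 1L) > 0L]
  N <- length(background); n <- length(downstream)
  K <- vapply(sets, length, 1L)
  k <- vapply(sets, function(s) length(intersect(downstream, s)), 1L)
  p <- hypergeom_upper(k, K, n, N)
  q <- stats::p.adjust(p, method = "BH")
  tab <- data.frame(pathway = names(sets), k = k, K = K, n = n, N = N,
                    p = p, q = q, stringsAsFactors = FALSE, row.names = NULL)
  tab <- tab[order(tab$p, tab$pathway), , drop = FALSE]
  list(table = tab, pass = nrow(tab) > 0L && any(tab$q < q_cut))
}

#' Run the three-condition driver cascade
#'
#' Chains [frequency_filter()] -> [cis_test()] -> [downstream_genes()] +
#' [permutation_test()] -> [pathway_enrichment()]. Downstream/permutation
#' statistics are computed for condition-1 survivors, pathway enrichment for
#' condition-2 survivors (matching the published cascade); the returned
#' table keeps every candidate with the statistics of every stage it
#' reached. A locus is a driver alteration when it passes all three
#' conditions; a driver gene has at least one driver locus.
#'
#' Permutation nulls are shared across candidates with equal group sizes
#' (replicate t-statistics reused; per-candidate discovery counts recomputed
#' with that candidate's gene removed from the BH family). Permutation
#' p-values are BH-adjusted across all candidates tested at condition 2.
#'
#' @param ternary Loci x tumors ternary alteration matrix.
#' @param expr Genes x samples expression matrix (must cover the tumors).
#' @param annotation Locus annotation (locus_id, gene_id).
#' @param pathways Named list: cancer-associated pathway gene sets.
#' @param config An [analysis_config()].
#' @return List of class `driver_result`: `calls` (per-candidate table),
#'   `drivers` (gene ids), `driver_loci`, `downstream` (named list keyed
#'   `locus|direction`), `enrichment` (named list of pathway tables),
#'   `counts` (cascade stage counts), `config`.
#' @export
call_drivers <- function(ternary, expr, annotation, pathways, config = analysis_config()) {
  tumors <- intersect(colnames(ternary), colnames(expr))
  if (length(tumors) == 0L) stop("no tumor samples shared between ternary and expression matrices")
  if (length(tumors) < ncol(ternary)) {
    message(sprintf("%d tumor(s) lack expression data and are ignored",
                    ncol(ternary) - length(tumors)))
  }
  ternary <- ternary[, tumors, drop = FALSE]
  expr_t <- expr[, tumors, drop = FALSE]
  background <- rownames(expr_t)

  cand <- frequency_filter(ternary, annotation, config$freq_min)
  if (nrow(cand) == 0L) {
    empty <- cand
    for (col in c("cis_p", "cis_q", "n_downstream", "perm_p", "perm_q",
                  "pathway_min_q")) empty[[col]] <- numeric(0)
    for (col in c("cis_pass", "perm_pass", "pathway_pass", "is_driver")) {
      empty[[col]] <- logical(0)
    }
    return(structure(list(calls = empty, drivers = character(0),
                          driver_loci = character(0), downstream = list(),
                          enrichment = list(),
                          counts = c(candidates = 0L, condition1 = 0L,
                                     condition2 = 0L, drivers = 0L),
                          config = config),
                     class = "driver_result"))
  }

  cand <- cis_test(cand, ternary, expr_t, q_cut = config$cis_q,
                   min_group = config$min_group, var_equal = config$var_equal)
  key <- paste(cand$locus_id, cand$direction, sep = "|")

  n <- nrow(cand)
  cand$n_downstream <- NA_integer_
  cand$perm_p <- NA_real_; cand$perm_q <- NA_real_
  cand$perm_pass <- FALSE
  cand$pathway_min_q <- NA_real_; cand$top_pathway <- NA_character_
  cand$pathway_pass <- FALSE
  downstream_sets <- list(); enrich_tables <- list()

  idx2 <- which(cand$cis_pass)
  null_cache <- new.env(parent = emptyenv())
  for (i in idx2) {
    ds <- downstream_genes(cand[i, ], ternary, expr_t, q_cut = config$de_q,
                           var_equal = config$var_equal)
    cand$n_downstream[i] <- ds$count
    downstream_sets[[key[i]]] <- ds$genes
    ck <- sprintf("%d_%d", cand$n_altered[i], cand$n_zero[i])
    sd_i <- stage_seed(config$seed, "permutation",
                       a = cand$n_altered[i], b = cand$n_zero[i])
    pmat <- if (config$perm_share_null && !is.null(null_cache[[ck]])) {
      null_cache[[ck]]
    } else {
      pm <- perm_p_matrix(expr_t, cand$n_altered[i], cand$n_zero[i],
                          config$perm_B,
                          if (config$perm_share_null) sd_i else sd_i + i,
                          var_equal = config$var_equal)
      if (config$perm_share_null) null_cache[[ck]] <- pm
      pm
    }
    pt <- permutation_test(cand[i, ], expr_t, ds$count, config$perm_B, sd_i,
                           q_cut = config$de_q, estimator = config$perm_estimator,
                           var_equal = config$var_equal, pmat = pmat)
    cand$perm_p[i] <- pt$p
  }
  cand$perm_q[idx2] <- stats::p.adjust(cand$perm_p[idx2], method = "BH")
  cand$perm_pass <- !is.na(cand$perm_q) & cand$perm_q < config$perm_q

  idx3 <- which(cand$perm_pass)
  if (config$pathway_scope == "within_candidate") {
    for (i in idx3) {
      en <- pathway_enrichment(downstream_sets[[key[i]]], pathways, background,
                               q_cut = config$pathway_q)
      enrich_tables[[key[i]]] <- en$table
      if (nrow(en$table) > 0L) {
        cand$pathway_min_q[i] <- min(en$table$q)
        cand$top_pathway[i] <- en$table$pathway[1L]
      }
      cand$pathway_pass[i] <- en$pass
    }
  } else {
    # pool every (candidate, pathway) p-value into one BH family
    raw <- lapply(idx3, function(i) {
      en <- pathway_enrichment(downstream_sets[[key[i]]], pathways, background,
                               q_cut = config$pathway_q)
      cbind(en$table[, setdiff(names(en$table), "q")], cand_idx = i)
    })
    if (length(raw) > 0L) {
      pooled <- do.call(rbind, raw)
      pooled$q <- stats::p.adjust(pooled$p, method = "BH")
      for (i in idx3) {
        tab <- pooled[pooled$cand_idx == i, setdiff(names(pooled), "cand_idx"),
                      drop = FALSE]
        enrich_tables[[key[i]]] <- tab
        if (nrow(tab) > 0L) {
          cand$pathway_min_q[i] <- min(tab$q)
          cand$top_pathway[i] <- tab$pathway[which.min(tab$q)]
        }
        cand$pathway_pass[i] <- any(tab$q < config$pathway_q)
      }
    }
  }

  cand$is_driver <- cand$cis_pass & cand$perm_pass & cand$pathway_pass
  structure(list(
    calls = cand,
    drivers = sort(unique(cand$gene_id[cand$is_driver])),
    driver_loci = sort(unique(cand$locus_id[cand$is_driver])),
    downstream = downstream_sets,
    enrichment = enrich_tables,
    counts = c(candidates = nrow(cand),
               condition1 = sum(cand$cis_pass),
               condition2 = sum(cand$perm_pass),
               drivers = sum(cand$is_driver)),
    config = config), class = "driver_result")
}

#' @export
print.driver_result <- function(x, ...) {
  cat("driver_result cascade:",
      sprintf("%d candidate loci -> %d cis survivors -> %d permutation survivors -> %d driver loci (%d driver genes)\n",
              x$counts[["candidates"]], x$counts[["condition1"]],
              x$counts[["condition2"]], x$counts[["drivers"]],
              length(x$drivers)))
  invisible(x)
}
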