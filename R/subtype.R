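#' Jaccard distance between two ternary alteration profiles
#'
#' Similarity is the number of positions where both profiles carry the SAME
#' nonzero state, divided by the number of positions where either is
#' nonzero; distance is 1 - similarity. Hyper (+1) and hypo (-1) count as
#' distinct categories unless `binarize = TRUE` (any nonzero treated as 1).
#' Two all-zero profiles have distance 0 (identical).
#'
#' @param a,b Integer vectors of equal length with entries in \{-1, 0, +1\}.
#' @param binarize Collapse both alteration directions into one category.
#' @return Distance in [0, 1].
#' @export
jaccard_distance <- function(a, b, binarize = FALSE) {
  if (length(a) != length(b)) stop("profiles must have equal length")
  if (binarize) { a <- as.integer(a != 0L); b <- as.integer(b != 0L) }
  union_nz <- sum(a != 0L | b != 0L)
  if (union_nz == 0L) return(0)
  1 - sum(a == b & a != 0L) / union_nz
}

# pairwise ternary Jaccard distances between the COLUMNS of a ternary
# matrix, via crossproducts of the per-state indicator matrices
ternary_jaccard_dist <- function(ternary, binarize = FALSE) {
  if (binarize) {
    same <- crossprod(ternary != 0L)
  } else {
    same <- crossprod(ternary == 1L) + crossprod(ternary == -1L)
  }
  nnz <- colSums(ternary != 0L)
  union_nz <- outer(nnz, nnz, `+`) - crossprod(ternary != 0L)
  sim <- ifelse(union_nz == 0, 1, same / union_nz)
  d <- 1 - sim
  dimnames(d) <- list(colnames(ternary), colnames(ternary))
  stats::as.dist(d)
}

#' Hierarchical clustering of tumors on ternary driver profiles
#'
#' Average-linkage (UPGMA) agglomeration of the tumor columns under the
#' ternary Jaccard distance, cut into `k` clusters. Tumor columns are first
#' sorted by sample id — the fixed rule that makes the result invariant to
#' input column order (distance ties are then always broken identically).
#'
#' @param ternary Ternary matrix restricted to driver loci (loci x tumors).
#' @param k Number of clusters (2 <= k <= number of tumors).
#' @param binarize Passed to the Jaccard distance.
#' @return List of class `cluster_result`: `labels` (named integer vector,
#'   1..k), `hclust` (the dendrogram), `dist` (the distance object).
#' @export
hierarchical_cluster <- function(ternary, k, binarize = FALSE) {
  if (nrow(ternary) == 0L) stop("no driver loci to cluster on")
  if (k > ncol(ternary)) stop("k exceeds the number of tumors")
  ternary <- ternary[, order(colnames(ternary)), drop = FALSE]
  d <- ternary_jaccard_dist(ternary, binarize = binarize)
  hc <- stats::hclust(d, method = "average")
  labels <- stats::cutree(hc, k = k)
  structure(list(labels = labels, hclust = hc, dist = d, k = k),
            class = "cluster_result")
}

#' Export a cluster dendrogram as Newick text
#' @param cluster A `cluster_result`.
#' @param path Output file path.
#' @export
write_dendrogram_newick <- function(cluster, path) {
  ape::write.tree(ape::as.phylo(cluster$hclust), file = path)
  invisible(path)
}

#' Subtype-specific driver alterations
#'
#' For each driver locus (in its driver direction) and each subtype, tests
#' whether the alteration concentrates in that subtype: with N labeled
#' tumors of which K carry the alteration, and a subtype of size n with k
#' altered members, p = P(X >= k) under the hypergeometric. BH across all
#' (locus, subtype) tests. A call is specific when q < `q_cut` and the
#' in-subtype alteration frequency exceeds the frequency in the remaining
#' tumors; a gene is subtype-specific when any of its driver loci is.
#'
#' @param ternary Ternary matrix over driver loci (loci x tumors).
#' @param driver_table Data frame with locus_id, gene_id, direction, state
#'   for the driver loci (e.g. driver rows of a `driver_result$calls`).
#' @param subtypes Named character vector: subtype label per tumor sample id
#'   (NA = unlabeled; unlabeled tumors are excluded with a message).
#' @param q_cut FDR threshold (default 0.05).
#' @return List: `calls` data frame (locus_id, gene_id, direction, subtype,
#'   k, n, K, N, freq_subtype, freq_rest, p, q, specific) and
#'   `specific_genes` (named list: subtype -> gene ids).
#' @export
subtype_specific_test <- function(ternary, driver_table, subtypes, q_cut = 0.05) {
  subtypes <- subtypes[intersect(names(subtypes), colnames(ternary))]
  labeled <- names(subtypes)[!is.na(subtypes)]
  dropped <- ncol(ternary) - length(labeled)
  if (dropped > 0L) message(sprintf("%d unlabeled tumor(s) excluded from the subtype test", dropped))
  subtypes <- subtypes[labeled]
  levels <- sort(unique(subtypes))
  if (length(levels) < 2L) stop("subtype test requires >= 2 subtype labels")
  N <- length(labeled)
  tern <- ternary[driver_table$locus_id, labeled, drop = FALSE]

  rows <- list()
  for (i in seq_len(nrow(driver_table))) {
    altered <- tern[i, ] == driver_table$state[i]
    K <- sum(altered)
    for (st in levels) {
      in_st <- subtypes == st
      n <- sum(in_st); k <- sum(altered & in_st)
      rows[[length(rows) + 1L]] <- data.frame(
        locus_id = driver_table$locus_id[i], gene_id = driver_table$gene_id[i],
        direction = driver_table$direction[i], subtype = st,
        k = k, n = n, K = K, N = N,
        freq_subtype = k / n, freq_rest = (K - k) / (N - n),
        p = hypergeom_upper(k, K, n, N), stringsAsFactors = FALSE)
    }
  }
  calls <- do.call(rbind, rows)
  calls$q <- stats::p.adjust(calls$p, method = "BH")
  calls$specific <- calls$q < q_cut & calls$freq_subtype > calls$freq_rest
  specific_genes <- lapply(stats::setNames(levels, levels), function(st) {
    sort(unique(calls$gene_id[calls$specific & calls$subtype == st]))
  })
  list(calls = calls, specific_genes = specific_genes)
}
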