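#' Beta value from methylated/unmethylated intensities
#'
#' beta = max(M, 0) / (|U| + |M| + 100). The +100 offset regularizes
#' low-intensity probes; negative raw intensities are legal (background
#' subtraction can under-shoot) and are clamped in the numerator only.
#' The result always lies in [0, 1).
#'
#' @param M Methylated signal intensity (vectorized).
#' @param U Unmethylated signal intensity (same length/shape as `M`).
#' @return Beta values in [0, 1).
#' @export
compute_beta <- function(M, U) {
  if (!all(is.finite(M)) || !all(is.finite(U))) {
    stop("compute_beta: intensities must be finite")
  }
  pmax(M, 0) / (abs(U) + abs(M) + 100)
}

#' Probe reliability filter from detection p-values
#'
#' A locus is dropped when the proportion of samples with detection
#' p-value > `p_cut` exceeds `max_fraction` ("more than" is strict, so a
#' locus failing in exactly 10% of samples is retained at the defaults).
#'
#' @param detection_p Loci x samples matrix of detection p-values.
#' @param p_cut Per-sample detection failure threshold (default 0.05).
#' @param max_fraction Maximum tolerated failing-sample fraction (default 0.10).
#' @return Character vector of retained locus ids.
#' @export
filter_unreliable_loci <- function(detection_p, p_cut = 0.05, max_fraction = 0.10) {
  stopifnot(is.matrix(detection_p), !is.null(rownames(detection_p)))
  fail_frac <- rowMeans(detection_p > p_cut)
  rownames(detection_p)[fail_frac <= max_fraction]
}

#' Exclude loci on the sex chromosomes
#'
#' Removes loci annotated to chromosome X or Y, eliminating gender-specific
#' methylation bias from the tumor/normal comparison.
#'
#' @param locus_ids Character vector of loci to filter.
#' @param annotation Data frame with columns locus_id, gene_id, chromosome.
#' @return Retained (autosomal) locus ids, in input order.
#' @export
exclude_sex_chromosomes <- function(locus_ids, annotation) {
  idx <- match(locus_ids, annotation$locus_id)
  if (anyNA(idx)) {
    stop(sprintf("loci missing from annotation: %s",
                 paste(utils::head(locus_ids[is.na(idx)], 10L), collapse = ", ")))
  }
  keep <- !(annotation$chromosome[idx] %in% c("X", "Y"))
  out <- locus_ids[keep]
  if (length(out) == 0L) warning("all loci lie on sex chromosomes; nothing retained")
  out
}

# Row-wise two-sample t-tests (Welch by default), vectorized over rows.
# Zero-variance rows (pooled standard error exactly 0) get p = 1: the test
# statistic is undefined there and p = 1 keeps BH adjustment conservative.
row_t_test <- function(X, idxA, idxB, var_equal = FALSE) {
  nA <- length(idxA); nB <- length(idxB)
  A <- X[, idxA, drop = FALSE]; B <- X[, idxB, drop = FALSE]
  mA <- rowMeans(A); mB <- rowMeans(B)
  vA <- rowSums((A - mA)^2) / (nA - 1)
  vB <- rowSums((B - mB)^2) / (nB - 1)
  if (var_equal) {
    sp2 <- ((nA - 1) * vA + (nB - 1) * vB) / (nA + nB - 2)
    se <- sqrt(sp2 * (1 / nA + 1 / nB))
    df <- rep(nA + nB - 2, nrow(X))
  } else {
    se <- sqrt(vA / nA + vB / nB)
    df <- (vA / nA + vB / nB)^2 /
      (vA^2 / (nA^2 * (nA - 1)) + vB^2 / (nB^2 * (nB - 1)))
  }
  stat <- (mA - mB) / se
  p <- 2 * stats::pt(abs(stat), df, lower.tail = FALSE)
  degenerate <- !is.finite(se) | se == 0
  p[degenerate] <- 1
  stat[degenerate] <- 0
  data.frame(stat = stat, p = p, mean_a = mA, mean_b = mB,
             direction = sign(mA - mB), row.names = rownames(X))
}

#' Differential expression between two sample groups
#'
#' Two-sided two-sample t-test per gene (Welch's unequal-variance form by
#' default; Student's pooled form via `var_equal = TRUE`), with
#' Benjamini-Hochberg adjustment across genes. A gene is called DE when its
#' adjusted p (q) falls below `q_cut`. Direction is the sign of
#' mean(groupA) - mean(groupB).
#'
#' @param expr Genes x samples expression matrix (normalized, log scale).
#' @param group_a,group_b Disjoint sample-id vectors, each of size >= 2.
#' @param q_cut BH-adjusted p threshold for the DE call (default 0.05).
#' @param var_equal Use the pooled-variance Student t instead of Welch.
#' @return Data frame with columns gene_id, stat, p, q, direction, de.
#' @export
differential_expression <- function(expr, group_a, group_b, q_cut = 0.05,
                                    var_equal = FALSE) {
  if (length(intersect(group_a, group_b)) > 0L) stop("groups must be disjoint")
  if (length(group_a) < 2L || length(group_b) < 2L) stop("each group needs >= 2 samples")
  missing <- setdiff(c(group_a, group_b), colnames(expr))
  if (length(missing) > 0L) {
    stop(sprintf("samples absent from expression matrix: %s",
                 paste(utils::head(missing, 5L), collapse = ", ")))
  }
  tt <- row_t_test(expr, match(group_a, colnames(expr)),
                   match(group_b, colnames(expr)), var_equal = var_equal)
  q <- stats::p.adjust(tt$p, method = "BH")
  data.frame(gene_id = rownames(expr), stat = tt$stat, p = tt$p, q = q,
             direction = tt$direction, de = q < q_cut,
             stringsAsFactors = FALSE, row.names = NULL)
}
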