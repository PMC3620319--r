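#' Per-locus normal reference (mean and sd of beta in normal samples)
#'
#' @param beta Loci x samples beta-value matrix.
#' @param normal_ids Sample ids of the normal samples (>= 2 required).
#' @return Data frame with columns locus_id, mean, sd.
#' @export
normal_reference <- function(beta, normal_ids) {
  if (length(normal_ids) < 2L) stop("normal reference requires >= 2 normal samples")
  missing <- setdiff(normal_ids, colnames(beta))
  if (length(missing) > 0L) {
    stop(sprintf("normal samples absent from beta matrix: %s",
                 paste(missing, collapse = ", ")))
  }
  N <- beta[, normal_ids, drop = FALSE]
  m <- rowMeans(N)
  s <- sqrt(rowSums((N - m)^2) / (ncol(N) - 1))
  data.frame(locus_id = rownames(beta), mean = m, sd = s,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Z-score of a tumor beta value against the normal reference
#' @param beta Beta value(s).
#' @param ref_mean,ref_sd Normal-reference mean and sd (sd must be > 0).
#' @return z = (beta - ref_mean) / ref_sd.
#' @export
zscore <- function(beta, ref_mean, ref_sd) {
  if (any(ref_sd <= 0)) stop("zscore: normal-reference sd must be positive")
  (beta - ref_mean) / ref_sd
}

#' Two-sided Z-test p-value
#' @param z Z-score(s).
#' @return p = 2 * (1 - Phi(|z|)).
#' @export
ztest_p <- function(z) {
  2 * stats::pnorm(abs(z), lower.tail = FALSE)
}

#' Discretize tumor methylation profiles against the normal reference
#'
#' Each tumor beta value is converted to a Z-score against the per-locus
#' normal mean/sd, tested two-sided, and BH-adjusted. States: +1
#' (hypermethylated) when the adjusted p is below `q_cut` and z > 0, -1
#' (hypomethylated) when z < 0, else 0. The adjustment family is each tumor
#' sample's own locus profile by default (`scope = "per_sample"`) —
#' discretization is defined sample by sample — or all (locus, tumor) pairs
#' jointly (`scope = "global"`).
#'
#' Loci whose normal-reference sd is zero have no defined Z-score and are
#' dropped with a message.
#'
#' @param tumor_beta Loci x tumor-samples beta matrix.
#' @param ref Normal reference from [normal_reference()].
#' @param q_cut BH-adjusted p threshold (default 0.05; 0.01 for the stricter
#'   robustness setting).
#' @param scope BH family: "per_sample" (default) or "global".
#' @return Integer matrix of states in \{-1, 0, +1\} (dropped loci absent).
#' @export
discretize_matrix <- function(tumor_beta, ref, q_cut = 0.05,
                              scope = c("per_sample", "global")) {
  scope <- match.arg(scope)
  idx <- match(rownames(tumor_beta), ref$locus_id)
  if (anyNA(idx)) {
    stop(sprintf("loci absent from normal reference: %s",
                 paste(utils::head(rownames(tumor_beta)[is.na(idx)], 5L), collapse = ", ")))
  }
  m <- ref$mean[idx]; s <- ref$sd[idx]
  degenerate <- s <= 0
  if (any(degenerate)) {
    message(sprintf("dropping %d locus/loci with zero normal-reference sd", sum(degenerate)))
    tumor_beta <- tumor_beta[!degenerate, , drop = FALSE]
    m <- m[!degenerate]; s <- s[!degenerate]
  }
  z <- (tumor_beta - m) / s
  p <- ztest_p(z)
  q <- if (scope == "per_sample") {
    apply(p, 2L, stats::p.adjust, method = "BH")
  } else {
    matrix(stats::p.adjust(p, method = "BH"), nrow = nrow(p), dimnames = dimnames(p))
  }
  state <- matrix(0L, nrow = nrow(z), ncol = ncol(z), dimnames = dimnames(z))
  hit <- q < q_cut
  state[hit] <- ifelse(z[hit] > 0, 1L, -1L)
  state
}

#' Write / read a ternary alteration matrix (integer TSV)
#' @param ternary Integer matrix with entries in \{-1, 0, 1\}.
#' @param path File path.
#' @rdname ternary_io
#' @export
write_ternary <- function(ternary, path) {
  write_matrix(ternary, path, feature_col = "locus_id")
}

#' @rdname ternary_io
#' @export
read_ternary <- function(path) {
  m <- read_matrix(path, what = "ternary")
  if (!all(m %in% c(-1, 0, 1))) stop("ternary matrix entries must be -1, 0 or 1")
  storage.mode(m) <- "integer"
  m
}
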