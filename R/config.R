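#' Analysis configuration
#'
#' Bundles every tunable threshold of the driver pipeline. Defaults follow
#' the published analysis: per-sample discretization at BH-adjusted p < 0.05
#' (0.01 as the stricter robustness setting), candidate loci altered in at
#' least 10% of tumors, cis test at FDR < 0.05, downstream DE at FDR < 0.05,
#' permutation null of B = 100,000 draws with pass at FDR < 1.00E-04, pathway
#' enrichment at FDR < 1.00E-04, subtype specificity at FDR < 0.05, k = 3
#' clusters.
#'
#' The empirical permutation p-value cannot fall below 1/(B+1) under the
#' add-one estimator, so `perm_q` must be chosen commensurate with `perm_B`:
#' the published pairing is (1e5, 1e-4); a reduced-B run (e.g. B = 1000)
#' needs a correspondingly achievable threshold such as 0.01.
#'
#' @param discretize_q BH threshold for per-sample discretization.
#' @param discretize_scope BH family for discretization: "per_sample" or "global".
#' @param freq_min Minimum altered-tumor fraction for candidate loci.
#' @param cis_q FDR threshold for the cis (own-gene) test.
#' @param de_q FDR threshold defining downstream DE genes.
#' @param perm_B Number of permutation replicates (>= 100).
#' @param perm_q FDR threshold on the permutation p-value.
#' @param perm_estimator "add_one" for (r+1)/(B+1) (default; never exactly 0)
#'   or "literal" for the plain fraction r/B.
#' @param pathway_q FDR threshold for pathway enrichment.
#' @param pathway_scope BH family for pathway enrichment: "within_candidate"
#'   (default) or "across_candidates".
#' @param subtype_q FDR threshold for subtype-specific calls.
#' @param n_clusters Number of clusters cut from the tumor dendrogram (>= 2).
#' @param min_group Minimum samples per group for any t-test stage.
#' @param var_equal Pooled-variance Student t instead of Welch everywhere.
#' @param jaccard_binarize Treat any nonzero state as 1 in the Jaccard distance.
#' @param perm_share_null Reuse permutation draws across candidates sharing
#'   group sizes (identical distributional semantics; pure speed).
#' @param seed Base random seed; per-stage seeds are derived from it.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(discretize_q = 0.05,
                            discretize_scope = c("per_sample", "global"),
                            freq_min = 0.10,
                            cis_q = 0.05,
                            de_q = 0.05,
                            perm_B = 100000L,
                            perm_q = 1e-4,
                            perm_estimator = c("add_one", "literal"),
                            pathway_q = 1e-4,
                            pathway_scope = c("within_candidate", "across_candidates"),
                            subtype_q = 0.05,
                            n_clusters = 3L,
                            min_group = 3L,
                            var_equal = FALSE,
                            jaccard_binarize = FALSE,
                            perm_share_null = TRUE,
                            seed = 1L) {
  cfg <- list(discretize_q = discretize_q,
              discretize_scope = match.arg(discretize_scope),
              freq_min = freq_min, cis_q = cis_q, de_q = de_q,
              perm_B = as.integer(perm_B), perm_q = perm_q,
              perm_estimator = match.arg(perm_estimator),
              pathway_q = pathway_q, pathway_scope = match.arg(pathway_scope),
              subtype_q = subtype_q, n_clusters = as.integer(n_clusters),
              min_group = as.integer(min_group), var_equal = var_equal,
              jaccard_binarize = jaccard_binarize,
              perm_share_null = perm_share_null, seed = as.integer(seed))
  for (nm in c("discretize_q", "freq_min", "cis_q", "de_q", "perm_q",
               "pathway_q", "subtype_q")) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || v <= 0 || v >= 1) {
      stop(sprintf("config '%s' must lie in (0, 1)", nm))
    }
  }
  if (cfg$perm_B < 100L) stop("perm_B must be >= 100")
  if (cfg$n_clusters < 2L) stop("n_clusters must be >= 2")
  structure(cfg, class = "analysis_config")
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("analysis_config:\n")
  for (nm in names(x)) cat(sprintf("  %-18s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

# deterministic per-stage seed fan-out from the base seed (kept well below
# 2^31 so set.seed always accepts it)
stage_seed <- function(base_seed, stage, a = 0L, b = 0L) {
  offs <- c(discretize = 11L, permutation = 23L, simulate = 37L, misc = 53L)
  s <- (as.double(base_seed) * 1009 + offs[[stage]] * 9973 +
          a * 7919 + b * 104729) %% 2147483629
  as.integer(s)
}
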