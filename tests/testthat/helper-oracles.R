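# Independent oracles and small fixture builders shared across tests.

# Upper-tail hypergeometric by full enumeration of all C(N, n) draws:
# universe 1..N, successes 1..K, count draws with >= k successes.
enum_hyper_upper <- function(k, K, n, N) {
  draws <- utils::combn(N, n)
  mean(colSums(draws <= K) >= k)
}

# Upper-tail hypergeometric as an explicit sum of choose() terms (used where
# full enumeration is too large but N is still modest).
sum_hyper_upper <- function(k, K, n, N) {
  x <- max(k, max(0, n - (N - K))):min(K, n)
  sum(choose(K, x) * choose(N - K, n - x)) / choose(N, n)
}

# Literal Benjamini-Hochberg step-up: largest r with p_(r) <= r*alpha/m is
# the rejection count; adjusted values by the defining min-max formula.
bh_adjust_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  running <- Inf
  for (r in m:1) {
    running <- min(running, m * p[o[r]] / r)
    q[o[r]] <- min(running, 1)
  }
  q
}

# Two-sided normal tail via the complementary error function, independent of
# pnorm (pracma's erfc uses its own series/continued-fraction evaluation).
ztail_erfc <- function(z) pracma::erfc(abs(z) / sqrt(2))

# Are two cluster labelings the same partition (up to label permutation)?
same_partition <- function(a, b) {
  tab <- table(a, b)
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
}

# Small, fast simulation settings for unit tests: fewer loci/genes/samples
# than the default study conditions, with proportionately stronger planted
# effects and looser enrichment/permutation thresholds so the mechanics are
# exercised with reliable power at this scale.
small_sim_config <- function(seed = 1, ...) {
  simulation_config(n_normal = 10, n_tumor = 30, n_loci = 80, n_genes = 400,
                    n_pathways = 5, pathway_size = 30, n_drivers = 3,
                    n_passengers = 10, downstream_size = 20,
                    cis_effect = 2.5, downstream_effect = 2,
                    n_sex_loci = 4, n_unreliable_loci = 2,
                    n_cancer_genes = 30, seed = seed, ...)
}

small_analysis_config <- function(seed = 1, ...) {
  analysis_config(perm_B = 200, perm_q = 0.05, pathway_q = 0.01,
                  seed = seed, ...)
}

# A ternary matrix with three planted tumor blocks, each altered at its own
# locus block (plus optional sprinkled noise).
block_ternary <- function(n_per_block = 6, loci_per_block = 5, noise = 0,
                          seed = 99) {
  set.seed(seed)
  n <- 3 * n_per_block
  m <- 3 * loci_per_block
  tern <- matrix(0L, m, n,
                 dimnames = list(sprintf("cg%03d", 1:m), sprintf("T%03d", 1:n)))
  for (blk in 1:3) {
    rows <- (blk - 1) * loci_per_block + seq_len(loci_per_block)
    cols <- (blk - 1) * n_per_block + seq_len(n_per_block)
    tern[rows, cols] <- if (blk == 2L) -1L else 1L
  }
  if (noise > 0) {
    flip <- sample(length(tern), noise)
    tern[flip] <- sample(c(-1L, 0L, 1L), noise, replace = TRUE)
  }
  tern
}
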