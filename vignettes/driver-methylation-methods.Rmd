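---
title: "Methods: calling driver genes from promoter methylation and expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calling driver genes from promoter methylation and expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methdriver)
```

## The problem

Tumor genomes carry thousands of promoter methylation changes, but only a
minority of them *drive* the malignant phenotype; the rest are passengers
carried along by genome-wide epigenetic disorder. With paired promoter
methylation (beta values) and gene expression measured on the same tumors,
plus a normal-tissue reference, driver alterations can be separated from
passengers by asking whether an alteration (i) silences or activates its own
gene in *cis*, (ii) propagates to a larger-than-chance set of downstream
expression changes, and (iii) funnels those changes into cancer-associated
pathways. `methdriver` implements that three-condition cascade, the
validation layer around it (known-cancer-gene and protein-interaction
neighborhood enrichment, cross-dataset overlap), subtype analysis on the
discrete alteration profiles, and a synthetic-data generator with planted
ground truth so the whole chain is testable end to end.

## Per-sample discretization

Methylation input is the standard beta value. When raw intensities are
supplied it is computed as

$$\beta = \frac{\max(M, 0)}{|U| + |M| + 100},$$

with $M$ and $U$ the methylated and unmethylated signal intensities; the
+100 offset regularizes dim probes and keeps $\beta \in [0, 1)$. Probes with
detection p-value $> 0.05$ in strictly more than 10% of samples are dropped,
as are all loci on the X and Y chromosomes (gender bias).

Each tumor sample is discretized on its own. For locus $\ell$ with normal
reference mean $\mu_\ell$ and standard deviation $\sigma_\ell$ (computed
from $\ge 2$ normal samples), a tumor beta value is converted to
$z = (\beta - \mu_\ell)/\sigma_\ell$ and tested two-sided against the
standard normal. Within each tumor sample, the p-values across loci form one
Benjamini–Hochberg family; states are

$$s = \begin{cases} \operatorname{sign}(z) & q < 0.05 \\ 0 & \text{otherwise,} \end{cases}$$

giving the ternary matrix of +1 (hyper), 0 (none), −1 (hypo). Design points:

* **Adjustment scope.** Discretization is defined sample by sample, so the
  default BH family is each tumor's own locus profile
  (`discretize_scope = "per_sample"`). A joint family over all
  (locus, tumor) pairs is available (`"global"`); both are calibrated under
  the null (tested).
* **Degenerate loci.** A locus whose normal-reference sd is zero has no
  defined Z-score; such loci are dropped before testing, with a logged
  count.
* **Robustness threshold.** The stricter setting $q < 0.01$ is exposed as a
  config value; because BH rejection regions are nested in the threshold,
  tightening can only remove nonzero states (a tested invariant).
* Only tumors are discretized; the normals serve purely as the reference.

## The three driver conditions

Candidates are loci hyper- or hypomethylated in **at least 10%** of tumors
(inclusive boundary), per direction. A gene with both a hyper- and a
hypo-candidate locus is excluded outright — it cannot be assigned one driver
direction. For every candidate, comparisons are between tumors carrying the
candidate state and tumors with state 0 at that locus; tumors with the
*opposite* state are excluded from both groups.

1. **Cis effect.** Welch's two-sided t-test on the candidate's own gene,
   altered vs unaltered tumors, BH across all candidates; pass at
   $q < 0.05$ *and* concordant direction (hypermethylation must lower, and
   hypomethylation raise, the gene's own expression). Welch is the default
   because the two groups routinely differ in size and variance; the pooled
   Student form is one config flag away. Zero-variance genes get $p = 1$
   (test undefined; conservative). Any t-test stage requires at least 3
   samples per group; smaller candidates are skipped and reported.
2. **Downstream load.** The candidate's downstream genes are the genes DE
   (BH $q < 0.05$) between the altered and unaltered tumors, excluding the
   candidate's own gene. The observed count is referred to a permutation
   null: each of $B$ replicates draws two *disjoint* random tumor groups of
   the same sizes and recomputes the DE count under the identical rule
   (same threshold, own gene removed from the BH family). The empirical
   p-value uses the add-one estimator $(r+1)/(B+1)$ with $r$ the number of
   replicate counts $\ge$ the observed one ("at least as extreme", the
   conservative convention for discrete statistics). The plain fraction
   $r/B$ is available (`perm_estimator = "literal"`) for strict replication,
   but the add-one form is the default because a p-value of exactly 0
   breaks BH and overstates significance at finite $B$. Permutation
   p-values are BH-adjusted **across candidates**.
3. **Pathway focus.** The downstream set is tested against each
   cancer-associated pathway with the upper-tail hypergeometric
   $P(X \ge k)$ over the background of all genes in the expression matrix
   (the universe on which downstream genes are defined; pathways are
   intersected with it first). BH is applied **within each candidate**
   across its pathways by default; a pooled across-candidates family is a
   config option. Pass when at least one pathway reaches $q < 10^{-4}$.

A locus passing all three conditions is a driver alteration; a gene with at
least one driver locus is a driver gene. Later conditions are evaluated only
for survivors of earlier ones, so the cascade counts are non-increasing by
construction, and the full candidate table with per-stage statistics is
always returned.

### Permutation depth and its threshold are a pair

The reference analysis pairs $B = 100{,}000$ replicates with a pass
threshold of FDR $< 10^{-4}$; that pairing is the package default. The two
numbers are not independent: the add-one estimator is bounded below by
$1/(B+1)$, so at $B = 1000$ no candidate can reach $10^{-4}$ no matter how
strong its signal. Reduced-depth runs — used throughout this package's test
suite and analysis scripts to keep runtimes in seconds — therefore use
$B = 1000$ with the commensurate threshold $0.01$, which still sits an
order of magnitude below the smallest BH-adjusted p-value a null candidate
plausibly attains at that depth. The shared-null cache reuses replicate
t-statistics across candidates with equal group sizes (the null law depends
only on the sizes); per-candidate counts are still exact, because each
candidate's own gene is removed from the cached p-value matrix before
counting.

## Validation layer

* **Known-cancer-gene enrichment**: overlap of the driver list with a
  curated cancer-gene compendium, upper-tail hypergeometric on a stated
  background. The pipeline's default background is the set of genes with at
  least one analyzable promoter locus — the universe the drivers were drawn
  from.
* **PPI neighborhood**: after removing the known cancer genes from the
  driver list, the remainder (restricted to network nodes) is tested for
  enrichment among direct neighbors of the cancer genes, over network nodes
  excluding the cancer genes.
* **POG** (percentage of overlapping genes) between two driver lists is
  symmetrized: $\mathrm{POG} = \tfrac{1}{2}(100k/|A| + 100k/|B|)$. The
  directional percentages are also reported. The symmetrized mean is the
  definition under which the published cross-dataset values (12.25% for
  lists of 222 and 189 genes; 26.10% for 222 and 58) are reproduced at
  integer overlap counts (25 and 24) — no single-direction definition does
  both.

All hypergeometric tails in the package (pathways, cancer genes, PPI,
overlap significance, subtype test) share one implementation, which the test
suite checks against full enumeration of draws for universes up to $N = 25$.

## Subtype analysis

Tumors are clustered on their ternary profiles over the called driver loci.
The distance is a ternary Jaccard: similarity is the fraction of
positions, among those nonzero in either profile, where both carry the
*same* nonzero state. Hyper and hypo are distinct categories — the two
alteration directions are biologically asymmetric — with a binarized variant
(`jaccard_binarize = TRUE`) that collapses them. Two all-zero profiles have
distance 0. Agglomeration is average linkage (UPGMA) with the dendrogram cut
at $k = 3$ by default ($k$ is a config parameter; no automatic selection).
Tumor columns are canonically sorted by sample id before clustering, which
makes the result invariant to input column order (distance ties are then
always broken identically).

Subtype specificity is tested per driver locus in its driver direction: with
$N$ labeled tumors of which $K$ carry the alteration, a subtype of size $n$
with $k$ altered members gets $p = P(X \ge k)$, BH across all
(locus, subtype) pairs, significant at $q < 0.05$ with the in-subtype
frequency required to exceed the out-of-subtype frequency. A gene is
subtype-specific when any of its driver loci is.

## The synthetic generator

`simulate_bundle()` produces the complete input bundle plus planted truth.
Its defaults are the package's study conditions: 20 normals and 60 tumors;
500 autosomal loci (one per gene) over 2000 genes; 10 driver and 50
passenger loci, each altered in 30% of tumors; methylation noise sd 0.05
around per-locus means in [0.2, 0.8], planted shifts of ±0.3 beta units;
expression noise sd 1.0, cis effect 1.5 sd, a 40-gene downstream program per
driver shifted by 1.0 sd (random sign per gene), drawn from one of 20
disjoint 50-gene pathways; 3 equal subtype blocks, with each driver
concentrating 90% of its altered samples in its designated subtype. A few
sex-chromosome and detection-unreliable decoy loci are appended so the
preprocessing filters always have work to do. In-subtype altered samples are
assigned round-robin over a shuffled subtype roster, so every tumor carries
at least one of its subtype's driver alterations — without that guarantee,
"exact recovery of the planted 3-block structure" would be an ill-posed
target for tumors whose profile is entirely zero.

Choices worth making explicit:

* Methylation noise is **truncated-Gaussian**, not Beta-distributed, so the
  Z-score model of the discretizer is exactly correct under the null and
  calibration tests have clean expectations (null nonzero fraction below
  the BH level). A Beta-noise mode exists for robustness probing, with no
  calibration assertion attached.
* One locus per gene by default, keeping truth scoring unambiguous at the
  gene level; a multi-locus mode exercises the both-direction exclusion.
* The generator does **not** emulate: the bimodal beta distribution of real
  arrays, probe-level correlation along promoters, batch effects,
  tumor purity gradients, or overlap structure among real pathway
  databases. Passing recovery tests therefore demonstrates the pipeline's
  statistical machinery under its stated model, not performance on real
  cohorts.

## Problem sizes and runtime

The analysis scripts and the acceptance checks run the default bundle (500
loci × 60 tumors × 2000 genes) with $B = 1000$ permutation replicates —
about ten seconds end to end on one core, dominated by the permutation
stage, which is vectorized across replicates as two matrix products per
group-size key. Unit tests use a smaller bundle (80 loci, 400 genes, 30
tumors) with proportionately stronger planted effects, since the published
thresholds are tuned to genome-scale backgrounds and would be underpowered
at toy scale. Full-depth runs ($B = 10^5$) scale linearly in $B$.

## Known limitations

* The pipeline consumes already-normalized expression and beta matrices; no
  array preprocessing, batch correction or probe remapping is attempted.
* Backgrounds for the enrichment tests on real data (and hence their exact
  p-values) depend on upstream filtering choices that published analyses
  rarely state; the machinery is exact, the universe is the caller's
  responsibility.
* Candidates whose comparison groups fall below 3 samples are skipped, not
  tested; very rare alterations are thus invisible regardless of effect
  size.
* Missing methylation values must be resolved upstream (drop the locus):
  all tests assume complete vectors.
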