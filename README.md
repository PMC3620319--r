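# methdriver

Separating **driver** from **passenger** promoter methylation alterations in
cancer, by integrating paired promoter methylation (beta values) and gene
expression matrices from tumor/normal cohorts. Intended for computational
cancer biologists working with array-style methylation data (beta values per
CpG locus) alongside expression profiles of the same tumors.

## The method

Each tumor sample is first discretized against a normal-tissue reference:
per locus, beta values are converted to Z-scores using the normal mean and
standard deviation, tested two-sided, BH-adjusted within the sample, and
translated into a ternary state — +1 (hypermethylated), 0 (no change), −1
(hypomethylated) at FDR < 0.05. Loci altered in ≥ 10% of tumors (per
direction; genes altered in both directions are excluded) are candidate
drivers, and a candidate is called a **driver alteration** when it passes
three conditions:

1. **cis effect** — the candidate's own gene is differentially expressed
   between altered and unaltered tumors (Welch t-test, BH across candidates,
   FDR < 0.05), in the concordant direction (hyper → down, hypo → up);
2. **downstream load** — the number of genes DE between altered and
   unaltered tumors (own gene excluded) exceeds a permutation null built
   from random disjoint tumor groups of the same sizes, with empirical
   p = (r+1)/(B+1) and BH across candidates;
3. **pathway focus** — the downstream genes are enriched in at least one
   cancer-associated pathway (upper-tail hypergeometric P(X ≥ k) over the
   expressed-gene background, BH within candidate).

A gene with ≥ 1 driver locus is a driver gene. Around the core call sit a
validation layer (known-cancer-gene enrichment, PPI direct-neighbor
enrichment, symmetrized percentage-of-overlapping-genes between driver
lists), a subtype layer (UPGMA clustering of tumors on ternary driver
profiles under a ternary Jaccard distance, plus a hypergeometric
subtype-specificity test), and a synthetic-data generator that plants
drivers, passengers, downstream programs and subtype structure with known
ground truth. The methods vignette
(`vignettes/driver-methylation-methods.Rmd`) documents every model choice,
threshold and limitation.

## Worked example

Simulate the default synthetic cohort (20 normals + 60 tumors, 500 loci,
2000 genes, 10 planted drivers, 50 passengers) and run the full pipeline
with 1000 permutation replicates:

```r
library(methdriver)
bundle <- simulate_bundle(simulation_config(seed = 101))
config <- analysis_config(perm_B = 1000, perm_q = 0.01, seed = 101)
result <- run_pipeline(bundle, config)
print(result)
#> pipeline_result: 500/515 loci analyzed, 60 tumors vs 20 normals
#>   cascade: 60 candidates -> 10 cis -> 10 permutation -> 10 driver loci (10 genes)
score_recovery(result$drivers, bundle)$locus[c("precision", "recall")]
#> $precision [1] 1     $recall [1] 1
result$subtype$contingency
#>        subtype
#> cluster basal-like HER2+ luminal-A
#>       1         20     0         0
#>       2          0    20         0
#>       3          0     0        20
```

Reading the output: 15 decoy loci (sex-chromosome and detection-unreliable)
were removed in preprocessing; 60 loci survived the ≥ 10% frequency filter
(the 10 planted drivers plus the 50 passengers); conditions 1–3 stripped the
passengers and kept all 10 planted drivers, and k = 3 clustering on the
called driver loci reproduced the three planted subtypes exactly. Per-locus
statistics for every candidate (cis q, downstream count, permutation q,
best pathway) are in `result$drivers$calls`.

The same run, presented as a stepwise analysis with tables written under
`results/`, is in the numbered scripts:

```sh
Rscript analysis/01_simulate.R      # write the synthetic bundle
Rscript analysis/02_discretize.R    # ternary matrix at FDR 0.05 and 0.01
Rscript analysis/03_call_drivers.R  # three-condition cascade + recovery
Rscript analysis/04_validate.R      # cancer-gene / PPI / POG evidence
Rscript analysis/05_subtype.R       # clustering + subtype-specific drivers
```

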