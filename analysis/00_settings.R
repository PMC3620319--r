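# Shared settings for the numbered analysis drivers.
# Large intermediates (matrices) live under scratch/, summary tables under
# results/.

library(methdriver)

SEED <- 101L
BUNDLE_DIR <- "scratch/bundle"
RESULTS_DIR <- "results"

# Study conditions: the generator defaults (20 normals / 60 tumors, 500 loci,
# 2000 genes, 10 drivers, 50 passengers; see ?simulation_config).
SIM_CONFIG <- simulation_config(seed = SEED)

# Analysis thresholds: published defaults except the permutation pair, run
# here at B = 1000 replicates with the commensurate FDR threshold 0.01 (the
# add-one empirical p cannot fall below 1/(B+1); the published pairing
# B = 1e5 / FDR < 1e-4 is the analysis_config() default).
ANA_CONFIG <- analysis_config(perm_B = 1000L, perm_q = 0.01, seed = SEED)

dir.create(BUNDLE_DIR, recursive = TRUE, showWarnings = FALSE)
dir.create(RESULTS_DIR, recursive = TRUE, showWarnings = FALSE)
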