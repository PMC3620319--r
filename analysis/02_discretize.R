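#!/usr/bin/env Rscript
# Preprocess (detection-p reliability filter, sex-chromosome exclusion) and
# discretize each tumor's methylation profile against the normal reference
# into the ternary hyper/none/hypo matrix, at the default per-sample BH
# threshold 0.05 and the stricter robustness setting 0.01.

source("analysis/00_settings.R")

bundle <- read_bundle(BUNDLE_DIR)
normals <- bundle$samples$sample_id[bundle$samples$group == "normal"]
tumors <- bundle$samples$sample_id[bundle$samples$group == "tumor"]

keep <- filter_unreliable_loci(bundle$detection_p)
keep <- exclude_sex_chromosomes(intersect(rownames(bundle$beta), keep),
                                bundle$annotation)
cat(sprintf("loci retained after filters: %d of %d\n", length(keep),
            nrow(bundle$beta)))

beta <- bundle$beta[keep, ]
ref <- normal_reference(beta, normals)
tern05 <- discretize_matrix(beta[, tumors], ref, q_cut = 0.05)
tern01 <- discretize_matrix(beta[, tumors], ref, q_cut = 0.01)
write_ternary(tern05, file.path(BUNDLE_DIR, "ternary_q05.tsv"))

stopifnot(all(tern01 == 0L | tern01 == tern05))  # tightening only removes states
tab <- data.frame(
  threshold = c(0.05, 0.01),
  hyper = c(sum(tern05 == 1), sum(tern01 == 1)),
  hypo = c(sum(tern05 == -1), sum(tern01 == -1)),
  nonzero_fraction = c(mean(tern05 != 0), mean(tern01 != 0)))
write.table(tab, file.path(RESULTS_DIR, "02_discretization_summary.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
print(tab, row.names = FALSE)
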