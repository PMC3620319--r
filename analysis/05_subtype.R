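#!/usr/bin/env Rscript
# Subtype analysis: UPGMA clustering of tumors on their ternary driver-locus
# profiles under the ternary Jaccard distance (k = 3), and the hypergeometric
# subtype-specificity test for each driver locus.

source("analysis/00_settings.R")

bundle <- read_bundle(BUNDLE_DIR)
tern <- read_ternary(file.path(BUNDLE_DIR, "ternary_q05.tsv"))
calls <- read.delim(file.path(RESULTS_DIR, "03_driver_calls.tsv"))
driver_rows <- calls[calls$is_driver, ]
stopifnot(nrow(driver_rows) > 0)

cl <- hierarchical_cluster(tern[driver_rows$locus_id, , drop = FALSE],
                           k = ANA_CONFIG$n_clusters)
subtypes <- setNames(bundle$samples$subtype, bundle$samples$sample_id)
subtypes <- subtypes[colnames(tern)]

cat("cluster x subtype contingency:\n")
print(table(cluster = cl$labels, subtype = subtypes[names(cl$labels)]))

st <- subtype_specific_test(tern, driver_rows, subtypes,
                            q_cut = ANA_CONFIG$subtype_q)
n_spec <- vapply(st$specific_genes, length, 1L)
cat("subtype-specific driver genes:\n")
print(n_spec)

write.table(data.frame(sample_id = names(cl$labels), cluster = cl$labels,
                       subtype = subtypes[names(cl$labels)]),
            file.path(RESULTS_DIR, "05_cluster_labels.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write_dendrogram_newick(cl, file.path(RESULTS_DIR, "05_dendrogram.nwk"))
write.table(st$calls, file.path(RESULTS_DIR, "05_subtype_calls.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
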