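#!/usr/bin/env Rscript
# Evidence layer: overlap of the called driver genes with the known
# cancer-gene list, enrichment of the novel drivers among direct PPI
# neighbors of known cancer genes, and the symmetrized percentage of
# overlapping genes (POG) machinery on the published list sizes.

source("analysis/00_settings.R")

bundle <- read_bundle(BUNDLE_DIR)
drivers <- readLines(file.path(RESULTS_DIR, "03_driver_genes.txt"))
tern <- read_ternary(file.path(BUNDLE_DIR, "ternary_q05.tsv"))
background <- unique(bundle$annotation$gene_id[
  match(rownames(tern), bundle$annotation$locus_id)])

cg <- cancer_gene_enrichment(drivers, bundle$cancer_genes, background)
cat(sprintf("known cancer genes among drivers: %d of %d (%.2f%%), p = %.3g\n",
            cg$overlap, cg$n_drivers, cg$percentage, cg$p))

ppi <- ppi_neighbor_enrichment(drivers, bundle$cancer_genes, bundle$network)
if (ppi$applicable) {
  cat(sprintf("novel drivers in cancer-gene PPI neighborhood: %d of %d, p = %.3g\n",
              ppi$in_neighborhood, ppi$n_tested, ppi$p))
}

# POG worked example on the published cross-dataset list sizes (222 vs 189,
# overlap 25; 222 vs 58, overlap 24) over a 14k-gene universe
universe <- sprintf("g%05d", 1:14000)
pogA <- pog(universe[1:222], c(universe[1:25], universe[1000:1163]))
pogB <- pog(universe[1:222], c(universe[1:24], universe[2000:2033]))

rows <- data.frame(
  test = c("cancer_gene_enrichment", "ppi_neighbor_enrichment",
           "pog_222_vs_189_overlap25", "pog_222_vs_58_overlap24"),
  n = c(cg$n_drivers, ppi$n_tested, 222 + 189, 222 + 58),
  k = c(cg$overlap, ppi$in_neighborhood, pogA$overlap, pogB$overlap),
  percentage = c(cg$percentage,
                 if (ppi$applicable) 100 * ppi$in_neighborhood / ppi$n_tested else NA,
                 pogA$pog, pogB$pog),
  p = c(cg$p, ppi$p, NA, NA))
write.table(rows, file.path(RESULTS_DIR, "04_validation.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
print(rows, row.names = FALSE)
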