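#' Read a pipeline input bundle from a directory
#'
#' Expects the file layout written by [write_bundle()]: methylation_beta.tsv,
#' expression.tsv, annotation.tsv, samples.tsv, pathways.gmt,
#' cancer_genes.txt, network_edges.tsv, optionally detection_p.tsv.
#'
#' @param dir Directory containing the input files.
#' @return A list shaped like a `synthetic_bundle` (without truth/config).
#' @export
read_bundle <- function(dir) {
  need <- c("methylation_beta.tsv", "expression.tsv", "annotation.tsv",
            "samples.tsv", "pathways.gmt")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing) > 0L) {
    stop(sprintf("missing input file(s) in '%s': %s", dir,
                 paste(missing, collapse = ", ")))
  }
  dp_path <- file.path(dir, "detection_p.tsv")
  cg_path <- file.path(dir, "cancer_genes.txt")
  net_path <- file.path(dir, "network_edges.tsv")
  list(beta = read_matrix(file.path(dir, "methylation_beta.tsv"), "methylation"),
       detection_p = if (file.exists(dp_path)) read_matrix(dp_path, "detection p") else NULL,
       expr = read_matrix(file.path(dir, "expression.tsv"), "expression"),
       annotation = read_annotation(file.path(dir, "annotation.tsv")),
       samples = read_sample_sheet(file.path(dir, "samples.tsv")),
       pathways = read_gmt(file.path(dir, "pathways.gmt")),
       cancer_genes = if (file.exists(cg_path)) read_gene_list(cg_path) else NULL,
       network = if (file.exists(net_path)) read_edge_list(net_path) else NULL)
}

#' Run the full analysis end to end
#'
#' preprocess (detection-p reliability filter, sex-chromosome exclusion) ->
#' per-sample discretization against the normal reference -> three-condition
#' driver cascade -> validation (cancer-gene and PPI-neighbor enrichment,
#' when a cancer-gene list / network are supplied) -> subtype analysis
#' (clustering on driver-locus profiles and the subtype-specificity test,
#' when subtype labels exist and drivers were found).
#'
#' @param bundle Input bundle: a `synthetic_bundle`, the output of
#'   [read_bundle()], or a directory path.
#' @param config An [analysis_config()].
#' @param out_dir Optional directory; when given, every stage artifact is
#'   written there as plain text (see Details in the package vignette).
#' @return List of class `pipeline_result`: ternary, drivers (driver_result),
#'   validation, subtype, manifest.
#' @export
run_pipeline <- function(bundle, config = analysis_config(), out_dir = NULL) {
  if (is.character(bundle)) bundle <- read_bundle(bundle)
  samples <- bundle$samples
  normals <- samples$sample_id[samples$group == "normal"]
  tumors <- samples$sample_id[samples$group == "tumor"]

  # --- preprocess ---------------------------------------------------------
  keep <- rownames(bundle$beta)
  if (!is.null(bundle$detection_p)) {
    keep <- intersect(keep, filter_unreliable_loci(bundle$detection_p))
  }
  keep <- exclude_sex_chromosomes(keep, bundle$annotation)
  beta <- bundle$beta[keep, , drop = FALSE]

  # --- discretize ---------------------------------------------------------
  ref <- normal_reference(beta, intersect(normals, colnames(beta)))
  ternary <- discretize_matrix(beta[, intersect(tumors, colnames(beta)), drop = FALSE],
                               ref, q_cut = config$discretize_q,
                               scope = config$discretize_scope)

  # --- drivers ------------------------------------------------------------
  drv <- call_drivers(ternary, bundle$expr, bundle$annotation,
                      bundle$pathways, config)

  # --- validation ---------------------------------------------------------
  validation <- NULL
  if (!is.null(bundle$cancer_genes) && length(drv$drivers) > 0L) {
    background <- unique(bundle$annotation$gene_id[
      match(rownames(ternary), bundle$annotation$locus_id)])
    validation <- list(
      cancer_gene = cancer_gene_enrichment(drv$drivers, bundle$cancer_genes,
                                           background))
    if (!is.null(bundle$network)) {
      validation$ppi_neighbor <- ppi_neighbor_enrichment(
        drv$drivers, bundle$cancer_genes, bundle$network)
    }
  }

  # --- subtype ------------------------------------------------------------
  subtype <- NULL
  subtypes <- stats::setNames(samples$subtype, samples$sample_id)[tumors]
  if (sum(!is.na(unique(subtypes))) >= 2L && length(drv$driver_loci) > 0L) {
    driver_rows <- drv$calls[drv$calls$is_driver, , drop = FALSE]
    tern_drv <- ternary[driver_rows$locus_id, , drop = FALSE]
    cl <- hierarchical_cluster(tern_drv, k = min(config$n_clusters, ncol(tern_drv)),
                               binarize = config$jaccard_binarize)
    st <- subtype_specific_test(ternary, driver_rows, subtypes,
                                q_cut = config$subtype_q)
    subtype <- list(cluster = cl, specific = st,
                    contingency = table(cluster = cl$labels,
                                        subtype = subtypes[names(cl$labels)],
                                        useNA = "no"))
  }

  manifest <- list(
    config = unclass(config),
    seed = config$seed,
    n_loci_input = nrow(bundle$beta), n_loci_analyzed = nrow(ternary),
    n_normal = length(intersect(normals, colnames(beta))),
    n_tumor = ncol(ternary),
    cascade = as.list(drv$counts),
    n_driver_genes = length(drv$drivers))

  result <- structure(list(ternary = ternary, drivers = drv,
                           validation = validation, subtype = subtype,
                           manifest = manifest),
                      class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_result(result, out_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("pipeline_result: %d/%d loci analyzed, %d tumors vs %d normals\n",
              m$n_loci_analyzed, m$n_loci_input, m$n_tumor, m$n_normal))
  cat(sprintf("  cascade: %d candidates -> %d cis -> %d permutation -> %d driver loci (%d genes)\n",
              m$cascade$candidates, m$cascade$condition1, m$cascade$condition2,
              m$cascade$drivers, m$n_driver_genes))
  invisible(x)
}

#' Write every stage artifact of a pipeline run as plain text
#'
#' Ternary matrix TSV, per-candidate driver-calls TSV, driver-gene list,
#' per-driver downstream GMT, enriched-pathways TSV, validation report TSV,
#' cluster labels TSV, dendrogram Newick, subtype-calls TSV and a JSON run
#' manifest with the cascade counts.
#'
#' @param result A `pipeline_result`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline_result <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_ternary(result$ternary, file.path(dir, "ternary.tsv"))
  calls <- result$drivers$calls
  utils::write.table(calls, file.path(dir, "driver_calls.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(result$drivers$drivers, file.path(dir, "driver_genes.txt"))
  if (length(result$drivers$downstream) > 0L) {
    write_gmt(result$drivers$downstream, file.path(dir, "downstream.gmt"))
  }
  if (length(result$drivers$enrichment) > 0L) {
    enr <- do.call(rbind, Map(function(nm, tab) cbind(candidate = nm, tab),
                              names(result$drivers$enrichment),
                              result$drivers$enrichment))
    utils::write.table(enr, file.path(dir, "enriched_pathways.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(result$validation)) {
    v <- result$validation
    rows <- data.frame(test = "cancer_gene_enrichment",
                       n = v$cancer_gene$n_drivers, k = v$cancer_gene$overlap,
                       percentage = v$cancer_gene$percentage, p = v$cancer_gene$p)
    if (!is.null(v$ppi_neighbor) && v$ppi_neighbor$applicable) {
      rows <- rbind(rows, data.frame(test = "ppi_neighbor_enrichment",
                                     n = v$ppi_neighbor$n_tested,
                                     k = v$ppi_neighbor$in_neighborhood,
                                     percentage = 100 * v$ppi_neighbor$in_neighborhood /
                                       v$ppi_neighbor$n_tested,
                                     p = v$ppi_neighbor$p))
    }
    utils::write.table(rows, file.path(dir, "validation.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(result$subtype)) {
    labs <- result$subtype$cluster$labels
    utils::write.table(data.frame(sample_id = names(labs), cluster = labs),
                       file.path(dir, "cluster_labels.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_dendrogram_newick(result$subtype$cluster, file.path(dir, "dendrogram.nwk"))
    utils::write.table(result$subtype$specific$calls,
                       file.path(dir, "subtype_calls.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
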