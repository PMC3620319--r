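#' Configuration for the synthetic methylation + expression generator
#'
#' Defaults define the study conditions used throughout the package's
#' recovery experiments: 20 normals and 60 tumors over 500 autosomal promoter
#' loci and 2000 expressed genes; 10 planted driver loci and 50 planted
#' passenger loci, each altered in 30% of tumors; a 0.3 beta-unit methylation
#' shift against normal-reference noise of sd 0.05; a cis effect of 1.5
#' expression-noise sds on the driver's own gene and a 1.0-sd shift on a
#' 40-gene downstream program drawn from one of 20 disjoint 50-gene
#' pathways; 3 tumor subtypes with planted drivers concentrating 90% of
#' their altered samples in one subtype.
#'
#' @param n_normal,n_tumor Sample counts (normals >= 2).
#' @param n_loci Autosomal promoter loci (one gene each by default).
#' @param n_genes Genes in the expression matrix.
#' @param n_pathways,pathway_size Disjoint pathway gene sets, placed over the
#'   high end of the gene range (never over locus-bearing genes).
#' @param n_drivers,n_passengers Planted driver / passenger locus counts.
#' @param altered_fraction Fraction of tumors carrying each planted alteration.
#' @param meth_shift Beta-value shift of a planted alteration (+ for hyper).
#' @param cis_effect Own-gene expression shift in noise-sd units (sign
#'   opposite to the methylation direction).
#' @param downstream_effect Downstream-program shift in noise-sd units
#'   (random sign per gene).
#' @param downstream_size Genes per downstream program (<= pathway_size).
#' @param noise_sd Expression noise sd (log-scale units).
#' @param beta_sd Methylation noise sd (beta units).
#' @param n_subtypes Number of tumor subtypes (contiguous equal blocks).
#' @param subtype_concentration Fraction of a planted driver's altered
#'   samples placed inside its designated subtype (>= 0.8).
#' @param n_sex_loci,n_unreliable_loci Decoy loci appended to exercise the
#'   sex-chromosome and detection-p filters (planted with no signal).
#' @param n_cancer_genes Size of the synthetic known-cancer-gene list.
#' @param loci_per_gene Promoter loci per gene (> 1 exercises the
#'   both-direction gene exclusion).
#' @param beta_mode "truncated_gaussian" (default; the discretization model's
#'   null is then exactly correct) or "beta" (Beta-distributed methylation
#'   noise for robustness probing).
#' @param seed Generator seed.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_normal = 20L, n_tumor = 60L, n_loci = 500L,
                              n_genes = 2000L, n_pathways = 20L,
                              pathway_size = 50L, n_drivers = 10L,
                              n_passengers = 50L, altered_fraction = 0.3,
                              meth_shift = 0.3, cis_effect = 1.5,
                              downstream_effect = 1.0, downstream_size = 40L,
                              noise_sd = 1.0, beta_sd = 0.05,
                              n_subtypes = 3L, subtype_concentration = 0.9,
                              n_sex_loci = 10L, n_unreliable_loci = 5L,
                              n_cancer_genes = 100L, loci_per_gene = 1L,
                              beta_mode = c("truncated_gaussian", "beta"),
                              seed = 1L) {
  cfg <- list(n_normal = as.integer(n_normal), n_tumor = as.integer(n_tumor),
              n_loci = as.integer(n_loci), n_genes = as.integer(n_genes),
              n_pathways = as.integer(n_pathways),
              pathway_size = as.integer(pathway_size),
              n_drivers = as.integer(n_drivers),
              n_passengers = as.integer(n_passengers),
              altered_fraction = altered_fraction, meth_shift = meth_shift,
              cis_effect = cis_effect, downstream_effect = downstream_effect,
              downstream_size = as.integer(downstream_size),
              noise_sd = noise_sd, beta_sd = beta_sd,
              n_subtypes = as.integer(n_subtypes),
              subtype_concentration = subtype_concentration,
              n_sex_loci = as.integer(n_sex_loci),
              n_unreliable_loci = as.integer(n_unreliable_loci),
              n_cancer_genes = as.integer(n_cancer_genes),
              loci_per_gene = as.integer(loci_per_gene),
              beta_mode = match.arg(beta_mode), seed = as.integer(seed))
  if (cfg$n_normal < 2L) stop("need >= 2 normal samples")
  if (cfg$n_drivers + cfg$n_passengers > cfg$n_loci) {
    stop("planted loci exceed n_loci")
  }
  if (cfg$downstream_size > cfg$pathway_size) {
    stop("downstream program larger than its pathway")
  }
  n_locus_genes <- ceiling((cfg$n_loci + cfg$n_sex_loci + cfg$n_unreliable_loci) /
                             cfg$loci_per_gene)
  if (n_locus_genes + cfg$n_pathways * cfg$pathway_size > cfg$n_genes) {
    stop("n_genes too small for the locus-bearing genes plus disjoint pathways")
  }
  if (cfg$subtype_concentration < 0.8 || cfg$subtype_concentration > 1) {
    stop("subtype_concentration must lie in [0.8, 1]")
  }
  structure(cfg, class = "simulation_config")
}

# Gaussian noise around `mean`, clamped into (0, 1); or Beta noise with
# matching mean/sd when mode == "beta"
rbeta_noise <- function(n, mean, sd, mode) {
  if (mode == "truncated_gaussian") {
    pmin(pmax(stats::rnorm(n, mean, sd), 1e-3), 1 - 1e-3)
  } else {
    nu <- pmax(mean * (1 - mean) / sd^2 - 1, 1)
    stats::rbeta(n, mean * nu, (1 - mean) * nu)
  }
}

#' Generate a complete synthetic input bundle with planted ground truth
#'
#' Produces every input the pipeline consumes — beta matrix (normals +
#' tumors), detection p-values, expression matrix, locus annotation, sample
#' sheet with subtypes, pathway GMT collection, cancer-gene list, PPI
#' network — plus the planted truth for recovery scoring.
#'
#' Structure planted (see [simulation_config()] for the knobs): normal
#' methylation is Gaussian noise around a per-locus mean in [0.2, 0.8];
#' tumors follow the normal law except at planted loci in their altered
#' samples, where beta shifts by +/- `meth_shift`. Driver loci additionally
#' shift their own gene's expression opposite to the methylation direction
#' and shift a downstream program drawn from one designated pathway;
#' passenger loci shift methylation only. Every planted driver is
#' subtype-specific: `subtype_concentration` of its altered samples lie in
#' its designated subtype, assigned round-robin so each tumor carries at
#' least one of its subtype's driver alterations. The known-cancer-gene list
#' and network are built so each driver gene is a direct neighbor of at
#' least one cancer gene, on top of an Erdos-Renyi background.
#'
#' @param config A [simulation_config()].
#' @return List of class `synthetic_bundle` with elements beta, detection_p,
#'   expr, annotation, samples, pathways, cancer_genes, network, truth,
#'   config.
#' @export
simulate_bundle <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(stage_seed(config$seed, "simulate"))
  cfg <- config

  n_extra <- cfg$n_sex_loci + cfg$n_unreliable_loci
  n_all_loci <- cfg$n_loci + n_extra
  loci <- sprintf("cg%05d", seq_len(n_all_loci))
  gene_idx <- ((seq_len(n_all_loci) - 1L) %/% cfg$loci_per_gene) + 1L
  genes <- sprintf("g%04d", seq_len(cfg$n_genes))
  locus_gene <- genes[gene_idx]
  chrom <- as.character(sample.int(22L, n_all_loci, replace = TRUE))
  sex_idx <- if (cfg$n_sex_loci > 0L) cfg$n_loci + seq_len(cfg$n_sex_loci) else integer(0)
  chrom[sex_idx] <- rep(c("X", "Y"), length.out = cfg$n_sex_loci)
  unrel_idx <- if (cfg$n_unreliable_loci > 0L) {
    cfg$n_loci + cfg$n_sex_loci + seq_len(cfg$n_unreliable_loci)
  } else integer(0)
  annotation <- data.frame(locus_id = loci, gene_id = locus_gene,
                           chromosome = chrom, stringsAsFactors = FALSE)

  normals <- sprintf("N%03d", seq_len(cfg$n_normal))
  tumors <- sprintf("T%03d", seq_len(cfg$n_tumor))
  subtype_names <- c("basal-like", "luminal-A", "HER2+",
                     sprintf("subtype%d", seq_len(max(0L, cfg$n_subtypes - 3L)) + 3L))
  # contiguous equal-as-possible blocks
  subtype_of <- sort(rep(subtype_names[seq_len(cfg$n_subtypes)],
                         length.out = cfg$n_tumor))
  names(subtype_of) <- tumors
  samples <- data.frame(sample_id = c(normals, tumors),
                        group = rep(c("normal", "tumor"),
                                    c(cfg$n_normal, cfg$n_tumor)),
                        subtype = c(rep(NA_character_, cfg$n_normal), subtype_of),
                        stringsAsFactors = FALSE)

  # planted loci: drivers first, then passengers; alternate directions
  driver_idx <- seq_len(cfg$n_drivers)
  passenger_idx <- cfg$n_drivers + seq_len(cfg$n_passengers)
  planted_idx <- c(driver_idx, passenger_idx)
  direction <- rep_len(c("hyper", "hypo"), length(planted_idx))
  state <- ifelse(direction == "hyper", 1L, -1L)

  # per-locus baseline methylation; keep planted shifts inside (0, 1)
  mu <- stats::runif(n_all_loci, 0.2, 0.8)
  mu[planted_idx[direction == "hyper"]] <- stats::runif(sum(direction == "hyper"), 0.2, 0.5)
  mu[planted_idx[direction == "hypo"]] <- stats::runif(sum(direction == "hypo"), 0.5, 0.8)

  n_alt <- max(1L, round(cfg$altered_fraction * cfg$n_tumor))
  # round-robin coverage of each subtype by its drivers' altered samples
  st_levels <- unique(subtype_of)
  rot <- lapply(stats::setNames(st_levels, st_levels), function(st) {
    members <- sample(tumors[subtype_of == st])
    list(members = members, ptr = 0L)
  })
  take_rotating <- function(st, m) {
    r <- rot[[st]]; nm <- length(r$members)
    pos <- ((r$ptr + seq_len(m) - 1L) %% nm) + 1L
    rot[[st]]$ptr <<- (r$ptr + m) %% nm
    unique(r$members[pos])
  }

  altered_samples <- vector("list", length(planted_idx))
  driver_subtype <- rep(NA_character_, length(planted_idx))
  for (j in seq_along(planted_idx)) {
    if (j <= cfg$n_drivers) {
      st <- st_levels[((j - 1L) %% length(st_levels)) + 1L]
      driver_subtype[j] <- st
      n_in <- min(round(cfg$subtype_concentration * n_alt),
                  sum(subtype_of == st))
      inside <- take_rotating(st, n_in)
      outside_pool <- tumors[subtype_of != st]
      outside <- if (n_alt - length(inside) > 0L) {
        sample(outside_pool, min(n_alt - length(inside), length(outside_pool)))
      } else character(0)
      altered_samples[[j]] <- c(inside, outside)
    } else {
      altered_samples[[j]] <- sample(tumors, n_alt)
    }
  }

  # methylation matrix: normals + tumors
  beta <- matrix(0, n_all_loci, cfg$n_normal + cfg$n_tumor,
                 dimnames = list(loci, c(normals, tumors)))
  for (i in seq_len(n_all_loci)) {
    beta[i, ] <- rbeta_noise(ncol(beta), mu[i], cfg$beta_sd, cfg$beta_mode)
  }
  for (j in seq_along(planted_idx)) {
    i <- planted_idx[j]
    shift <- cfg$meth_shift * state[j]
    cols <- altered_samples[[j]]
    beta[i, cols] <- pmin(pmax(beta[i, cols] + shift, 1e-3), 1 - 1e-3)
  }

  # detection p-values: clean except the designated unreliable loci
  detection_p <- matrix(stats::runif(length(beta), 0, 0.04),
                        n_all_loci, ncol(beta), dimnames = dimnames(beta))
  for (i in unrel_idx) {
    fail <- sample(ncol(beta), ceiling(0.2 * ncol(beta)))
    detection_p[i, fail] <- stats::runif(length(fail), 0.06, 1)
  }

  # disjoint pathways over the top of the gene range
  pw_start <- cfg$n_genes - cfg$n_pathways * cfg$pathway_size
  pathways <- lapply(seq_len(cfg$n_pathways), function(p) {
    genes[pw_start + (p - 1L) * cfg$pathway_size + seq_len(cfg$pathway_size)]
  })
  names(pathways) <- sprintf("pathway_%02d", seq_len(cfg$n_pathways))

  # expression: baseline noise, cis + downstream shifts in altered tumors
  gmean <- stats::runif(cfg$n_genes, 4, 10)
  expr <- matrix(stats::rnorm(cfg$n_genes * ncol(beta), gmean, cfg$noise_sd),
                 cfg$n_genes, ncol(beta), dimnames = list(genes, colnames(beta)))
  downstream_of <- vector("list", cfg$n_drivers)
  target_pathway <- character(cfg$n_drivers)
  for (j in seq_len(cfg$n_drivers)) {
    i <- planted_idx[j]; cols <- altered_samples[[j]]
    own <- locus_gene[i]
    expr[own, cols] <- expr[own, cols] - state[j] * cfg$cis_effect * cfg$noise_sd
    p <- ((j - 1L) %% cfg$n_pathways) + 1L
    target_pathway[j] <- names(pathways)[p]
    prog <- sample(setdiff(pathways[[p]], own), cfg$downstream_size)
    sgn <- sample(c(-1, 1), length(prog), replace = TRUE)
    expr[prog, cols] <- expr[prog, cols] +
      sgn * cfg$downstream_effect * cfg$noise_sd
    downstream_of[[j]] <- prog
  }

  # cancer genes + network: every driver gene adjacent to >= 1 cancer gene
  driver_genes <- unique(locus_gene[driver_idx])
  cg_pool <- setdiff(genes, locus_gene[planted_idx])
  cancer_genes <- sample(cg_pool, min(cfg$n_cancer_genes, length(cg_pool)))
  node_pool <- unique(c(driver_genes, cancer_genes,
                        sample(genes, min(300L, cfg$n_genes))))
  anchor <- if (length(driver_genes) > 0L && length(cancer_genes) > 0L) {
    cbind(driver_genes, sample(cancer_genes, length(driver_genes), replace = TRUE))
  } else matrix(character(0), ncol = 2)
  n_bg <- 3L * length(node_pool)
  bg <- cbind(sample(node_pool, n_bg, replace = TRUE),
              sample(node_pool, n_bg, replace = TRUE))
  network <- suppressMessages(interaction_network(rbind(anchor, bg)))

  truth <- data.frame(
    locus_id = loci[planted_idx], gene_id = locus_gene[planted_idx],
    direction = direction, state = state,
    role = rep(c("driver", "passenger"), c(cfg$n_drivers, cfg$n_passengers)),
    subtype = driver_subtype,
    target_pathway = c(target_pathway, rep(NA_character_, cfg$n_passengers)),
    stringsAsFactors = FALSE)
  truth$altered_samples <- altered_samples
  truth$downstream <- c(downstream_of,
                        rep(list(character(0)), cfg$n_passengers))

  structure(list(beta = beta, detection_p = detection_p, expr = expr,
                 annotation = annotation, samples = samples,
                 pathways = pathways, cancer_genes = cancer_genes,
                 network = network, truth = truth, config = cfg),
            class = "synthetic_bundle")
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat(sprintf(paste0("synthetic_bundle: %d loci x %d samples (%d normal), ",
                     "%d genes, %d planted drivers, %d passengers\n"),
              nrow(x$beta), ncol(x$beta), x$config$n_normal,
              nrow(x$expr), x$config$n_drivers, x$config$n_passengers))
  invisible(x)
}

#' Score driver recovery against the planted truth
#'
#' Planted drivers are the positives; passengers and every unplanted locus
#' are negatives. A locus-level true positive must match the planted
#' direction. Precision is NA (not applicable) when nothing was called.
#'
#' @param result A `driver_result` from [call_drivers()] / [run_pipeline()].
#' @param truth The `truth` table of a `synthetic_bundle` (or the bundle).
#' @return List with locus- and gene-level precision/recall and TP/FP/FN
#'   counts.
#' @export
score_recovery <- function(result, truth) {
  if (inherits(truth, "synthetic_bundle")) truth <- truth$truth
  pos <- truth[truth$role == "driver", , drop = FALSE]
  calls <- result$calls[result$calls$is_driver, , drop = FALSE]
  called_keys <- paste(calls$locus_id, calls$direction)
  true_keys <- paste(pos$locus_id, pos$direction)
  tp_l <- length(intersect(called_keys, true_keys))
  prec_l <- if (length(called_keys) > 0L) tp_l / length(called_keys) else NA_real_
  rec_l <- if (length(true_keys) > 0L) tp_l / length(true_keys) else NA_real_
  called_g <- unique(calls$gene_id); true_g <- unique(pos$gene_id)
  tp_g <- length(intersect(called_g, true_g))
  list(locus = list(tp = tp_l, fp = length(called_keys) - tp_l,
                    fn = length(true_keys) - tp_l,
                    precision = prec_l, recall = rec_l),
       gene = list(tp = tp_g, fp = length(called_g) - tp_g,
                   fn = length(true_g) - tp_g,
                   precision = if (length(called_g) > 0L) tp_g / length(called_g) else NA_real_,
                   recall = if (length(true_g) > 0L) tp_g / length(true_g) else NA_real_))
}

#' Write a synthetic bundle to disk in the pipeline's input formats
#'
#' TSV matrices, sample sheet and annotation; GMT pathways; one-gene-per-line
#' cancer genes; two-column edge list; truth as JSON (labelled synthetic).
#'
#' @param bundle A `synthetic_bundle`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix(bundle$beta, file.path(dir, "methylation_beta.tsv"), "locus_id")
  write_matrix(bundle$detection_p, file.path(dir, "detection_p.tsv"), "locus_id")
  write_matrix(bundle$expr, file.path(dir, "expression.tsv"), "gene_id")
  utils::write.table(bundle$annotation, file.path(dir, "annotation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$samples, file.path(dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  write_gmt(bundle$pathways, file.path(dir, "pathways.gmt"))
  writeLines(bundle$cancer_genes, file.path(dir, "cancer_genes.txt"))
  utils::write.table(bundle$network$edges, file.path(dir, "network_edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  truth <- bundle$truth
  jsonlite::write_json(
    list(planted = truth[, setdiff(names(truth), c("altered_samples", "downstream"))],
         altered_samples = stats::setNames(truth$altered_samples, truth$locus_id),
         downstream = stats::setNames(truth$downstream, truth$locus_id)),
    file.path(dir, "synthetic_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
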