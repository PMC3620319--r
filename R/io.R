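#' Read a feature-by-sample numeric matrix from TSV
#'
#' Expects a tab-delimited file with a header row of sample identifiers and
#' a first column of feature (locus or gene) identifiers. Used for beta-value
#' matrices, expression matrices, intensity matrices and detection p-value
#' matrices alike; the caller decides the role of rows and columns.
#'
#' @param path Path to a TSV file.
#' @param what Label used in error messages (e.g. "methylation", "expression").
#' @return Numeric matrix with feature rownames and sample colnames.
#' @export
read_matrix <- function(path, what = "matrix") {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", row.names = NULL,
                           check.names = FALSE, colClasses = "character")
  if (ncol(raw) < 2L) stop(sprintf("%s file '%s' needs a feature column plus >=1 sample column", what, path))
  ids <- raw[[1L]]
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate feature id(s) in %s file: %s", what,
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  samples <- colnames(raw)[-1L]
  if (anyDuplicated(samples)) {
    stop(sprintf("duplicate sample id(s) in %s file: %s", what,
                 paste(unique(samples[duplicated(samples)]), collapse = ", ")))
  }
  body <- as.matrix(raw[, -1L, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(body), nrow = nrow(body)))
  bad <- which(is.na(num) & !(toupper(body) %in% c("NA", "NAN", "")), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-numeric cell in %s file at feature '%s', sample '%s': '%s'",
                 what, ids[bad[1L, 1L]], samples[bad[1L, 2L]], body[bad[1L, , drop = FALSE]]))
  }
  dimnames(num) <- list(ids, samples)
  num
}

#' Write a feature-by-sample matrix as TSV
#'
#' Inverse of [read_matrix()]; values are written with up to 10 significant
#' digits so that a read/write round trip reproduces them exactly.
#'
#' @param mat Numeric matrix with rownames and colnames.
#' @param path Output path.
#' @param feature_col Name for the first (feature id) column.
#' @export
write_matrix <- function(mat, path, feature_col = "feature_id") {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  df <- data.frame(rownames(mat), format(mat, trim = TRUE, digits = 10, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c(feature_col, colnames(mat))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' Standard GMT: one set per line, tab-separated fields `name`, `description`,
#' then member genes. Duplicate members within a line are collapsed.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors (set name -> unique member genes).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(structure(list(), names = character(0)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, 1L) < 3L)
  if (length(short) > 0L) {
    stop(sprintf("GMT line %d has fewer than 3 tab-separated fields", short[1L]))
  }
  nm <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nm)) {
    stop(sprintf("duplicate gene-set name(s) in GMT: %s",
                 paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nm
  sets
}

#' Write gene sets in GMT format
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of per-set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- mapply(function(nm, d, genes) paste(c(nm, d, genes), collapse = "\t"),
                  names(sets), descriptions, sets)
  writeLines(unname(lines), path)
  invisible(path)
}

#' Read an undirected protein-interaction network from a two-column edge list
#'
#' Edges are deduplicated regardless of orientation; self-loops are dropped
#' (with a message giving the count).
#'
#' @param path Path to a tab- or whitespace-separated two-column file.
#' @return An `interaction_network`: list with `edges` (two-column character
#'   matrix, each row sorted), `nodes`, and an adjacency list `adj`.
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(interaction_network(matrix(character(0), ncol = 2)))
  fields <- strsplit(trimws(lines), "[\t ]+")
  bad <- which(vapply(fields, length, 1L) != 2L)
  if (length(bad) > 0L) stop(sprintf("edge-list line %d does not have exactly two columns", bad[1L]))
  interaction_network(do.call(rbind, fields))
}

#' Construct an interaction network from an edge matrix
#'
#' @param edges Two-column character matrix of gene-id pairs.
#' @return An `interaction_network` object.
#' @export
interaction_network <- function(edges) {
  edges <- matrix(as.character(edges), ncol = 2)
  loops <- edges[, 1L] == edges[, 2L]
  if (any(loops)) {
    message(sprintf("dropped %d self-loop(s) from edge list", sum(loops)))
    edges <- edges[!loops, , drop = FALSE]
  }
  # canonical orientation, then dedup
  flip <- edges[, 1L] > edges[, 2L]
  edges[flip, ] <- edges[flip, c(2L, 1L)]
  edges <- unique(edges)
  nodes <- sort(unique(as.vector(edges)))
  adj <- lapply(stats::setNames(nodes, nodes), function(x) character(0))
  if (nrow(edges) > 0L) {
    nb <- split(c(edges[, 2L], edges[, 1L]), c(edges[, 1L], edges[, 2L]))
    adj[names(nb)] <- lapply(nb, function(v) sort(unique(v)))
  }
  structure(list(edges = edges, nodes = nodes, adj = adj),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("interaction_network: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Direct neighbors of a seed gene set, excluding the seeds
#'
#' Union of the direct interaction partners of every seed gene, minus the
#' seeds themselves. Seeds absent from the network contribute nothing.
#'
#' @param network An `interaction_network`.
#' @param seeds Character vector of seed gene ids.
#' @return Character vector of neighbor gene ids (sorted).
#' @export
neighbors_of_set <- function(network, seeds) {
  stopifnot(inherits(network, "interaction_network"))
  present <- intersect(seeds, network$nodes)
  nb <- unique(unlist(network$adj[present], use.names = FALSE))
  sort(setdiff(nb, seeds))
}

#' Read the sample sheet
#'
#' TSV with columns `sample_id`, `group` (tumor/normal) and optionally
#' `subtype` (defined only for tumors).
#'
#' @param path Path to the sample sheet TSV.
#' @return Data frame with columns sample_id, group, subtype (NA where absent).
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% colnames(df))) {
    stop("sample sheet needs columns 'sample_id' and 'group'")
  }
  if (!all(df$group %in% c("tumor", "normal"))) {
    stop("sample sheet 'group' must be 'tumor' or 'normal'")
  }
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in sample sheet")
  if (is.null(df$subtype)) df$subtype <- NA_character_
  df$subtype[!nzchar(trimws(ifelse(is.na(df$subtype), "", df$subtype)))] <- NA_character_
  if (any(!is.na(df$subtype) & df$group == "normal")) {
    stop("subtype labels are only defined for tumor samples")
  }
  df[, c("sample_id", "group", "subtype")]
}

#' Read a one-gene-per-line list (e.g. known cancer genes)
#' @param path Path to a text file.
#' @return Character vector of unique gene ids.
#' @export
read_gene_list <- function(path) {
  g <- trimws(readLines(path, warn = FALSE))
  unique(g[nzchar(g)])
}

#' Read a locus annotation table
#'
#' TSV with columns `locus_id`, `gene_id`, `chromosome`. Every locus maps to
#' exactly one gene; chromosome is an autosome name, "X" or "Y".
#'
#' @param path Path to the annotation TSV.
#' @return Data frame with those three character columns.
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character")
  need <- c("locus_id", "gene_id", "chromosome")
  if (!all(need %in% colnames(df))) {
    stop("annotation needs columns locus_id, gene_id, chromosome")
  }
  if (anyDuplicated(df$locus_id)) stop("annotation maps some locus_id more than once")
  df[, need]
}
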