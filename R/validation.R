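#' Enrichment of a driver-gene list for known cancer genes
#'
#' Overlap of the driver list with a curated cancer-gene set (e.g. an
#' F-census-style compendium), with an upper-tail hypergeometric p-value
#' against a stated background universe. The default background in the
#' pipeline is the set of genes with at least one analyzable promoter locus.
#'
#' @param drivers Character vector of driver gene ids (nonempty).
#' @param cancer_genes Character vector of known cancer gene ids.
#' @param background Character vector: the gene universe.
#' @return List: n_drivers, overlap, percentage (100 * overlap / n_drivers),
#'   p (hypergeometric upper tail).
#' @export
cancer_gene_enrichment <- function(drivers, cancer_genes, background) {
  if (length(drivers) == 0L) stop("driver list is empty")
  drivers <- unique(drivers)
  outside <- setdiff(drivers, background)
  if (length(outside) > 0L) {
    stop(sprintf("driver gene(s) outside the background: %s",
                 paste(utils::head(outside, 5L), collapse = ", ")))
  }
  kc <- intersect(cancer_genes, background)
  k <- length(intersect(drivers, kc))
  list(n_drivers = length(drivers), overlap = k,
       percentage = 100 * k / length(drivers),
       p = hypergeom_upper(k, length(kc), length(drivers), length(background)))
}

#' Enrichment of novel drivers among direct PPI neighbors of cancer genes
#'
#' Removes the known cancer genes from the driver list, restricts the
#' remainder to network nodes, and tests whether they fall into the direct
#' interaction neighborhood of the cancer genes more often than chance
#' (upper-tail hypergeometric over network nodes excluding the cancer genes).
#'
#' @param drivers Character vector of driver gene ids.
#' @param cancer_genes Character vector of known cancer gene ids.
#' @param network An `interaction_network`.
#' @return List: applicable (FALSE when no novel driver maps to the network,
#'   then no p), n_tested, in_neighborhood, neighborhood_size,
#'   background_size, p.
#' @export
ppi_neighbor_enrichment <- function(drivers, cancer_genes, network) {
  test_set <- intersect(setdiff(unique(drivers), cancer_genes), network$nodes)
  if (length(test_set) == 0L) {
    return(list(applicable = FALSE, n_tested = 0L, in_neighborhood = NA_integer_,
                neighborhood_size = NA_integer_, background_size = NA_integer_,
                p = NA_real_))
  }
  target <- neighbors_of_set(network, cancer_genes)
  bg <- setdiff(network$nodes, cancer_genes)
  k <- length(intersect(test_set, target))
  list(applicable = TRUE, n_tested = length(test_set), in_neighborhood = k,
       neighborhood_size = length(target), background_size = length(bg),
       p = hypergeom_upper(k, length(target), length(test_set), length(bg)))
}

#' Percentage of overlapping genes (POG) between two driver lists
#'
#' Symmetrized overlap percentage: the mean of the two directional
#' percentages 100*k/|A| and 100*k/|B|, where k is the overlap count. Both
#' directional values are also reported.
#'
#' @param list_a,list_b Nonempty character vectors of gene ids.
#' @return List: overlap, pct_a (100*k/|A|), pct_b (100*k/|B|),
#'   pog (their mean).
#' @export
pog <- function(list_a, list_b) {
  list_a <- unique(list_a); list_b <- unique(list_b)
  if (length(list_a) == 0L || length(list_b) == 0L) stop("POG requires nonempty lists")
  k <- length(intersect(list_a, list_b))
  pa <- 100 * k / length(list_a)
  pb <- 100 * k / length(list_b)
  list(overlap = k, pct_a = pa, pct_b = pb, pog = (pa + pb) / 2)
}

#' Hypergeometric significance of the overlap behind a POG value
#'
#' @param list_a,list_b Gene lists, both subsets of `background`.
#' @param background The gene universe both lists were drawn from.
#' @return Upper-tail hypergeometric p for the observed overlap.
#' @export
pog_significance <- function(list_a, list_b, background) {
  list_a <- unique(list_a); list_b <- unique(list_b)
  if (length(list_a) == 0L || length(list_b) == 0L) stop("POG requires nonempty lists")
  if (length(setdiff(c(list_a, list_b), background)) > 0L) {
    stop("both lists must be subsets of the background")
  }
  k <- length(intersect(list_a, list_b))
  hypergeom_upper(k, length(list_a), length(list_b), length(background))
}
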