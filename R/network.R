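#' Build the bipartite gene-drug connection network
#'
#' Edges are the retained connection records (duplicate
#' (gene, drug, modality) edges are collapsed with a warning). Degrees are
#' counted per gene and per drug. When a cancer-gene list is supplied, the
#' top `top_k` genes by degree are tested for enrichment of the list by a
#' one-sided Fisher exact test against the `universe` of genes.
#'
#' @param records a [connect_cohort()] table (or compatible data frame);
#'   rows with `retained == FALSE` are dropped if the column is present.
#' @param gene_list optional character vector of cancer census genes.
#' @param universe gene universe for the enrichment test; defaults to the
#'   union of tested genes and `gene_list`.
#' @param top_k number of top-degree genes entering the enrichment test
#'   (default 15, the hub-gene panel size).
#' @return object of class `connection_network`: list with `edges`,
#'   `gene_degree`, `drug_degree`, `enrichment` (NULL without a gene list).
#' @export
build_network <- function(records, gene_list = NULL, universe = NULL,
                          top_k = 15L) {
  if ("retained" %in% names(records))
    records <- records[records$retained, , drop = FALSE]
  records <- as.data.frame(records)
  if (nrow(records)) {
    key <- paste(records$gene, records$drug, records$modality, sep = "\r")
    if (anyDuplicated(key)) {
      warning("duplicate (gene, drug, modality) records collapsed",
              call. = FALSE)
      records <- records[!duplicated(key), , drop = FALSE]
    }
  }
  gene_degree <- sort(table(factor(records$gene)), decreasing = TRUE)
  drug_degree <- sort(table(factor(records$drug)), decreasing = TRUE)

  enrichment <- NULL
  if (!is.null(gene_list) && nrow(records)) {
    if (is.null(universe))
      universe <- union(unique(records$gene), gene_list)
    top <- names(gene_degree)[seq_len(min(top_k, length(gene_degree)))]
    in_list <- sum(top %in% gene_list)
    tab <- matrix(c(in_list, length(top) - in_list,
                    sum(universe %in% gene_list) - in_list,
                    length(universe) - length(top) -
                      sum(universe %in% gene_list) + in_list),
                  nrow = 2)
    enrichment <- list(
      top_genes = top, in_list = in_list,
      p = fisher.test(tab, alternative = "greater")$p.value,
      table = tab)
  }
  structure(list(edges = records, gene_degree = gene_degree,
                 drug_degree = drug_degree, enrichment = enrichment),
            class = "connection_network")
}

#' @export
print.connection_network <- function(x, ...) {
  cat(sprintf("<connection_network> %d edges, %d genes, %d drugs\n",
              nrow(x$edges), length(x$gene_degree), length(x$drug_degree)))
  if (!is.null(x$enrichment))
    cat(sprintf("  census enrichment in top %d hubs: %d hits, p = %.3g\n",
                length(x$enrichment$top_genes), x$enrichment$in_list,
                x$enrichment$p))
  invisible(x)
}
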