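#' Hierarchical clustering of a similarity matrix
#'
#' Agglomerative clustering on row-vector Euclidean distances of the
#' similarity matrix ([similarity_to_distance()]), dendrogram cut to
#' exactly `k` clusters. Ward linkage (`"ward.D2"`, Ward on Euclidean
#' distances) is the default; average and complete linkage are available.
#' Cutting at an absolute dendrogram height is supported through `h`.
#'
#' @param similarity square symmetric matrix (or [cell_similarity()] object).
#' @param k requested number of clusters (ignored when `h` is given).
#' @param h optional absolute cut height.
#' @param linkage `"ward.D2"`, `"average"` or `"complete"`.
#' @return object of class `cluster_assignment`: list with `items`,
#'   `cluster` (named integer vector), `k`, `hclust`.
#' @export
cluster_items <- function(similarity, k = 2L, h = NULL,
                          linkage = c("ward.D2", "average", "complete")) {
  linkage <- match.arg(linkage)
  S <- if (inherits(similarity, "cell_similarity")) similarity$S
       else as.matrix(similarity)
  items <- rownames(S)
  if (is.null(items)) items <- paste0("item", seq_len(nrow(S)))
  if (is.null(h) && (k < 2L || k > nrow(S)))
    stop("k must lie in [2, number of items]", call. = FALSE)
  D <- similarity_to_distance(S)
  if (all(D[upper.tri(D)] == 0))
    warning("all pairwise distances are zero; clustering is degenerate",
            call. = FALSE)
  hc <- hclust(stats::as.dist(D), method = linkage)
  cl <- if (is.null(h)) cutree(hc, k = k) else cutree(hc, h = h)
  names(cl) <- items
  structure(list(items = items, cluster = cl,
                 k = length(unique(cl)), hclust = hc),
            class = "cluster_assignment")
}

#' Fisher-exact phenotype enrichment per cluster
#'
#' For every (cluster, phenotype) combination, a two-sided Fisher exact test
#' on the 2x2 table (in cluster vs not) x (phenotype vs not).
#'
#' @param assignment a [cluster_items()] result.
#' @param phenotype named character vector of per-item phenotype labels.
#' @return data frame: `cluster`, `phenotype`, `in_cluster`, `expected`, `p`,
#'   `enrichment` (`"over"`/`"under"`).
#' @export
cluster_phenotype_enrichment <- function(assignment, phenotype) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  items <- assignment$items
  if (!all(items %in% names(phenotype)))
    stop("every item needs a phenotype label", call. = FALSE)
  ph <- phenotype[items]
  cl <- assignment$cluster[items]
  clusters <- sort(unique(cl))
  if (length(clusters) < 2L)
    return(data.frame(cluster = integer(0), phenotype = character(0),
                      in_cluster = integer(0), expected = numeric(0),
                      p = numeric(0), enrichment = character(0)))
  rows <- list()
  n <- length(items)
  for (cc in clusters) for (pp in sort(unique(ph))) {
    a <- sum(cl == cc & ph == pp)
    b <- sum(cl == cc & ph != pp)
    c_ <- sum(cl != cc & ph == pp)
    d <- sum(cl != cc & ph != pp)
    expected <- sum(cl == cc) * sum(ph == pp) / n
    p <- fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE))$p.value
    rows[[length(rows) + 1L]] <- data.frame(
      cluster = cc, phenotype = pp, in_cluster = a, expected = expected,
      p = p, enrichment = if (a >= expected) "over" else "under",
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Per-cancer subtype-count distributions (treatment heterogeneity)
#'
#' For each histology with enough data, grows per-drug subtype trees on the
#' cells of that histology only and collects the leaf counts. A cancer is
#' flagged eligible when its mean number of assayed cells per drug exceeds
#' `min_mean_cells` (default 35).
#'
#' @param rm a [response_matrix()] with histology labels.
#' @param cancers histology labels to profile (default: all observed).
#' @param min_mean_cells eligibility threshold on mean cells per drug.
#' @param min_cells_per_drug drugs with fewer assayed cells of the histology
#'   are skipped (default 1, i.e. any assayed cell).
#' @inheritParams grow_tree
#' @return object of class `heterogeneity_profile`: named list per cancer
#'   with `counts` (integer vector of per-drug leaf counts), `eligible`,
#'   `mean_cells_per_drug`.
#' @export
heterogeneity_profile <- function(rm, cancers = NULL, min_mean_cells = 35,
                                  min_cells_per_drug = 1L, alpha = 0.05,
                                  min_node = 6L, method = "auto") {
  stopifnot(inherits(rm, "response_matrix"))
  if (is.null(rm$histology))
    stop("response matrix carries no histology labels", call. = FALSE)
  if (is.null(cancers)) cancers <- sort(unique(rm$histology))
  out <- lapply(cancers, function(cc) {
    cells <- rm$cells[rm$histology == cc]
    sub_ln <- rm$ln_ic50[cells, , drop = FALSE]
    per_drug <- colSums(!is.na(sub_ln))
    drugs <- rm$drugs[per_drug >= min_cells_per_drug]
    mean_cells <- if (length(drugs)) mean(per_drug[drugs]) else 0
    counts <- integer(0)
    if (length(cells) && length(drugs)) {
      sub <- response_matrix(sub_ln, rm$max_conc,
                             rm$histology[cells])
      counts <- vapply(drugs, function(d)
        subtype_count(grow_tree(sub, d, alpha = alpha, min_node = min_node,
                                method = method)), integer(1))
      names(counts) <- drugs
    }
    list(cancer = cc, counts = counts,
         eligible = mean_cells > min_mean_cells,
         mean_cells_per_drug = mean_cells)
  })
  names(out) <- cancers
  class(out) <- "heterogeneity_profile"
  out
}

#' Two-sample Kolmogorov-Smirnov comparison of count distributions
#'
#' @param dist_a,dist_b non-empty numeric vectors (e.g. per-drug subtype
#'   counts of two cancers).
#' @return list with `statistic` (D) and `p` (two-sided).
#' @export
ks_compare <- function(dist_a, dist_b) {
  if (!length(dist_a) || !length(dist_b))
    stop("both samples must be non-empty", call. = FALSE)
  res <- suppressWarnings(ks.test(dist_a, dist_b, alternative = "two.sided"))
  list(statistic = unname(res$statistic), p = res$p.value)
}

#' Hypergeometric enrichment of a histology in a subtype
#'
#' Upper-tail (over-representation) hypergeometric test for the count of
#' cells of one histology inside a tree leaf, given the leaf size, the
#' histology's prevalence in the assayed universe, and the universe size.
#'
#' @param leaf_cells cell IDs of the subtype (non-empty).
#' @param cancer histology label.
#' @param histology named per-cell histology labels covering the universe.
#' @param universe cell IDs of the assayed universe (default: all labeled).
#' @return list with `p`, `overlap`, `leaf_size`, `prevalence`, `universe`.
#' @export
subtype_enrichment <- function(leaf_cells, cancer, histology,
                               universe = names(histology)) {
  if (!length(leaf_cells)) stop("leaf is empty", call. = FALSE)
  stopifnot(all(leaf_cells %in% universe))
  n_univ <- length(universe)
  n_cancer <- sum(histology[universe] == cancer)
  x <- sum(histology[leaf_cells] == cancer)
  p <- phyper(x - 1, n_cancer, n_univ - n_cancer, length(leaf_cells),
              lower.tail = FALSE)
  list(p = p, overlap = x, leaf_size = length(leaf_cells),
       prevalence = n_cancer, universe = n_univ)
}
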