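#' Label cells sensitive or resistant against the screening ceiling
#'
#' A cell is *sensitive* to a drug when its IC50 is strictly smaller than the
#' maximum screened concentration, i.e. `ln_ic50 < log(max_conc)`; otherwise
#' it is *resistant* (values exactly at the ceiling are resistant). Missing
#' ln-IC50 values give `"missing"`.
#'
#' @param ln_ic50 numeric vector of natural-log IC50 values (ln uM), `NA`
#'   allowed.
#' @param max_conc positive scalar, maximum screened concentration in uM.
#' @return character vector in `{"sensitive", "resistant", "missing"}`,
#'   names preserved.
#' @export
label_sensitivity <- function(ln_ic50, max_conc) {
  stopifnot(is.numeric(max_conc), length(max_conc) == 1L, max_conc > 0)
  if (any(!is.na(ln_ic50) & !is.finite(ln_ic50)))
    stop("non-finite ln-IC50 (other than NA) is not a valid response", call. = FALSE)
  out <- ifelse(is.na(ln_ic50), "missing",
                ifelse(ln_ic50 < log(max_conc), "sensitive", "resistant"))
  names(out) <- names(ln_ic50)
  out
}

#' Sensitivity labels for one drug of a response matrix
#'
#' @param rm a [response_matrix()].
#' @param drug drug ID.
#' @param drop_missing drop cells not assayed for the drug (default `TRUE`).
#' @return named character vector of labels.
#' @export
drug_labels <- function(rm, drug, drop_missing = TRUE) {
  stopifnot(inherits(rm, "response_matrix"), drug %in% rm$drugs)
  lab <- label_sensitivity(setNames(rm$ln_ic50[, drug], rm$cells),
                           rm$max_conc[[drug]])
  if (drop_missing) lab <- lab[lab != "missing"]
  lab
}

#' Candidate left-block sizes for splitting a node
#'
#' With cells sorted by ln-IC50 ascending, admissible divisions leave at
#' least 3 cells on each side, giving left sizes `3 .. n_s - 3` — exactly
#' `n_s - 5` divisions. Nodes with fewer than 6 cells are unsplittable.
#'
#' @param n_s node size.
#' @return integer vector of left-block sizes (empty when `n_s < 6`).
#' @export
enumerate_divisions <- function(n_s) {
  n_s <- as.integer(n_s)
  if (n_s < 6L) return(integer(0))
  3L:(n_s - 3L)
}

# Deterministic assay ordering: ln-IC50 ascending, ties broken by cell ID.
order_cells <- function(values) {
  stopifnot(!is.null(names(values)))
  values[order(values, names(values))]
}

#' Best Mann-Whitney division of a node
#'
#' Sorts the cells by ln-IC50 ascending (ties broken by cell ID), evaluates
#' every admissible division ([enumerate_divisions()]) with a two-sided
#' Mann-Whitney test between the left (more sensitive) and right blocks, and
#' returns the division with the smallest p-value, or `NULL` when that
#' minimum is not below `alpha`. Ties on the minimal p are broken toward the
#' most balanced division, then the smaller left size.
#'
#' @param values named numeric vector of ln-IC50, one entry per cell, no
#'   missing values; at least 6 cells.
#' @param alpha split acceptance threshold on the raw p-value (default 0.05).
#' @param method Mann-Whitney route, see [mann_whitney()].
#' @return `NULL` (no admissible significant division) or a list with
#'   `left`, `right` (cell ID vectors), `p`, and `left_size`.
#' @export
best_split <- function(values, alpha = 0.05,
                       method = c("auto", "exact", "asymptotic")) {
  method <- match.arg(method)
  if (anyNA(values)) stop("missing response for some cells", call. = FALSE)
  n <- length(values)
  sizes <- enumerate_divisions(n)
  if (!length(sizes)) return(NULL)
  sorted <- order_cells(values)
  ps <- vapply(sizes, function(k) {
    mann_whitney(sorted[seq_len(k)], sorted[(k + 1):n], method = method)$p
  }, numeric(1))
  pmin <- min(ps)
  if (pmin >= alpha) return(NULL)
  cand <- sizes[ps == pmin]
  cand <- cand[order(abs(n - 2 * cand), cand)][1]
  list(left = names(sorted)[seq_len(cand)],
       right = names(sorted)[(cand + 1):n],
       p = pmin, left_size = cand)
}

#' Classify a leaf by its cells' sensitivity labels
#'
#' @param cells cell IDs in the leaf.
#' @param labels named character vector of sensitivity labels.
#' @return `"sensitive"`, `"resistant"`, or `"mixed"`.
#' @export
classify_leaf <- function(cells, labels) {
  lab <- labels[cells]
  if (anyNA(lab) || any(lab == "missing"))
    stop("leaf contains unlabeled cells", call. = FALSE)
  u <- unique(lab)
  if (length(u) == 1L) u else "mixed"
}

#' Grow the pharmacological subtype tree for one drug
#'
#' Cells assayed for the drug are recursively split into two blocks by
#' [best_split()]. A node becomes a leaf when it holds fewer than `min_node`
#' cells, when all its cells share one sensitivity label, or when no division
#' reaches `p < alpha`. Leaves are ordered C1..Ck by in-order traversal (left
#' subtree first), so C1 is the most sensitive subtype.
#'
#' @param rm a [response_matrix()].
#' @param drug drug ID present in `rm`.
#' @param alpha split acceptance threshold (default 0.05).
#' @param min_node minimum splittable node size (default 6).
#' @param method Mann-Whitney route, see [mann_whitney()].
#' @return object of class `subtype_tree`: list with `drug`, `root` (nested
#'   node records), `leaves` (list of leaf records with `cells`,
#'   `response_class`), `cells` (assayed cells), `alpha`, `min_node`.
#' @export
grow_tree <- function(rm, drug, alpha = 0.05, min_node = 6L,
                      method = c("auto", "exact", "asymptotic")) {
  method <- match.arg(method)
  stopifnot(inherits(rm, "response_matrix"))
  if (!drug %in% rm$drugs) stop("unknown drug: ", drug, call. = FALSE)
  values <- setNames(rm$ln_ic50[, drug], rm$cells)
  values <- values[!is.na(values)]
  if (!length(values))
    stop("no assayed cells for drug ", drug, call. = FALSE)
  labels <- label_sensitivity(values, rm$max_conc[[drug]])

  build <- function(vals) {
    cells <- names(order_cells(vals))
    node <- list(cells = cells, n = length(cells))
    homogeneous <- length(unique(labels[cells])) == 1L
    split <- NULL
    if (node$n >= min_node && !homogeneous)
      split <- best_split(vals, alpha = alpha, method = method)
    if (is.null(split)) {
      node$response_class <- classify_leaf(cells, labels)
      return(node)
    }
    node$split_p <- split$p
    node$left <- build(vals[split$left])
    node$right <- build(vals[split$right])
    node
  }
  root <- build(values)
  tree <- structure(
    list(drug = drug, root = root, cells = root$cells,
         alpha = alpha, min_node = as.integer(min_node)),
    class = "subtype_tree")
  tree$leaves <- tree_leaves(tree)
  tree
}

#' Leaves of a subtype tree in C1..Ck order
#'
#' @param tree a `subtype_tree`.
#' @return list of leaf records (`cells`, `n`, `response_class`), most
#'   sensitive first.
#' @export
tree_leaves <- function(tree) {
  stopifnot(inherits(tree, "subtype_tree"))
  acc <- list()
  walk <- function(node) {
    if (is.null(node$left)) {
      acc[[length(acc) + 1L]] <<- node[c("cells", "n", "response_class")]
    } else {
      walk(node$left); walk(node$right)
    }
  }
  walk(tree$root)
  acc
}

#' Number of pharmacological subtypes (leaves) of a tree
#' @param tree a `subtype_tree`.
#' @return integer leaf count `k`.
#' @export
subtype_count <- function(tree) {
  length(tree_leaves(tree))
}

#' Leaf membership as a named partition vector
#'
#' @param tree a `subtype_tree`.
#' @return named integer vector: for each assayed cell, the index (1 = most
#'   sensitive) of its leaf.
#' @export
leaf_partition <- function(tree) {
  leaves <- tree_leaves(tree)
  out <- integer(0)
  for (i in seq_along(leaves))
    out[leaves[[i]]$cells] <- i
  out[tree$cells]
}

#' @export
print.subtype_tree <- function(x, ...) {
  leaves <- tree_leaves(x)
  cat(sprintf("<subtype_tree> drug '%s': %d cells, %d subtype(s)\n",
              x$drug, length(x$cells), length(leaves)))
  for (i in seq_along(leaves))
    cat(sprintf("  C%d: n=%d [%s]\n", i, leaves[[i]]$n,
                leaves[[i]]$response_class))
  invisible(x)
}

#' Grow trees for every drug of a cohort
#'
#' @param rm a [response_matrix()].
#' @param drugs drug IDs (default: all drugs with at least one assayed cell).
#' @inheritParams grow_tree
#' @return named list of `subtype_tree` objects.
#' @export
grow_trees <- function(rm, drugs = NULL, alpha = 0.05, min_node = 6L,
                       method = "auto") {
  if (is.null(drugs))
    drugs <- rm$drugs[colSums(!is.na(rm$ln_ic50)) > 0]
  out <- lapply(drugs, function(d)
    grow_tree(rm, d, alpha = alpha, min_node = min_node, method = method))
  names(out) <- drugs
  out
}
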