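#' Pair-concordance matrix for one drug
#'
#' For every pair of cells assayed for the drug, scores 1 when the two cells
#' share a subtype (tree leaf) and both are sensitive, -1 when they share a
#' leaf and both are resistant, and 0 otherwise (different leaves, discordant
#' labels, or the diagonal).
#'
#' @param tree a `subtype_tree`.
#' @param labels named sensitivity labels covering all assayed cells of the
#'   tree (see [drug_labels()]).
#' @return object of class `pair_concordance`: list with `drug`, `cells`, and
#'   the symmetric integer matrix `D`.
#' @export
pair_concordance <- function(tree, labels) {
  stopifnot(inherits(tree, "subtype_tree"))
  cells <- tree$cells
  missing_lab <- setdiff(cells, names(labels))
  if (length(missing_lab))
    stop("cells without sensitivity label: ",
         paste(head(missing_lab, 5), collapse = ", "), call. = FALSE)
  D <- matrix(0L, length(cells), length(cells),
              dimnames = list(cells, cells))
  for (leaf in tree_leaves(tree)) {
    s <- leaf$cells[labels[leaf$cells] == "sensitive"]
    r <- leaf$cells[labels[leaf$cells] == "resistant"]
    if (length(s) > 1) D[s, s] <- 1L
    if (length(r) > 1) D[r, r] <- -1L
  }
  diag(D) <- 0L
  structure(list(drug = tree$drug, cells = cells, D = D),
            class = "pair_concordance")
}

#' Cell-cell similarity across drugs
#'
#' For each cell pair, Cellsim = (sum over co-tested drugs of |D|) / q, where
#' q counts the drugs in which both cells were assayed. Pairs never co-tested
#' are undefined (`NA` similarity, q = 0). The diagonal follows the formula
#' (D is 0 on the diagonal, so self-similarity is 0).
#'
#' @param concordances list of [pair_concordance()] objects.
#' @return object of class `cell_similarity`: list with `cells`, symmetric
#'   matrix `S` in `[0,1]` (`NA` where undefined), and integer matrix `q`.
#' @export
cell_similarity <- function(concordances) {
  stopifnot(length(concordances) >= 1L)
  cells <- sort(unique(unlist(lapply(concordances, `[[`, "cells"))))
  m <- length(cells)
  num <- matrix(0, m, m, dimnames = list(cells, cells))
  q <- matrix(0L, m, m, dimnames = list(cells, cells))
  for (pc in concordances) {
    idx <- match(pc$cells, cells)
    num[idx, idx] <- num[idx, idx] + abs(pc$D)
    q[idx, idx] <- q[idx, idx] + 1L
  }
  S <- ifelse(q > 0, num / pmax(q, 1L), NA_real_)
  if (all(q[upper.tri(q)] == 0))
    warning("no cell pair shares any drug; all similarities undefined",
            call. = FALSE)
  structure(list(cells = cells, S = S, q = q), class = "cell_similarity")
}

#' Drug-drug similarity from pair-concordance matrices
#'
#' Tanimoto-style ratio over the shared assayed cells of two drugs:
#' `sum(Da*Db) / (sum(Da^2) + sum(Db^2) - sum(Da*Db))`, all sums over
#' off-diagonal pairs of the shared cell set. Equals 1 when the restricted
#' matrices are identical and nonzero; can be negative when pairs are
#' concordant-sensitive under one drug and concordant-resistant under the
#' other. A zero denominator yields value 0 with `undefined = TRUE`.
#'
#' @param pa,pb [pair_concordance()] objects for the two drugs.
#' @return object of class `drug_similarity`: list with `drug_a`, `drug_b`,
#'   `value`, `m` (shared cells), `undefined`.
#' @export
drug_similarity <- function(pa, pb) {
  stopifnot(inherits(pa, "pair_concordance"), inherits(pb, "pair_concordance"))
  shared <- intersect(pa$cells, pb$cells)
  if (length(shared) < 2L)
    stop("fewer than 2 cells assayed for both drugs; score undefined",
         call. = FALSE)
  Da <- pa$D[shared, shared]
  Db <- pb$D[shared, shared]
  ab <- sum(Da * Db); aa <- sum(Da * Da); bb <- sum(Db * Db)
  denom <- aa + bb - ab
  undefined <- denom == 0
  structure(list(drug_a = pa$drug, drug_b = pb$drug,
                 value = if (undefined) 0 else ab / denom,
                 m = length(shared), undefined = undefined),
            class = "drug_similarity")
}

#' All pairwise drug similarities as a long table
#'
#' @param concordances named list of [pair_concordance()] objects.
#' @param min_shared drop pairs with fewer shared cells (default 2).
#' @return data frame with columns `drug_a`, `drug_b`, `value`, `m`,
#'   `undefined`.
#' @export
drug_similarity_table <- function(concordances, min_shared = 2L) {
  drugs <- vapply(concordances, `[[`, "", "drug")
  rows <- list()
  for (i in seq_along(concordances)) for (j in seq_along(concordances)) {
    if (i >= j) next
    shared <- intersect(concordances[[i]]$cells, concordances[[j]]$cells)
    if (length(shared) < min_shared) next
    ds <- drug_similarity(concordances[[i]], concordances[[j]])
    rows[[length(rows) + 1L]] <- data.frame(
      drug_a = ds$drug_a, drug_b = ds$drug_b, value = ds$value,
      m = ds$m, undefined = ds$undefined, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(drug_a = character(0), drug_b = character(0),
                      value = numeric(0), m = integer(0),
                      undefined = logical(0)))
  do.call(rbind, rows)
}

#' Row-vector Euclidean distance from a cell similarity matrix
#'
#' Undefined similarities are imputed to 0, then the distance between two
#' cells is the Euclidean distance between their similarity-matrix rows.
#'
#' @param cs a [cell_similarity()] object or a plain numeric square matrix.
#' @return symmetric distance matrix with zero diagonal.
#' @export
similarity_to_distance <- function(cs) {
  S <- if (inherits(cs, "cell_similarity")) cs$S else as.matrix(cs)
  S[is.na(S)] <- 0
  as.matrix(dist(S, method = "euclidean"))
}
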