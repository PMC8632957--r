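#' Benjamini-Hochberg step-up adjustment
#'
#' Classic step-up FDR adjustment: sort p ascending, multiply by n/rank,
#' enforce monotonicity from the largest rank down, cap at 1.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted values in the original order.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(n / (n:1) * p[o]))[ro]
  adj
}

# Pools of analyzed cells for one drug: cells in non-mixed leaves, split by
# leaf response class. NULL when the connection analysis is not applicable
# (< 2 non-mixed leaves, or one of the classes absent).
connection_pools <- function(tree, labels) {
  leaves <- tree_leaves(tree)
  keep <- Filter(function(l) l$response_class != "mixed", leaves)
  if (length(keep) < 2L) return(NULL)
  classes <- vapply(keep, `[[`, "", "response_class")
  if (length(unique(classes)) < 2L) return(NULL)
  list(
    leaves = keep,
    leaf_class = classes,
    sensitive = unlist(lapply(keep[classes == "sensitive"], `[[`, "cells")),
    resistant = unlist(lapply(keep[classes == "resistant"], `[[`, "cells"))
  )
}

#' Chi-squared association between a genomic alteration and subtypes
#'
#' Builds the 2 x K contingency table of altered/unaltered status against
#' membership in the K non-mixed leaves of the drug's tree (mixed leaves are
#' excluded) and applies the chi-squared test without continuity correction.
#' Direction is `"sensitive"` when the alteration frequency among cells of
#' sensitive-class leaves exceeds that among resistant-class leaves,
#' `"resistant"` otherwise. With `table = "pooled"` a 2 x 2 table
#' (altered x sensitive/resistant pool) is used instead.
#'
#' @param status named 0/1 vector of alteration status per cell.
#' @param tree a `subtype_tree`.
#' @param labels sensitivity labels for the tree's cells.
#' @param min_altered minimum altered cells among analyzed cells (default 3).
#' @param table `"per_leaf"` (default) or `"pooled"`.
#' @return `NULL` when not testable, else list with `p`, `direction`,
#'   `freq_sensitive`, `freq_resistant`, `n`.
#' @export
genomic_connection_test <- function(status, tree, labels, min_altered = 3L,
                                    table = c("per_leaf", "pooled")) {
  table <- match.arg(table)
  pools <- connection_pools(tree, labels)
  if (is.null(pools)) return(NULL)
  analyzed <- c(pools$sensitive, pools$resistant)
  analyzed <- analyzed[analyzed %in% names(status)]
  if (length(analyzed) < length(c(pools$sensitive, pools$resistant)))
    return(NULL)                       # alteration calls missing for some cells
  st <- status[analyzed]
  if (sum(st) < min_altered || sum(st) == length(st)) return(NULL)

  if (table == "per_leaf") {
    tab <- vapply(pools$leaves, function(l) {
      c(altered = sum(status[l$cells]), unaltered = sum(1 - status[l$cells]))
    }, numeric(2))
  } else {
    tab <- cbind(
      sensitive = c(sum(status[pools$sensitive]),
                    length(pools$sensitive) - sum(status[pools$sensitive])),
      resistant = c(sum(status[pools$resistant]),
                    length(pools$resistant) - sum(status[pools$resistant])))
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(NULL)
  p <- suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
  if (!is.finite(p)) return(NULL)

  fs <- mean(status[pools$sensitive])
  fr <- mean(status[pools$resistant])
  list(p = p,
       direction = if (fs > fr) "sensitive" else "resistant",
       freq_sensitive = fs, freq_resistant = fr, n = length(analyzed))
}

#' t-test association between gene expression and subtypes
#'
#' Two-sided equal-variance two-sample t-test of expression in
#' sensitive-class-leaf cells versus resistant-class-leaf cells (mixed leaves
#' excluded; each pool needs at least `min_pool` cells). Direction is
#' `"sensitive"` when mean expression is higher in the sensitive pool. The
#' Pearson correlation (`pcc`) between ln-IC50 and expression is computed
#' over the sensitive-pool cells; the confidence filter applied downstream
#' keeps records with `|pcc| > pcc_threshold` and sign consistent with the
#' direction (sensitive connections: expression rises as ln-IC50 falls, so
#' pcc < 0).
#'
#' @param expr named numeric vector of expression per cell.
#' @param tree a `subtype_tree`.
#' @param labels sensitivity labels for the tree's cells.
#' @param ln_ic50 named numeric vector of ln-IC50 for the drug.
#' @param min_pool minimum cells per pool (default 3).
#' @return `NULL` when not testable, else list with `p`, `direction`, `pcc`,
#'   `mean_sensitive`, `mean_resistant`, `n`.
#' @export
expression_connection_test <- function(expr, tree, labels, ln_ic50,
                                       min_pool = 3L) {
  pools <- connection_pools(tree, labels)
  if (is.null(pools)) return(NULL)
  s <- pools$sensitive[pools$sensitive %in% names(expr)]
  r <- pools$resistant[pools$resistant %in% names(expr)]
  if (length(s) < min_pool || length(r) < min_pool) return(NULL)
  es <- expr[s]; er <- expr[r]
  if (sd(es) == 0 || sd(er) == 0) return(NULL)
  p <- t.test(es, er, var.equal = TRUE)$p.value
  pcc <- if (sd(ln_ic50[s]) == 0) NA_real_ else cor(ln_ic50[s], es)
  list(p = p,
       direction = if (mean(es) > mean(er)) "sensitive" else "resistant",
       pcc = pcc, mean_sensitive = mean(es), mean_resistant = mean(er),
       n = length(s) + length(r))
}

#' Gene-drug connection table for a cohort
#'
#' For every drug tree, tests every alteration row (chi-squared, per-leaf
#' table) and every expression row (pooled t-test) against the drug's
#' pharmacological subtypes. p-values are BH-adjusted per drug within each
#' modality (`bh_scope = "per_drug"`, the default) or across all drugs
#' (`"global"`). A record is `retained` when `q_fdr < fdr` and, for the
#' expression modality, `|pcc| > pcc_threshold` with sign consistent with
#' the direction label.
#'
#' @param rm a [response_matrix()].
#' @param trees named list of `subtype_tree` objects.
#' @param alterations 0/1 gene x cell matrix, or `NULL` to skip.
#' @param expression numeric gene x cell matrix, or `NULL` to skip.
#' @param fdr FDR threshold on the adjusted p (default 0.1).
#' @param pcc_threshold PCC confidence threshold (default 0.3).
#' @param min_altered,min_pool guards, see the per-test functions.
#' @param bh_scope `"per_drug"` or `"global"` BH family.
#' @param table contingency-table orientation for the genomic test.
#' @return data frame of class `connection_table`: columns `gene`, `drug`,
#'   `modality`, `p`, `q_fdr`, `direction`, `pcc`, `retained`.
#' @export
connect_cohort <- function(rm, trees, alterations = NULL, expression = NULL,
                           fdr = 0.1, pcc_threshold = 0.3,
                           min_altered = 3L, min_pool = 3L,
                           bh_scope = c("per_drug", "global"),
                           table = c("per_leaf", "pooled")) {
  bh_scope <- match.arg(bh_scope)
  table <- match.arg(table)
  stopifnot(inherits(rm, "response_matrix"))
  rows <- list()
  for (tr in trees) {
    drug <- tr$drug
    labels <- drug_labels(rm, drug)
    ln <- setNames(rm$ln_ic50[, drug], rm$cells)
    ln <- ln[!is.na(ln)]
    if (!is.null(alterations)) {
      for (g in rownames(alterations)) {
        res <- genomic_connection_test(alterations[g, ], tr, labels,
                                       min_altered = min_altered,
                                       table = table)
        if (is.null(res)) next
        rows[[length(rows) + 1L]] <- data.frame(
          gene = g, drug = drug, modality = "genomic", p = res$p,
          direction = res$direction, pcc = NA_real_,
          stringsAsFactors = FALSE)
      }
    }
    if (!is.null(expression)) {
      for (g in rownames(expression)) {
        res <- expression_connection_test(expression[g, ], tr, labels, ln,
                                          min_pool = min_pool)
        if (is.null(res)) next
        rows[[length(rows) + 1L]] <- data.frame(
          gene = g, drug = drug, modality = "expression", p = res$p,
          direction = res$direction, pcc = res$pcc,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    out <- data.frame(gene = character(0), drug = character(0),
                      modality = character(0), p = numeric(0),
                      q_fdr = numeric(0), direction = character(0),
                      pcc = numeric(0), retained = logical(0))
    class(out) <- c("connection_table", class(out))
    return(out)
  }
  out <- do.call(rbind, rows)
  out$q_fdr <- NA_real_
  fams <- if (bh_scope == "per_drug") interaction(out$drug, out$modality,
                                                 drop = TRUE)
          else factor(out$modality)
  for (f in levels(fams)) {
    i <- fams == f
    out$q_fdr[i] <- bh_adjust(out$p[i])
  }
  pcc_ok <- ifelse(out$modality == "expression",
                   !is.na(out$pcc) & abs(out$pcc) > pcc_threshold &
                     ((out$direction == "sensitive" & out$pcc < 0) |
                      (out$direction == "resistant" & out$pcc > 0)),
                   TRUE)
  out$retained <- out$q_fdr < fdr & pcc_ok
  out <- out[, c("gene", "drug", "modality", "p", "q_fdr", "direction",
                 "pcc", "retained")]
  rownames(out) <- NULL
  class(out) <- c("connection_table", class(out))
  out
}
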