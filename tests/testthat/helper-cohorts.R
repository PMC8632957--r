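# Shared fixtures and independent oracles.

# Response matrix for a single drug from a named ln-IC50 vector.
one_drug_rm <- function(values, max_conc = 1, drug = "D1", histology = NULL) {
  m <- matrix(values, ncol = 1, dimnames = list(names(values), drug))
  response_matrix(m, setNames(max_conc, drug), histology)
}

# A cohort with planted blocks at given ln-IC50 means; cells named in mean
# order so the planted partition is contiguous in rank.
block_cohort <- function(sizes, means, sd = 0.5, max_conc = 1, drug = "D1") {
  stopifnot(length(sizes) == length(means))
  v <- unlist(mapply(function(n, mu) rnorm(n, mu, sd), sizes, means,
                     SIMPLIFY = FALSE))
  names(v) <- sprintf("CL%03d", seq_along(v))
  list(rm = one_drug_rm(v, max_conc, drug),
       truth = rep(seq_along(sizes), sizes))
}

# Independent exact two-sided Mann-Whitney p for tie-free data, via the
# closed-form Wilcoxon distribution in base R (pwilcox), not the package DP.
oracle_mw_exact_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  stopifnot(!anyDuplicated(c(x, y)))   # pwilcox assumes no ties
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  min(1, 2 * min(stats::pwilcox(u, n1, n2),
                 1 - stats::pwilcox(u - 1, n1, n2)))
}

# Exhaustive division scan with the oracle p and the package's documented
# tie-break (most balanced, then smaller left size).
oracle_best_left <- function(values) {
  n <- length(values)
  if (n < 6) return(NULL)
  sorted <- values[order(values, names(values))]
  sizes <- 3:(n - 3)
  ps <- vapply(sizes, function(k)
    oracle_mw_exact_p(sorted[1:k], sorted[(k + 1):n]), numeric(1))
  if (min(ps) >= 0.05) return(NULL)
  cand <- sizes[ps == min(ps)]
  cand[order(abs(n - 2 * cand), cand)][1]
}

# Hand-built subtype tree from explicit leaf cell sets (left-deep nesting),
# for similarity/connection tests that need a fixed topology.
make_tree <- function(leaves, classes, drug = "D1", split_p = 1e-6) {
  mk_leaf <- function(cells, cls)
    list(cells = cells, n = length(cells), response_class = cls)
  node <- mk_leaf(leaves[[length(leaves)]], classes[[length(leaves)]])
  for (i in rev(seq_len(length(leaves) - 1L))) {
    left <- mk_leaf(leaves[[i]], classes[[i]])
    node <- list(cells = c(left$cells, node$cells),
                 n = left$n + node$n, split_p = split_p,
                 left = left, right = node)
  }
  tree <- structure(list(drug = drug, root = node, cells = node$cells,
                         alpha = 0.05, min_node = 6L),
                    class = "subtype_tree")
  tree$leaves <- tree_leaves(tree)
  tree
}

# Pair-concordance object straight from a D matrix.
make_pcm <- function(D, drug = "D1") {
  structure(list(drug = drug, cells = rownames(D), D = D),
            class = "pair_concordance")
}

# Two-sided Fisher p by exhaustive hypergeometric enumeration.
oracle_fisher2x2 <- function(a, b, c_, d) {
  m <- a + b; n <- c_ + d; k <- a + c_
  xs <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(xs, m, n, k)
  sum(probs[probs <= stats::dhyper(a, m, n, k) * (1 + 1e-7)])
}
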