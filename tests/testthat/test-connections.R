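# Fixed 4-leaf tree (two sensitive-class, two resistant-class leaves) with
# 10 cells per leaf, used across the connection tests.
conn_fixture <- function() {
  cells <- sprintf("c%02d", 1:40)
  leaves <- split(cells, rep(1:4, each = 10))
  tr <- make_tree(unname(leaves),
                  c("sensitive", "sensitive", "resistant", "resistant"))
  labs <- setNames(rep(c("sensitive", "resistant"), each = 20), cells)
  ln <- setNames(c(seq(-6, -1, length.out = 20),
                   seq(0.5, 4, length.out = 20)), cells)
  list(cells = cells, leaves = leaves, tree = tr, labels = labs, ln = ln)
}

test_that("genomic connection test matches a textbook chi-squared oracle", {
  fx <- conn_fixture()
  # alteration frequencies 0.5 / 0.3 / 0.1 / 0.0 across C1..C4
  status <- setNames(integer(40), fx$cells)
  status[fx$leaves[[1]][1:5]] <- 1L
  status[fx$leaves[[2]][1:3]] <- 1L
  status[fx$leaves[[3]][1]] <- 1L
  res <- genomic_connection_test(status, fx$tree, fx$labels)
  expect_equal(res$direction, "sensitive")
  expect_equal(res$freq_sensitive, 0.4)
  expect_equal(res$freq_resistant, 0.05)
  # independent oracle: Pearson statistic from expected counts by hand
  tab <- rbind(altered = c(5, 3, 1, 0), unaltered = c(5, 7, 9, 10))
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - E)^2 / E)
  expect_equal(res$p, pchisq(stat, df = 3, lower.tail = FALSE))

  # identical frequency in every leaf: statistic 0, p = 1
  flat <- setNames(rep(c(1L, 0L), 20), fx$cells)
  flat[] <- 0L
  for (l in fx$leaves) flat[l[1:3]] <- 1L
  expect_equal(genomic_connection_test(flat, fx$tree, fx$labels)$p, 1)
})

test_that("genomic test guards: sparse genes, degenerate tables, pools", {
  fx <- conn_fixture()
  sparse <- setNames(integer(40), fx$cells)
  sparse[fx$cells[1:2]] <- 1L        # altered in only 2 analyzed cells
  expect_null(genomic_connection_test(sparse, fx$tree, fx$labels))
  expect_null(genomic_connection_test(setNames(rep(1L, 40), fx$cells),
                                      fx$tree, fx$labels))  # zero variance
  # mixed leaves excluded: a tree whose only two leaves are mixed+sensitive
  tr2 <- make_tree(list(fx$cells[1:10], fx$cells[11:20]),
                   c("mixed", "sensitive"))
  status <- setNames(rbinom(40, 1, 0.5), fx$cells)
  expect_null(genomic_connection_test(status, tr2, fx$labels))
  # direction is antisymmetric under swapping pool classes
  st <- setNames(integer(40), fx$cells)
  st[fx$cells[1:12]] <- 1L
  a <- genomic_connection_test(st, fx$tree, fx$labels)
  tr_swapped <- make_tree(unname(fx$leaves),
                          c("resistant", "resistant", "sensitive", "sensitive"))
  labs_swapped <- setNames(rep(c("resistant", "sensitive"), each = 20),
                           fx$cells)
  b <- genomic_connection_test(st, tr_swapped, labs_swapped)
  expect_equal(a$direction, "sensitive")
  expect_equal(b$direction, "resistant")
  expect_equal(a$p, b$p)
})

test_that("expression connection test: direction, PCC and guards", {
  fx <- conn_fixture()
  set.seed(8)
  # expression tracks sensitivity: high where ln-IC50 low
  expr <- -fx$ln + rnorm(40, sd = 0.01)
  res <- expression_connection_test(expr, fx$tree, fx$labels, fx$ln)
  expect_equal(res$direction, "sensitive")
  expect_lt(res$pcc, -0.95)
  expect_lt(res$p, 1e-6)
  # oracle: equal-variance t-test on the two pools
  s <- fx$cells[1:20]; r <- fx$cells[21:40]
  expect_equal(res$p, t.test(expr[s], expr[r], var.equal = TRUE)$p.value)
  expect_equal(res$pcc, cor(fx$ln[s], expr[s]))

  # constant expression is not testable
  expect_null(expression_connection_test(setNames(rep(1, 40), fx$cells),
                                         fx$tree, fx$labels, fx$ln))
  # pools below the minimum size are not testable
  tiny <- make_tree(list(fx$cells[1:2], fx$cells[21:40]),
                    c("sensitive", "resistant"))
  labs <- fx$labels[c(fx$cells[1:2], fx$cells[21:40])]
  expect_null(expression_connection_test(expr, tiny, fx$labels, fx$ln))
})

test_that("bh_adjust reproduces the step-up adjustment", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(1, 1)), c(1, 1))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, NA)))
  set.seed(5)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))
    expect_equal(bh_adjust(p), p.adjust(p, "BH"))   # independent oracle
  }
  # order invariance after matching back
  p <- runif(30)
  o <- sample(30)
  expect_equal(bh_adjust(p[o])[order(o)], bh_adjust(p))
})

test_that("connect_cohort assembles records, BH families and the PCC filter", {
  set.seed(14)
  ge <- data.frame(gene = "BRAFlike", drug = "DRUG001",
                   stringsAsFactors = FALSE)
  ge$freqs <- list(c(0.65, 0.05))
  cfg <- synthetic_config(
    n_cells = 60, n_drugs = 1, group_means = c(-4, 4), group_sd = 0.5,
    genomic_effects = ge,
    expression_effects = data.frame(gene = "EXPR1", drug = "DRUG001",
                                    slope = -1, noise_sd = 0.3,
                                    stringsAsFactors = FALSE),
    n_null_genes = 20, seed = 14)
  sim <- generate_cohort(cfg)
  trees <- grow_trees(sim$responses)
  conn <- connect_cohort(sim$responses, trees, sim$alterations,
                         sim$expression)
  expect_s3_class(conn, "connection_table")
  braf <- conn[conn$gene == "BRAFlike", ]
  expect_equal(nrow(braf), 1L)
  expect_true(braf$retained)
  expect_equal(braf$direction, "sensitive")
  expect_lt(braf$q_fdr, 0.1)
  ex <- conn[conn$gene == "EXPR1", ]
  expect_true(ex$retained)
  expect_equal(ex$direction, "sensitive")
  expect_lt(ex$pcc, -0.3)

  # a gene whose expression separates the pools but with |PCC| ~ 0 inside
  # the sensitive pool is filtered out
  rmx <- sim$responses
  lab <- drug_labels(rmx, "DRUG001")
  flat <- setNames(ifelse(lab[rmx$cells] == "sensitive", 5, 0), rmx$cells)
  # noise orthogonal to ln-IC50 inside the sensitive pool actually used by
  # the test, so its within-pool PCC is exactly 0 while the pools stay
  # cleanly separated
  pools <- pharmtree:::connection_pools(trees[[1]], lab)
  e <- rnorm(length(pools$sensitive), sd = 0.2)
  flat[pools$sensitive] <- flat[pools$sensitive] +
    residuals(lm(e ~ rmx$ln_ic50[pools$sensitive, "DRUG001"]))
  flat[pools$resistant] <- flat[pools$resistant] +
    rnorm(length(pools$resistant), sd = 0.2)
  expr2 <- rbind(sim$expression, FLAT = flat)
  conn2 <- connect_cohort(rmx, trees, NULL, expr2)
  flat_rec <- conn2[conn2$gene == "FLAT", ]
  expect_lt(flat_rec$q_fdr, 0.1)
  expect_false(flat_rec$retained)
})

test_that("null cohorts keep the discovery fraction near the nominal FDR", {
  set.seed(77)
  fracs <- vapply(1:25, function(s) {
    cfg <- synthetic_config(n_cells = 50, group_means = c(-2, 2),
                            group_sd = 1, n_null_genes = 40, seed = 7000 + s)
    sim <- generate_cohort(cfg)
    trees <- grow_trees(sim$responses)
    conn <- connect_cohort(sim$responses, trees, sim$alterations, NULL)
    if (!nrow(conn)) return(0)
    sum(conn$q_fdr < 0.1) / 40
  }, numeric(1))
  expect_lte(mean(fracs), 0.15)
})

test_that("build_network degrees, dedup and census enrichment", {
  rec <- data.frame(
    gene = c("gA", "gA", "gB"), drug = c("d1", "d2", "d1"),
    modality = "genomic", p = 0.001, q_fdr = 0.01,
    direction = "sensitive", pcc = NA_real_, retained = TRUE,
    stringsAsFactors = FALSE)
  net <- build_network(rec)
  expect_equal(as.vector(net$gene_degree[c("gA", "gB")]), c(2L, 1L))
  expect_equal(as.vector(net$drug_degree["d1"]), 2L)
  expect_warning(build_network(rbind(rec, rec[1, ])), "duplicate")

  # enrichment: 3 of top 10 in a 700-gene census over a 21972-gene universe
  rec2 <- data.frame(
    gene = sprintf("g%02d", 1:10), drug = "d1", modality = "genomic",
    p = 0.001, q_fdr = 0.01, direction = "sensitive", pcc = NA_real_,
    retained = TRUE, stringsAsFactors = FALSE)
  census <- c("g01", "g02", "g03", sprintf("CG%03d", 1:697))
  universe <- c(sprintf("g%02d", 1:10), census[4:700],
                sprintf("BG%05d", seq_len(21972 - 707)))
  net2 <- build_network(rec2, gene_list = census, universe = universe,
                        top_k = 10)
  expect_equal(net2$enrichment$in_list, 3L)
  # exact hypergeometric oracle: P(X >= 3) drawing 10 from the universe
  p_oracle <- phyper(2, 700, length(universe) - 700, 10, lower.tail = FALSE)
  expect_equal(net2$enrichment$p, p_oracle, tolerance = 1e-10)

  empty <- build_network(rec[0, ])
  expect_equal(nrow(empty$edges), 0L)
})
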