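test_that("sensitivity labeling uses the strict ceiling rule", {
  expect_equal(unname(label_sensitivity(log(0.5), 1)), "sensitive")
  expect_equal(unname(label_sensitivity(log(25), 20)), "resistant")
  expect_equal(unname(label_sensitivity(log(20), 20)), "resistant") # boundary
  expect_equal(unname(label_sensitivity(c(a = NA, b = -1), 1)),
               c("missing", "sensitive"))
  expect_error(label_sensitivity(Inf, 1), "non-finite")
  expect_error(label_sensitivity(0, -1))
})

test_that("enumerate_divisions yields n_s - 5 left sizes, each side >= 3", {
  expect_equal(enumerate_divisions(11), 3:8)
  expect_length(enumerate_divisions(11), 6)
  expect_equal(enumerate_divisions(6), 3L)
  expect_equal(enumerate_divisions(5), integer(0))
  for (n in 6:25) {
    d <- enumerate_divisions(n)
    expect_length(d, n - 5)
    expect_true(all(d >= 3 & n - d >= 3))
  }
})

test_that("best_split picks the minimum-p division (frozen small cases)", {
  # two clean blocks of 4: balanced 4|4 has exact p = 2/C(8,4) = 1/35
  v <- setNames(c(-5, -5, -5, -5, 5, 5, 5, 5), letters[1:8])
  bs <- best_split(v, method = "exact")
  expect_equal(bs$left_size, 4L)
  expect_equal(bs$p, 2 / choose(8, 4))
  # brute-force oracle over the 3 admissible divisions
  sorted <- v[order(v, names(v))]
  brute <- vapply(3:5, function(k) {
    r <- rank(sorted); w <- sum(r[1:k])
    ws <- combn(8, k, function(i) sum(r[i]))
    min(1, 2 * min(mean(ws <= w + 1e-9), mean(ws >= w - 1e-9)))
  }, numeric(1))
  expect_equal(bs$p, min(brute))
  expect_equal((3:5)[which.min(brute)], bs$left_size)

  # exchangeable ties: every division p = 1, no split
  expect_null(best_split(setNames(rep(2, 10), letters[1:10])))

  # planted 6|6 with tiny spread recovers the generating partition
  set.seed(99)
  v2 <- setNames(c(rnorm(6, -4, 0.1), rnorm(6, 4, 0.1)), letters[1:12])
  bs2 <- best_split(v2, method = "exact")
  expect_equal(bs2$left_size, 6L)
  expect_setequal(bs2$left, letters[1:6])
  ps <- vapply(3:9, function(k) {
    s <- v2[order(v2, names(v2))]
    oracle_mw_exact_p(s[1:k], s[(k + 1):12])
  }, numeric(1))
  expect_equal((3:9)[which.min(ps)], 6L)
})

test_that("best_split agrees with an exhaustive exact-p oracle scan", {
  set.seed(21)
  for (i in 1:60) {
    n <- sample(6:24, 1)
    v <- setNames(rnorm(n, sd = 2), sprintf("c%02d", seq_len(n)))
    bs <- best_split(v, method = "exact")
    oracle <- oracle_best_left(v)
    if (is.null(oracle)) expect_null(bs)
    else expect_equal(bs$left_size, oracle)
  }
})

test_that("best_split preconditions and tie handling", {
  expect_error(best_split(setNames(c(1, NA, 3, 4, 5, 6), letters[1:6])),
               "missing")
  expect_null(best_split(setNames(rnorm(5), letters[1:5]))) # unsplittable
  # tied values are ordered by cell ID, deterministically
  v <- setNames(c(1, 1, 1, 5, 5, 5, 9, 9), c("h", "g", "f", "e", "d", "c", "b", "a"))
  bs1 <- best_split(v, method = "exact")
  bs2 <- best_split(rev(v), method = "exact")
  expect_equal(bs1, bs2)
})

test_that("terminal conditions: small or homogeneous nodes stay single leaves", {
  v <- setNames(rnorm(5), letters[1:5])
  expect_equal(subtype_count(grow_tree(one_drug_rm(v), "D1")), 1L)

  # 40 spread-out but uniformly sensitive cells: one leaf despite the spread
  v2 <- setNames(seq(-8, -0.5, length.out = 40), sprintf("c%02d", 1:40))
  tr <- grow_tree(one_drug_rm(v2, max_conc = 1), "D1")
  expect_equal(subtype_count(tr), 1L)
  expect_equal(tree_leaves(tr)[[1]]$response_class, "sensitive")
})

test_that("balanced two-component cohort is recovered exactly", {
  set.seed(7)
  v <- setNames(c(rnorm(10, -4, 0.5), rnorm(10, 4, 0.5)),
                sprintf("c%02d", 1:20))
  tr <- grow_tree(one_drug_rm(v, max_conc = 1), "D1")
  leaves <- tree_leaves(tr)
  expect_equal(length(leaves), 2L)
  expect_setequal(leaves[[1]]$cells, sprintf("c%02d", 1:10))
  expect_equal(leaves[[1]]$response_class, "sensitive")
  expect_equal(leaves[[2]]$response_class, "resistant")
})

test_that("leaf partition, order and determinism invariants hold", {
  set.seed(31)
  for (i in 1:10) {
    n <- sample(10:40, 1)
    v <- setNames(rnorm(n, 0, 3), sprintf("c%02d", seq_len(n)))
    rm <- one_drug_rm(v, max_conc = 1)
    tr <- grow_tree(rm, "D1")
    leaves <- tree_leaves(tr)
    # partition property
    all_cells <- unlist(lapply(leaves, `[[`, "cells"))
    expect_false(anyDuplicated(all_cells) > 0)
    expect_setequal(all_cells, names(v))
    # monotone leaf order: mean ln-IC50 non-decreasing C1..Ck
    mu <- vapply(leaves, function(l) mean(v[l$cells]), numeric(1))
    expect_true(all(diff(mu) >= 0))
    # internal split p-values below the threshold
    walk <- function(node) {
      if (is.null(node$left)) return(invisible())
      expect_lt(node$split_p, 0.05)
      walk(node$left); walk(node$right)
    }
    walk(tr$root)
  }
  # byte-identical serialization for identical input
  v <- setNames(rnorm(25), sprintf("c%02d", 1:25))
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_tree(grow_tree(one_drug_rm(v), "D1"), f1)
  write_tree(grow_tree(one_drug_rm(v), "D1"), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("classify_leaf and error paths", {
  labs <- c(a = "sensitive", b = "sensitive", c = "resistant", d = "sensitive")
  expect_equal(classify_leaf(c("a", "b"), labs), "sensitive")
  expect_equal(classify_leaf("c", labs), "resistant")
  expect_equal(classify_leaf(c("a", "b", "c", "d"), labs), "mixed")
  expect_error(classify_leaf("z", labs), "unlabeled")

  rm <- one_drug_rm(setNames(c(NA_real_, NA_real_, 1), c("a", "b", "c")))
  tr <- grow_tree(rm, "D1")          # missing responses dropped
  expect_equal(tr$cells, "c")
  expect_error(grow_tree(rm, "nope"), "unknown drug")
})

test_that("mann_whitney asymptotic route matches wilcox.test without continuity", {
  set.seed(4)
  for (i in 1:20) {
    x <- rnorm(sample(5:15, 1)); y <- rnorm(sample(5:15, 1), 0.5)
    expect_equal(mann_whitney(x, y, method = "asymptotic")$p,
                 wilcox.test(x, y, exact = FALSE, correct = FALSE)$p.value,
                 tolerance = 1e-12)
  }
  # tie-corrected variance: duplicate-heavy data still matches
  x <- c(1, 1, 2, 2, 3); y <- c(2, 3, 3, 4, 4)
  expect_equal(mann_whitney(x, y, method = "asymptotic")$p,
               suppressWarnings(wilcox.test(x, y, exact = FALSE,
                                            correct = FALSE)$p.value),
               tolerance = 1e-12)
})
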