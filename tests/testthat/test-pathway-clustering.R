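test_that("sample clustering merges duplicates first and anti-correlates last", {
  set.seed(12)
  base <- rnorm(20)
  m <- cbind(s1 = base, s2 = base + rnorm(20, sd = 0.5), s3 = rev(base))
  rownames(m) <- sprintf("set%02d", 1:20)
  tree <- cluster_columns(m)
  expect_equal(sort(tree$labels[-tree$merge[1, ]]), c("s1", "s2"))
  expect_equal(tree$height[2], max(tree$height))

  dup <- cbind(m, s4 = m[, "s1"])          # exact duplicate: dissimilarity 0
  tree2 <- cluster_columns(dup)
  expect_equal(tree2$height[1], 0)
  expect_equal(sort(tree2$labels[-tree2$merge[1, ]]), c("s1", "s4"))

  const <- cbind(m, flat = rep(1, 20))
  expect_warning(tree3 <- cluster_columns(const), "constant")
  expect_false("flat" %in% tree3$labels)
})

test_that("clustering is invariant to pathway (row) order", {
  set.seed(14)
  m <- matrix(rnorm(120), 20, 6,
              dimnames = list(sprintf("set%02d", 1:20), sprintf("s%d", 1:6)))
  t1 <- cluster_columns(m)
  t2 <- cluster_columns(m[sample(20), ])
  expect_equal(write_newick(t1), write_newick(t2))
  expect_identical(split_two(t1), split_two(t2))
})

test_that("split_two cuts at the root with deterministic group naming", {
  two <- average_linkage(matrix(c(0, 0.4, 0.4, 0), 2, 2,
                                dimnames = list(c("b", "a"), c("b", "a"))))
  g <- split_two(two)
  expect_equal(g, c(a = "K1", b = "K2"))    # K1 holds the smallest sample id

  # two planted blocks are recovered as K1/K2
  set.seed(15)
  block <- rbind(matrix(rnorm(5 * 8, mean = 2), 5, 8), matrix(rnorm(5 * 8), 5, 8))
  block[, 5:8] <- block[c(6:10, 1:5), 5:8]
  colnames(block) <- sprintf("s%d", 1:8)
  rownames(block) <- sprintf("set%02d", 1:10)
  g2 <- split_two(cluster_columns(block))
  expect_equal(unname(g2[c("s1", "s2", "s3", "s4")]), rep("K1", 4))
  expect_equal(unname(g2[c("s5", "s6", "s7", "s8")]), rep("K2", 4))
})

test_that("subtype enrichment reproduces the 2x2 chi-squared arithmetic", {
  # table [[10, 0], [0, 10]]: all expected counts 5, chi2 = sum (O-E)^2/E = 20
  groups <- stats::setNames(rep(c("K1", "K2"), each = 10), sprintf("s%02d", 1:20))
  labels <- stats::setNames(rep(c("T", "other"), each = 10), sprintf("s%02d", 1:20))
  res <- subtype_enrichment(groups, labels)
  row <- res[res$subtype == "T", ]
  expect_equal(row$statistic, 20)
  expect_lt(row$p_value, 0.001)
  expect_equal(row$enriched_group, "K1")
  expect_equal(row$method, "chisq")

  # proportional table: no association
  labels2 <- stats::setNames(rep(c("T", "other"), 10), sprintf("s%02d", 1:20))
  res2 <- subtype_enrichment(groups, labels2)
  expect_equal(res2$statistic[res2$subtype == "T"], 0)
  expect_equal(res2$p_value[res2$subtype == "T"], 1)

  # swapping group labels leaves the statistic unchanged
  swapped <- ifelse(groups == "K1", "K2", "K1")
  names(swapped) <- names(groups)
  res3 <- subtype_enrichment(swapped, labels)
  expect_equal(res3$statistic, res$statistic)
  expect_equal(res3$p_value, res$p_value)

  # small expected counts fall back to Fisher's exact test, flagged
  g4 <- stats::setNames(rep(c("K1", "K2"), c(4, 16)), sprintf("s%02d", 1:20))
  l4 <- stats::setNames(rep(c("T", "other"), c(4, 16)), sprintf("s%02d", 1:20))
  res4 <- subtype_enrichment(g4, l4)
  expect_equal(res4$method[res4$subtype == "T"], "fisher")
  expect_lt(res4$p_value[res4$subtype == "T"], 0.05)

  # degenerate margin: every sample in one subtype
  l5 <- stats::setNames(rep("T", 20), sprintf("s%02d", 1:20))
  expect_warning(res5 <- subtype_enrichment(groups, l5), "degenerate")
  expect_equal(res5$method, "skipped")
})
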