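test_that("spearman_rho reproduces the rank-formula values", {
  expect_equal(spearman_rho(c(1, 5, 9), c(1, 5, 9)), 1)
  expect_equal(spearman_rho(1:5, 5:1), -1)
  # 1 - 6 * sum(d^2) / (n (n^2 - 1)) with sum(d^2) = 2
  expect_equal(spearman_rho(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_error(spearman_rho(c(1, 1, 1), c(1, 2, 3)), "undefined-correlation")
  expect_error(spearman_rho(1:2, 2:1), "at least 3")
})

test_that("spearman_rho matches the brute-force rank oracle, with ties", {
  set.seed(21)
  for (i in 1:200) {
    n <- sample(3:20, 1)
    x <- sample(1:6, n, replace = TRUE) + sample(0:1, n, replace = TRUE) / 2
    y <- sample(1:6, n, replace = TRUE)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    expect_equal(spearman_rho(x, y), brute_spearman(x, y), tolerance = 1e-12)
  }
})

test_that("spearman_rho is invariant under strictly monotone transforms", {
  set.seed(4)
  x <- rnorm(15)
  y <- rnorm(15)
  rho <- spearman_rho(x, y)
  expect_equal(spearman_rho(exp(x), y), rho)
  expect_equal(spearman_rho(x, y^3), rho)   # odd power is monotone on the reals
  expect_equal(spearman_rho(2 * x + 5, atan(y)), rho)
})

test_that("cross-cohort correlation maps agree with the per-pair oracle", {
  co <- toy_cohort(seed = 2, n_genes = 5, n_samples = 4)
  self <- cross_cohort_correlation(co, co, rownames(co$values))
  expect_equal(unname(diag(self)), rep(1, 4))
  expect_equal(unclass(self), t(unclass(self)), ignore_attr = TRUE)

  other <- toy_cohort(seed = 3, n_genes = 5, n_samples = 4, cohort_id = "other")
  other$values[, 2] <- co$values[, 1]       # a sample duplicated across cohorts
  map <- cross_cohort_correlation(co, other, rownames(co$values))
  for (i in rownames(map)) {
    for (j in colnames(map)) {
      expect_equal(map[i, j], spearman_rho(co$values[, i], other$values[, j]))
    }
  }
  expect_equal(map["S01", colnames(other$values)[2]], 1)

  expect_error(cross_cohort_correlation(co, other, c("g01", "g02")), "fewer than 3")
})

test_that("subtype medians summarise sample-pair correlations correctly", {
  # two cohorts, engineered so every pairwise rho is checkable by the oracle
  set.seed(8)
  a <- toy_cohort(seed = 5, n_genes = 10, n_samples = 6, cohort_id = "A")
  b <- toy_cohort(seed = 6, n_genes = 10, n_samples = 4, cohort_id = "B")
  profiles <- list(A = a$values, B = b$values)
  labels <- list(A = a$subtypes, B = b$subtypes)
  sim <- subtype_median_correlation(profiles, labels)

  # cross-cohort entry: median over all 3x2 sample pairs
  sa <- names(a$subtypes)[a$subtypes == "a"]
  sb <- names(b$subtypes)[b$subtypes == "b"]
  rhos <- as.vector(outer(sa, sb, Vectorize(function(i, j)
    spearman_rho(a$values[, i], b$values[, j]))))
  expect_equal(sim$median_rho["A.a", "B.b"], median(rhos))
  expect_equal(sim$n_pairs["A.a", "B.b"], length(rhos))

  # within-cohort, within-subtype diagonal: distinct pairs only (no self-pairs)
  rhos_aa <- utils::combn(sa, 2, function(p) spearman_rho(a$values[, p[1]], a$values[, p[2]]))
  expect_equal(sim$median_rho["A.a", "A.a"], median(rhos_aa))
  expect_equal(sim$n_pairs["A.a", "A.a"], choose(length(sa), 2))

  expect_true(all(sim$median_rho >= -1 & sim$median_rho <= 1))
  expect_equal(sim$median_rho, t(sim$median_rho))
})

test_that("subtypes with fewer than two samples are excluded with a warning", {
  a <- toy_cohort(seed = 5, n_genes = 10, n_samples = 6, cohort_id = "A")
  labels <- a$subtypes
  labels[6] <- "orphan"
  expect_warning(
    sim <- subtype_median_correlation(list(A = a$values, A2 = a$values),
                                      list(A = labels, A2 = a$subtypes)),
    "excluded")
  expect_false(any(grepl("orphan", rownames(sim$median_rho))))
})
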