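test_that("signal-to-noise applies the variance floors", {
  m <- matrix(c(2, 2, 1, 1), 1, 4, dimnames = list("g1", paste0("S", 1:4)))
  # sds are 0, floored at 0.2 * |mean|: (2 - 1) / (0.4 + 0.2)
  expect_equal(unname(signal_to_noise(m, c(TRUE, TRUE, FALSE, FALSE))), 1 / 0.6)
  # all-zero gene: both floors fall back to 0.2, metric 0
  z <- matrix(0, 1, 4, dimnames = list("g1", paste0("S", 1:4)))
  expect_equal(unname(signal_to_noise(z, c(TRUE, TRUE, FALSE, FALSE))), 0)

  set.seed(2)
  mm <- matrix(rnorm(40), 4, 10, dimnames = list(paste0("g", 1:4), paste0("S", 1:10)))
  cls <- rep(c(TRUE, FALSE), 5)
  expect_equal(signal_to_noise(mm, cls), -signal_to_noise(mm, !cls))
  same <- matrix(rep(c(1, 2, 3, 2), 2), 1, 8)
  dimnames(same) <- list("g1", paste0("S", 1:8))
  expect_equal(unname(signal_to_noise(same, rep(c(TRUE, FALSE), each = 4))), 0)
  expect_error(signal_to_noise(mm, c(TRUE, rep(FALSE, 9))), ">= 2 samples")
})

test_that("class mean difference behaves as a log-ratio fold change", {
  m <- matrix(c(1, 3, 0, 2), 1, 4, dimnames = list("g1", paste0("S", 1:4)))
  cls <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(unname(class_mean_difference(m, cls)), 1)
  expect_equal(class_mean_difference(m, cls), -class_mean_difference(m, !cls))
  same <- matrix(c(1, 2, 1, 2), 1, 4, dimnames = list("g1", paste0("S", 1:4)))
  expect_equal(unname(class_mean_difference(same, cls)), 0)
})

test_that("enrichment score reproduces hand walks and the exhaustive oracle", {
  m <- stats::setNames(c(4, 3, 2, 1), paste0("g", 1:4))
  expect_equal(enrichment_score(m, "g1", weight_p = 0)$es, 1)
  expect_equal(enrichment_score(m, "g4", weight_p = 0)$es, -1)

  set.seed(31)
  x <- stats::setNames(rnorm(8), paste0("g", 1:8))
  genes <- names(x)
  for (p in c(0, 1)) {
    for (mask in 1:(2^8 - 2)) {
      s <- genes[as.logical(bitwAnd(mask, 2^(0:7)))]
      expect_equal(enrichment_score(x, s, weight_p = p)$es, brute_es(x, s, p),
                   tolerance = 1e-12)
    }
  }
})

test_that("at p = 0 the ES depends only on in-set positions", {
  m1 <- stats::setNames(c(10, 5, 4, 0.1, -3), paste0("g", 1:5))
  m2 <- stats::setNames(c(2, 1.9, 1.5, 1.2, -90), paste0("g", 1:5))  # same order
  s <- c("g2", "g4")
  expect_equal(enrichment_score(m1, s, weight_p = 0)$es,
               enrichment_score(m2, s, weight_p = 0)$es)
})

test_that("enrichment score agrees with fgsea's walk", {
  skip_if_not_installed("fgsea")
  set.seed(6)
  for (i in 1:10) {
    m <- stats::setNames(rnorm(60), sprintf("g%03d", 1:60))
    s <- sample(names(m), sample(5:15, 1))
    srt <- sort(m, decreasing = TRUE)
    expect_equal(enrichment_score(m, s, weight_p = 1)$es,
                 fgsea::calcGseaStat(srt, which(names(srt) %in% s), gseaParam = 1),
                 tolerance = 1e-12)
  }
})

test_that("permutation GSEA recovers planted sets and is seed-deterministic", {
  des <- mini_design(seed = 41)
  sim <- generate_cohorts(des)
  gs <- generate_gene_sets(des, n_decoys = 10, set_size = 30)
  suppressWarnings({
    tab1 <- gsea_all_cohorts(sim$cohorts, gs, n_perm = 200, seed = 41)
    tab2 <- gsea_all_cohorts(sim$cohorts, gs, n_perm = 200, seed = 41)
    tab3 <- gsea_all_cohorts(sim$cohorts, gs, n_perm = 200, seed = 42)
  })
  expect_identical(tab1, tab2)
  expect_false(identical(tab1$p_nominal, tab3$p_nominal))

  truth <- sim$truth$dysregulated
  for (i in seq_len(nrow(truth))) {
    row <- tab1[tab1$cohort_id == truth$cohort_id[i] &
                tab1$subtype == truth$subtype[i] &
                tab1$set_name == truth$set_name[i], ]
    expect_equal(nrow(row), 1L)
    expect_lt(row$fdr_q, 0.25)
    expect_equal(row$direction, truth$direction[i])
  }
  expect_true(all(tab1$fdr_q >= 0 & tab1$fdr_q <= 1))
  expect_true(all(tab1$p_nominal >= 0 & tab1$p_nominal <= 1))
  expect_equal(tab1$direction, ifelse(tab1$es >= 0, "up", "down"))
})

test_that("retention uses a strict FDR threshold over subtypes", {
  tab <- data.frame(
    cohort_id = "c1", subtype = c("s1", "s2", "s1", "s2", "s1"),
    set_name = c("A", "A", "B", "B", "C"),
    es = 0.5, nes = 1.5, p_nominal = 0.01,
    fdr_q = c(0.30, 0.24, 0.25, 0.40, 0.26),
    direction = "up", stringsAsFactors = FALSE)
  kept <- retain_significant(tab, 0.25)
  expect_setequal(unique(kept$set_name), "A")   # 0.24 < 0.25 keeps A; B at exactly 0.25 is dropped
  expect_equal(nrow(kept), 2L)                  # all rows of a retained set survive
  empty <- retain_significant(tab[0, ], 0.25)
  expect_equal(nrow(empty), 0L)
})

test_that("recurrence classifies sets by tissue breadth", {
  tab <- data.frame(
    cohort_id = c("c1", "c1", "c1", "c2", "c3", "c4", "c5", "c6"),
    subtype = c("s1", "s2", "s3", "s1", "s1", "s1", "s1", "s1"),
    set_name = c(rep("ONLY_LIVER", 3), rep("EVERYWHERE", 5)),
    es = 0.5, nes = 1.5, p_nominal = 0.01, fdr_q = 0.01, direction = "up",
    stringsAsFactors = FALSE)
  tissues <- stats::setNames(c("liver", "breast", "brain", "lung", "ovary", "skin"),
                             paste0("c", 1:6))
  rec <- tabulate_recurrence(tab, tissues)
  expect_equal(rec$class[rec$set_name == "ONLY_LIVER"], "tissue_specific")
  expect_equal(rec$n_subtypes[rec$set_name == "ONLY_LIVER"], 3L)
  expect_equal(rec$class[rec$set_name == "EVERYWHERE"], "common")
  expect_equal(rec$n_tissues[rec$set_name == "EVERYWHERE"], 5L)
  expect_error(tabulate_recurrence(tab, tissues[-1]), "config error")
})
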