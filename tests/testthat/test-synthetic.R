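test_that("the generator is deterministic and respects the design", {
  des <- mini_design(seed = 51)
  a <- generate_cohorts(des)
  b <- generate_cohorts(des)
  expect_identical(a, b)
  ga <- generate_gene_sets(des, n_decoys = 5, set_size = 30)
  gb <- generate_gene_sets(des, n_decoys = 5, set_size = 30)
  expect_identical(ga$sets, gb$sets)

  expect_equal(length(a$cohorts), 3L)
  for (co in a$cohorts) {
    expect_equal(ncol(co$values), 30L)
    expect_equal(nrow(co$values), 400L)
    expect_equal(unname(table(co$subtypes)), rep(10L, 3), ignore_attr = TRUE)
  }
  # scale dialects: absolute cohorts sit near 8, log-ratio cohorts near 0
  expect_equal(a$cohorts[[1]]$scale, "absolute")
  expect_gt(mean(a$cohorts[[1]]$values), 6)
  expect_equal(a$cohorts[[3]]$scale, "log_ratio")
  expect_lt(abs(mean(a$cohorts[[3]]$values)), 0.5)
})

test_that("ground truth bookkeeping names the planted structure", {
  des <- mini_design(seed = 52)
  sim <- generate_cohorts(des)
  pn <- sim$truth$partnerships
  expect_equal(nrow(pn), 3L)
  expect_true(all(pn$cohort_a != pn$cohort_b))
  expect_equal(nrow(sim$truth$dysregulated), 7L)  # 3 pair programs + 1 singleton

  # a single shared program yields exactly that partnership
  genes <- des$core_genes[1:30]
  custom <- synthetic_design(
    n_genes = 400, n_samples = 30, module_size = 30, seed = 5,
    programs = list(list(name = "P", genes = genes,
                         members = data.frame(cohort_id = c("cohort1", "cohort2"),
                                              subtype = c("s1", "s2"),
                                              stringsAsFactors = FALSE),
                         direction = "up")))
  st <- generate_cohorts(custom)$truth
  expect_equal(nrow(st$partnerships), 1L)
  expect_equal(st$partnerships$subtype_a, "s1")
  expect_equal(st$partnerships$subtype_b, "s2")

  # module genes outside a member cohort's universe are a design error
  priv2 <- setdiff(rownames(generate_cohorts(custom)$cohorts[[2]]$values), custom$core_genes)
  expect_error(
    synthetic_design(
      n_genes = 400, n_samples = 30, seed = 5,
      programs = list(list(name = "BAD", genes = priv2[1:10],
                           members = data.frame(cohort_id = "cohort1", subtype = "s1",
                                                stringsAsFactors = FALSE),
                           direction = "up"))),
    "design error")
})

test_that("null mode plants nothing", {
  des <- mini_design(seed = 53, null_mode = TRUE)
  sim <- generate_cohorts(des)
  expect_equal(nrow(sim$truth$partnerships), 0L)
  expect_equal(nrow(sim$truth$dysregulated), 0L)
  # subtype means of a module gene are exchangeable: no systematic offset
  co <- sim$cohorts[[1]]
  g <- des$programs[[1]]$genes[1]
  mns <- tapply(co$values[g, ], co$subtypes, mean)
  expect_lt(diff(range(mns)), 1.5)          # pure noise at sd 1, n = 10 per group
})

test_that("stronger planted effects raise the partner correlation", {
  meds <- vapply(c(0, 1, 2), function(delta) {
    des <- synthetic_design(n_genes = 600, n_samples = 30, module_size = 40,
                            delta = delta, seed = 60)
    sim <- generate_cohorts(des)
    centered <- lapply(sim$cohorts, median_center_genes)
    common <- intersect_genes(sim$cohorts, min_common = 100)
    sim_tx <- subtype_median_correlation(lapply(centered, `[[`, "values"),
                                         lapply(sim$cohorts, `[[`, "subtypes"),
                                         features = common$genes)
    p <- sim$truth$partnerships   # recorded even at delta = 0 (not null_mode)
    mean(vapply(seq_len(nrow(p)), function(i)
      sim_tx$median_rho[paste(p$cohort_a[i], p$subtype_a[i], sep = "."),
                        paste(p$cohort_b[i], p$subtype_b[i], sep = ".")], 0))
  }, 0)
  expect_true(all(diff(meds) > 0))
})

test_that("decoy gene sets record their module overlap", {
  des <- mini_design(seed = 54)
  gs0 <- generate_gene_sets(des, n_decoys = 0)
  expect_equal(names(gs0$sets), vapply(des$programs, `[[`, "", "name"))
  gs <- generate_gene_sets(des, n_decoys = 8, set_size = 30)
  ov <- attr(gs, "overlap_with_modules")
  expect_equal(length(ov), 8L)
  modules <- unique(unlist(gs0$sets))
  for (nm in names(ov))
    expect_equal(unname(ov[nm]), length(intersect(gs$sets[[nm]], modules)))
})

test_that("the two-group preset tags every sample with its planted group", {
  des <- two_group_design(n_genes = 400, n_samples = 20, module_size = 30, seed = 55)
  sim <- generate_cohorts(des)
  g <- sim$truth$group_of
  expect_equal(length(g), 3L * 20L)
  expect_setequal(unique(g), c("G1", "G2"))
  for (co in sim$cohorts) {
    s1 <- names(co$subtypes)[co$subtypes == "s1"]
    expect_true(all(g[s1] == "G1"))
  }
})
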