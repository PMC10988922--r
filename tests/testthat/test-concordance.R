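test_that("second-round coefficients match a brute-force oracle", {
  st <- small_study(seed = 4, n_genes = 150, markers_per_type = 4,
                    cells_per_type = 17)  # 51 cells
  sim <- compute_cell_similarity(st$cells_log, st$refs_log)
  r <- second_round_correlations(sim, st$cells_log, st$catalog,
                                 method = "spearman")
  expect_equal(dim(r), c(12, 9))
  expr <- as.matrix(st$cells_log)
  for (g in rownames(r)) {
    for (s in colnames(r)) {
      expect_equal(r[g, s], oracle_spearman(expr[g, ], sim$r[, s]),
                   tolerance = 1e-10)
    }
  }
  # pearson route too
  rp <- second_round_correlations(sim, st$cells_log, st$catalog,
                                  method = "pearson")
  for (g in rownames(rp)) {
    expect_equal(rp[g, 1], oracle_pearson(expr[g, ], sim$r[, 1]),
                 tolerance = 1e-10)
  }
})

test_that("a marker equal to a similarity column correlates perfectly with it", {
  st <- small_study(seed = 8, n_genes = 100, markers_per_type = 2,
                    cells_per_type = 10)
  sim <- compute_cell_similarity(st$cells_log, st$refs_log)
  cells2 <- as.matrix(st$cells_log)
  g <- st$catalog$gene[1]
  cells2[g, ] <- sim$r[, 3]
  cells2 <- gene_matrix(cells2, layer = "logcpm")
  r <- second_round_correlations(sim, cells2, st$catalog, method = "pearson")
  expect_equal(unname(r[g, 3]), 1, tolerance = 1e-12)
})

test_that("missing and constant markers are skipped/flagged, not fatal", {
  st <- small_study(seed = 9, n_genes = 100, markers_per_type = 2,
                    cells_per_type = 10)
  sim <- compute_cell_similarity(st$cells_log, st$refs_log)
  cat2 <- rbind(st$catalog,
                data.frame(gene = "not_a_gene", claimed_type = "fiber",
                           source = "synthetic"))
  cells2 <- as.matrix(st$cells_log)
  cells2[st$catalog$gene[1], ] <- 0  # constant marker
  cells2 <- gene_matrix(cells2, layer = "logcpm")
  expect_message(r <- second_round_correlations(sim, cells2, cat2),
                 "skipped")
  expect_equal(attr(r, "skipped"), "not_a_gene")
  expect_equal(attr(r, "constant"), st$catalog$gene[1])
  expect_true(all(is.na(r[st$catalog$gene[1], ])))

  conc <- suppressMessages(
    concordance_analysis(sim, cells2, cat2))
  expect_equal(conc$calls$status[conc$calls$gene == "not_a_gene"], "skipped")
  expect_equal(conc$calls$status[conc$calls$gene == st$catalog$gene[1]],
               "constant")
})

test_that("t-test statistics and p-values match textbook formulas", {
  # closed-form example
  res <- two_sample_ttest(c(1, 2, 3), c(4, 5, 6), "student")
  exp_t <- oracle_student_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$t, exp_t$t, tolerance = 1e-12)
  expect_equal(res$p, exp_t$p, tolerance = 1e-12)
  expect_equal(res$t, -3 / sqrt(2 / 3), tolerance = 1e-12)

  # random small groups against both oracles
  set.seed(99)
  for (i in 1:200) {
    a <- rnorm(sample(2:8, 1))
    b <- rnorm(sample(2:8, 1), mean = runif(1, -1, 1))
    s <- two_sample_ttest(a, b, "student")
    os <- oracle_student_t(a, b)
    expect_equal(s$t, os$t, tolerance = 1e-10)
    expect_equal(s$p, os$p, tolerance = 1e-10)
    w <- two_sample_ttest(a, b, "welch")
    ow <- oracle_welch_t(a, b)
    expect_equal(w$t, ow$t, tolerance = 1e-10)
    expect_equal(w$p, ow$p, tolerance = 1e-10)
  }

  # equal sizes + equal variances: student and welch coincide
  a <- c(1, 2, 4, 8); b <- a + 3
  expect_equal(two_sample_ttest(a, b, "student")$t,
               two_sample_ttest(a, b, "welch")$t, tolerance = 1e-12)

  # degenerate cases
  expect_equal(two_sample_ttest(rep(0.5, 3), rep(0.5, 3)),
               list(t = 0, p = 1))
  d <- two_sample_ttest(rep(1, 3), rep(0, 3))
  expect_equal(d$t, Inf)
  expect_equal(d$p, 0)
  expect_error(two_sample_ttest(1, c(1, 2)), "at least 2")
})

test_that("significance stars follow the strict threshold convention", {
  expect_equal(significance_stars(0.0005), "***")
  expect_equal(significance_stars(0.005), "**")
  expect_equal(significance_stars(0.03), "*")
  expect_equal(significance_stars(0.05), "ns")  # strict inequality
  expect_equal(significance_stars(0.001), "**")
  expect_equal(significance_stars(0.01), "*")
  expect_equal(significance_stars(c(0, 1)), c("***", "ns"))
  expect_error(significance_stars(1.2), "0, 1")
  expect_error(significance_stars(-0.1), "0, 1")
})

test_that("the call rule separates unique, ambiguous and none", {
  fiber <- c(0.80, 0.82, 0.78)
  vessel <- c(0.10, 0.05, 0.12)
  ray <- c(0.00, -0.02, 0.03)
  cl <- call_marker_type(list(fiber = fiber, vessel = vessel, ray = ray))
  expect_equal(cl$call, "fiber")
  expect_equal(cl$status, "unique")
  # the rule's own t-tests agree with the oracle at alpha 0.05
  expect_lt(oracle_student_t(fiber, vessel)$p, 0.05)
  expect_lt(oracle_student_t(fiber, ray)$p, 0.05)

  # identical replicate vectors across types: full ambiguity
  same <- c(0.4, 0.5, 0.45)
  cl2 <- call_marker_type(list(fiber = same, vessel = same, ray = same))
  expect_equal(cl2$status, "ambiguous")
  expect_equal(cl2$call, c("fiber", "vessel", "ray"))

  # all means non-positive: no call
  cl3 <- call_marker_type(list(fiber = -fiber, vessel = -vessel, ray = -ray))
  expect_equal(cl3$status, "none")
  expect_equal(cl3$call, character(0))

  expect_error(call_marker_type(list(fiber = c(0.1, 0.2))), "2 types")
  expect_error(call_marker_type(list(fiber = 0.1, vessel = 0.2)),
               ">= 2 replicate")
})

test_that("catalog evaluation counts consistent and mislabeled markers", {
  st <- small_study(seed = 1, n_genes = 2000, markers_per_type = 10,
                    log2_fold_change = 3, cells_per_type = 150,
                    mean_depth = 5000)
  sim <- compute_cell_similarity(st$cells_log, st$refs_log)
  # mislabel 10 of the 30 markers with a wrong claimed type
  catalog <- st$catalog
  rot <- setNames(c("vessel", "ray", "fiber"), c("fiber", "vessel", "ray"))
  flip <- seq(1, 30, by = 3)
  catalog$claimed_type[flip] <- rot[catalog$claimed_type[flip]]
  conc <- concordance_analysis(sim, st$cells_log, catalog)
  summ <- evaluate_catalog(conc)
  expect_equal(summ$n_markers, 30)
  expect_equal(summ$consistent, 20)
  expect_equal(summ$inconsistent, 10)
  # inconsistency is on the claim, not the call: calls match the truth
  called <- conc$calls
  truth_type <- st$truth$marker_table$true_type[
    match(called$gene, st$truth$marker_table$gene)]
  expect_equal(called$call[called$status == "unique"],
               truth_type[called$status == "unique"])
})

test_that("an all-consistent catalog and an empty catalog summarize cleanly", {
  st <- small_study(seed = 6, n_genes = 600, markers_per_type = 4,
                    log2_fold_change = 3, cells_per_type = 80)
  sim <- compute_cell_similarity(st$cells_log, st$refs_log)
  conc <- concordance_analysis(sim, st$cells_log, st$catalog)
  summ <- evaluate_catalog(conc)
  expect_equal(summ$consistent, 12)
  expect_equal(summ$inconsistent + summ$ambiguous + summ$none + summ$skipped,
               0)

  empty <- marker_catalog(data.frame(gene = character(0),
                                     claimed_type = character(0),
                                     source = character(0)))
  conc0 <- concordance_analysis(sim, st$cells_log, empty)
  summ0 <- evaluate_catalog(conc0)
  expect_equal(nrow(summ0), 0)
})

test_that("mean true-type correlation is non-decreasing in the planted fold", {
  means <- vapply(c(0, 1, 2, 3), function(fold) {
    st <- small_study(seed = 13, n_genes = 500, markers_per_type = 8,
                      log2_fold_change = fold, cells_per_type = 50)
    sim <- compute_cell_similarity(st$cells_log, st$refs_log)
    conc <- concordance_analysis(sim, st$cells_log, st$catalog)
    pt <- conc$per_type
    truth_type <- st$truth$marker_table$true_type[
      match(pt$gene, st$truth$marker_table$gene)]
    mean(pt$mean_r[pt$cell_type == truth_type])
  }, numeric(1))
  expect_true(all(diff(means) >= 0))
})
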