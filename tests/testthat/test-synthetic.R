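test_that("simulate_truth plants disjoint markers with the stated geometry", {
  tr <- simulate_truth(n_types = 3, n_genes = 300, markers_per_type = 20,
                       seed = 7)
  expect_equal(nrow(tr$marker_table), 60)
  expect_false(anyDuplicated(tr$marker_table$gene) > 0)
  expect_true(all(tr$marker_table$gene %in% tr$gene_ids))
  # marker fold applies in the marker's own type only
  for (i in seq_len(nrow(tr$marker_table))) {
    g <- tr$marker_table$gene[i]
    ty <- tr$marker_table$true_type[i]
    others <- setdiff(tr$type_names, ty)
    expect_equal(unname(tr$type_mean_profile[g, ty]),
                 unname(2^3 * tr$type_mean_profile[g, others[1]]))
    expect_equal(unname(tr$type_mean_profile[g, others[1]]),
                 unname(tr$type_mean_profile[g, others[2]]))
  }
})

test_that("degenerate truth parameters behave as identities", {
  tr0 <- simulate_truth(n_genes = 100, markers_per_type = 0, seed = 1)
  expect_equal(nrow(tr0$marker_table), 0)
  expect_true(all(tr0$type_mean_profile[, 1] == tr0$type_mean_profile[, 2]))

  trf0 <- simulate_truth(n_genes = 100, markers_per_type = 10,
                         log2_fold_change = 0, seed = 1)
  expect_equal(nrow(trf0$marker_table), 30)
  expect_true(all(trf0$type_mean_profile[, 1] == trf0$type_mean_profile[, 3]))
})

test_that("truth generation validates its sizing and sign preconditions", {
  expect_error(simulate_truth(n_genes = 10, markers_per_type = 5),
               "too small")
  expect_error(simulate_truth(log2_fold_change = -1), "log2_fold_change")
  expect_error(simulate_truth(n_types = 1), "n_types")
})

test_that("reference simulation matches the triplicate LCM design", {
  tr <- simulate_truth(n_genes = 150, markers_per_type = 5, seed = 3)
  refs <- simulate_lcm_references(tr, n_replicates = 3, seed = 4)
  expect_equal(ncol(refs$matrix), 9)
  expect_equal(as.integer(table(refs$sample_meta$cell_type)), rep(3L, 3))
  expect_true(all(as.matrix(refs$matrix) > 0))

  # zero replicate noise collapses replicates onto the type mean profile
  refs0 <- simulate_lcm_references(tr, replicate_noise_sd = 0, seed = 4)
  expect_equal(unname(as.matrix(refs0$matrix)[, "fiber_rep1"]),
               unname(as.matrix(refs0$matrix)[, "fiber_rep2"]))
  expect_equal(unname(as.matrix(refs0$matrix)[, "fiber_rep1"]),
               unname(tr$type_mean_profile[, "fiber"]))
})

test_that("simulators are bit-identical under a fixed seed", {
  tr <- simulate_truth(n_genes = 150, markers_per_type = 5, seed = 11)
  expect_identical(tr, simulate_truth(n_genes = 150, markers_per_type = 5,
                                      seed = 11))
  expect_identical(simulate_lcm_references(tr, seed = 2),
                   simulate_lcm_references(tr, seed = 2))
  expect_identical(simulate_cells(tr, cells_per_type = 10, seed = 5),
                   simulate_cells(tr, cells_per_type = 10, seed = 5))
})

test_that("simulated cells are integer counts with the requested shape and depth", {
  tr <- simulate_truth(n_genes = 500, markers_per_type = 5, seed = 2)
  cells <- simulate_cells(tr, cells_per_type = 300, mean_depth = 4000,
                          seed = 9)
  cm <- as.matrix(cells$counts)
  expect_equal(dim(cm), c(500, 900))
  expect_true(all(cm >= 0))
  expect_true(all(cm == round(cm)))
  expect_equal(cells$cell_labels,
               rep(tr$type_names, each = 300))
  # NB mean identity: mean library size converges to mean_depth
  expect_lt(abs(mean(colSums(cm)) / 4000 - 1), 0.05)
})

test_that("planted log2 fold-change is recoverable from simulated counts", {
  # fold 8 with a single marker per type on a large gene space, so the
  # marker's contribution to the library total stays negligible
  tr <- simulate_truth(n_genes = 4000, markers_per_type = 1,
                       log2_fold_change = 8, seed = 5)
  cells <- simulate_cells(tr, cells_per_type = 300, seed = 6)
  cm <- as.matrix(cells$counts)
  lab <- cells$cell_labels
  for (i in seq_len(nrow(tr$marker_table))) {
    g <- tr$marker_table$gene[i]
    ty <- tr$marker_table$true_type[i]
    own <- mean(cm[g, lab == ty])
    other <- mean(cm[g, lab != ty])
    expect_lt(abs(log2(own / other) - 8), 0.3)
  }
  # the default geometry at fold 3
  tr3 <- simulate_truth(n_genes = 2000, markers_per_type = 20,
                        log2_fold_change = 3, seed = 5)
  cells3 <- simulate_cells(tr3, cells_per_type = 300, seed = 6)
  cm3 <- as.matrix(cells3$counts)
  lab3 <- cells3$cell_labels
  ratios <- vapply(seq_len(nrow(tr3$marker_table)), function(i) {
    g <- tr3$marker_table$gene[i]
    ty <- tr3$marker_table$true_type[i]
    log2(mean(cm3[g, lab3 == ty]) / mean(cm3[g, lab3 != ty]))
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 3), 0.3)
})

test_that("a written synthetic dataset round-trips through the readers", {
  st <- small_study(seed = 21, n_genes = 120, markers_per_type = 4,
                    cells_per_type = 8)
  out <- file.path(tempdir(), "synth-roundtrip")
  paths <- write_synthetic_dataset(st$truth, st$refs, st$cells, out)

  cells_rt <- read_matrix(paths[["cells"]], format = "mtx_triplet")
  expect_equal(as.matrix(cells_rt), as.matrix(st$cells$counts))
  expect_equal(gem_layer(cells_rt), "raw")

  refs_rt <- read_lcm_references(paths[["references"]])
  expect_equal(as.matrix(refs_rt$matrix), as.matrix(st$refs$matrix),
               tolerance = 1e-12)
  expect_equal(refs_rt$sample_meta, st$refs$sample_meta)

  cat_rt <- read_marker_catalog(paths[["markers"]])
  expect_equal(nrow(cat_rt), nrow(st$truth$marker_table))
  expect_equal(cat_rt$gene, st$truth$marker_table$gene)

  # MTX nonzero count equals the number of nonzero entries
  header <- readLines(file.path(paths[["cells"]], "matrix.mtx"), n = 5)
  size_line <- header[!startsWith(header, "%")][1]
  dims <- scan(text = size_line, quiet = TRUE)
  expect_equal(dims[3], sum(as.matrix(st$cells$counts) != 0))
})
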