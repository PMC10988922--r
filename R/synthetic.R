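#' Simulate ground truth for a marker-validation experiment
#'
#' Draws a baseline mean-expression profile and plants marker genes: each
#' cell type receives `markers_per_type` genes whose mean in that type is
#' multiplied by `2^log2_fold_change` relative to every other type. The
#' multiplicative planting makes `log2_fold_change` the expected log2
#' expression difference between a marker's own type and any other type.
#' Marker gene sets of different types are disjoint.
#'
#' @param n_types number of cell types (>= 2; the first three are named
#'   fiber, vessel, ray after the differentiating-xylem cell types).
#' @param n_genes number of genes (>= `n_types * markers_per_type`).
#' @param markers_per_type planted markers per type (>= 0).
#' @param log2_fold_change planted log2 fold-change (>= 0).
#' @param base_mean_log_sd sdlog of the lognormal baseline gene means
#'   (meanlog 0).
#' @param seed integer RNG seed; identical seed and parameters give
#'   bit-identical output.
#' @return an object of class `synthetic_truth`: list with `type_names`,
#'   `gene_ids`, `type_mean_profile` (genes x types matrix, linear scale),
#'   `marker_table` (data.frame gene / true_type / log2_fold_change),
#'   `params`.
#' @examples
#' tr <- simulate_truth(n_genes = 100, markers_per_type = 5, seed = 1)
#' nrow(tr$marker_table)  # 15
#' @export
simulate_truth <- function(n_types = 3L, n_genes = 2000L,
                           markers_per_type = 20L, log2_fold_change = 3,
                           base_mean_log_sd = 1, seed = 1L) {
  if (n_types < 2L) stop("`n_types` must be >= 2", call. = FALSE)
  if (markers_per_type < 0L) {
    stop("`markers_per_type` must be >= 0", call. = FALSE)
  }
  if (log2_fold_change < 0) {
    stop("`log2_fold_change` must be >= 0", call. = FALSE)
  }
  if (n_genes < n_types * markers_per_type) {
    stop(sprintf("`n_genes` (%d) too small for %d types x %d markers",
                 n_genes, n_types, markers_per_type), call. = FALSE)
  }
  type_names <- default_type_names(n_types)
  gene_ids <- sprintf("gene%05d", seq_len(n_genes))
  with_seed(seed, {
    base <- rlnorm(n_genes, meanlog = 0, sdlog = base_mean_log_sd)
    marker_idx <- if (markers_per_type > 0L) {
      sample.int(n_genes, n_types * markers_per_type)
    } else integer(0)
    profiles <- matrix(base, nrow = n_genes, ncol = n_types,
                       dimnames = list(gene_ids, type_names))
    marker_table <- data.frame(gene = character(0), true_type = character(0),
                               log2_fold_change = numeric(0))
    if (markers_per_type > 0L) {
      assign_type <- rep(type_names, each = markers_per_type)
      profiles[cbind(marker_idx, match(assign_type, type_names))] <-
        base[marker_idx] * 2^log2_fold_change
      marker_table <- data.frame(gene = gene_ids[marker_idx],
                                 true_type = assign_type,
                                 log2_fold_change = log2_fold_change)
    }
    structure(list(type_names = type_names, gene_ids = gene_ids,
                   type_mean_profile = profiles, marker_table = marker_table,
                   params = list(n_types = n_types, n_genes = n_genes,
                                 markers_per_type = markers_per_type,
                                 log2_fold_change = log2_fold_change,
                                 base_mean_log_sd = base_mean_log_sd,
                                 seed = as.integer(seed))),
              class = "synthetic_truth")
  })
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(
    "<synthetic_truth> %d genes, %d types (%s), %d planted markers (log2 FC %g)\n",
    length(x$gene_ids), length(x$type_names),
    paste(x$type_names, collapse = ", "), nrow(x$marker_table),
    x$params$log2_fold_change))
  invisible(x)
}

#' Simulate LCM-style bulk reference profiles
#'
#' One profile per (cell type, replicate): the type's mean profile multiplied
#' gene-wise by lognormal replicate noise. The default of three replicates
#' per type mirrors the standard LCM design of three cell types dissected in
#' triplicate. Profiles are continuous and strictly positive.
#'
#' @param truth a [simulate_truth()] object.
#' @param n_replicates replicates per type (>= 1).
#' @param replicate_noise_sd sdlog of the lognormal replicate noise (>= 0).
#' @param seed integer RNG seed.
#' @return an [lcm_reference_set()]; sample ids follow `<type>_rep<k>`.
#' @export
simulate_lcm_references <- function(truth, n_replicates = 3L,
                                    replicate_noise_sd = 0.2, seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (n_replicates < 1L) stop("`n_replicates` must be >= 1", call. = FALSE)
  if (replicate_noise_sd < 0) {
    stop("`replicate_noise_sd` must be >= 0", call. = FALSE)
  }
  n_genes <- length(truth$gene_ids)
  types <- truth$type_names
  with_seed(seed, {
    cols <- vector("list", length(types) * n_replicates)
    meta <- vector("list", length(cols))
    k <- 0L
    for (ty in types) {
      for (r in seq_len(n_replicates)) {
        k <- k + 1L
        noise <- rlnorm(n_genes, meanlog = 0, sdlog = replicate_noise_sd)
        cols[[k]] <- truth$type_mean_profile[, ty] * noise
        meta[[k]] <- data.frame(sample_id = sprintf("%s_rep%d", ty, r),
                                cell_type = ty, replicate = r)
      }
    }
    meta <- do.call(rbind, meta)
    mat <- do.call(cbind, cols)
    dimnames(mat) <- list(truth$gene_ids, meta$sample_id)
    lcm_reference_set(gene_matrix(mat, layer = "raw"), meta)
  })
}

#' Simulate a single-cell count matrix
#'
#' For each cell of type T, gene counts are drawn negative-binomial with mean
#' `mean_depth * p_T` where `p_T` is the type's mean profile normalized to
#' sum 1, and dispersion `nb_dispersion` (variance `mu + nb_dispersion *
#' mu^2`). Per-cell depth is held at `mean_depth` in expectation; library-size
#' variation is deliberately not modeled so that planted effects stay sharp.
#'
#' @param truth a [simulate_truth()] object.
#' @param cells_per_type cells per type (>= 1).
#' @param mean_depth expected total counts per cell (> 0).
#' @param nb_dispersion negative-binomial dispersion (> 0).
#' @param seed integer RNG seed.
#' @return list with `counts` (a raw-layer [gene_matrix()], integer counts,
#'   cell ids `<type>_cell<i>`) and `cell_labels` (character vector of true
#'   types in cell order).
#' @export
simulate_cells <- function(truth, cells_per_type = 300L, mean_depth = 5000,
                           nb_dispersion = 0.5, seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (cells_per_type < 1L) stop("`cells_per_type` must be >= 1", call. = FALSE)
  if (mean_depth <= 0) stop("`mean_depth` must be > 0", call. = FALSE)
  if (nb_dispersion <= 0) stop("`nb_dispersion` must be > 0", call. = FALSE)
  n_genes <- length(truth$gene_ids)
  types <- truth$type_names
  size <- 1 / nb_dispersion
  with_seed(seed, {
    n_cells <- length(types) * cells_per_type
    counts <- matrix(0L, nrow = n_genes, ncol = n_cells)
    labels <- character(n_cells)
    ids <- character(n_cells)
    j <- 0L
    for (ty in types) {
      mu <- truth$type_mean_profile[, ty]
      mu <- mean_depth * mu / sum(mu)
      for (i in seq_len(cells_per_type)) {
        j <- j + 1L
        counts[, j] <- rnbinom(n_genes, size = size, mu = mu)
        labels[j] <- ty
        ids[j] <- sprintf("%s_cell%03d", ty, i)
      }
    }
    dimnames(counts) <- list(truth$gene_ids, ids)
    storage.mode(counts) <- "double"
    list(counts = gene_matrix(counts, layer = "raw"), cell_labels = labels)
  })
}

#' Write a synthetic dataset to disk
#'
#' Writes the cell counts as a 10x-style MTX triplet, the reference profiles
#' as a dense TSV, the planted markers as a marker catalog TSV
#' (`gene`, `claimed_type`, `source`), and the true cell labels as
#' `truth.tsv`. Everything round-trips through [read_matrix()],
#' [read_lcm_references()], and [read_marker_catalog()].
#'
#' @param truth a [simulate_truth()] object.
#' @param refs an [lcm_reference_set()].
#' @param cells the list returned by [simulate_cells()].
#' @param out_dir output directory (created if needed).
#' @param source label recorded in the marker catalog's `source` column.
#' @return named character vector of the written paths, invisibly.
#' @export
write_synthetic_dataset <- function(truth, refs, cells, out_dir,
                                    source = "synthetic") {
  stopifnot(inherits(truth, "synthetic_truth"),
            inherits(refs, "lcm_reference_set"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    cells = file.path(out_dir, "cells"),
    references = file.path(out_dir, "lcm_references.tsv"),
    markers = file.path(out_dir, "markers.tsv"),
    truth = file.path(out_dir, "truth.tsv")
  )
  write_mtx_triplet(cells$counts, paths[["cells"]])
  write_dense_tsv(refs$matrix, paths[["references"]])
  catalog <- data.frame(gene = truth$marker_table$gene,
                        claimed_type = truth$marker_table$true_type,
                        source = if (nrow(truth$marker_table)) source
                                 else character(0))
  write.table(catalog, paths[["markers"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(cell_id = colnames(cells$counts),
                         true_type = cells$cell_labels),
              paths[["truth"]], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
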