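#' Correlate every single cell with every reference sample (round one)
#'
#' For each cell, a correlation coefficient is computed against each LCM
#' reference sample over the aligned gene space (the intersection of gene
#' ids, optionally restricted to `gene_subset`). Spearman (the default) is
#' robust to the mean-variance mismatch between bulk and single-cell
#' profiles; Pearson on log-CPM is available as an alternative. References
#' are kept per replicate so downstream tests can form replicate-level
#' groups.
#'
#' Cells whose aligned expression vector is constant have no defined
#' correlation; their row is set to `NA` and counted in `n_flagged` rather
#' than silently dropped or zeroed.
#'
#' @param cells a [gene_matrix()] of single-cell expression.
#' @param refs an [lcm_reference_set()]; its matrix must be on the same
#'   layer as `cells`.
#' @param method `"spearman"` or `"pearson"`.
#' @param gene_subset optional character vector restricting the genes used.
#' @param min_shared_genes minimum size of the aligned gene space.
#' @return an object of class `cell_similarity`: list with `r` (cells x
#'   reference samples matrix of coefficients in \[-1, 1\]), `method`,
#'   `n_genes_used`, `ref_meta`, `n_flagged`.
#' @export
compute_cell_similarity <- function(cells, refs,
                                    method = c("spearman", "pearson"),
                                    gene_subset = NULL,
                                    min_shared_genes = 50L) {
  method <- match.arg(method)
  stopifnot(inherits(cells, "gene_matrix"), inherits(refs, "lcm_reference_set"))
  if (gem_layer(cells) != gem_layer(refs$matrix)) {
    stop("cells (", gem_layer(cells), ") and references (",
         gem_layer(refs$matrix), ") must be on the same layer", call. = FALSE)
  }
  al <- align_genes(cells, refs$matrix)
  if (!is.null(gene_subset)) {
    keep <- intersect(rownames(al$a), gene_subset)
    if (length(keep) == 0L) {
      stop("gene_subset shares no genes with the aligned matrices",
           call. = FALSE)
    }
    al$a <- gene_matrix(as.matrix(unclass(al$a))[keep, , drop = FALSE],
                        layer = gem_layer(al$a))
    al$b <- gene_matrix(as.matrix(unclass(al$b))[keep, , drop = FALSE],
                        layer = gem_layer(al$b))
    al$n_shared <- length(keep)
  }
  if (al$n_shared < min_shared_genes) {
    stop(sprintf("only %d shared genes; need >= %d", al$n_shared,
                 min_shared_genes), call. = FALSE)
  }
  x <- as.matrix(unclass(al$a))
  y <- as.matrix(unclass(al$b))
  const_cells <- apply(x, 2L, function(v) max(v) == min(v))
  const_refs <- apply(y, 2L, function(v) max(v) == min(v))
  r <- suppressWarnings(cor(x, y, method = method))
  r[const_cells, ] <- NA_real_
  r[, const_refs] <- NA_real_
  structure(list(r = r, method = method, n_genes_used = al$n_shared,
                 ref_meta = refs$sample_meta,
                 n_flagged = sum(const_cells)),
            class = "cell_similarity")
}

#' @export
print.cell_similarity <- function(x, ...) {
  cat(sprintf(
    "<cell_similarity> %d cells x %d references (%s over %d genes, %d cell(s) flagged)\n",
    nrow(x$r), ncol(x$r), x$method, x$n_genes_used, x$n_flagged))
  invisible(x)
}

#' Write a first-round similarity table
#'
#' TSV with a two-row header (cell type, then replicate index of each
#' reference sample) above the cells-by-references coefficient matrix.
#'
#' @param sim a [compute_cell_similarity()] result.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_similarity_tsv <- function(sim, path) {
  stopifnot(inherits(sim, "cell_similarity"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("cell_type", sim$ref_meta$cell_type), collapse = "\t"),
             con)
  writeLines(paste(c("replicate", sim$ref_meta$replicate), collapse = "\t"),
             con)
  writeLines(paste(c("cell_id", sim$ref_meta$sample_id), collapse = "\t"),
             con)
  body <- cbind(rownames(sim$r),
                format(sim$r, digits = 15, trim = TRUE, scientific = FALSE))
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  invisible(path)
}
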