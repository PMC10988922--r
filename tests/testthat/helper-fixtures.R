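# Small in-code fixtures shared across test files.

tiny_matrix <- function(values, genes = NULL, samples = NULL,
                        layer = "raw") {
  if (is.null(genes)) genes <- sprintf("g%d", seq_len(nrow(values)))
  if (is.null(samples)) samples <- sprintf("s%d", seq_len(ncol(values)))
  dimnames(values) <- list(genes, samples)
  gene_matrix(values, layer = layer)
}

# a complete small synthetic study: truth + references + cells, normalized
small_study <- function(seed = 1, n_genes = 400, markers_per_type = 5,
                        log2_fold_change = 3, cells_per_type = 60,
                        mean_depth = 3000) {
  truth <- simulate_truth(n_genes = n_genes,
                          markers_per_type = markers_per_type,
                          log2_fold_change = log2_fold_change, seed = seed)
  refs <- simulate_lcm_references(truth, seed = seed + 100)
  cells <- simulate_cells(truth, cells_per_type = cells_per_type,
                          mean_depth = mean_depth, seed = seed + 200)
  list(truth = truth, refs = refs, cells = cells,
       cells_log = normalize_matrix(cells$counts, "logcpm"),
       refs_log = lcm_reference_set(
         normalize_matrix(refs$matrix, "logcpm"), refs$sample_meta),
       catalog = marker_catalog(data.frame(
         gene = truth$marker_table$gene,
         claimed_type = truth$marker_table$true_type,
         source = rep("synthetic", nrow(truth$marker_table)))))
}
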