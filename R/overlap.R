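#' Expressed-gene overlap between two datasets
#'
#' Detects the expressed-gene complement of each raw count matrix via
#' [detect_expressed_genes()] and reports how much the two sets overlap.
#' Two metrics are computed and both are always reported so the choice is
#' auditable: `min_denominator` divides the intersection by the smaller set
#' (the conventional "overlap rate of the smaller set") and `jaccard`
#' divides it by the union. `jaccard <= min_denominator` always holds, and
#' both are symmetric in the two inputs.
#'
#' @param a,b raw-layer [gene_matrix()] objects.
#' @param metric which metric to report as `value`.
#' @param min_count,min_samples detection thresholds, see
#'   [detect_expressed_genes()].
#' @return an object of class `overlap_result`: list with `metric`, `value`,
#'   `min_denominator`, `jaccard`, the set sizes `n_a`, `n_b`,
#'   `n_intersection`, `n_union`, and the detection parameters.
#' @examples
#' m <- gene_matrix(matrix(1, 4, 2, dimnames = list(paste0("g", 1:4),
#'                                                  c("s1", "s2"))))
#' expressed_gene_overlap(m, m)$value  # 1
#' @export
expressed_gene_overlap <- function(a, b,
                                   metric = c("min_denominator", "jaccard"),
                                   min_count = 1L, min_samples = 1L) {
  metric <- match.arg(metric)
  ga <- detect_expressed_genes(a, min_count, min_samples)
  gb <- detect_expressed_genes(b, min_count, min_samples)
  if (length(ga) == 0L || length(gb) == 0L) {
    stop("no expressed genes detected in ",
         if (length(ga) == 0L) "the first" else "the second",
         " dataset at these thresholds", call. = FALSE)
  }
  n_int <- length(intersect(ga, gb))
  n_union <- length(union(ga, gb))
  res <- list(
    metric = metric,
    min_denominator = n_int / min(length(ga), length(gb)),
    jaccard = n_int / n_union,
    n_a = length(ga), n_b = length(gb),
    n_intersection = n_int, n_union = n_union,
    min_count = min_count, min_samples = min_samples)
  res$value <- res[[metric]]
  structure(res, class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    "<overlap_result> %s = %.4f (min_denominator %.4f, jaccard %.4f; |A|=%d, |B|=%d, shared=%d)\n",
    x$metric, x$value, x$min_denominator, x$jaccard,
    x$n_a, x$n_b, x$n_intersection))
  invisible(x)
}
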