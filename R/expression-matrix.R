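#' Construct a gene expression matrix
#'
#' A light container for a genes-by-samples expression matrix carrying a
#' layer tag that records what the values are: `"raw"` (unnormalized input,
#' integer counts for single-cell data), `"cpm"` (each column scaled to a
#' total of 1e6), or `"logcpm"` (`log2(cpm + 1)`).
#'
#' @param values numeric matrix, genes in rows, samples (cells or bulk
#'   libraries) in columns; must carry unique rownames (gene ids) and unique
#'   colnames (sample ids).
#' @param layer one of `"raw"`, `"cpm"`, `"logcpm"`.
#' @return an object of class `gene_matrix`: the matrix with a `layer`
#'   attribute.
#' @examples
#' m <- gene_matrix(matrix(0:5, nrow = 3,
#'                         dimnames = list(paste0("g", 1:3), c("a", "b"))))
#' gem_layer(m)
#' @export
gene_matrix <- function(values, layer = c("raw", "cpm", "logcpm")) {
  layer <- match.arg(layer)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  gid <- rownames(values)
  sid <- colnames(values)
  if (is.null(gid) || is.null(sid)) {
    stop("`values` must have gene ids as rownames and sample ids as colnames",
         call. = FALSE)
  }
  dup <- gid[duplicated(gid)]
  if (length(dup)) {
    stop("duplicate gene id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  dup <- sid[duplicated(sid)]
  if (length(dup)) {
    stop("duplicate sample id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("expression values must be finite and non-missing", call. = FALSE)
  }
  if (layer != "logcpm" && any(values < 0)) {
    stop("raw and cpm layers must be non-negative", call. = FALSE)
  }
  structure(values, layer = layer, class = c("gene_matrix", "matrix", "array"))
}

#' @rdname gene_matrix
#' @param m a `gene_matrix`.
#' @export
gem_layer <- function(m) attr(m, "layer")

#' @export
as.matrix.gene_matrix <- function(x, ...) {
  attr(x, "layer") <- NULL
  class(x) <- NULL
  x
}

#' @export
print.gene_matrix <- function(x, ...) {
  cat(sprintf("<gene_matrix> %d genes x %d samples, layer = %s\n",
              nrow(x), ncol(x), gem_layer(x)))
  invisible(x)
}

assert_layer <- function(m, layer, what) {
  if (!inherits(m, "gene_matrix")) stop(what, " must be a gene_matrix", call. = FALSE)
  if (gem_layer(m) != layer) {
    stop(what, " must be on the '", layer, "' layer, got '", gem_layer(m), "'",
         call. = FALSE)
  }
  invisible(m)
}

#' Read an expression matrix from disk
#'
#' Supports the 10x-style MatrixMarket triplet (a directory containing
#' `matrix.mtx`, `features.tsv`, `barcodes.tsv`; MTX coordinates are 1-based
#' per the MatrixMarket standard) and a dense TSV (header row of sample ids,
#' first column gene ids). The returned layer is always `"raw"`; ids are kept
#' in file order.
#'
#' @param path for `mtx_triplet`, the directory holding the three files; for
#'   `dense_tsv`, the TSV file.
#' @param format `"mtx_triplet"` or `"dense_tsv"`.
#' @param transpose logical; set `TRUE` when a dense TSV stores genes in
#'   columns instead of rows.
#' @return a [gene_matrix()] with `layer = "raw"`.
#' @export
read_matrix <- function(path, format = c("mtx_triplet", "dense_tsv"),
                        transpose = FALSE) {
  format <- match.arg(format)
  if (format == "mtx_triplet") {
    files <- file.path(path, c("matrix.mtx", "features.tsv", "barcodes.tsv"))
    missing <- files[!file.exists(files)]
    if (length(missing)) {
      stop("missing file(s): ", paste(missing, collapse = ", "), call. = FALSE)
    }
    mm <- as.matrix(Matrix::readMM(files[1]))
    features <- read.delim(files[2], header = FALSE,
                           colClasses = "character")[[1]]
    barcodes <- read.delim(files[3], header = FALSE,
                           colClasses = "character")[[1]]
    if (nrow(mm) != length(features)) {
      stop(sprintf("matrix.mtx has %d rows but features.tsv has %d entries",
                   nrow(mm), length(features)), call. = FALSE)
    }
    if (ncol(mm) != length(barcodes)) {
      stop(sprintf("matrix.mtx has %d columns but barcodes.tsv has %d entries",
                   ncol(mm), length(barcodes)), call. = FALSE)
    }
    dimnames(mm) <- list(features, barcodes)
    gene_matrix(mm, layer = "raw")
  } else {
    df <- read.delim(path, header = TRUE, check.names = FALSE)
    ids <- as.character(df[[1]])
    vals <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(vals) <- "double"
    rownames(vals) <- ids
    if (isTRUE(transpose)) vals <- t(vals)
    gene_matrix(vals, layer = "raw")
  }
}

#' Write an expression matrix
#'
#' `write_dense_tsv()` writes the dense TSV dialect read by [read_matrix()]
#' (header row of sample ids, first column `gene` holding gene ids).
#' `write_mtx_triplet()` writes the 10x-style MatrixMarket triplet; values
#' must be integer counts.
#'
#' @param m a [gene_matrix()].
#' @param path output TSV file (`write_dense_tsv`) or directory
#'   (`write_mtx_triplet`).
#' @return the path, invisibly.
#' @export
write_dense_tsv <- function(m, path) {
  stopifnot(inherits(m, "gene_matrix"))
  df <- data.frame(gene = rownames(m), as.matrix(unclass(m)),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dense_tsv
#' @export
write_mtx_triplet <- function(m, path) {
  stopifnot(inherits(m, "gene_matrix"))
  v <- as.matrix(unclass(m))
  if (any(v != round(v))) {
    stop("MTX triplet output requires integer counts", call. = FALSE)
  }
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  sp <- Matrix::Matrix(v, sparse = TRUE)
  Matrix::writeMM(sp, file.path(path, "matrix.mtx"))
  writeLines(rownames(m), file.path(path, "features.tsv"))
  writeLines(colnames(m), file.path(path, "barcodes.tsv"))
  invisible(path)
}

#' Normalize a raw expression matrix
#'
#' `cpm` rescales every column to a total of 1e6; `logcpm` additionally
#' applies `log2(x + 1)`. Columns whose raw total is zero carry no
#' information and are dropped with a warning.
#'
#' @param m a raw-layer [gene_matrix()].
#' @param method `"cpm"` or `"logcpm"`.
#' @return a [gene_matrix()] with the updated layer tag.
#' @examples
#' m <- gene_matrix(matrix(c(1, 1, 2), ncol = 1,
#'                         dimnames = list(paste0("g", 1:3), "s1")))
#' normalize_matrix(m, "cpm")[, 1]
#' @export
normalize_matrix <- function(m, method = c("cpm", "logcpm")) {
  method <- match.arg(method)
  assert_layer(m, "raw", "`m`")
  v <- as.matrix(unclass(m))
  totals <- colSums(v)
  zero <- totals == 0
  if (any(zero)) {
    warning(sum(zero), " zero-total column(s) dropped: ",
            paste(colnames(v)[zero], collapse = ", "), call. = FALSE)
    v <- v[, !zero, drop = FALSE]
    totals <- totals[!zero]
  }
  if (ncol(v) == 0L) stop("no non-zero columns to normalize", call. = FALSE)
  out <- sweep(v, 2L, totals, "/") * 1e6
  if (method == "logcpm") out <- log2(out + 1)
  gene_matrix(out, layer = method)
}

#' Restrict two matrices to their shared gene space
#'
#' Both matrices are subset to the intersection of their gene ids and the
#' rows are put in identical (lexicographic, C-locale) order so that
#' correlation over genes is well defined.
#'
#' @param a,b [gene_matrix()] objects.
#' @return a list with elements `a`, `b` (the aligned matrices) and
#'   `n_shared` (intersection size).
#' @export
align_genes <- function(a, b) {
  stopifnot(inherits(a, "gene_matrix"), inherits(b, "gene_matrix"))
  shared <- sort_c(intersect(rownames(a), rownames(b)))
  if (length(shared) == 0L) {
    stop("no shared genes between the two matrices", call. = FALSE)
  }
  list(a = gene_matrix(as.matrix(unclass(a))[shared, , drop = FALSE],
                       layer = gem_layer(a)),
       b = gene_matrix(as.matrix(unclass(b))[shared, , drop = FALSE],
                       layer = gem_layer(b)),
       n_shared = length(shared))
}

#' Detect expressed genes
#'
#' A gene counts as expressed when it reaches at least `min_count` in at
#' least `min_samples` columns of the raw count matrix.
#'
#' @param m a raw-layer [gene_matrix()].
#' @param min_count minimum count per sample (>= 1).
#' @param min_samples minimum number of samples reaching `min_count` (>= 1).
#' @return character vector of expressed gene ids (file order).
#' @export
detect_expressed_genes <- function(m, min_count = 1L, min_samples = 1L) {
  assert_layer(m, "raw", "`m`")
  stopifnot(min_count >= 1, min_samples >= 1)
  v <- as.matrix(unclass(m))
  n_hit <- rowSums(v >= min_count)
  rownames(v)[n_hit >= min_samples]
}

#' Construct an LCM reference set
#'
#' Bundles a bulk reference expression matrix with per-sample metadata: the
#' cell type each LCM sample was dissected from and its replicate index.
#'
#' @param matrix a [gene_matrix()] of reference profiles, one column per
#'   reference sample.
#' @param sample_meta data.frame with columns `sample_id`, `cell_type`,
#'   `replicate`, one row per column of `matrix` (matched by `sample_id`).
#' @return an object of class `lcm_reference_set`.
#' @export
lcm_reference_set <- function(matrix, sample_meta) {
  stopifnot(inherits(matrix, "gene_matrix"), is.data.frame(sample_meta))
  need <- c("sample_id", "cell_type", "replicate")
  if (!all(need %in% names(sample_meta))) {
    stop("sample_meta needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!setequal(sample_meta$sample_id, colnames(matrix)) ||
      nrow(sample_meta) != ncol(matrix)) {
    stop("sample_meta$sample_id must match the matrix columns exactly",
         call. = FALSE)
  }
  sample_meta <- sample_meta[match(colnames(matrix), sample_meta$sample_id), ]
  rownames(sample_meta) <- NULL
  rep_key <- paste(sample_meta$cell_type, sample_meta$replicate)
  if (anyDuplicated(rep_key)) {
    stop("replicate indices must be unique within a cell type", call. = FALSE)
  }
  structure(list(matrix = matrix, sample_meta = sample_meta),
            class = "lcm_reference_set")
}

#' @export
print.lcm_reference_set <- function(x, ...) {
  tab <- table(x$sample_meta$cell_type)
  cat(sprintf("<lcm_reference_set> %d genes, %d samples (%s)\n",
              nrow(x$matrix), ncol(x$matrix),
              paste(sprintf("%s x%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Read LCM reference profiles from a dense TSV
#'
#' Sample metadata is taken from the column names, which must follow the
#' `<cell_type>_rep<k>` convention used by [write_synthetic_dataset()], or be
#' supplied explicitly.
#'
#' @param path dense TSV (as written by [write_dense_tsv()]).
#' @param sample_meta optional data.frame overriding the parsed metadata.
#' @return an [lcm_reference_set()].
#' @export
read_lcm_references <- function(path, sample_meta = NULL) {
  m <- read_matrix(path, format = "dense_tsv")
  if (is.null(sample_meta)) {
    ids <- colnames(m)
    ok <- grepl("^.+_rep[0-9]+$", ids)
    if (!all(ok)) {
      stop("cannot parse cell type/replicate from sample id(s): ",
           paste(ids[!ok], collapse = ", "),
           "; supply `sample_meta` explicitly", call. = FALSE)
    }
    sample_meta <- data.frame(
      sample_id = ids,
      cell_type = sub("_rep[0-9]+$", "", ids),
      replicate = as.integer(sub("^.+_rep", "", ids))
    )
  }
  lcm_reference_set(m, sample_meta)
}
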