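#' Read a marker catalog
#'
#' A marker catalog is a TSV with columns `gene`, `claimed_type`, `source`
#' (a free-text study label). Gene ids must be unique within a source.
#'
#' @param path TSV file.
#' @return data.frame of class `marker_catalog`.
#' @export
read_marker_catalog <- function(path) {
  df <- read.delim(path, header = TRUE, colClasses = "character")
  marker_catalog(df)
}

#' @rdname read_marker_catalog
#' @param df data.frame with columns `gene`, `claimed_type`, `source`.
#' @export
marker_catalog <- function(df) {
  need <- c("gene", "claimed_type", "source")
  if (!all(need %in% names(df))) {
    stop("marker catalog needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df <- as.data.frame(df)[, need]
  key <- paste(df$source, df$gene)
  if (anyDuplicated(key)) {
    stop("duplicate gene id(s) within a source: ",
         paste(unique(df$gene[duplicated(key)]), collapse = ", "),
         call. = FALSE)
  }
  class(df) <- c("marker_catalog", "data.frame")
  df
}

#' Second-round correlations: marker expression vs cell similarity
#'
#' For each marker gene g and each reference sample s, computes the
#' correlation, across cells, between the expression of g and the cells'
#' first-round similarity to s. A marker that truly labels a type should
#' correlate positively with similarity to that type's references only.
#'
#' Catalog genes absent from `cells` are skipped (recorded in the `skipped`
#' attribute), and markers constant across all cells are flagged as `NA`
#' rows rather than given a coefficient.
#'
#' @param sim a [compute_cell_similarity()] result; its cells must be
#'   exactly the columns of `cells`.
#' @param cells the [gene_matrix()] the similarities were computed from (or
#'   the same cells on another layer).
#' @param catalog a [marker_catalog()] (or data.frame with its columns).
#' @param method `"spearman"` or `"pearson"`.
#' @return markers-by-references numeric matrix of correlations, with
#'   attributes `skipped` (missing gene ids) and `constant` (flagged ids).
#' @export
second_round_correlations <- function(sim, cells, catalog,
                                      method = c("spearman", "pearson")) {
  method <- match.arg(method)
  stopifnot(inherits(sim, "cell_similarity"), inherits(cells, "gene_matrix"))
  catalog <- marker_catalog(catalog)
  if (!identical(rownames(sim$r), colnames(cells))) {
    stop("cell ids of `sim` and `cells` must be identical and in order",
         call. = FALSE)
  }
  genes <- unique(catalog$gene)
  present <- genes[genes %in% rownames(cells)]
  skipped <- setdiff(genes, present)
  if (length(skipped)) {
    message(length(skipped), " catalog gene(s) absent from the cell matrix; skipped")
  }
  if (length(present) == 0L) {
    out <- matrix(numeric(0), nrow = 0, ncol = ncol(sim$r),
                  dimnames = list(NULL, colnames(sim$r)))
    attr(out, "skipped") <- skipped
    attr(out, "constant") <- character(0)
    return(out)
  }
  expr <- t(as.matrix(unclass(cells))[present, , drop = FALSE])
  const <- present[apply(expr, 2L, function(v) max(v) == min(v))]
  r <- suppressWarnings(cor(expr, sim$r, method = method))
  r[const, ] <- NA_real_
  attr(r, "skipped") <- skipped
  attr(r, "constant") <- const
  r
}

#' Two-sample t-test (pooled or Welch)
#'
#' `student` is the classical pooled-variance two-sample t-test; `welch`
#' does not assume equal variances. Two-sided p-values come from the t
#' distribution. If both groups are constant the test is degenerate:
#' equal constants give `t = 0, p = 1`; unequal constants give an infinite
#' statistic and `p = 0`.
#'
#' @param group_a,group_b numeric vectors of length >= 2.
#' @param variant `"student"` or `"welch"`.
#' @return list with elements `t` and `p`.
#' @examples
#' two_sample_ttest(c(1, 2, 3), c(4, 5, 6))
#' @export
two_sample_ttest <- function(group_a, group_b,
                             variant = c("student", "welch")) {
  variant <- match.arg(variant)
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  if (anyNA(group_a) || anyNA(group_b)) {
    stop("groups must not contain missing values", call. = FALSE)
  }
  if (sd(group_a) == 0 && sd(group_b) == 0) {
    d <- mean(group_a) - mean(group_b)
    if (d == 0) return(list(t = 0, p = 1))
    return(list(t = sign(d) * Inf, p = 0))
  }
  fit <- t.test(group_a, group_b, var.equal = variant == "student")
  list(t = unname(fit$statistic), p = fit$p.value)
}

#' Map a p-value to a significance star string
#'
#' The convention is strict: `p < 0.001` gives `"***"`, `p < 0.01` gives
#' `"**"`, `p < 0.05` gives `"*"`, anything else (including `p = 0.05`
#' exactly) gives `"ns"`.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return character vector of star strings.
#' @examples
#' significance_stars(c(0.0005, 0.005, 0.03, 0.05))
#' @export
significance_stars <- function(p) {
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  out <- rep("ns", length(p))
  out[p < 0.05] <- "*"
  out[p < 0.01] <- "**"
  out[p < 0.001] <- "***"
  out
}

#' Call the cell type a marker annotates
#'
#' Given replicate-level second-round correlations for each type, the call
#' is built around the type with the largest mean r (`T*`): if that mean is
#' not positive the marker annotates nothing (`"none"`); otherwise the call
#' is `T*` together with every type whose correlations are not significantly
#' below `T*`'s (two-sample test p >= `alpha`). A singleton set is a unique
#' call; ties in the maximal mean are declared ambiguous, never broken by
#' order.
#'
#' @param r_by_type named list of numeric vectors, one per type: the
#'   marker's second-round correlations against each replicate reference of
#'   that type (>= 2 replicates each).
#' @param alpha significance level for the pairwise comparisons.
#' @param variant t-test variant, `"student"` or `"welch"`.
#' @return list with `call` (character vector of annotated types; empty for
#'   "none"), `status` (`"unique"`, `"ambiguous"` or `"none"`), and
#'   `mean_r` (named vector).
#' @export
call_marker_type <- function(r_by_type, alpha = 0.05,
                             variant = c("student", "welch")) {
  variant <- match.arg(variant)
  if (length(r_by_type) < 2L) stop("need at least 2 types", call. = FALSE)
  if (is.null(names(r_by_type)) || any(!nzchar(names(r_by_type)))) {
    stop("`r_by_type` must be a named list", call. = FALSE)
  }
  if (any(vapply(r_by_type, length, 1L) < 2L)) {
    stop("each type needs >= 2 replicate correlations", call. = FALSE)
  }
  mean_r <- vapply(r_by_type, mean, numeric(1))
  best <- names(mean_r)[mean_r == max(mean_r)]
  if (max(mean_r) <= 0) {
    return(list(call = character(0), status = "none", mean_r = mean_r))
  }
  anchor <- best[1L]
  others <- setdiff(names(mean_r), best)
  keep <- best
  for (ty in others) {
    p <- two_sample_ttest(r_by_type[[anchor]], r_by_type[[ty]],
                          variant = variant)$p
    if (p >= alpha) keep <- c(keep, ty)
  }
  keep <- names(mean_r)[names(mean_r) %in% keep]  # stable type order
  list(call = keep,
       status = if (length(keep) == 1L) "unique" else "ambiguous",
       mean_r = mean_r)
}

#' Full second-round concordance analysis
#'
#' Runs [second_round_correlations()], groups the per-reference coefficients
#' by cell type at replicate level, performs all ordered between-type
#' t-tests with significance stars, calls each marker's annotated type(s)
#' via [call_marker_type()], and flags consistency against the catalog's
#' claimed types. A marker is `consistent` only when its call is unique and
#' equals the claimed type.
#'
#' @inheritParams second_round_correlations
#' @param alpha significance level for the call rule and stars.
#' @param variant t-test variant (`"student"` default, matching the
#'   conventional Student's t-test; `"welch"` optional).
#' @param p_adjust `"none"` (default; stars reflect raw p-values) or
#'   `"BH"` for Benjamini-Hochberg, reported in an extra column.
#' @param pooled logical; if `TRUE`, the call rule compares the best type
#'   against all other types' replicates pooled into one group instead of
#'   pairwise.
#' @return an object of class `concordance_table`: list with
#'   `r` (marker x reference matrix), `per_type` (marker x type mean and
#'   replicate r's), `tests` (pairwise t, p, optional adjusted p, stars),
#'   `calls` (per-marker call, status, consistency), `skipped`.
#' @export
concordance_analysis <- function(sim, cells, catalog,
                                 method = c("spearman", "pearson"),
                                 alpha = 0.05,
                                 variant = c("student", "welch"),
                                 p_adjust = c("none", "BH"),
                                 pooled = FALSE) {
  method <- match.arg(method)
  variant <- match.arg(variant)
  p_adjust <- match.arg(p_adjust)
  catalog <- marker_catalog(catalog)
  r <- second_round_correlations(sim, cells, catalog, method = method)
  skipped <- attr(r, "skipped")
  constant <- attr(r, "constant")
  types <- unique(sim$ref_meta$cell_type)
  bad_claim <- setdiff(unique(catalog$claimed_type), types)
  if (length(bad_claim)) {
    stop("claimed_type(s) absent from the reference set: ",
         paste(bad_claim, collapse = ", "), call. = FALSE)
  }
  type_cols <- lapply(setNames(types, types),
                      function(ty) which(sim$ref_meta$cell_type == ty))
  usable <- setdiff(rownames(r), constant)

  per_type <- list(); tests <- list(); calls <- list()
  for (g in rownames(r)) {
    rg <- r[g, ]
    by_type <- lapply(type_cols, function(ix) unname(rg[ix]))
    for (ty in types) {
      per_type[[length(per_type) + 1L]] <- data.frame(
        gene = g, cell_type = ty, mean_r = mean(by_type[[ty]]),
        replicate_r = paste(format(by_type[[ty]], digits = 6, trim = TRUE),
                            collapse = ","))
    }
    if (!(g %in% usable)) next
    cmb <- utils::combn(types, 2L)
    for (k in seq_len(ncol(cmb))) {
      tt <- two_sample_ttest(by_type[[cmb[1L, k]]], by_type[[cmb[2L, k]]],
                             variant = variant)
      tests[[length(tests) + 1L]] <- data.frame(
        gene = g, type_a = cmb[1L, k], type_b = cmb[2L, k],
        t = tt$t, p = tt$p)
    }
    cl <- if (pooled) {
      pooled_call(by_type, alpha = alpha, variant = variant)
    } else {
      call_marker_type(by_type, alpha = alpha, variant = variant)
    }
    calls[[length(calls) + 1L]] <- data.frame(
      gene = g,
      call = if (cl$status == "none") "none"
             else paste(cl$call, collapse = "+"),
      status = cl$status, top_mean_r = max(cl$mean_r))
  }

  per_type <- do.call(rbind, per_type) %||%
    data.frame(gene = character(0), cell_type = character(0),
               mean_r = numeric(0), replicate_r = character(0))
  tests <- do.call(rbind, tests) %||%
    data.frame(gene = character(0), type_a = character(0),
               type_b = character(0), t = numeric(0), p = numeric(0))
  if (nrow(tests)) {
    if (p_adjust == "BH") tests$p_bh <- stats::p.adjust(tests$p, "BH")
    tests$stars <- significance_stars(tests$p)
  } else {
    tests$stars <- character(0)
  }
  calls <- do.call(rbind, calls) %||%
    data.frame(gene = character(0), call = character(0),
               status = character(0), top_mean_r = numeric(0))

  # one catalog row per (source, gene); markers can recur across sources
  out_calls <- catalog
  ix <- match(out_calls$gene, calls$gene)
  out_calls$call <- ifelse(is.na(ix), NA_character_, calls$call[ix])
  out_calls$status <- ifelse(out_calls$gene %in% skipped, "skipped",
                       ifelse(out_calls$gene %in% constant, "constant",
                              calls$status[ix]))
  out_calls$consistent <- !is.na(out_calls$call) &
    out_calls$status == "unique" & out_calls$call == out_calls$claimed_type
  rownames(out_calls) <- NULL
  class(out_calls) <- "data.frame"

  structure(list(r = r, per_type = per_type, tests = tests,
                 calls = out_calls,
                 skipped = skipped, constant = constant,
                 params = list(method = method, alpha = alpha,
                               variant = variant, p_adjust = p_adjust,
                               pooled = pooled)),
            class = "concordance_table")
}

# best type vs all other replicates pooled into one comparison group
pooled_call <- function(by_type, alpha, variant) {
  mean_r <- vapply(by_type, mean, numeric(1))
  best <- names(mean_r)[mean_r == max(mean_r)]
  if (max(mean_r) <= 0) {
    return(list(call = character(0), status = "none", mean_r = mean_r))
  }
  if (length(best) > 1L) {
    return(list(call = best, status = "ambiguous", mean_r = mean_r))
  }
  rest <- unlist(by_type[setdiff(names(by_type), best)], use.names = FALSE)
  p <- two_sample_ttest(by_type[[best]], rest, variant = variant)$p
  if (p < alpha) list(call = best, status = "unique", mean_r = mean_r)
  else list(call = names(mean_r), status = "ambiguous", mean_r = mean_r)
}

#' @export
print.concordance_table <- function(x, ...) {
  cat(sprintf(
    "<concordance_table> %d markers x %d references; %d unique, %d ambiguous, %d none, %d skipped/constant\n",
    nrow(x$r), ncol(x$r),
    sum(x$calls$status == "unique"), sum(x$calls$status == "ambiguous"),
    sum(x$calls$status == "none"),
    sum(x$calls$status %in% c("skipped", "constant"))))
  invisible(x)
}

#' Summarize marker consistency per source study
#'
#' Per source: how many markers received a unique call matching the claimed
#' type (consistent), a unique call for a different type (inconsistent), an
#' ambiguous multi-type call, no call ("none"), or were skipped/constant.
#'
#' @param concordance a [concordance_analysis()] result.
#' @return data.frame with one row per source plus the per-marker `calls`
#'   table as attribute `per_marker`.
#' @export
evaluate_catalog <- function(concordance) {
  stopifnot(inherits(concordance, "concordance_table"))
  calls <- concordance$calls
  if (nrow(calls) == 0L) {
    out <- data.frame(source = character(0), n_markers = integer(0),
                      consistent = integer(0), inconsistent = integer(0),
                      ambiguous = integer(0), none = integer(0),
                      skipped = integer(0))
    attr(out, "per_marker") <- calls
    return(out)
  }
  split_rows <- split(calls, calls$source)
  out <- do.call(rbind, lapply(names(split_rows), function(src) {
    d <- split_rows[[src]]
    data.frame(
      source = src,
      n_markers = nrow(d),
      consistent = sum(d$consistent),
      inconsistent = sum(d$status == "unique" & !d$consistent),
      ambiguous = sum(d$status == "ambiguous"),
      none = sum(d$status == "none"),
      skipped = sum(d$status %in% c("skipped", "constant")))
  }))
  rownames(out) <- NULL
  attr(out, "per_marker") <- calls
  out
}
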