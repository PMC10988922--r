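#' Run the full validation pipeline from a declarative config
#'
#' Orchestrates preprocess -> first-round similarity -> second-round
#' concordance (and, when a second dataset is given, the expressed-gene
#' overlap comparison). Inputs come either from files or from a `simulate`
#' block that generates a synthetic dataset in place. Every option and seed
#' (including defaults) is echoed into `run_log.json` so no analysis choice
#' is silent, and the whole run is deterministic given the config.
#'
#' Config keys (a named list, or the path of a YAML file):
#' \describe{
#'   \item{simulate}{list of [simulate_truth()] / [simulate_lcm_references()]
#'     / [simulate_cells()] arguments (`n_types`, `n_genes`,
#'     `markers_per_type`, `log2_fold_change`, `base_mean_log_sd`,
#'     `n_replicates`, `replicate_noise_sd`, `cells_per_type`, `mean_depth`,
#'     `nb_dispersion`, `seed`). Mutually exclusive with `inputs`.}
#'   \item{inputs}{list with `cells` (list: `path`, `format`, `transpose`),
#'     `references` (path), `markers` (path).}
#'   \item{layer}{working layer for the correlations: `"logcpm"` (default),
#'     `"cpm"`, or `"raw"`.}
#'   \item{method}{correlation method, `"spearman"` (default) or
#'     `"pearson"`.}
#'   \item{alpha, test, p_adjust, pooled}{see [concordance_analysis()].}
#'   \item{min_shared_genes}{see [compute_cell_similarity()].}
#'   \item{overlap}{optional list: `with` (list: `path`, `format`), plus
#'     `metric`, `min_count`, `min_samples`.}
#'   \item{out_dir}{output directory.}
#' }
#'
#' Outputs written to `out_dir`: `similarity.tsv`, `concordance.tsv`,
#' `summary_by_source.tsv`, `report.txt`, `run_log.json`, and `overlap.json`
#' when an overlap comparison ran. On a stage failure, a `MANIFEST` file
#' marks the run incomplete and the error names the failed stage.
#'
#' @param config named list or YAML file path.
#' @return (invisibly) a list with the in-memory results (`similarity`,
#'   `concordance`, `summary`, optionally `overlap`) and `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  cfg <- pipeline_defaults(config)
  validate_config(cfg)

  out_dir <- cfg$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- file.path(out_dir, "MANIFEST")
  writeLines(c("status: incomplete"), manifest)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  # ---- preprocess -----------------------------------------------------
  dat <- stage("preprocess", {
    if (!is.null(cfg$simulate)) {
      sb <- cfg$simulate
      truth <- simulate_truth(n_types = sb$n_types, n_genes = sb$n_genes,
                              markers_per_type = sb$markers_per_type,
                              log2_fold_change = sb$log2_fold_change,
                              base_mean_log_sd = sb$base_mean_log_sd,
                              seed = sb$seed)
      refs <- simulate_lcm_references(truth, n_replicates = sb$n_replicates,
                                      replicate_noise_sd = sb$replicate_noise_sd,
                                      seed = sb$seed + 1L)
      cells <- simulate_cells(truth, cells_per_type = sb$cells_per_type,
                              mean_depth = sb$mean_depth,
                              nb_dispersion = sb$nb_dispersion,
                              seed = sb$seed + 2L)
      catalog <- marker_catalog(data.frame(
        gene = truth$marker_table$gene,
        claimed_type = truth$marker_table$true_type,
        source = rep("synthetic", nrow(truth$marker_table))))
      list(cells_raw = cells$counts, refs_raw = refs, catalog = catalog)
    } else {
      ip <- cfg$inputs
      cells_raw <- read_matrix(ip$cells$path,
                               format = ip$cells$format %||% "mtx_triplet",
                               transpose = isTRUE(ip$cells$transpose))
      refs_raw <- read_lcm_references(ip$references)
      catalog <- read_marker_catalog(ip$markers)
      list(cells_raw = cells_raw, refs_raw = refs_raw, catalog = catalog)
    }
  })

  norm <- stage("normalize", {
    if (cfg$layer == "raw") {
      list(cells = dat$cells_raw, refs = dat$refs_raw)
    } else {
      list(cells = normalize_matrix(dat$cells_raw, cfg$layer),
           refs = lcm_reference_set(
             normalize_matrix(dat$refs_raw$matrix, cfg$layer),
             dat$refs_raw$sample_meta))
    }
  })

  # ---- first round ----------------------------------------------------
  sim <- stage("similarity", {
    compute_cell_similarity(norm$cells, norm$refs, method = cfg$method,
                            min_shared_genes = cfg$min_shared_genes)
  })
  write_similarity_tsv(sim, file.path(out_dir, "similarity.tsv"))

  # ---- second round ---------------------------------------------------
  conc <- stage("concordance", {
    concordance_analysis(sim, norm$cells, dat$catalog, method = cfg$method,
                         alpha = cfg$alpha, variant = cfg$test,
                         p_adjust = cfg$p_adjust, pooled = cfg$pooled)
  })
  summary_tab <- evaluate_catalog(conc)
  write_concordance_tsv(conc, file.path(out_dir, "concordance.tsv"))
  write.table(summary_tab, file.path(out_dir, "summary_by_source.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  # ---- optional overlap ----------------------------------------------
  overlap <- NULL
  if (!is.null(cfg$overlap)) {
    overlap <- stage("overlap", {
      ov <- cfg$overlap
      other <- read_matrix(ov$with$path,
                           format = ov$with$format %||% "mtx_triplet",
                           transpose = isTRUE(ov$with$transpose))
      expressed_gene_overlap(dat$cells_raw, other,
                             metric = ov$metric %||% "min_denominator",
                             min_count = ov$min_count %||% 1L,
                             min_samples = ov$min_samples %||% 1L)
    })
    jsonlite::write_json(unclass(overlap),
                         file.path(out_dir, "overlap.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  # ---- report + run log ----------------------------------------------
  write_text_report(conc, summary_tab, file.path(out_dir, "report.txt"),
                    overlap = overlap)
  cfg_log <- cfg
  cfg_log$out_dir <- NULL  # the log lives in out_dir; keep logs path-free
  log <- list(package = "insituanno",
              version = as.character(packageVersion("insituanno")),
              config = cfg_log,
              n_cells = ncol(norm$cells),
              n_references = ncol(norm$refs$matrix),
              n_genes_used = sim$n_genes_used,
              n_cells_flagged = sim$n_flagged,
              n_markers_skipped = length(conc$skipped))
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines("status: complete", manifest)

  invisible(list(similarity = sim, concordance = conc,
                 summary = summary_tab, overlap = overlap,
                 out_dir = out_dir))
}

pipeline_defaults <- function(config) {
  cfg <- list(layer = "logcpm", method = "spearman", alpha = 0.05,
              test = "student", p_adjust = "none", pooled = FALSE,
              min_shared_genes = 50L, simulate = NULL, inputs = NULL,
              overlap = NULL, out_dir = NULL)
  cfg[names(config)] <- config
  if (!is.null(cfg$simulate)) {
    sim_def <- list(n_types = 3L, n_genes = 2000L, markers_per_type = 20L,
                    log2_fold_change = 3, base_mean_log_sd = 1,
                    n_replicates = 3L, replicate_noise_sd = 0.2,
                    cells_per_type = 300L, mean_depth = 5000,
                    nb_dispersion = 0.5, seed = 1L)
    sim_def[names(cfg$simulate)] <- cfg$simulate
    cfg$simulate <- sim_def
  }
  cfg
}

validate_config <- function(cfg) {
  if (is.null(cfg$out_dir)) stop("config must set `out_dir`", call. = FALSE)
  if (is.null(cfg$simulate) && is.null(cfg$inputs)) {
    stop("config must provide either a `simulate` block or `inputs`",
         call. = FALSE)
  }
  if (!is.null(cfg$simulate) && !is.null(cfg$inputs)) {
    stop("`simulate` and `inputs` are mutually exclusive", call. = FALSE)
  }
  if (!is.null(cfg$inputs)) {
    ip <- cfg$inputs
    for (key in c("cells", "references", "markers")) {
      if (is.null(ip[[key]])) {
        stop("config `inputs` is missing `", key, "`", call. = FALSE)
      }
    }
    paths <- c(ip$cells$path, ip$references, ip$markers)
    missing <- paths[!file.exists(paths)]
    if (length(missing)) {
      stop("input path(s) not found: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
  }
  if (!cfg$layer %in% c("raw", "cpm", "logcpm")) {
    stop("`layer` must be raw, cpm or logcpm", call. = FALSE)
  }
  invisible(cfg)
}

#' Write the per-marker concordance table
#'
#' One row per (source, marker) with the claimed type, per-type mean and
#' replicate second-round correlations, pairwise p-values with stars, the
#' call and the consistency flag.
#'
#' @param conc a [concordance_analysis()] result.
#' @param path output TSV.
#' @return the path, invisibly.
#' @export
write_concordance_tsv <- function(conc, path) {
  stopifnot(inherits(conc, "concordance_table"))
  calls <- conc$calls
  if (nrow(calls) == 0L) {
    write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  wide_mean <- stats::reshape(
    conc$per_type[, c("gene", "cell_type", "mean_r")],
    idvar = "gene", timevar = "cell_type", direction = "wide")
  names(wide_mean) <- sub("^mean_r\\.", "mean_r_", names(wide_mean))
  wide_rep <- stats::reshape(
    conc$per_type[, c("gene", "cell_type", "replicate_r")],
    idvar = "gene", timevar = "cell_type", direction = "wide")
  names(wide_rep) <- sub("^replicate_r\\.", "replicate_r_", names(wide_rep))
  tst <- conc$tests
  if (nrow(tst)) {
    tst$pair <- paste0("p_", tst$type_a, "_vs_", tst$type_b)
    wide_p <- stats::reshape(tst[, c("gene", "pair", "p")],
                             idvar = "gene", timevar = "pair",
                             direction = "wide")
    names(wide_p) <- sub("^p\\.", "", names(wide_p))
    tst$spair <- sub("^p_", "stars_", tst$pair)
    wide_s <- stats::reshape(tst[, c("gene", "spair", "stars")],
                             idvar = "gene", timevar = "spair",
                             direction = "wide")
    names(wide_s) <- sub("^stars\\.", "", names(wide_s))
  } else {
    wide_p <- wide_s <- data.frame(gene = character(0))
  }
  out <- Reduce(function(x, y) merge(x, y, by = "gene", all.x = TRUE,
                                     sort = FALSE),
                list(calls, wide_mean, wide_rep, wide_p, wide_s))
  out <- out[order(out$source, out$gene), ]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Write a plain-text report
#'
#' One table per marker source: each marker's claimed type, called type(s),
#' status, and the pairwise between-type tests with their p-values and
#' significance stars (strictly `p < 0.05 / 0.01 / 0.001` for one, two and
#' three asterisks; `ns` otherwise).
#'
#' @param conc a [concordance_analysis()] result.
#' @param summary_tab the [evaluate_catalog()] summary.
#' @param path output file.
#' @param overlap optional [expressed_gene_overlap()] result to append.
#' @return the path, invisibly.
#' @export
write_text_report <- function(conc, summary_tab, path, overlap = NULL) {
  stopifnot(inherits(conc, "concordance_table"))
  lines <- c("Marker concordance report",
             "=========================", "")
  calls <- conc$calls
  if (nrow(calls) == 0L) {
    lines <- c(lines, "no markers evaluated")
  } else {
    for (src in unique(calls$source)) {
      d <- calls[calls$source == src, ]
      s <- summary_tab[summary_tab$source == src, ]
      lines <- c(lines,
                 sprintf("Source: %s (%d markers: %d consistent, %d inconsistent, %d ambiguous, %d none, %d skipped)",
                         src, s$n_markers, s$consistent, s$inconsistent,
                         s$ambiguous, s$none, s$skipped), "")
      for (i in seq_len(nrow(d))) {
        row <- d[i, ]
        lines <- c(lines, sprintf(
          "  %s  claimed=%s  called=%s  [%s]%s",
          row$gene, row$claimed_type,
          if (is.na(row$call)) "NA" else row$call, row$status,
          if (isTRUE(row$consistent)) "  consistent" else ""))
        tst <- conc$tests[conc$tests$gene == row$gene, , drop = FALSE]
        for (k in seq_len(nrow(tst))) {
          lines <- c(lines, sprintf(
            "      %s vs %s: t=%.3f, p=%.6g %s",
            tst$type_a[k], tst$type_b[k], tst$t[k], tst$p[k], tst$stars[k]))
        }
      }
      lines <- c(lines, "")
    }
  }
  if (!is.null(overlap)) {
    lines <- c(lines, "Expressed-gene overlap",
               "----------------------",
               sprintf("  min_denominator = %.4f", overlap$min_denominator),
               sprintf("  jaccard         = %.4f", overlap$jaccard),
               sprintf("  |A|=%d |B|=%d |A.and.B|=%d (min_count=%d, min_samples=%d)",
                       overlap$n_a, overlap$n_b, overlap$n_intersection,
                       overlap$min_count, overlap$min_samples), "")
  }
  writeLines(lines, path)
  invisible(path)
}
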