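# Delimited-text readers/writers and the end-to-end pipeline runner.

#' Read a taxa count table from delimited text
#'
#' @param path TSV/CSV file; the first column holds row ids.  The delimiter is
#'   inferred from the extension (`.csv` -> comma, otherwise tab) unless `sep`
#'   is given.
#' @param taxa_in_rows set `TRUE` when the file stores taxa in rows and
#'   samples in columns; the table is transposed to the package's
#'   samples-in-rows convention.
#' @param sep optional field separator override.
#' @return a [count_table()].
#' @export
read_count_table <- function(path, taxa_in_rows = FALSE, sep = NULL) {
  if (!file.exists(path)) stop("count table file not found: ", path)
  sep <- sep %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.delim(path, sep = sep, check.names = FALSE, row.names = 1L)
  m <- as.matrix(df)
  if (taxa_in_rows) m <- t(m)
  count_table(m)
}

#' Write a count table as round-trippable TSV
#'
#' @param table a [count_table()] (or matrix).
#' @param path output path.
#' @return the input, invisibly.
#' @export
write_count_table <- function(table, path) {
  df <- data.frame(sample_id = rownames(table), as.data.frame(unclass(table)),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(table)
}

#' Read sample metadata
#'
#' @param path delimited text file with one row per sample.
#' @param sample_col name of the sample-id column.
#' @param label_col name of the class-label column.
#' @param strata_col,block_col optional restricted-permutation columns.
#' @param sep optional separator override (default: by extension).
#' @return data.frame with columns `sample_id`, `label`, and optionally
#'   `strata` / `block`.
#' @export
read_metadata <- function(path, sample_col = "sample_id", label_col = "label",
                          strata_col = NULL, block_col = NULL, sep = NULL) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  sep <- sep %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.delim(path, sep = sep, check.names = FALSE)
  for (col in c(sample_col, label_col, strata_col, block_col)) {
    if (!col %in% names(df))
      stop("metadata is missing required column '", col, "'")
  }
  out <- data.frame(sample_id = as.character(df[[sample_col]]),
                    label = as.character(df[[label_col]]),
                    stringsAsFactors = FALSE)
  if (!is.null(strata_col)) out$strata <- as.character(df[[strata_col]])
  if (!is.null(block_col)) out$block <- as.character(df[[block_col]])
  if (anyDuplicated(out$sample_id)) stop("duplicate sample ids in metadata")
  out
}

#' Configuration for an end-to-end pipeline run
#'
#' @param counts path to the count table (see [read_count_table()]).
#' @param metadata path to the sample metadata.
#' @param output_dir directory for report artifacts (created if absent).
#' @param sample_col,label_col,strata_col,block_col metadata column names;
#'   supplying `strata_col` or `block_col` switches the permutation scheme to
#'   `within_strata` / `block`.
#' @param prevalence prevalence filter threshold.
#' @param k permutations for the significance test.
#' @param taxa_in_rows orientation flag for the count table file.
#' @param cfg a [selection_config()].
#' @param seed master seed (propagated to the scheme and selection config).
#' @param verbose print progress.
#' @return a `run_config` list.
#' @export
run_config <- function(counts, metadata, output_dir = ".",
                       sample_col = "sample_id", label_col = "label",
                       strata_col = NULL, block_col = NULL,
                       prevalence = 0.10, k = 999L, taxa_in_rows = FALSE,
                       cfg = selection_config(), seed = NULL, verbose = TRUE) {
  structure(list(counts = counts, metadata = metadata, output_dir = output_dir,
                 sample_col = sample_col, label_col = label_col,
                 strata_col = strata_col, block_col = block_col,
                 prevalence = prevalence, k = as.integer(k),
                 taxa_in_rows = taxa_in_rows, cfg = cfg, seed = seed,
                 verbose = verbose),
            class = "run_config")
}

#' Run the full association-testing pipeline and write artifacts
#'
#' Reads counts and metadata, aligns samples by id (never by row order),
#' runs [sel_energy_perm_test()], and writes: `report.json` (observed
#' statistic, p-value, signature, settings), `signature.tsv`, `dcv_report.tsv`
#' (per-ratio scores), `network.graphml` (spanning tree), `null_values.tsv`,
#' and `run_log.txt` (seeds, settings, package version).
#'
#' @param config a [run_config()].
#' @return the `selenergy_test` report, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)

  tab <- read_count_table(config$counts, taxa_in_rows = config$taxa_in_rows)
  meta <- read_metadata(config$metadata, config$sample_col, config$label_col,
                        config$strata_col, config$block_col)
  idx <- match(rownames(tab), meta$sample_id)
  if (anyNA(idx))
    stop("sample id(s) in counts but not metadata: ",
         paste(head(rownames(tab)[is.na(idx)], 5L), collapse = ", "))
  meta <- meta[idx, , drop = FALSE]

  mode <- if (!is.null(config$block_col)) "block"
          else if (!is.null(config$strata_col)) "within_strata" else "free"
  strata <- if (mode == "block") meta$block else if (mode == "within_strata") meta$strata
  cfg <- config$cfg
  if (!is.null(config$seed)) cfg$seed <- child_seed(config$seed, 1L)
  scheme <- permutation_scheme(mode, k = config$k, strata = strata,
                               seed = child_seed(config$seed, 2L))

  if (isTRUE(config$verbose))
    message("selenergy: ", nrow(tab), " samples x ", ncol(tab), " taxa; scheme = ",
            mode, ", k = ", config$k)
  report <- sel_energy_perm_test(tab, meta$label, scheme, cfg,
                                 prevalence = config$prevalence)

  out <- function(f) file.path(config$output_dir, f)
  write_signature(report$selection, out("signature.tsv"))
  write_dcv_report(report$selection$scores, out("dcv_report.tsv"))
  write_graphml(report$selection$tree, out("network.graphml"))
  write.table(data.frame(replicate = seq_along(report$null_values),
                         F_null = report$null_values),
              out("null_values.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(report_to_list(report), out("report.json"),
                       auto_unbox = TRUE, digits = 12, pretty = TRUE)
  writeLines(c(
    paste0("selenergy version: ", as.character(utils::packageVersion("selenergy"))),
    paste0("R version: ", R.version.string),
    paste0("seed: ", config$seed %||% "NULL"),
    paste0("k: ", config$k),
    paste0("scheme: ", mode),
    paste0("prevalence: ", config$prevalence),
    paste0("statistic_kind: ", report$statistic_kind),
    paste0("alpha_exponent: ", cfg$alpha_exponent),
    paste0("scaling_m: ", cfg$scaling_m)),
    out("run_log.txt"))
  invisible(report)
}

report_to_list <- function(report) {
  list(statistic_kind = report$statistic_kind,
       F_obs = signif(report$F_obs, 12),
       p_value = report$p_value,
       k = report$k,
       k_requested = report$k_requested,
       failed_replicates = report$failed_replicates,
       signature = report$signature,
       settings = list(scheme_mode = report$settings$scheme$mode,
                       seed = report$settings$scheme$seed,
                       prevalence = report$settings$prevalence,
                       statistic_mode = report$settings$config$statistic_mode,
                       alpha_exponent = report$settings$config$alpha_exponent,
                       scaling_m = report$settings$config$scaling_m,
                       dispersion_k = report$settings$config$dispersion_k,
                       dispersion_alpha = report$settings$config$dispersion_alpha))
}
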