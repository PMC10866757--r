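#' Read a flat key=value configuration file
#'
#' Lines of the form `key = value`; blank lines and `#` comments are
#' ignored. Values are kept as strings; consumers coerce.
#'
#' @param path Path to the configuration file.
#' @return Named list of character values.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  bad <- lines[lengths(kv) != 3L]
  if (length(bad) > 0L) stop("malformed config line(s): ",
                             paste(bad, collapse = "; "))
  stats::setNames(lapply(kv, function(m) trimws(m[3L])),
                  vapply(kv, function(m) trimws(m[2L]), character(1)))
}

#' Run the variant-study pipeline end to end
#'
#' Builds (or loads) the codon-usage reference table, scores every query
#' gene against it, and emits a study report: one row per variant with its
#' GC, GC3, average and minimal adaptation, plus full provenance. This is
#' the programmatic core of the comparative variant table a transgene
#' design study reports.
#'
#' Configuration keys (file via [read_config()], or a named list; entries
#' in `overrides` win): either `usage_table` (prebuilt TSV) or all of
#' `counts`, `lengths`, `reference_fasta` (the table is then built from
#' the top genes after normalization and stability filtering); always
#' `query_fasta`; optional `out_dir`, `mode` (rca), `mean_kind`
#' (geometric), `k` (92), `alpha` (0.05), `timepoints` (comma-separated
#' hours to pool; default all), `pseudocount` (0.5), `seed` (recorded in
#' provenance).
#'
#' @param config Path to a key=value file, or a named list.
#' @param overrides Named list overriding config entries (flags win).
#' @return A `study_report`: list with `rows` (one data frame row per
#'   query), `profiles` (list of `adaptation_profile`s) and `provenance`.
#'   When `out_dir` is set, also writes `report.tsv`, `report.json` and
#'   per-variant `profiles/<id>_profile.tsv`.
#' @export
run_pipeline <- function(config, overrides = list()) {
  cfg <- if (is.character(config) && length(config) == 1L) read_config(config)
         else as.list(config)
  cfg[names(overrides)] <- overrides
  get_num <- function(key, default) {
    if (is.null(cfg[[key]])) default else as.numeric(cfg[[key]])
  }
  mode <- tolower(if (is.null(cfg$mode)) "rca" else cfg$mode)
  mean_kind <- if (is.null(cfg$mean_kind)) "geometric" else cfg$mean_kind
  k <- get_num("k", 92)
  alpha <- get_num("alpha", 0.05)
  pseudocount <- get_num("pseudocount", 0.5)

  has_table <- !is.null(cfg$usage_table)
  has_matrix <- !is.null(cfg$counts) && !is.null(cfg$lengths) &&
    !is.null(cfg$reference_fasta)
  if (has_table && has_matrix) {
    stop("config names both a prebuilt usage table and a count matrix; ",
         "choose one table source")
  }
  if (!has_table && !has_matrix) {
    stop("config must name either 'usage_table' or all of ",
         "'counts', 'lengths', 'reference_fasta'")
  }
  if (is.null(cfg$query_fasta)) stop("config must name 'query_fasta'")

  queries <- read_fasta(cfg$query_fasta)

  if (has_table) {
    table <- read_usage_table(cfg$usage_table)
    table_source <- list(kind = "prebuilt", usage_table = cfg$usage_table)
  } else {
    counts <- read_counts_tsv(cfg$counts)
    lengths <- read_lengths_tsv(cfg$lengths)
    em <- expression_matrix(counts, lengths)
    keep <- stability_filter(em, alpha = alpha)$retained
    tps <- if (is.null(cfg$timepoints)) NULL else
      as.numeric(strsplit(cfg$timepoints, ",")[[1L]])
    top <- rank_genes(em, k = min(k, length(keep)), timepoints = tps,
                      genes = keep)
    ref <- read_fasta(cfg$reference_fasta)
    missing <- setdiff(top, names(ref))
    if (length(missing) > 0L) {
      stop("top genes missing from reference FASTA: ",
           paste(utils::head(missing, 5L), collapse = ", "))
    }
    table <- build_usage_table(ref[top])
    table_source <- list(kind = "built", counts = cfg$counts,
                         lengths = cfg$lengths,
                         reference_fasta = cfg$reference_fasta,
                         k = k, alpha = alpha,
                         timepoints = cfg$timepoints)
  }

  w <- relative_adaptiveness(table, mode = mode, pseudocount = pseudocount)
  profiles <- lapply(names(queries), function(id) {
    score_gene(queries[[id]], table, mode = mode, mean_kind = mean_kind,
               pseudocount = pseudocount, id = id, w = w)
  })
  names(profiles) <- names(queries)
  rows <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(id = p$gene_id, gc_pct = p$gc_pct, gc3_pct = p$gc3_pct,
               average_pct = p$average_pct, min_pct = p$min_pct,
               mode = p$mode, mean_kind = p$mean_kind,
               stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  provenance <- list(
    table_source = table_source,
    parameters = list(mode = mode, mean_kind = mean_kind,
                      pseudocount = pseudocount),
    seed = if (is.null(cfg$seed)) NA else as.integer(cfg$seed),
    package_version = as.character(utils::packageVersion("codonrca"))
  )
  report <- structure(list(rows = rows, profiles = profiles,
                           provenance = provenance),
                      class = "study_report")
  if (!is.null(cfg$out_dir)) write_study_report(report, cfg$out_dir)
  report
}

#' Write a study report (TSV + JSON + per-variant profile TSVs)
#'
#' @param report A `study_report`.
#' @param dir Output directory (created if needed).
#' @return Invisible named list of written paths.
#' @export
write_study_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(file.path(dir, "profiles"), showWarnings = FALSE,
             recursive = TRUE)
  tsv <- file.path(dir, "report.tsv")
  json <- file.path(dir, "report.json")
  utils::write.table(report$rows, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(schema = "codonrca-study-report/1",
         variants = report$rows, provenance = report$provenance),
    json, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  prof_paths <- vapply(report$profiles, function(p) {
    path <- file.path(dir, "profiles", paste0(p$gene_id, "_profile.tsv"))
    profile_export(p, path)
    path
  }, character(1))
  invisible(list(tsv = tsv, json = json, profiles = prof_paths))
}

#' @export
print.study_report <- function(x, ...) {
  cat("Variant study report (", nrow(x$rows), " variants, mode ",
      toupper(x$provenance$parameters$mode), ")\n", sep = "")
  df <- x$rows
  df$gc_pct <- round(df$gc_pct, 1)
  df$gc3_pct <- round(df$gc3_pct, 1)
  df$average_pct <- round(df$average_pct, 1)
  df$min_pct <- round(df$min_pct, 1)
  print(df)
  invisible(x)
}
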