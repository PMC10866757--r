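#' Median-of-ratios size factors
#'
#' Per-sample normalization constants computed exactly as in the
#' median-of-ratios scheme: each gene with strictly positive counts in
#' every sample contributes its cross-sample geometric mean as reference;
#' a sample's size factor is the median over those genes of
#' count / reference.
#'
#' @param counts Gene x sample matrix of non-negative counts (>= 2
#'   columns).
#' @return Named numeric vector of strictly positive size factors, one
#'   per sample.
#' @examples
#' m <- cbind(s1 = c(4, 10), s2 = c(9, 10))
#' size_factors_median_of_ratios(m)
#' @export
size_factors_median_of_ratios <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stop("need at least two samples")
  if (any(counts < 0)) stop("negative counts")
  keep <- rowSums(counts > 0) == ncol(counts)
  if (!any(keep)) stop("no gene has positive counts in all samples")
  lr <- log(counts[keep, , drop = FALSE])
  ref <- rowMeans(lr)                       # log geometric mean
  sf <- apply(exp(lr - ref), 2L, stats::median)
  stats::setNames(sf, colnames(counts))
}

#' Transcripts per million
#'
#' `TPM_gs = 1e6 * (c_gs / l_g) / sum_g' (c_g's / l_g')`: counts are first
#' converted to length-normalized rates, then each sample column is
#' rescaled to sum to one million.
#'
#' @param counts Gene x sample matrix of non-negative counts.
#' @param lengths Per-gene lengths in nucleotides (recycled by position or
#'   matched by name).
#' @return Matrix of TPM values; every column sums to 1e6.
#' @export
compute_tpm <- function(counts, lengths) {
  counts <- as.matrix(counts)
  if (!is.null(names(lengths)) && !is.null(rownames(counts))) {
    lengths <- lengths[rownames(counts)]
  }
  if (length(lengths) != nrow(counts)) {
    stop("lengths do not match the count matrix rows")
  }
  if (any(is.na(lengths)) || any(lengths <= 0)) stop("lengths must be positive")
  rate <- counts / lengths
  tot <- colSums(rate)
  if (any(tot == 0)) {
    stop("all-zero sample column(s): ",
         paste(colnames(counts)[tot == 0], collapse = ", "))
  }
  sweep(rate, 2L, tot / 1e6, "/")
}

#' Parse "t<hours>_r<rep>" sample labels
#' @keywords internal
parse_sample_labels <- function(labels) {
  m <- regmatches(labels, regexec("^t([0-9]+)_r([0-9]+)$", labels))
  bad <- labels[lengths(m) != 3L]
  if (length(bad) > 0L) {
    stop("malformed sample label(s) (expected t<hours>_r<rep>): ",
         paste(bad, collapse = ", "))
  }
  data.frame(sample = labels,
             timepoint = as.integer(vapply(m, `[`, character(1), 2L)),
             replicate = as.integer(vapply(m, `[`, character(1), 3L)),
             stringsAsFactors = FALSE)
}

#' Gene x sample expression matrix with lengths, size factors and TPM
#'
#' The container the reference-selection stage works on. Size factors
#' (median of ratios) and TPM are computed on construction; normalized
#' counts are counts divided by their sample's size factor.
#'
#' @param counts Gene x sample matrix of non-negative integers with gene
#'   rownames and sample-label colnames of the form `t<hours>_r<rep>`.
#' @param lengths Named per-gene CDS lengths in nucleotides.
#' @param sample_labels Optional; defaults to `colnames(counts)`.
#' @return An `expression_matrix`: list with `counts`, `lengths`,
#'   `labels` (parsed data frame), `size_factors`, `normalized`, `tpm`.
#' @export
expression_matrix <- function(counts, lengths, sample_labels = colnames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts need gene rownames")
  colnames(counts) <- sample_labels
  labels <- parse_sample_labels(sample_labels)
  if (!is.null(names(lengths))) {
    if (!all(rownames(counts) %in% names(lengths))) {
      stop("lengths missing for some genes")
    }
    lengths <- lengths[rownames(counts)]
  } else {
    names(lengths) <- rownames(counts)
  }
  sf <- size_factors_median_of_ratios(counts)
  structure(
    list(counts = counts,
         lengths = lengths,
         labels = labels,
         size_factors = sf,
         normalized = sweep(counts, 2L, sf, "/"),
         tpm = compute_tpm(counts, lengths)),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("Expression matrix:", nrow(x$counts), "genes x", ncol(x$counts),
      "samples (", length(unique(x$labels$timepoint)), "time points )\n")
  cat("  size factors:",
      paste(sprintf("%.3f", x$size_factors), collapse = ", "), "\n")
  invisible(x)
}

#' Remove genes whose expression differs across time points
#'
#' Per-gene one-way analysis of variance of log2(TPM + 1) across time
#' points; genes with a Benjamini-Hochberg-adjusted p-value below `alpha`
#' are removed, keeping only genes expressed stably over the time course
#' (the reference-set selection targets constitutively high expression,
#' not time-point-specific spikes). Genes with identical values in all
#' samples get statistic 0 and p-value 1.
#'
#' @param x An [expression_matrix()].
#' @param alpha Significance level on the adjusted p-value (default 0.05);
#'   `alpha = 0` retains everything.
#' @param adjust Multiple-testing method for [stats::p.adjust()]
#'   (default `"BH"`).
#' @return List with `retained` (character vector of gene ids) and
#'   `report` (per-gene data frame: `gene`, `statistic`, `p_value`,
#'   `p_adjusted`, `removed`).
#' @export
stability_filter <- function(x, alpha = 0.05, adjust = "BH") {
  stopifnot(inherits(x, "expression_matrix"))
  tp <- factor(x$labels$timepoint)
  if (nlevels(tp) < 2L) stop("need at least two time points")
  if (any(table(tp) < 2L)) stop("need at least two replicates per time point")
  y <- log2(x$tpm + 1)
  stat <- p <- numeric(nrow(y))
  for (i in seq_len(nrow(y))) {
    yi <- y[i, ]
    if (stats::var(yi) == 0) { stat[i] <- 0; p[i] <- 1; next }
    a <- stats::anova(stats::lm(yi ~ tp))
    Fi <- a[["F value"]][1L]
    pi <- a[["Pr(>F)"]][1L]
    if (is.na(pi)) { pi <- if (!is.finite(Fi) && !is.na(Fi)) 0 else 1 }
    if (is.na(Fi)) Fi <- 0
    stat[i] <- Fi
    p[i] <- pi
  }
  padj <- stats::p.adjust(p, method = adjust)
  removed <- padj < alpha
  report <- data.frame(gene = rownames(y), statistic = stat, p_value = p,
                       p_adjusted = padj, removed = removed,
                       stringsAsFactors = FALSE)
  list(retained = rownames(y)[!removed], report = report)
}

#' Rank genes by pooled mean expression and take the top k
#'
#' Genes are ordered by their mean TPM (or mean normalized counts) over
#' the pooled samples, descending. Ties are broken by gene identifier
#' (lexicographic) and reported via the `"ties"` attribute.
#'
#' @param x An [expression_matrix()].
#' @param k Number of top genes to return.
#' @param timepoints Optional vector of time points (hours) to pool;
#'   default pools every sample.
#' @param genes Optional subset of genes to rank (e.g. the output of
#'   [stability_filter()]).
#' @param use `"tpm"` (default) or `"normalized"`.
#' @return Character vector of the top-`k` gene identifiers, with
#'   attributes `means` (pooled means, named, for the ranked genes) and
#'   `ties` (ids involved in ties at equal means).
#' @export
rank_genes <- function(x, k, timepoints = NULL, genes = NULL,
                       use = c("tpm", "normalized")) {
  stopifnot(inherits(x, "expression_matrix"))
  use <- match.arg(use)
  m <- if (use == "tpm") x$tpm else x$normalized
  if (!is.null(genes)) {
    if (!all(genes %in% rownames(m))) stop("unknown gene id(s) in 'genes'")
    m <- m[genes, , drop = FALSE]
  }
  sel <- if (is.null(timepoints)) seq_len(ncol(m)) else
    which(x$labels$timepoint %in% timepoints)
  if (length(sel) == 0L) stop("no samples at the requested time points")
  if (k > nrow(m)) stop("k (", k, ") exceeds the number of genes (", nrow(m), ")")
  mu <- rowMeans(m[, sel, drop = FALSE])
  ord <- order(-mu, rownames(m))
  ids <- rownames(m)[ord]
  top <- ids[seq_len(k)]
  tied <- names(mu)[mu %in% mu[duplicated(mu)]]
  structure(top, means = mu[top], ties = tied)
}

#' Read a count matrix TSV (first column gene id, header of sample labels)
#' @param path Path to the TSV.
#' @return Integer matrix with gene rownames and sample colnames.
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "numeric"
  m
}

#' Read a two-column gene-length TSV
#' @param path Path to the TSV (columns: gene id, length in nt).
#' @return Named numeric vector of lengths.
#' @export
read_lengths_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  stats::setNames(as.numeric(df[[2L]]), df[[1L]])
}
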