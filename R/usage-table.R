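#' Build a codon-usage table from a reference CDS set
#'
#' Tallies codon counts over a set of coding sequences (the "reference
#' set" of highly expressed genes) and derives the usual summaries:
#' per-thousand usage, within-family synonymous fractions, and the
#' nucleotide frequency backgrounds at codon positions 1, 2 and 3 used by
#' the RCA index. Stop codons are counted by default, so `n_codons` equals
#' total nucleotides / 3 for whole CDSs.
#'
#' @param cds_set Named character vector of coding sequences.
#' @param include_stops Count stop codons (default `TRUE`).
#' @param fragment Accept partial CDSs / codon multisets (see
#'   [validate_cds()]).
#' @param code A [genetic_code()].
#' @return A `codon_usage_table`: list with `counts`, `per_thousand`,
#'   `fraction` (all named over the 64 codons; `fraction` is `NA` for
#'   families absent from the reference set), `pos_freq` (3 x 4 matrix of
#'   nucleotide frequencies at the three codon positions), `n_codons`,
#'   `n_cds` and the genetic `code`.
#' @examples
#' tab <- build_usage_table(c(g1 = "ATGAAATAA", g2 = "ATGAAGAAATAA"))
#' tab$counts[c("AAA", "AAG")]
#' @export
build_usage_table <- function(cds_set, include_stops = TRUE,
                              fragment = FALSE, code = genetic_code()) {
  if (length(cds_set) == 0L) stop("empty reference CDS set")
  if (is.null(names(cds_set))) names(cds_set) <- paste0("seq", seq_along(cds_set))
  validate_cds(cds_set, fragment = fragment, code = code)
  cod <- unlist(lapply(unname(cds_set), split_codons), use.names = FALSE)
  if (!include_stops) cod <- cod[code$codon_to_aa[cod] != "*"]
  counts <- table(factor(cod, levels = CODONS))
  counts <- stats::setNames(as.integer(counts), CODONS)
  new_usage_table(counts, n_cds = length(cds_set), code = code)
}

#' Assemble a codon_usage_table from a count vector
#' @keywords internal
new_usage_table <- function(counts, n_cds = NA_integer_, code = genetic_code()) {
  stopifnot(identical(names(counts), CODONS), all(counts >= 0))
  n <- sum(counts)
  if (n == 0) stop("codon-usage table has zero total count")
  per_thousand <- 1000 * counts / n
  fraction <- family_fractions(counts, code)
  structure(
    list(counts = counts,
         per_thousand = per_thousand,
         fraction = fraction,
         pos_freq = positional_frequencies(counts),
         n_codons = n,
         n_cds = n_cds,
         code = code),
    class = "codon_usage_table"
  )
}

#' Within-family synonymous fractions from codon counts
#' @keywords internal
family_fractions <- function(counts, code) {
  fraction <- stats::setNames(rep(NA_real_, 64L), CODONS)
  for (fam in code$families) {
    tot <- sum(counts[fam])
    if (tot > 0) fraction[fam] <- counts[fam] / tot
  }
  fraction
}

#' Nucleotide frequencies at the three codon positions
#'
#' Computes the f1/f2/f3 background frequencies from a weight per codon
#' (counts or any proportional measure).
#' @keywords internal
positional_frequencies <- function(weights) {
  w <- weights / sum(weights)
  pf <- matrix(0, nrow = 3L, ncol = 4L,
               dimnames = list(paste0("pos", 1:3), NUCLEOTIDES))
  for (j in 1:3) {
    nt <- substr(CODONS, j, j)
    pf[j, ] <- vapply(NUCLEOTIDES, function(b) sum(w[nt == b]), numeric(1))
  }
  pf
}

#' @export
print.codon_usage_table <- function(x, ...) {
  cat("Codon-usage table:", x$n_codons, "codons")
  if (!is.na(x$n_cds)) cat(" from", x$n_cds, "CDSs")
  cat("\n")
  gc_bg <- sum(x$pos_freq[, c("C", "G")]) / 3
  cat(sprintf("  background GC %.1f%%, GC3 %.1f%%\n",
              100 * gc_bg, 100 * sum(x$pos_freq[3, c("C", "G")])))
  top <- sort(x$per_thousand, decreasing = TRUE)[1:5]
  cat("  top codons (per thousand):",
      paste(sprintf("%s %.1f", names(top), top), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.codon_usage_table <- function(object, ...) {
  code <- object$code
  df <- data.frame(
    codon = CODONS,
    amino_acid = unname(code$codon_to_aa[CODONS]),
    count = unname(object$counts),
    per_thousand = unname(object$per_thousand),
    fraction = unname(object$fraction),
    stringsAsFactors = FALSE
  )
  df[order(df$amino_acid, df$codon), ]
}

#' Write a codon-usage table as TSV
#'
#' Columns `codon`, `amino_acid`, `count`, `per_thousand`, `fraction`
#' (the dialect of common codon-usage reports).
#'
#' @param table A `codon_usage_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_usage_table <- function(table, path) {
  stopifnot(inherits(table, "codon_usage_table"))
  df <- summary(table)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a codon-usage table from TSV
#'
#' Accepts tables carrying any subset of `{count, per_thousand, fraction}`
#' and reconstructs what it can: counts (or per-thousand values, treated as
#' relative counts) suffice to rebuild everything, including the positional
#' backgrounds needed for RCA; a fraction-only table supports CAI scoring
#' but not RCA, because within-family fractions carry no information on
#' amino-acid composition or positional nucleotide backgrounds.
#'
#' @param path Path to a TSV with a `codon` column and at least one of
#'   `count`, `per_thousand`, `fraction`.
#' @param code A [genetic_code()].
#' @return A `codon_usage_table`; fraction-only input yields a table whose
#'   `counts`, `per_thousand` and `pos_freq` are `NA`.
#' @export
read_usage_table <- function(path, code = genetic_code()) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"codon" %in% names(df)) stop("usage-table TSV needs a 'codon' column")
  df$codon <- toupper(chartr("U", "T", df$codon))
  if (anyDuplicated(df$codon)) stop("duplicate codons in usage table")
  missing <- setdiff(CODONS, df$codon)
  if (length(missing) > 0L) {
    stop("usage table is missing codons: ", paste(missing[1:min(5, length(missing))],
                                                  collapse = ", "))
  }
  rownames(df) <- df$codon
  df <- df[CODONS, ]
  if ("count" %in% names(df)) {
    counts <- stats::setNames(as.numeric(df$count), CODONS)
    tab <- new_usage_table(counts, code = code)
  } else if ("per_thousand" %in% names(df)) {
    counts <- stats::setNames(as.numeric(df$per_thousand), CODONS)
    tab <- new_usage_table(counts, code = code)
    tab$counts <- stats::setNames(rep(NA_real_, 64L), CODONS)
    tab$n_codons <- NA_real_
  } else if ("fraction" %in% names(df)) {
    fraction <- stats::setNames(as.numeric(df$fraction), CODONS)
    tab <- structure(
      list(counts = stats::setNames(rep(NA_real_, 64L), CODONS),
           per_thousand = stats::setNames(rep(NA_real_, 64L), CODONS),
           fraction = fraction,
           pos_freq = NULL,
           n_codons = NA_real_,
           n_cds = NA_integer_,
           code = code),
      class = "codon_usage_table")
  } else {
    stop("usage-table TSV carries none of count/per_thousand/fraction")
  }
  tab
}
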