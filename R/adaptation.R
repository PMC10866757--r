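#' Per-codon relative adaptiveness under CAI or RCA
#'
#' Computes, for every codon, its relative adaptiveness w in `[0, 1]`
#' against a reference codon-usage table.
#'
#' In CAI mode, `w(c) = f(c) / max f` over c's synonymous family, where f
#' is the codon's frequency in the reference set. In RCA mode each codon
#' frequency is first background-corrected by the product of the
#' reference set's nucleotide frequencies at the three codon positions,
#' `RCA(xyz) = f(xyz) / (f1(x) f2(y) f3(z))`, and w is the within-family
#' ratio `RCA(c) / max RCA`. RCA therefore discounts adaptation that is
#' explained by overall nucleotide (e.g. GC) composition rather than by
#' codon preference proper.
#'
#' Zero-count codons receive `pseudocount` before frequencies are formed;
#' both the codon frequencies and the positional backgrounds are computed
#' from the adjusted counts, so the two indices coincide exactly whenever
#' the adjusted backgrounds are uniform. With `pseudocount = 0`, families
#' entirely absent from the reference set get `NA` adaptiveness; scoring a
#' gene that uses such a codon is an error.
#'
#' Single-codon families (Met, Trp) always have w = 1. Stop-codon w values
#' are computed but flagged, and are never part of gene-level scores.
#'
#' @param table A `codon_usage_table`.
#' @param mode `"rca"` or `"cai"`.
#' @param pseudocount Non-negative count added to zero-count codons
#'   (default 0.5).
#' @return A `codon_w` object: named numeric vector of length 64 with
#'   attributes `mode`, `pseudocount` and `stop_codons`.
#' @examples
#' tab <- build_usage_table(c(g = "ATGAAAAAGTAA"))
#' relative_adaptiveness(tab, mode = "cai")[c("AAA", "AAG")]
#' @export
relative_adaptiveness <- function(table, mode = c("rca", "cai"),
                                  pseudocount = 0.5) {
  stopifnot(inherits(table, "codon_usage_table"), pseudocount >= 0)
  mode <- match.arg(tolower(mode[1L]), c("rca", "cai"))
  code <- table$code

  basis <- table$counts
  if (all(is.na(basis))) basis <- table$per_thousand
  if (all(is.na(basis))) {
    # fraction-only table: scale fractions to a common per-family mass so
    # the count-style pseudocount applies; only CAI is defined.
    if (mode == "rca") {
      stop("RCA needs codon counts or per-thousand values; ",
           "this table carries only within-family fractions")
    }
    basis <- 1000 * table$fraction
    basis[is.na(basis)] <- 0
  }

  adj <- basis
  adj[adj == 0] <- pseudocount
  f <- adj / sum(adj)

  if (mode == "rca") {
    pf <- positional_frequencies(adj)
    bg <- pf[1L, substr(CODONS, 1L, 1L)] *
      pf[2L, substr(CODONS, 2L, 2L)] *
      pf[3L, substr(CODONS, 3L, 3L)]
    score <- f / bg
  } else {
    score <- f
  }
  names(score) <- CODONS

  w <- stats::setNames(rep(NA_real_, 64L), CODONS)
  for (fam in code$families) {
    if (length(fam) == 1L) { w[fam] <- 1; next }  # Met, Trp: always preferred
    m <- max(score[fam])
    if (is.finite(m) && m > 0) w[fam] <- score[fam] / m
  }
  structure(w,
            mode = mode,
            pseudocount = pseudocount,
            stop_codons = code$families[["*"]],
            class = "codon_w")
}

#' @export
print.codon_w <- function(x, ...) {
  cat("Relative adaptiveness (", toupper(attr(x, "mode")), "), ",
      sum(unclass(x) == 1, na.rm = TRUE), " preferred codons\n", sep = "")
  print(round(unclass(x), 3))
  invisible(x)
}

#' GC content of a sequence, overall and at third codon positions
#'
#' @param seq A single nucleotide string (A/C/G/T); incomplete trailing
#'   codons are ignored for GC3.
#' @return Named numeric vector `c(gc_pct, gc3_pct)`, in percent.
#' @examples
#' gc_metrics("GGCC")  # gc_pct 100
#' @export
gc_metrics <- function(seq) {
  stopifnot(length(seq) == 1L, nchar(seq) > 0L)
  if (grepl("[^ACGT]", seq)) stop("non-ACGT character in sequence")
  n <- nchar(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  gc <- 100 * sum(chars %in% c("G", "C")) / n
  third <- chars[seq(3L, n, by = 3L)]
  gc3 <- if (length(third)) 100 * sum(third %in% c("G", "C")) / length(third)
         else NA_real_
  c(gc_pct = gc, gc3_pct = gc3)
}

#' Score a gene against a codon-usage reference table
#'
#' Assigns each non-stop codon of the CDS its relative adaptiveness w
#' (see [relative_adaptiveness()]) and summarizes: the gene-level average
#' adaptation (geometric mean of w by default, the convention of the
#' CAI/RCA index family; arithmetic mean available), the minimal per-codon
#' adaptation, and the GC / GC3 content of the full CDS. All percentages.
#'
#' @param seq A single CDS string.
#' @param table A `codon_usage_table`.
#' @param mode `"rca"` or `"cai"`.
#' @param mean_kind `"geometric"` (default) or `"arithmetic"`.
#' @param pseudocount Passed to [relative_adaptiveness()].
#' @param id Gene identifier recorded in the profile.
#' @param fragment Allow partial CDSs.
#' @param w Optional precomputed `codon_w` (must match `mode`); avoids
#'   recomputation when scoring many genes.
#' @return An `adaptation_profile`: list with `gene_id`, `mode`,
#'   `mean_kind`, per-position `codons` and `w`, `average_pct`, `min_pct`,
#'   `gc_pct`, `gc3_pct`, `n_codons`.
#' @export
score_gene <- function(seq, table, mode = c("rca", "cai"),
                       mean_kind = c("geometric", "arithmetic"),
                       pseudocount = 0.5, id = "gene", fragment = FALSE,
                       w = NULL) {
  mode <- match.arg(tolower(mode[1L]), c("rca", "cai"))
  mean_kind <- match.arg(mean_kind)
  if (is.null(w)) {
    w <- relative_adaptiveness(table, mode = mode, pseudocount = pseudocount)
  } else {
    stopifnot(inherits(w, "codon_w"))
    if (!identical(attr(w, "mode"), mode)) {
      stop("precomputed w was built in mode '", attr(w, "mode"),
           "', not '", mode, "'")
    }
  }
  code <- table$code
  validate_cds(stats::setNames(unname(seq), id), fragment = fragment,
               code = code)
  cod <- split_codons(seq)
  keep <- code$codon_to_aa[cod] != "*"
  cod_ns <- cod[keep]
  if (length(cod_ns) == 0L) stop("no non-stop codons to score")
  wv <- unclass(w)[cod_ns]
  if (anyNA(wv)) {
    stop("codon(s) from families absent in the reference table: ",
         paste(unique(cod_ns[is.na(wv)]), collapse = ", "),
         " (use a positive pseudocount)")
  }
  avg <- if (mean_kind == "geometric") exp(mean(log(wv))) else mean(wv)
  gcm <- gc_metrics(seq)
  structure(
    list(gene_id = id, mode = mode, mean_kind = mean_kind,
         codons = cod_ns, w = unname(wv),
         average_pct = 100 * avg,
         min_pct = 100 * min(wv),
         gc_pct = unname(gcm["gc_pct"]),
         gc3_pct = unname(gcm["gc3_pct"]),
         n_codons = length(cod_ns)),
    class = "adaptation_profile"
  )
}

#' @export
print.adaptation_profile <- function(x, ...) {
  cat(sprintf("%s [%s, %s mean]: average %.1f%%, minimum %.1f%%, GC %.1f%%, GC3 %.1f%% (%d codons)\n",
              x$gene_id, toupper(x$mode), x$mean_kind, x$average_pct,
              x$min_pct, x$gc_pct, x$gc3_pct, x$n_codons))
  invisible(x)
}

#' @export
as.data.frame.adaptation_profile <- function(x, ...) {
  data.frame(position = seq_along(x$codons),
             codon = x$codons,
             amino_acid = unname(genetic_code()$codon_to_aa[x$codons]),
             w_pct = 100 * x$w,
             stringsAsFactors = FALSE)
}

#' Export a positional adaptation profile as TSV
#'
#' One row per non-stop codon position: `position`, `codon`,
#' `amino_acid`, `w_pct`.
#'
#' @param profile An `adaptation_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
profile_export <- function(profile, path) {
  stopifnot(inherits(profile, "adaptation_profile"))
  utils::write.table(as.data.frame(profile), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back an exported positional profile
#' @param path Path to a TSV written by [profile_export()].
#' @return Data frame with columns position, codon, amino_acid, w_pct.
#' @export
read_profile <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Plot a positional adaptation profile
#'
#' Bar chart of per-codon relative adaptation (in percent) against codon
#' position, with the gene-level average and minimum annotated.
#'
#' @param x An `adaptation_profile`.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.adaptation_profile <- function(x, ...) {
  graphics::barplot(100 * x$w, border = NA, col = "steelblue3",
                    names.arg = NULL, space = 0, ylim = c(0, 105),
                    xlab = "codon position", ylab = "relative adaptation (%)",
                    main = x$gene_id, ...)
  graphics::abline(h = x$average_pct, lty = 2)
  graphics::mtext(sprintf("average %.1f%%", x$average_pct), side = 4,
                  at = x$average_pct, las = 1, cex = 0.8)
  graphics::mtext(sprintf("min %.1f%%", x$min_pct), side = 4,
                  at = x$min_pct, las = 1, cex = 0.8, col = "red")
  invisible(x)
}
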