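NUCLEOTIDES <- c("A", "C", "G", "T")

#' All 64 DNA codons in lexicographic order
#' @keywords internal
all_codons <- function() {
  g <- expand.grid(p3 = NUCLEOTIDES, p2 = NUCLEOTIDES, p1 = NUCLEOTIDES,
                   stringsAsFactors = FALSE)
  sort(paste0(g$p1, g$p2, g$p3))
}

CODONS <- all_codons()

#' Genetic code with synonymous-family structure
#'
#' Wraps an NCBI genetic-code table (standard nuclear code by default) as a
#' codon-to-amino-acid map plus the partition of the 64 codons into
#' synonymous families. Stops are a family of their own, keyed `"*"`.
#'
#' @param id NCBI genetic-code table identifier as understood by
#'   [Biostrings::getGeneticCode()]; `"1"` is the standard code.
#' @return An object of class `genetic_code`: a list with elements
#'   `codon_to_aa` (named character vector over the 64 codons) and
#'   `families` (named list, one character vector of codons per amino acid
#'   and for `"*"`), plus the `id`.
#' @examples
#' gc <- genetic_code()
#' gc$codon_to_aa[["ATG"]]   # "M"
#' gc$families[["K"]]        # "AAA" "AAG"
#' @export
genetic_code <- function(id = "1") {
  tab <- Biostrings::getGeneticCode(id)
  tab <- tab[CODONS]
  stopifnot(!anyNA(tab), length(tab) == 64L)
  structure(
    list(codon_to_aa = tab,
         families = split(names(tab), tab),
         id = id),
    class = "genetic_code"
  )
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("Genetic code table", x$id, "-", length(x$families) - 1L,
      "amino acids,", length(x$families[["*"]]), "stop codons\n")
  invisible(x)
}

#' @keywords internal
is_stop <- function(codon, code) {
  code$codon_to_aa[codon] == "*"
}

#' Number of G or C bases per codon
#' @keywords internal
codon_gc <- function(codons) {
  nchar(codons) - nchar(gsub("[GCgc]", "", codons))
}

#' Split a CDS string into codons
#' @keywords internal
split_codons <- function(seq) {
  n <- nchar(seq)
  stopifnot(n %% 3L == 0L)
  substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
}
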