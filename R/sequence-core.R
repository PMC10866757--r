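#' Read coding sequences from a FASTA file
#'
#' Reads a (possibly line-wrapped) multi-record FASTA file. Sequences are
#' uppercased and RNA `U` is coerced to `T`, so everything downstream works
#' on uppercase DNA. Record identifiers are the first whitespace-delimited
#' token of each header. No CDS validation is performed at read time; use
#' [validate_cds()] for that.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences, in file order.
#' @seealso [write_fasta()], [validate_cds()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0L) stop("FASTA file contains no records: ", path)
  ids <- sub("\\s.*$", "", names(recs))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop("duplicate FASTA identifiers: ", paste(dup, collapse = ", "))
  }
  seqs <- toupper(as.character(recs))
  seqs <- chartr("U", "T", seqs)
  names(seqs) <- ids
  seqs
}

#' Write sequences to FASTA (60-column wrapped)
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(length(seqs) > 0L, !is.null(names(seqs)))
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' List rule violations for putative coding sequences
#'
#' Checks each sequence against the CDS contract: alphabet restricted to
#' A/C/G/T (no ambiguity codes -- these are rejected, never resolved),
#' length divisible by three, no internal stop codon, a terminal stop
#' codon, and an ATG start. With `fragment = TRUE` the start and terminal
#' stop requirements are waived (for partial CDSs and codon multisets);
#' internal stops remain forbidden.
#'
#' @param seqs Named character vector of sequences.
#' @param fragment Waive the start-codon and terminal-stop requirements.
#' @param code A [genetic_code()].
#' @return A data frame with columns `id`, `rule`, `detail`, `position`
#'   (codon position where applicable, `NA` otherwise); zero rows when all
#'   sequences pass.
#' @export
cds_violations <- function(seqs, fragment = FALSE, code = genetic_code()) {
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  out <- list()
  push <- function(id, rule, detail, position = NA_integer_) {
    out[[length(out) + 1L]] <<- data.frame(
      id = id, rule = rule, detail = detail, position = position,
      stringsAsFactors = FALSE)
  }
  for (id in names(seqs)) {
    s <- seqs[[id]]
    if (is.na(s) || nchar(s) == 0L) {
      push(id, "empty", "sequence is empty")
      next
    }
    bad <- gregexpr("[^ACGT]", s)[[1L]]
    if (bad[1L] != -1L) {
      push(id, "alphabet",
           paste0("non-ACGT character '", substr(s, bad[1L], bad[1L]),
                  "' at nt ", bad[1L]))
      next
    }
    if (nchar(s) %% 3L != 0L) {
      push(id, "length", paste0("length ", nchar(s), " not divisible by 3"))
      next
    }
    cod <- split_codons(s)
    n <- length(cod)
    stops <- which(code$codon_to_aa[cod] == "*")
    internal <- stops[stops < n]
    for (p in internal) {
      push(id, "internal_stop", paste0("stop codon ", cod[p], " at codon ", p),
           p)
    }
    if (!fragment) {
      if (!(n %in% stops)) {
        push(id, "missing_stop", "no terminal stop codon", n)
      }
      if (cod[1L] != "ATG") {
        push(id, "missing_start", paste0("first codon is ", cod[1L],
                                         ", not ATG"), 1L)
      }
    }
  }
  if (length(out) == 0L) {
    data.frame(id = character(), rule = character(), detail = character(),
               position = integer(), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, out)
  }
}

#' Validate coding sequences
#'
#' Errors with a report of every violated rule (see [cds_violations()]) or
#' returns the input invisibly when all sequences are valid CDSs.
#'
#' @inheritParams cds_violations
#' @return `seqs`, invisibly, when valid.
#' @examples
#' validate_cds(c(g1 = "ATGTAA"))
#' @export
validate_cds <- function(seqs, fragment = FALSE, code = genetic_code()) {
  v <- cds_violations(seqs, fragment = fragment, code = code)
  if (nrow(v) > 0L) {
    msg <- paste0("  ", v$id, ": [", v$rule, "] ", v$detail, collapse = "\n")
    stop("invalid coding sequence(s):\n", msg, call. = FALSE)
  }
  invisible(seqs)
}

#' Translate a coding sequence
#'
#' Codon-by-codon translation under the given genetic code; a terminal stop
#' codon is dropped from the product. Internal stops or invalid sequences
#' are errors.
#'
#' @param seq A single CDS string.
#' @param code A [genetic_code()].
#' @param fragment Allow partial CDSs (no start/terminal-stop requirement).
#' @return Amino-acid string (stop excluded).
#' @examples
#' translate_cds("ATGAAATAA")  # "MK"
#' @export
translate_cds <- function(seq, code = genetic_code(), fragment = FALSE) {
  stopifnot(length(seq) == 1L)
  validate_cds(c(cds = unname(seq)), fragment = fragment, code = code)
  cod <- split_codons(seq)
  aa <- code$codon_to_aa[cod]
  if (aa[length(aa)] == "*") aa <- aa[-length(aa)]
  paste(aa, collapse = "")
}
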