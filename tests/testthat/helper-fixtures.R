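# Shared fixtures, all built in code.

# The codon multiset {AAA x3, AAG x1, GGG x4}, whose CAI/RCA values are
# known in closed form: f1(A)=f2(A)=1/2, f3(A)=3/8, f3(G)=5/8,
# RCA(AAA)=4, RCA(AAG)=0.8.
toy_table <- function() {
  build_usage_table(c(a = "AAAAAAAAAAAG", g = "GGGGGGGGGGGG"),
                    fragment = TRUE)
}

# Usage table with identical counts for all 64 codons (uniform background).
uniform_table <- function(count = 10L) {
  counts <- stats::setNames(rep(count, 64L), codonrca:::CODONS)
  codonrca:::new_usage_table(counts)
}

# Random strictly positive counts over all 64 codons.
random_table <- function(seed, max_count = 200L) {
  set.seed(seed)
  counts <- stats::setNames(sample.int(max_count, 64L, replace = TRUE),
                            codonrca:::CODONS)
  codonrca:::new_usage_table(counts)
}

# Random valid CDS of n_codons non-stop codons (incl. ATG) plus a stop.
random_cds <- function(seed, n_codons = 30L) {
  set.seed(seed)
  code <- genetic_code()
  sense <- names(code$codon_to_aa)[code$codon_to_aa != "*"]
  paste0("ATG",
         paste(sample(sense, n_codons - 1L, replace = TRUE), collapse = ""),
         sample(code$families[["*"]], 1L))
}

write_temp_fasta <- function(lines) {
  path <- tempfile(fileext = ".fasta")
  writeLines(lines, path)
  path
}

# Exhaustive minimum of sum(cost) over synonymous encodings within a GC
# count window; independent oracle for the dynamic program.
enumerate_min_gc <- function(seq, table, lo, hi, mode = "rca",
                             pseudocount = 0.5) {
  code <- table$code
  w <- unclass(relative_adaptiveness(table, mode, pseudocount))
  cod <- codonrca:::split_codons(seq)
  fams <- lapply(cod, function(cc) sort(code$families[[code$codon_to_aa[[cc]]]]))
  grid <- expand.grid(rev(lapply(fams, seq_along)))[, length(fams):1, drop = FALSE]
  best <- NULL
  best_cost <- Inf
  for (r in seq_len(nrow(grid))) {
    codons <- vapply(seq_along(fams),
                     function(i) fams[[i]][grid[r, i]], character(1))
    g <- sum(codonrca:::codon_gc(codons))
    if (g < lo || g > hi) next
    ns <- code$codon_to_aa[codons] != "*"
    cost <- sum(log(w[codons[ns]]))
    if (cost < best_cost - 1e-12) {
      best_cost <- cost
      best <- paste(codons, collapse = "")
    }
  }
  list(seq = best, cost = best_cost)
}

# Plain named numeric w values (class and metadata attributes stripped).
w_values <- function(w) stats::setNames(as.vector(unclass(w)), names(w))
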