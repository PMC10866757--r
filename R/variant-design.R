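#' @keywords internal
new_variant_design <- function(source_id, strategy, seq, constraint_report) {
  structure(list(source_id = source_id, strategy = strategy, seq = seq,
                 constraint_report = constraint_report),
            class = "variant_design")
}

#' @export
print.variant_design <- function(x, ...) {
  r <- x$constraint_report
  cat(sprintf("Variant of %s [%s]: %d nt, GC %.1f%%", x$source_id,
              x$strategy, nchar(x$seq), r$gc_pct))
  if (!is.null(r$average_pct)) {
    cat(sprintf(", average w %.1f%%, min w %.1f%%", r$average_pct, r$min_pct))
  }
  cat("\n")
  if (!is.null(r$substitutions) && nrow(r$substitutions) > 0L) {
    cat("  ", nrow(r$substitutions), "synonymous substitutions\n")
  }
  invisible(x)
}

# Resolve an input that may be a CDS or a protein string into the
# amino-acid sequence to encode (stop excluded) and a source id.
#' @keywords internal
resolve_design_input <- function(input, code, id = NULL,
                                 input_type = c("auto", "cds", "protein")) {
  input_type <- match.arg(input_type)
  if (is.null(id)) id <- if (!is.null(names(input))) names(input)[1L] else "design"
  s <- toupper(unname(input[1L]))
  if (input_type == "auto") {
    input_type <- if (!grepl("[^ACGTU]", s) && nchar(s) %% 3L == 0L &&
                      nchar(s) >= 6L) "cds" else "protein"
  }
  if (input_type == "cds") {
    s <- chartr("U", "T", s)
    aa <- translate_cds(s, code = code)
    list(aa = strsplit(aa, "")[[1L]], cds = s, id = id)
  } else {
    aa <- strsplit(s, "")[[1L]]
    unknown <- setdiff(aa, names(code$families))
    if (length(unknown) > 0L) {
      stop("amino acid(s) not encodable under this genetic code: ",
           paste(unique(unknown), collapse = ", "))
    }
    if ("*" %in% aa) stop("protein input must not contain stop symbols")
    list(aa = aa, cds = NULL, id = id)
  }
}

# Most frequent stop codon of the table (ties and all-zero counts fall
# back to the lexicographically smallest stop).
#' @keywords internal
preferred_stop <- function(table) {
  stops <- sort(table$code$families[["*"]])
  basis <- table$counts[stops]
  if (all(is.na(basis))) basis <- table$per_thousand[stops]
  if (all(is.na(basis))) return(stops[1L])
  stops[which.max(basis)]
}

# Per-position synonymous substitutions between two same-protein CDSs.
#' @keywords internal
substitution_list <- function(from, to) {
  cf <- split_codons(from)
  ct <- split_codons(to)
  stopifnot(length(cf) == length(ct))
  d <- which(cf != ct)
  data.frame(position = d, from = cf[d], to = ct[d],
             stringsAsFactors = FALSE)
}

#' @keywords internal
design_report <- function(seq, table, mode, pseudocount, source_cds = NULL,
                          fragment = FALSE, extra = list()) {
  rep <- list()
  gcm <- gc_metrics(seq)
  rep$gc_pct <- unname(gcm["gc_pct"])
  rep$gc3_pct <- unname(gcm["gc3_pct"])
  if (!is.null(table)) {
    pr <- score_gene(seq, table, mode = mode, pseudocount = pseudocount,
                     fragment = fragment)
    rep$average_pct <- pr$average_pct
    rep$min_pct <- pr$min_pct
  }
  if (!is.null(source_cds) && nchar(source_cds) == nchar(seq)) {
    rep$substitutions <- substitution_list(source_cds, seq)
  }
  c(rep, extra)
}

#' Fully codon-optimize a gene for a reference table
#'
#' Encodes every amino acid by its synonymous family's maximal-w codon
#' (w from [relative_adaptiveness()]), so the result scores an average
#' and minimum adaptation of exactly 100%. Ties are broken by the
#' lexicographically smallest codon; the stop codon is the reference
#' table's most frequent stop. Deterministic by construction.
#'
#' @param input A CDS (synonymously recoded) or an amino-acid string
#'   (encoded de novo; a stop codon is appended either way).
#' @param table A `codon_usage_table`.
#' @param mode Index used for w, `"rca"` (default) or `"cai"`.
#' @param pseudocount Passed to [relative_adaptiveness()].
#' @param id Identifier for the design (defaults to the input's name).
#' @param input_type `"auto"` (default), `"cds"` or `"protein"`.
#' @return A `variant_design` with strategy `"max"`.
#' @examples
#' tab <- build_usage_table(c(g = "ATGAAAAAGAAATAA"))
#' optimize_max("MKK", tab)$seq
#' @export
optimize_max <- function(input, table, mode = c("rca", "cai"),
                         pseudocount = 0.5, id = NULL,
                         input_type = c("auto", "cds", "protein")) {
  mode <- match.arg(tolower(mode[1L]), c("rca", "cai"))
  code <- table$code
  inp <- resolve_design_input(input, code, id, input_type)
  w <- relative_adaptiveness(table, mode = mode, pseudocount = pseudocount)
  best <- best_codon_per_family(w, code)
  if (anyNA(best[inp$aa])) {
    stop("no usable codon for amino acid(s): ",
         paste(unique(inp$aa[is.na(best[inp$aa])]), collapse = ", "))
  }
  seq <- paste0(paste(best[inp$aa], collapse = ""), preferred_stop(table))
  fragment <- inp$aa[1L] != "M"
  new_variant_design(
    inp$id, "max", seq,
    design_report(seq, table, mode, pseudocount, source_cds = inp$cds,
                  fragment = fragment))
}

# Argmax-w codon per amino acid; lexicographic tie-break.
#' @keywords internal
best_codon_per_family <- function(w, code) {
  wv <- unclass(w)
  fams <- code$families[setdiff(names(code$families), "*")]
  out <- vapply(fams, function(fam) {
    fam <- sort(fam)
    ww <- wv[fam]
    if (all(is.na(ww))) return(NA_character_)
    fam[which.max(ww)]
  }, character(1))
  out
}

#' Minimize codon adaptation under a fixed GC-content window (exact DP)
#'
#' Finds, among all synonymous recodings of the input CDS, the one that
#' minimizes the gene's adaptation to the reference table while keeping
#' total GC content inside a window around a target. This emulates the
#' design of "low-adaptation, host-like GC" gene variants, in which rare
#' codons are enriched largely through G-to-C / C-to-G style swaps; the
#' optimizer is not restricted to literal G/C swaps, it solves the general
#' GC-constrained minimization.
#'
#' The optimum is exact: a dynamic program over (codon position,
#' cumulative G+C count) minimizes the sum of log w (geometric-mean
#' consistent; an arithmetic-mean objective is available) subject to the
#' integer G+C count landing inside the window. The percentage-point
#' tolerance is converted to an integer count window by ceiling/flooring,
#' so feasibility is decided on whole bases, without floating-point slack.
#' Stop codons carry no adaptation cost but their G+C counts do bind.
#' Ties are resolved deterministically (lexicographically smallest codon;
#' final GC closest to the target).
#'
#' @param input A valid CDS string (named or use `id`).
#' @param table A `codon_usage_table`.
#' @param gc_target_pct Target GC in percent, or `"input"` (default) for
#'   the input sequence's own GC content.
#' @param tolerance_pp Half-width of the GC window in percentage points.
#' @param mode `"rca"` or `"cai"`.
#' @param mean_kind Objective: `"geometric"` (sum of log w, default) or
#'   `"arithmetic"` (sum of w).
#' @param pseudocount Passed to [relative_adaptiveness()].
#' @param id Identifier for the design.
#' @return A `variant_design` with strategy `"min_gc_constrained"`; its
#'   `constraint_report` includes the achieved GC, the deviation from the
#'   target and the integer count window used.
#' @export
deoptimize_fixed_gc <- function(input, table, gc_target_pct = "input",
                                tolerance_pp = 1,
                                mode = c("rca", "cai"),
                                mean_kind = c("geometric", "arithmetic"),
                                pseudocount = 0.5, id = NULL) {
  mode <- match.arg(tolower(mode[1L]), c("rca", "cai"))
  mean_kind <- match.arg(mean_kind)
  code <- table$code
  if (is.null(id)) id <- if (!is.null(names(input))) names(input)[1L] else "design"
  seq <- chartr("U", "T", toupper(unname(input[1L])))
  validate_cds(stats::setNames(seq, id), code = code)
  cod <- split_codons(seq)
  n_nt <- nchar(seq)

  w <- relative_adaptiveness(table, mode = mode, pseudocount = pseudocount)
  wv <- unclass(w)

  # per-position candidate codons (synonymous family, sorted for
  # deterministic tie-breaks) and their costs / GC counts
  fams <- lapply(cod, function(cc) sort(code$families[[code$codon_to_aa[[cc]]]]))
  is_stop_pos <- code$codon_to_aa[cod] == "*"
  costs <- Map(function(fam, stp) {
    if (stp) return(rep(0, length(fam)))
    ww <- wv[fam]
    if (anyNA(ww)) stop("family absent from reference table (codon ",
                        fam[1L], "); use a positive pseudocount")
    if (mean_kind == "geometric") log(ww) else ww
  }, fams, is_stop_pos)
  gcs <- lapply(fams, codon_gc)

  if (identical(gc_target_pct, "input")) {
    target_count <- sum(codon_gc(cod))
    target_pct <- 100 * target_count / n_nt
  } else {
    target_pct <- as.numeric(gc_target_pct)
    target_count <- target_pct / 100 * n_nt
  }
  lo <- max(0L, as.integer(ceiling(target_count - tolerance_pp / 100 * n_nt - 1e-9)))
  hi <- min(n_nt, as.integer(floor(target_count + tolerance_pp / 100 * n_nt + 1e-9)))

  reach_lo <- sum(vapply(gcs, min, numeric(1)))
  reach_hi <- sum(vapply(gcs, max, numeric(1)))
  if (hi < reach_lo || lo > reach_hi || lo > hi) {
    stop(sprintf(paste0("infeasible GC window: target %.2f%% +/- %.2f pp ",
                        "(counts %d..%d of %d nt), achievable %.2f%%..%.2f%%"),
                 target_pct, tolerance_pp, lo, hi, n_nt,
                 100 * reach_lo / n_nt, 100 * reach_hi / n_nt))
  }

  sol <- dp_min_cost_gc(costs, gcs, lo, hi, target_count)
  out_cod <- vapply(seq_along(fams), function(i) fams[[i]][sol$choice[i]],
                    character(1))
  out_seq <- paste(out_cod, collapse = "")

  new_variant_design(
    id, "min_gc_constrained", out_seq,
    design_report(out_seq, table, mode, pseudocount, source_cds = seq,
                  extra = list(
                    gc_target_pct = target_pct,
                    gc_tolerance_pp = tolerance_pp,
                    gc_window_counts = c(lo, hi),
                    gc_deviation_pp = 100 * sol$gc / n_nt - target_pct,
                    objective = mean_kind)))
}

# Exact DP over (position, cumulative GC count). Minimizes total cost with
# final count in [lo, hi]; among equal costs prefers the earlier
# (lexicographically smaller) codon and the final count closest to target.
#' @keywords internal
dp_min_cost_gc <- function(costs, gcs, lo, hi, target_count) {
  L <- length(costs)
  G <- sum(vapply(gcs, max, numeric(1)))
  best <- rep(Inf, G + 1L)           # index g+1 = cumulative count g
  best[1L] <- 0
  choice <- matrix(0L, nrow = L, ncol = G + 1L)
  for (i in seq_len(L)) {
    nb <- rep(Inf, G + 1L)
    ch <- integer(G + 1L)
    for (k in seq_along(costs[[i]])) {
      g <- gcs[[i]][k]
      shifted <- c(rep(Inf, g), best[seq_len(G + 1L - g)]) + costs[[i]][k]
      upd <- shifted < nb      # strict: first (lexicographic) codon wins ties
      nb[upd] <- shifted[upd]
      ch[upd] <- k
    }
    best <- nb
    choice[i, ] <- ch
  }
  feas <- seq.int(lo, hi) + 1L
  feas <- feas[is.finite(best[feas])]
  if (length(feas) == 0L) stop("infeasible GC window (no synonymous assignment)")
  cost <- best[feas]
  cand <- feas[cost <= min(cost) + 1e-12]
  gfin <- cand[order(abs((cand - 1L) - target_count), cand)][1L]
  # traceback
  pick <- integer(L)
  g <- gfin
  for (i in rev(seq_len(L))) {
    pick[i] <- choice[i, g]
    g <- g - gcs[[i]][pick[i]]
  }
  list(choice = pick, gc = gfin - 1L, cost = best[gfin])
}

#' Design an AT-rich synonymous variant
#'
#' Encodes each amino acid (and the stop) with the synonymous codon of
#' minimal G+C count, emulating chloroplast-style AT-rich gene versions
#' biased toward A/T in the third position. Ties go to the lowest-w codon
#' under `table` (rarest), or to the lexicographically smallest codon when
#' no table is given. The result's GC is provably minimal over all
#' synonymous encodings.
#'
#' @param input CDS or amino-acid string (see [optimize_max()]).
#' @param table Optional `codon_usage_table` for tie-breaking and scoring.
#' @param mode,pseudocount Passed to scoring when `table` is given.
#' @param id Identifier.
#' @param input_type `"auto"`, `"cds"` or `"protein"`.
#' @return A `variant_design` with strategy `"at_rich"`.
#' @examples
#' design_at_rich("MKF")$seq  # "ATGAAATTTTAA"
#' @export
design_at_rich <- function(input, table = NULL, mode = c("rca", "cai"),
                           pseudocount = 0.5, id = NULL,
                           input_type = c("auto", "cds", "protein")) {
  mode <- match.arg(tolower(mode[1L]), c("rca", "cai"))
  code <- if (is.null(table)) genetic_code() else table$code
  inp <- resolve_design_input(input, code, id, input_type)
  wv <- if (is.null(table)) NULL else
    unclass(relative_adaptiveness(table, mode = mode, pseudocount = pseudocount))
  pick <- function(aa) {
    fam <- sort(code$families[[aa]])
    g <- codon_gc(fam)
    fam <- fam[g == min(g)]
    if (length(fam) > 1L && !is.null(wv) && !anyNA(wv[fam])) {
      fam <- fam[order(wv[fam], fam)]
    }
    fam[1L]
  }
  body <- vapply(inp$aa, pick, character(1))
  seq <- paste0(paste(body, collapse = ""), pick("*"))
  fragment <- inp$aa[1L] != "M"
  new_variant_design(
    inp$id, "at_rich", seq,
    design_report(seq, table, mode, pseudocount, source_cds = inp$cds,
                  fragment = fragment))
}

#' Build a secretion or ER-retention fusion construct
#'
#' Fuses a signal peptide (given as an amino-acid sequence, e.g. the
#' 21-residue signal peptide of a secreted carbonic anhydrase) to the
#' N-terminus of a mature CDS. The signal-peptide codons are
#' codon-optimized for the reference table ([optimize_max()] per residue).
#' Optionally the mature protein's initiator Met is dropped (both
#' conventions occur in fusion designs; signal-peptidase cleavage leaves
#' either way a near-native N-terminus), and an HDEL ER-retention
#' tetrapeptide (table-optimal codons) is inserted before the stop codon.
#' The mature CDS's own stop codon is retained.
#'
#' @param mature A valid CDS string (named, or use `id`).
#' @param signal_peptide Amino-acid string starting with Met.
#' @param table A `codon_usage_table`.
#' @param er_retention Append HDEL before the stop (ER construct).
#' @param drop_initiator_met Remove the mature CDS's initial ATG codon.
#' @param mode,pseudocount Passed to [relative_adaptiveness()].
#' @param id Identifier for the design.
#' @return A `variant_design` with strategy `"fusion"`; the
#'   `constraint_report` carries the fusion protein sequence and segment
#'   lengths.
#' @export
build_secretion_variant <- function(mature, signal_peptide, table,
                                    er_retention = FALSE,
                                    drop_initiator_met = FALSE,
                                    mode = c("rca", "cai"),
                                    pseudocount = 0.5, id = NULL) {
  mode <- match.arg(tolower(mode[1L]), c("rca", "cai"))
  code <- table$code
  if (is.null(id)) id <- if (!is.null(names(mature))) names(mature)[1L] else "fusion"
  m <- chartr("U", "T", toupper(unname(mature[1L])))
  if (nchar(m) == 0L) stop("empty mature CDS")
  validate_cds(stats::setNames(m, id), code = code)
  sp <- toupper(signal_peptide)
  if (substr(sp, 1L, 1L) != "M") {
    stop("signal peptide must start with an initiator Met")
  }
  w <- relative_adaptiveness(table, mode = mode, pseudocount = pseudocount)
  best <- best_codon_per_family(w, code)
  encode <- function(aa_string) {
    aa <- strsplit(aa_string, "")[[1L]]
    if (anyNA(best[aa])) stop("amino acid(s) not encodable: ",
                              paste(aa[is.na(best[aa])], collapse = ", "))
    paste(best[aa], collapse = "")
  }
  cod <- split_codons(m)
  stop_codon <- cod[length(cod)]
  body <- cod[-length(cod)]
  if (drop_initiator_met) body <- body[-1L]
  hdel <- if (er_retention) encode("HDEL") else ""
  seq <- paste0(encode(sp), paste(body, collapse = ""), hdel, stop_codon)
  validate_cds(stats::setNames(seq, id), code = code)
  new_variant_design(
    id, "fusion", seq,
    design_report(seq, table, mode, pseudocount, extra = list(
      signal_peptide = sp,
      sp_length = nchar(sp),
      er_retention = er_retention,
      drop_initiator_met = drop_initiator_met,
      translation = translate_cds(seq, code = code))))
}

#' Write a variant's constraint report as JSON
#'
#' @param design A `variant_design`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_design_report <- function(design, path) {
  stopifnot(inherits(design, "variant_design"))
  rep <- design$constraint_report
  if (!is.null(rep$substitutions)) {
    rep$n_substitutions <- nrow(rep$substitutions)
  }
  out <- list(source_id = design$source_id, strategy = design$strategy,
              seq = design$seq, constraint_report = rep)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
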