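#' Synthetic five-variant transgene design study
#'
#' Composes the package's design strategies into the canonical comparative
#' experiment of codon-usage studies: one reporter protein, several
#' synonymous gene versions, all scored against the host's codon-usage
#' table. Everything is synthetic and seeded; the sequences stand in for
#' real supplementary material, with known construction rather than known
#' provenance.
#'
#' The emulated cast:
#' \describe{
#'   \item{at_rich}{chloroplast-style AT-rich version (minimal-GC codons):
#'     very low adaptation to a GC-rich host.}
#'   \item{gc_matched_rare}{adaptation-minimized at host-like GC via the
#'     exact GC-constrained dynamic program: high GC yet rare codons.}
#'   \item{distant_opt}{fully optimized for a distantly related usage
#'     (foreign table only loosely correlated with the host): fairly high
#'     adaptation with residual rare codons.}
#'   \item{similar_opt}{fully optimized for a closely related usage: high
#'     adaptation, no rare codons (minimal adaptation above 50%).}
#'   \item{host_opt}{fully optimized for the host itself: average and
#'     minimal adaptation exactly 100%.}
#' }
#'
#' The host usage is a per-family Dirichlet draw whose shape is boosted
#' for G/C-ending codons (a GC3-rich nuclear genome); foreign usages are
#' per-family Dirichlet draws centred on the host probabilities with
#' concentration `kappa_similar` / `kappa_distant` (large concentration =
#' similar codon usage).
#'
#' @param seed Integer seed for the whole study.
#' @param protein_length Reporter protein length in residues (default 239,
#'   a fluorescent-reporter-sized protein starting with Met).
#' @param n_codons_table Codon mass of the synthetic usage tables
#'   (default 27040, a ~92-CDS reference set's worth).
#' @param kappa_similar,kappa_distant Dirichlet concentrations tying the
#'   two foreign genomes to the host (defaults 200 and 2).
#' @param gc3_shape_boost Shape multiplier for G/C-ending codons in the
#'   host usage draw (default 3).
#' @param bias_concentration Base Dirichlet concentration of the host
#'   usage (default 0.5, strong codon bias).
#' @param gc_target_pct,gc_tolerance_pp GC window for the
#'   `gc_matched_rare` variant (defaults 55 and 3, a GC-rich-genome-like
#'   target).
#' @param mode Scoring index, `"rca"` (default) or `"cai"`.
#' @return A `study_report` whose rows are the five variants scored
#'   against the host table, with extra elements `host_table`,
#'   `foreign_tables`, `protein` and `designs` attached as attributes.
#' @examples
#' rep <- synthetic_variant_study(seed = 1, protein_length = 60)
#' rep$rows[, c("id", "average_pct", "min_pct")]
#' @export
synthetic_variant_study <- function(seed = 1L, protein_length = 239L,
                                    n_codons_table = 27040,
                                    kappa_similar = 200,
                                    kappa_distant = 2,
                                    gc3_shape_boost = 3,
                                    bias_concentration = 0.5,
                                    gc_target_pct = 55,
                                    gc_tolerance_pp = 3,
                                    mode = "rca") {
  code <- genetic_code()
  usage_to_table <- function(u) {
    cts <- stats::setNames(rep(0, 64L), CODONS)
    for (aa in names(code$families)) {
      fam <- sort(code$families[[aa]])
      cts[fam] <- u[[aa]][fam] / length(code$families)
    }
    new_usage_table(cts * n_codons_table, code = code)
  }
  draw <- function(shapes) {
    g <- stats::rgamma(length(shapes), shape = shapes)
    while (sum(g) == 0) g <- stats::rgamma(length(shapes), shape = shapes)
    g / sum(g)
  }
  out <- with_seed(as.integer(seed) + 515L, {
    host <- lapply(code$families, function(fam) {
      fam <- sort(fam)
      shape <- bias_concentration *
        ifelse(substr(fam, 3L, 3L) %in% c("G", "C"), gc3_shape_boost, 1)
      stats::setNames(draw(shape), fam)
    })
    perturb <- function(u, kappa) {
      lapply(u, function(p) stats::setNames(draw(kappa * p), names(p)))
    }
    similar <- perturb(host, kappa_similar)
    distant <- perturb(host, kappa_distant)
    prot <- paste0("M", paste(sample(AMINO_ACIDS_20, protein_length - 1L,
                                     replace = TRUE), collapse = ""))
    list(host = host, similar = similar, distant = distant, prot = prot)
  })
  host_tab <- usage_to_table(out$host)
  similar_tab <- usage_to_table(out$similar)
  distant_tab <- usage_to_table(out$distant)

  host_opt <- optimize_max(out$prot, host_tab, mode = mode,
                           id = "host_opt", input_type = "protein")
  designs <- list(
    at_rich = design_at_rich(out$prot, host_tab, mode = mode,
                             id = "at_rich", input_type = "protein"),
    gc_matched_rare = deoptimize_fixed_gc(
      stats::setNames(host_opt$seq, "gc_matched_rare"), host_tab,
      gc_target_pct = gc_target_pct, tolerance_pp = gc_tolerance_pp,
      mode = mode),
    distant_opt = optimize_max(out$prot, distant_tab, mode = mode,
                               id = "distant_opt", input_type = "protein"),
    similar_opt = optimize_max(out$prot, similar_tab, mode = mode,
                               id = "similar_opt", input_type = "protein"),
    host_opt = host_opt
  )
  w <- relative_adaptiveness(host_tab, mode = mode)
  profiles <- lapply(designs, function(d) {
    score_gene(d$seq, host_tab, mode = mode, id = d$source_id, w = w)
  })
  rows <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(id = p$gene_id, gc_pct = p$gc_pct, gc3_pct = p$gc3_pct,
               average_pct = p$average_pct, min_pct = p$min_pct,
               mode = p$mode, mean_kind = p$mean_kind,
               stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  report <- structure(
    list(rows = rows, profiles = profiles,
         provenance = list(
           table_source = list(kind = "synthetic",
                               n_codons = n_codons_table,
                               kappa_similar = kappa_similar,
                               kappa_distant = kappa_distant),
           parameters = list(mode = mode, mean_kind = "geometric",
                             pseudocount = 0.5),
           seed = as.integer(seed),
           package_version = as.character(utils::packageVersion("codonrca")))),
    class = "study_report")
  attr(report, "host_table") <- host_tab
  attr(report, "foreign_tables") <- list(similar = similar_tab,
                                         distant = distant_tab)
  attr(report, "protein") <- out$prot
  attr(report, "designs") <- designs
  report
}
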