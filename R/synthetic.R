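# Run expr with a locally seeded RNG, restoring the caller's RNG state.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

AMINO_ACIDS_20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Specification for a synthetic codon-usage / RNA-seq study
#'
#' Bundles every tunable of the generator with the seed, so each artifact
#' can be replayed. Defaults emulate the kind of study the pipeline is
#' built for: a GC-rich unicellular transcriptome sampled in triplicate at
#' three time points of the light phase (9 libraries in all), with a
#' strongly biased codon usage and a heavy-tailed expression distribution
#' in which a small set of genes dominates.
#'
#' @param seed Integer seed; every stochastic operation derives its own
#'   stream from it.
#' @param n_genes Number of genes.
#' @param length_codons Non-stop codons per CDS (including the ATG):
#'   either a single value or a `c(min, max)` sampling range. Default
#'   150-450 (mean ~300, matching reference CDSs of ~900 nt).
#' @param bias_concentration Symmetric Dirichlet concentration per
#'   synonymous family; small values give strong codon bias (default 0.5).
#' @param expression_sdlog Log-normal sd of gene expression levels
#'   (default 1.5; heavy-tailed so a few genes are very highly expressed).
#' @param n_timepoints Time points, sampled every two hours starting at
#'   5 h of light (default 3, i.e. 5/7/9 h).
#' @param replicates_per_timepoint Replicates per time point (default 3).
#' @param nb_dispersion Negative-binomial dispersion of counts
#'   (`size = 1/dispersion`); `0` means noiseless rounded means.
#' @param bias_coupling In `[0, 1]`: 0 gives every gene the same codon
#'   usage; 1 makes bias strength proportional to expression rank (highly
#'   expressed genes fully biased, lowly expressed ones near-uniform).
#' @param n_unstable Number of genes given a time-point effect (removed by
#'   the stability filter in a faithful analysis).
#' @param unstable_fold Fold change applied to unstable genes at one time
#'   point (default 8).
#' @param depth_sdlog Log-normal sd of per-sample depth factors.
#' @param aa_palette `"uniform"` over the 20 amino acids, or a named
#'   probability vector.
#' @return A `synthetic_spec` (validated list).
#' @export
synthetic_spec <- function(seed = 1L, n_genes = 600L,
                           length_codons = c(150L, 450L),
                           bias_concentration = 0.5,
                           expression_sdlog = 1.5,
                           n_timepoints = 3L,
                           replicates_per_timepoint = 3L,
                           nb_dispersion = 0.05,
                           bias_coupling = 0,
                           n_unstable = 10L,
                           unstable_fold = 8,
                           depth_sdlog = 0.15,
                           aa_palette = "uniform") {
  stopifnot(bias_concentration > 0, n_genes >= 1,
            bias_coupling >= 0, bias_coupling <= 1,
            n_timepoints >= 1, replicates_per_timepoint >= 1,
            nb_dispersion >= 0, n_unstable >= 0, n_unstable <= n_genes,
            unstable_fold > 0, all(length_codons >= 2))
  if (identical(aa_palette, "uniform")) {
    aa_palette <- stats::setNames(rep(1 / 20, 20), AMINO_ACIDS_20)
  }
  stopifnot(!is.null(names(aa_palette)),
            all(names(aa_palette) %in% AMINO_ACIDS_20))
  aa_palette <- aa_palette / sum(aa_palette)
  structure(
    list(seed = as.integer(seed), n_genes = as.integer(n_genes),
         length_codons = as.integer(length_codons),
         bias_concentration = bias_concentration,
         expression_sdlog = expression_sdlog,
         n_timepoints = as.integer(n_timepoints),
         replicates_per_timepoint = as.integer(replicates_per_timepoint),
         nb_dispersion = nb_dispersion,
         bias_coupling = bias_coupling,
         n_unstable = as.integer(n_unstable),
         unstable_fold = unstable_fold,
         depth_sdlog = depth_sdlog,
         aa_palette = aa_palette),
    class = "synthetic_spec"
  )
}

#' Draw ground-truth within-family codon probabilities
#'
#' For each synonymous family of size m, probabilities come from a
#' symmetric Dirichlet(`bias_concentration`) of dimension m (sampled as
#' normalized gammas). Single-codon families get probability 1.
#' Seed-reproducible: the same spec always yields the same usage.
#'
#' @param spec A [synthetic_spec()].
#' @param code A [genetic_code()].
#' @return Named list, one numeric probability vector per family (amino
#'   acids and `"*"`), each summing to 1.
#' @export
sample_usage <- function(spec, code = genetic_code()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed + 101L, {
    lapply(code$families, function(fam) {
      fam <- sort(fam)
      g <- stats::rgamma(length(fam), shape = spec$bias_concentration)
      while (sum(g) == 0) g <- stats::rgamma(length(fam),
                                             shape = spec$bias_concentration)
      stats::setNames(g / sum(g), fam)
    })
  })
}

# Deterministic (seeded) per-gene truths shared by the reference and
# count generators: lengths, expression levels, unstable-gene assignment.
#' @keywords internal
synthetic_truth <- function(spec) {
  with_seed(spec$seed + 202L, {
    ids <- sprintf("gene%04d", seq_len(spec$n_genes))
    len <- if (length(spec$length_codons) == 1L) {
      rep(spec$length_codons, spec$n_genes)
    } else {
      sample(spec$length_codons[1L]:spec$length_codons[2L], spec$n_genes,
             replace = TRUE)
    }
    expr <- stats::rlnorm(spec$n_genes, meanlog = 0,
                          sdlog = spec$expression_sdlog)
    unstable <- sort(sample(ids, spec$n_unstable))
    unstable_tp <- sample(seq_len(spec$n_timepoints), spec$n_unstable,
                          replace = TRUE)
    list(ids = ids,
         length_codons = stats::setNames(len, ids),
         length_nt = stats::setNames(3L * (len + 1L), ids),
         expression = stats::setNames(expr, ids),
         true_order = ids[order(-expr, ids)],
         unstable = unstable,
         unstable_tp = stats::setNames(unstable_tp, unstable))
  })
}

#' Generate a reference set of coding sequences with known codon bias
#'
#' Each gene is an ATG, `length_codons - 1` codons drawn from the
#' amino-acid palette and the within-family ground-truth probabilities,
#' and a stop codon drawn from the stop family's probabilities. With
#' `bias_coupling > 0` a gene's within-family probabilities are shrunk
#' toward uniform in proportion to how lowly expressed it is, coupling
#' codon bias to expression rank as selection-driven codon usage would.
#' All outputs are valid CDSs.
#'
#' @param spec A [synthetic_spec()].
#' @param usage Ground-truth probabilities from [sample_usage()]
#'   (defaults to `sample_usage(spec)`).
#' @param code A [genetic_code()].
#' @return Named character vector of CDSs with attribute `"truth"` (the
#'   shared per-gene truths; see also [generate_counts()]).
#' @export
generate_reference <- function(spec, usage = NULL, code = genetic_code()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (is.null(usage)) usage <- sample_usage(spec, code)
  truth <- synthetic_truth(spec)
  n <- spec$n_genes
  # expression percentile in (0, 1]; 1 = most expressed
  pr <- stats::setNames(
    (n + 1L - rank(-truth$expression, ties.method = "first")) / n, truth$ids)
  aa_pool <- names(spec$aa_palette)
  seqs <- with_seed(spec$seed + 303L, {
    vapply(truth$ids, function(id) {
      strength <- (1 - spec$bias_coupling) + spec$bias_coupling * pr[[id]]
      p_gene <- lapply(usage, function(p) {
        q <- strength * p + (1 - strength) / length(p)
        q / sum(q)
      })
      L <- truth$length_codons[[id]]
      aas <- sample(aa_pool, L - 1L, replace = TRUE, prob = spec$aa_palette)
      cods <- character(L - 1L)
      for (aa in unique(aas)) {
        idx <- which(aas == aa)
        p <- p_gene[[aa]]
        cods[idx] <- sample(names(p), length(idx), replace = TRUE, prob = p)
      }
      pstop <- p_gene[["*"]]
      paste0("ATG", paste(cods, collapse = ""),
             sample(names(pstop), 1L, prob = pstop))
    }, character(1))
  })
  attr(seqs, "truth") <- c(truth, list(usage = usage))
  seqs
}

#' Generate a replicate count matrix with known expression structure
#'
#' The mean count of gene g in sample s is
#' `expression_g * length_nt_g * depth_s`, times the unstable-gene fold
#' effect at the affected time point; counts are drawn negative-binomially
#' with the spec's dispersion (noiseless rounded means when the dispersion
#' is 0). Because means are proportional to expression times length, TPM
#' rank equals expression rank, and the ground-truth top-k set is exactly
#' the head of the recorded `true_order`.
#'
#' @param spec A [synthetic_spec()].
#' @return An [expression_matrix()] with attribute `"truth"`: list with
#'   the per-gene `expression`, `true_order`, `unstable` gene ids, their
#'   affected time point, the sample `depth` factors and the `spec`.
#' @export
generate_counts <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  truth <- synthetic_truth(spec)
  tps <- 5L + 2L * (seq_len(spec$n_timepoints) - 1L)
  labels <- as.vector(t(outer(tps, seq_len(spec$replicates_per_timepoint),
                              function(t, r) sprintf("t%d_r%d", t, r))))
  tp_of_sample <- rep(seq_len(spec$n_timepoints),
                      each = spec$replicates_per_timepoint)
  n_s <- length(labels)
  out <- with_seed(spec$seed + 404L, {
    depth <- stats::rlnorm(n_s, meanlog = log(0.2), sdlog = spec$depth_sdlog)
    mu <- outer(truth$expression * truth$length_nt, depth)
    for (g in truth$unstable) {
      hit <- tp_of_sample == truth$unstable_tp[[g]]
      mu[g, hit] <- mu[g, hit] * spec$unstable_fold
    }
    counts <- if (spec$nb_dispersion > 0) {
      matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / spec$nb_dispersion),
             nrow = nrow(mu))
    } else {
      round(mu)
    }
    dimnames(counts) <- list(truth$ids, labels)
    list(counts = counts, depth = depth)
  })
  em <- expression_matrix(out$counts, truth$length_nt, labels)
  attr(em, "truth") <- c(truth, list(depth = out$depth, spec = spec))
  em
}

#' Write a complete synthetic fixture directory
#'
#' Emits the same file dialects the pipeline reads (reference FASTA,
#' count and length TSVs) plus a ground-truth JSON, so an end-to-end run
#' can be replayed from disk.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Output directory (created if needed).
#' @return Invisible named list of the written paths.
#' @export
simulate_study <- function(spec, dir) {
  stopifnot(inherits(spec, "synthetic_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  usage <- sample_usage(spec)
  ref <- generate_reference(spec, usage)
  em <- generate_counts(spec)
  truth <- attr(em, "truth")
  paths <- list(
    reference_fasta = file.path(dir, "reference.fasta"),
    counts = file.path(dir, "counts.tsv"),
    lengths = file.path(dir, "lengths.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_fasta(ref, paths$reference_fasta)
  utils::write.table(
    data.frame(gene = rownames(em$counts), em$counts, check.names = FALSE),
    paths$counts, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(gene = names(em$lengths), length = unname(em$lengths)),
    paths$lengths, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(spec = unclass(spec), usage = usage,
         expression = as.list(truth$expression),
         true_order = truth$true_order, unstable = truth$unstable),
    paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
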