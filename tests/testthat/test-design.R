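test_that("optimize_max picks the argmax-w codon and is idempotent", {
  toy <- toy_table()
  d <- optimize_max("MK", toy, mode = "cai", pseudocount = 0)
  expect_identical(d$seq, "ATGAAATAA")   # AAA beats AAG 3:1; stops tie -> TAA
  d2 <- optimize_max(stats::setNames(d$seq, "v1"), toy, mode = "cai",
                     pseudocount = 0)
  expect_identical(d2$seq, d$seq)
  expect_identical(translate_cds(d$seq), "MK")

  tab <- random_table(41)
  cds <- random_cds(5, n_codons = 30L)
  dd <- optimize_max(c(x = cds), tab)
  expect_identical(translate_cds(dd$seq), translate_cds(cds))
  expect_equal(dd$constraint_report$average_pct, 100)
  ddd <- optimize_max(c(x = dd$seq), tab)
  expect_identical(ddd$seq, dd$seq)
})

test_that("GC-constrained deoptimization matches the hand enumeration on the toy", {
  toy <- toy_table()
  # window pinned to the input's own GC: AAG would add a G, so unchanged
  d0 <- deoptimize_fixed_gc(c(x = "ATGAAAAAATAA"), toy, tolerance_pp = 0,
                            mode = "rca", pseudocount = 0)
  expect_identical(d0$seq, "ATGAAAAAATAA")
  expect_equal(d0$constraint_report$gc_deviation_pp, 0)
  # two extra G allowed: both Lys flip to the rare AAG
  d2 <- deoptimize_fixed_gc(c(x = "ATGAAAAAATAA"), toy, tolerance_pp = 20,
                            mode = "rca", pseudocount = 0)
  expect_identical(d2$seq, "ATGAAGAAGTAA")
})

test_that("single-codon-family proteins pass through the deoptimizer", {
  tab <- random_table(43)
  mw <- optimize_max("MWWM", tab)$seq
  d <- deoptimize_fixed_gc(c(x = mw), tab, tolerance_pp = 0)
  expect_identical(substr(d$seq, 1, nchar(mw) - 3),
                   substr(mw, 1, nchar(mw) - 3))
})

test_that("the DP equals exhaustive enumeration on short inputs", {
  set.seed(71)
  for (i in 1:12) {
    tab <- random_table(1000 + i)
    cds <- random_cds(2000 + i, n_codons = sample(2:6, 1))
    n_nt <- nchar(cds)
    target <- 100 * sum(codonrca:::codon_gc(codonrca:::split_codons(cds))) / n_nt
    tol <- sample(c(0, 5, 10, 25), 1)
    lo <- max(0L, as.integer(ceiling(target / 100 * n_nt - tol / 100 * n_nt - 1e-9)))
    hi <- min(n_nt, as.integer(floor(target / 100 * n_nt + tol / 100 * n_nt + 1e-9)))
    d <- deoptimize_fixed_gc(c(x = cds), tab, tolerance_pp = tol)
    oracle <- enumerate_min_gc(cds, tab, lo, hi)
    w <- unclass(relative_adaptiveness(tab, "rca"))
    code <- tab$code
    cost_of <- function(s) {
      cc <- codonrca:::split_codons(s)
      cc <- cc[code$codon_to_aa[cc] != "*"]
      sum(log(w[cc]))
    }
    expect_equal(cost_of(d$seq), oracle$cost, tolerance = 1e-9)
    expect_identical(translate_cds(d$seq), translate_cds(cds))
  }
})

test_that("deoptimization respects its integer GC window exactly", {
  set.seed(77)
  for (i in 1:10) {
    tab <- random_table(3000 + i)
    cds <- random_cds(4000 + i, n_codons = 20L)
    n_nt <- nchar(cds)
    tol <- runif(1, 0, 8)
    target <- runif(1, 35, 65)
    d <- tryCatch(
      deoptimize_fixed_gc(c(x = cds), tab, gc_target_pct = target,
                          tolerance_pp = tol),
      error = function(e) e)
    if (inherits(d, "error")) {
      expect_match(conditionMessage(d), "infeasible")
      next
    }
    gc_count <- sum(codonrca:::codon_gc(codonrca:::split_codons(d$seq)))
    win <- d$constraint_report$gc_window_counts
    expect_gte(gc_count, win[1])
    expect_lte(gc_count, win[2])
    expect_lte(abs(d$constraint_report$gc_deviation_pp), tol + 100 * 1 / n_nt)
  }
})

test_that("deoptimizing a fully optimized gene cannot raise its score", {
  tab <- random_table(53)
  x <- random_cds(54, n_codons = 30L)
  opt <- optimize_max(c(x = x), tab)$seq
  deopt <- deoptimize_fixed_gc(c(x = opt), tab, tolerance_pp = 10)$seq
  s <- function(z) score_gene(z, tab)$average_pct
  expect_lte(s(deopt), s(opt) + 1e-9)
  expect_lte(s(deopt), 100)
})

test_that("AT-rich design achieves the minimal GC over synonymous encodings", {
  expect_identical(design_at_rich("K")$seq, "AAATAA")
  expect_identical(design_at_rich("F")$seq, "TTTTAA")
  expect_identical(design_at_rich("MKF")$seq, "ATGAAATTTTAA")
  # exhaustive check for short random proteins
  code <- genetic_code()
  set.seed(81)
  aas <- setdiff(names(code$families), "*")
  for (i in 1:8) {
    prot <- paste(sample(aas, sample(1:5, 1), replace = TRUE), collapse = "")
    d <- design_at_rich(prot, input_type = "protein")
    fams <- lapply(strsplit(prot, "")[[1]], function(a) code$families[[a]])
    fams <- c(fams, list(code$families[["*"]]))
    grid <- expand.grid(lapply(fams, seq_along))
    gcs <- apply(grid, 1, function(r) {
      sum(codonrca:::codon_gc(vapply(seq_along(fams),
                                     function(j) fams[[j]][r[j]], "")))
    })
    achieved <- sum(codonrca:::codon_gc(codonrca:::split_codons(d$seq)))
    expect_equal(achieved, min(gcs))
    expect_identical(translate_cds(d$seq, fragment = TRUE), prot)
  }
  # tie-break by lowest w when a table is given
  toy <- toy_table()
  expect_identical(design_at_rich("MK", toy)$seq, "ATGAAATAA")
})

test_that("secretion/ER fusions concatenate, optimize the SP, and retain HDEL", {
  tab <- random_table(91)
  sp <- "MKSAVLLALCLVATAFAAPQA"      # synthetic 21-residue signal peptide
  mature <- c(y = random_cds(92, n_codons = 40L))
  mat_prot <- translate_cds(mature[[1]])

  plain <- build_secretion_variant(mature, sp, tab)
  expect_identical(translate_cds(plain$seq), paste0(sp, mat_prot))

  er <- build_secretion_variant(mature, sp, tab, er_retention = TRUE)
  tr <- translate_cds(er$seq)
  expect_identical(substr(tr, nchar(tr) - 3, nchar(tr)), "HDEL")
  expect_equal(nchar(tr), 21 + nchar(mat_prot) + 4)

  nomet <- build_secretion_variant(mature, sp, tab,
                                   drop_initiator_met = TRUE)
  expect_identical(translate_cds(nomet$seq),
                   paste0(sp, substr(mat_prot, 2, nchar(mat_prot))))

  # the SP segment is fully codon-optimized for the table
  sp_cds <- substr(plain$seq, 1, 3 * nchar(sp))
  expect_equal(score_gene(sp_cds, tab, fragment = TRUE)$average_pct, 100)

  expect_error(build_secretion_variant(mature, "KSAVL", tab), "Met")
  expect_error(build_secretion_variant(c(y = ""), sp, tab), "empty")
})

test_that("every design strategy preserves the encoded protein", {
  tab <- random_table(99)
  for (seed in 1:5) {
    cds <- c(x = random_cds(500 + seed, n_codons = 20L))
    prot <- translate_cds(cds[[1]])
    expect_identical(translate_cds(optimize_max(cds, tab)$seq), prot)
    expect_identical(translate_cds(design_at_rich(cds, tab)$seq), prot)
    expect_identical(
      translate_cds(deoptimize_fixed_gc(cds, tab, tolerance_pp = 15)$seq),
      prot)
  }
})

test_that("design reports serialize to JSON with the constraint fields", {
  tab <- random_table(101)
  d <- deoptimize_fixed_gc(c(x = random_cds(102, n_codons = 15L)), tab,
                           tolerance_pp = 5)
  path <- tempfile(fileext = ".json")
  write_design_report(d, path)
  got <- jsonlite::read_json(path)
  expect_identical(got$strategy, "min_gc_constrained")
  expect_identical(got$seq, d$seq)
  expect_true(is.numeric(got$constraint_report$gc_pct))
})
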