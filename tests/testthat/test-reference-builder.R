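test_that("median-of-ratios size factors match the hand formula", {
  m <- cbind(s1 = c(10, 40, 7), s2 = c(10, 40, 7))
  rownames(m) <- paste0("g", 1:3)
  expect_equal(unname(size_factors_median_of_ratios(m)), c(1, 1))

  # column2 = 2 x column1: reference = sqrt(2) c, factors (1/sqrt2, sqrt2)
  m2 <- cbind(s1 = c(10, 40, 7), s2 = c(20, 80, 14))
  expect_equal(unname(size_factors_median_of_ratios(m2)),
               c(1 / sqrt(2), sqrt(2)))

  # single gene, counts (4, 9): geometric mean 6, factors (2/3, 3/2)
  m3 <- matrix(c(4, 9), nrow = 1, dimnames = list("g1", c("a", "b")))
  expect_equal(unname(size_factors_median_of_ratios(m3)), c(2 / 3, 3 / 2))

  expect_error(size_factors_median_of_ratios(cbind(c(0, 1), c(1, 0))),
               "no gene")
})

test_that("size factors agree with the DESeq2 oracle on a random matrix", {
  skip_if_not_installed("DESeq2")
  set.seed(7)
  # odd gene count: the median picks one element, on which the plain
  # ratio median and DESeq2's log-scale median provably coincide
  m <- matrix(rnbinom(294, mu = 100, size = 5) + 1, nrow = 49,
              dimnames = list(paste0("g", 1:49), paste0("t5_r", 1:6)))
  expect_equal(unname(size_factors_median_of_ratios(m)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-10)
})

test_that("TPM matches its defining formula and normalizes columns", {
  one <- matrix(57, 1, 1, dimnames = list("g1", "t5_r1"))
  expect_equal(unname(compute_tpm(one, 300)[1, 1]), 1e6)

  two <- matrix(c(30, 30), 2, 1, dimnames = list(c("g1", "g2"), "t5_r1"))
  expect_equal(unname(compute_tpm(two, c(100, 200))[, 1]),
               c(2e6 / 3, 1e6 / 3))

  set.seed(11)
  m <- matrix(rpois(9, 50) + 1, 3, 3,
              dimnames = list(paste0("g", 1:3), paste0("t5_r", 1:3)))
  len <- c(g1 = 150, g2 = 900, g3 = 420)
  got <- compute_tpm(m, len)
  # brute-force two-step rate/renormalize oracle with explicit loops
  want <- m * NA
  for (s in 1:3) {
    rate <- numeric(3)
    for (g in 1:3) rate[g] <- m[g, s] / len[g]
    for (g in 1:3) want[g, s] <- 1e6 * rate[g] / sum(rate)
  }
  expect_equal(got, want)
  expect_equal(unname(colSums(got)), rep(1e6, 3), tolerance = 1e-9)
  expect_error(compute_tpm(cbind(a = c(0, 0)), c(1, 1)), "all-zero")
})

test_that("stability filter removes time-shifted genes and keeps flat ones", {
  # proportional columns: every gene has identical TPM in all samples
  labels <- paste0(rep(c("t5", "t7", "t9"), each = 3), "_r", 1:3)
  base <- (1:8) * 10
  flat <- outer(base, c(1, 2, 1, 3, 1, 1, 2, 1, 1))
  dimnames(flat) <- list(paste0("g", 1:8), labels)
  emf <- expression_matrix(flat, stats::setNames(rep(900, 8),
                                                 rownames(flat)))
  fltf <- stability_filter(emf, alpha = 0.05)
  expect_identical(fltf$retained, rownames(flat))
  expect_equal(fltf$report$statistic, rep(0, 8))

  set.seed(3)
  n <- 40
  counts <- matrix(rpois(n * 9, 200), nrow = n,
                   dimnames = list(sprintf("g%02d", 1:n), labels))
  counts["g02", 7:9] <- rpois(3, 1600)        # 8-fold shift at t9
  em <- expression_matrix(counts, stats::setNames(rep(900, n),
                                                  rownames(counts)))
  flt <- stability_filter(em, alpha = 0.05)
  expect_false("g02" %in% flt$retained)

  # textbook one-way F statistic, computed from the hand formula
  y <- log2(em$tpm["g02", ] + 1)
  gm <- mean(y)
  mg <- tapply(y, rep(1:3, each = 3), mean)
  ssb <- 3 * sum((mg - gm)^2)
  ssw <- sum((y - rep(mg, each = 3))^2)
  f_hand <- (ssb / 2) / (ssw / 6)
  expect_equal(flt$report$statistic[flt$report$gene == "g02"], f_hand)

  expect_identical(stability_filter(em, alpha = 0)$retained,
                   rownames(counts))
})

test_that("rank_genes orders by pooled mean TPM with lexicographic ties", {
  set.seed(5)
  counts <- matrix(rpois(10 * 4, 100), nrow = 10,
                   dimnames = list(sprintf("g%02d", 10:1),
                                   c("t5_r1", "t5_r2", "t7_r1", "t7_r2")))
  counts["g07", ] <- counts["g07", ] * 50     # dominant gene
  em <- expression_matrix(counts, stats::setNames(rep(300, 10),
                                                  rownames(counts)))
  expect_identical(rank_genes(em, k = 1)[[1]], "g07")
  all10 <- rank_genes(em, k = 10)
  expect_setequal(as.character(all10), rownames(counts))
  expect_error(rank_genes(em, k = 11), "exceeds")

  # exact ties break lexicographically
  tied <- matrix(60, nrow = 3, ncol = 4,
                 dimnames = list(c("gb", "ga", "gc"), colnames(counts)))
  em2 <- expression_matrix(tied, stats::setNames(rep(300, 3), rownames(tied)))
  r <- rank_genes(em2, k = 3)
  expect_identical(as.character(r), c("ga", "gb", "gc"))
  expect_setequal(attr(r, "ties"), c("ga", "gb", "gc"))
})

test_that("usage table tallies, fractions and positional backgrounds", {
  tab <- build_usage_table(c(g1 = "ATGTAA"))
  expect_equal(sum(tab$counts), 2)
  expect_equal(unname(tab$counts[c("ATG", "TAA")]), c(1, 1))
  expect_equal(unname(tab$pos_freq[3, c("G", "A")]), c(0.5, 0.5))

  toy <- toy_table()
  # global frequencies (per thousand): 3/8, 1/8, 4/8 of the tally
  expect_equal(unname(toy$per_thousand[c("AAA", "AAG", "GGG")]),
               1000 * c(3 / 8, 1 / 8, 4 / 8))
  # within-family synonymous fractions
  expect_equal(unname(toy$fraction[c("AAA", "AAG", "GGG")]),
               c(3 / 4, 1 / 4, 1))
  expect_equal(toy$pos_freq[1, "A"], 0.5)
  expect_equal(toy$pos_freq[3, "A"], 3 / 8)
  expect_equal(toy$pos_freq[3, "G"], 5 / 8)
  expect_equal(unname(rowSums(toy$pos_freq)), rep(1, 3))
  expect_equal(sum(toy$counts), toy$n_codons)
})

test_that("usage tables are order-invariant and additive over records", {
  seqs <- stats::setNames(vapply(1:4, random_cds, "", n_codons = 25L),
                          paste0("g", 1:4))
  t1 <- build_usage_table(seqs)
  t2 <- build_usage_table(rev(seqs))
  expect_equal(t1$counts, t2$counts)
  # splitting one CDS into two fragments at a codon boundary
  s <- seqs[[1]]
  halves <- c(a = substr(s, 1, 30), b = substr(s, 31, nchar(s)))
  t3 <- build_usage_table(c(halves, seqs[-1]), fragment = TRUE)
  expect_equal(t3$counts, t1$counts)
})

test_that("include_stops flag drops stop codons from the tally", {
  tab <- build_usage_table(c(g1 = "ATGAAATAA"), include_stops = FALSE)
  expect_equal(tab$n_codons, 2)
  expect_equal(unname(tab$counts[["TAA"]]), 0)
})

test_that("usage-table TSV round-trips and partial tables reconstruct", {
  toy <- random_table(19)
  path <- tempfile(fileext = ".tsv")
  write_usage_table(toy, path)
  back <- read_usage_table(path)
  expect_equal(back$counts, toy$counts)
  expect_equal(back$fraction, toy$fraction)
  expect_equal(back$pos_freq, toy$pos_freq)

  # per-thousand-only table: fractions and backgrounds reconstructed
  df <- utils::read.delim(path)
  utils::write.table(df[, c("codon", "per_thousand")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  pt <- read_usage_table(path)
  expect_equal(pt$fraction, toy$fraction)
  expect_equal(pt$pos_freq, toy$pos_freq)
  expect_true(all(is.na(pt$counts)))

  # fraction-only table: CAI possible, RCA refused
  write_usage_table(toy, path)
  df <- utils::read.delim(path)
  utils::write.table(df[, c("codon", "fraction")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  fr <- read_usage_table(path)
  expect_equal(unclass(relative_adaptiveness(fr, "cai")),
               unclass(relative_adaptiveness(toy, "cai")),
               tolerance = 1e-12)
  expect_error(relative_adaptiveness(fr, "rca"), "fraction")
})
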