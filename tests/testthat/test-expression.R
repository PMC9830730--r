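test_that("median-of-ratios size factors behave on constructed matrices", {
  # identical columns: all factors equal (symmetry)
  m <- matrix(rep(c(10L, 20L, 35L), 4), ncol = 4,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  expect_equal(unname(size_factors(m)), rep(1, 4), tolerance = 1e-12)
  # single gene, counts (2, 4): factors proportional to (1, 2)
  m1 <- matrix(c(2L, 4L), nrow = 1)
  s1 <- size_factors(m1)
  expect_equal(unname(s1[2] / s1[1]), 2, tolerance = 1e-12)
  # doubled column: its factor about twice the others; checked against an
  # inline brute-force median-of-ratios on an 11-gene toy (odd count, so
  # the log-space and ratio-space medians pick the same gene)
  set.seed(42)
  base <- matrix(rpois(11 * 4, 50), nrow = 11)
  base[, 4] <- base[, 1] * 2L
  s <- size_factors(base)
  gm <- exp(rowMeans(log(base)))
  brute <- apply(base, 2, function(col) median(col / gm))
  expect_equal(unname(s), unname(brute), tolerance = 1e-12)
  expect_equal(unname(s[4] / s[1]), 2, tolerance = 0.15)
  # no all-positive gene: error advising filtering
  expect_error(size_factors(matrix(c(0L, 1L, 1L, 0L), 2)), "filter")
})

test_that("dispersion estimation recovers simulated regimes", {
  set.seed(7)
  n <- 2000
  # Poisson counts at large mean: estimates near the floor
  mp <- matrix(rpois(n * 11, 200), nrow = n)
  ap <- estimate_dispersion(mp, sf = rep(1, 11))
  expect_lt(mean(ap), 0.02)
  # NB with alpha = 0.5: mean estimate within 30%
  mn <- matrix(rnbinom(n * 11, mu = 100, size = 2), nrow = n)
  an <- estimate_dispersion(mn, sf = rep(1, 11))
  expect_lt(abs(mean(an) / 0.5 - 1), 0.3)
  # all-zero gene excluded with NA
  mz <- rbind(matrix(rpois(50 * 11, 20), nrow = 50), 0L)
  expect_true(is.na(estimate_dispersion(mz, sf = rep(1, 11))[51]))
})

test_that("Wald DE calls recover planted fold changes and stay calibrated", {
  cfg <- small_cfg(seed = 41)
  cnt <- simulate_counts(cfg)
  de <- de_test(cnt$counts, cnt$design)
  td <- cnt$truth
  idx <- td$is_de & !td$is_lnc & td$base_mean > 20
  expect_gt(cor(de$log2fc[idx], td$log2fc[idx]), 0.95)
  # null genes: roughly uniform p (no gross anticonservativeness)
  p0 <- de$pvalue[!td$is_de & !td$is_lnc]
  expect_lt(mean(p0 < 0.05, na.rm = TRUE), 0.08)
  # up + down always partitions the DEG total
  deg <- de[de$is_deg, ]
  expect_identical(sum(deg$direction == "up") + sum(deg$direction == "down"),
                   nrow(deg))
  # padj is never smaller than p and is monotone in p-rank
  ok <- !is.na(de$padj)
  expect_true(all(de$padj[ok] >= de$pvalue[ok] - 1e-12))
  o <- order(de$pvalue[ok])
  expect_true(!is.unsorted(de$padj[ok][o]))
})

test_that("swapping group labels negates every log2 fold change exactly", {
  cfg <- small_cfg(seed = 43)
  cnt <- simulate_counts(cfg)
  de1 <- de_test(cnt$counts, cnt$design)
  swapped <- sample_design(cnt$design$sample_id,
                           ifelse(cnt$design$group == "PA-E", "CTR", "PA-E"))
  de2 <- de_test(cnt$counts, swapped)
  ok <- !is.na(de1$log2fc)
  expect_equal(de2$log2fc[ok], -de1$log2fc[ok], tolerance = 1e-6)
})

test_that("DE calls agree with an established NB implementation", {
  # independent cross-check, not the implementation: DESeq2 on the same
  # simulated matrix should produce tightly correlated fold changes
  suppressPackageStartupMessages(requireNamespace("DESeq2"))
  cfg <- sim_config(seed = 44, n_genes = 400, frac_de = 0.15,
                    frac_lnc_genes = 0, n_links = 0)
  cnt <- simulate_counts(cfg)
  keep <- rowSums(cnt$counts) > 10
  de <- de_test(cnt$counts[keep, ], cnt$design)
  dds <- DESeq2::DESeqDataSetFromMatrix(
    cnt$counts[keep, ],
    S4Vectors::DataFrame(condition = factor(cnt$design$group,
                                            levels = c("CTR", "PA-E"))),
    ~condition)
  res <- DESeq2::results(suppressMessages(DESeq2::DESeq(dds, quiet = TRUE)))
  common <- !is.na(res$log2FoldChange) & !is.na(de$log2fc)
  expect_gt(cor(de$log2fc[common], res$log2FoldChange[common]), 0.98)
  expect_equal(unname(size_factors(cnt$counts[keep, ])),
               unname(DESeq2::sizeFactors(
                 DESeq2::estimateSizeFactors(dds))), tolerance = 1e-6)
})

test_that("FPKM follows its closed form, classes and invariances", {
  m <- matrix(c(100L, 10L), nrow = 2,
              dimnames = list(c("gA", "gB"), "s1"))
  m["gB", 1] <- 1e6L - 100L # library total 1e6
  lens <- c(gA = 1000, gB = 1e6)
  fp <- compute_fpkm(m, lens)
  expect_equal(fp$fpkm_sum[fp$gene_id == "gA"], 100, tolerance = 1e-9)
  # class boundaries are strict
  cut_class <- function(x) {
    f <- compute_fpkm(matrix(1L, 1, 1, dimnames = list("g", "s")),
                      c(g = 1e9 / x))
    f$class
  }
  expect_equal(cut_class(150), "high")
  expect_equal(cut_class(100), "medium") # exactly 100 is not high
  expect_equal(cut_class(10), "low")     # exactly 10 is not medium
  # doubling counts (and thus library sizes) leaves FPKM unchanged
  cfg <- small_cfg(seed = 45)
  cnt <- simulate_counts(cfg)
  lens2 <- stats::setNames(rep(1000, nrow(cnt$counts)),
                           rownames(cnt$counts))
  f1 <- compute_fpkm(cnt$counts, lens2)
  f2 <- compute_fpkm(cnt$counts * 2L, lens2)
  expect_equal(f1$fpkm_sum, f2$fpkm_sum, tolerance = 1e-9)
  expect_error(compute_fpkm(cnt$counts, lens2 * 0), "zero-length")
})

test_that("BH adjustment matches the hand step-up procedure", {
  expect_equal(benjamini_hochberg(0.04), 0.04)
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03)),
               c(0.03, 0.03, 0.03))
  expect_equal(benjamini_hochberg(rep(0.2, 5)), rep(0.2, 5))
  set.seed(9)
  for (i in 1:10) {
    p <- runif(50)
    p[sample(50, 5)] <- NA
    expect_equal(benjamini_hochberg(p), bh_brute(p), tolerance = 1e-12)
  }
})
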