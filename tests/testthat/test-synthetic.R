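test_that("same seed reproduces a byte-identical fixture bundle", {
  cfg <- small_cfg(seed = 21)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_bundle(cfg, d1)
  simulate_bundle(cfg, d2)
  files <- list.files(d1)
  expect_true(length(files) > 15)
  for (f in files)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     info = f)
})

test_that("NB count generator matches its declared moments", {
  cfg <- sim_config(seed = 31, n_genes = 5000, frac_de = 0,
                    frac_lnc_genes = 0, n_links = 0, libsize_sd = 0)
  cnt <- simulate_counts(cfg)
  mu <- cnt$truth$base_mean
  alpha <- cnt$truth$dispersion
  keep <- mu > 50
  emp_mean <- rowMeans(cnt$counts)[keep]
  # mean recovery, aggregated over genes
  expect_lt(abs(mean(emp_mean / mu[keep]) - 1), 0.05)
  # variance follows mu + alpha mu^2 on average
  emp_var <- apply(cnt$counts, 1, stats::var)[keep]
  expected_var <- (mu + alpha * mu^2)[keep]
  expect_lt(abs(median(emp_var / expected_var) - 1), 0.25)
  # no systematic group difference when nothing is planted
  case <- rowMeans(cnt$counts[keep, 1:6])
  ctrl <- rowMeans(cnt$counts[keep, 7:11])
  expect_lt(abs(mean(log2((case + 1) / (ctrl + 1)))), 0.05)
})

test_that("vanishing dispersion at large mean approaches Poisson", {
  cfg <- sim_config(seed = 32, n_genes = 2000, frac_de = 0,
                    frac_lnc_genes = 0, n_links = 0, libsize_sd = 0,
                    disp_shape = 1e-4, disp_rate = 1e4,
                    mean_log_mu = log(500), sd_log_mu = 0.1)
  cnt <- simulate_counts(cfg)
  ratio <- apply(cnt$counts, 1, stats::var) / rowMeans(cnt$counts)
  expect_lt(abs(mean(ratio) - 1), 0.1)
})

test_that("junction generator respects PSI extremes and planted values", {
  cfg <- sim_config(seed = 33, n_events = 200, frac_das = 0,
                    junction_coverage = 200)
  jx <- simulate_junctions(cfg)
  # all counts in domain
  expect_true(all(jx$junctions$inclusion >= 0 & jx$junctions$skipping >= 0))
  # planted PSI recovered by the estimator
  das <- das_test(jx$junctions, jx$events, sim_design(cfg))
  est <- (das$psi_case * cfg$n_case + das$psi_ctrl * cfg$n_ctrl) /
    (cfg$n_case + cfg$n_ctrl)
  expect_lt(mean(abs(est - jx$truth$psi_ctrl)), 0.02)
  # psi = 1 gives zero skipping reads always
  n <- 50L
  theta <- compute_psi(1, 0, 210, 105) # degenerate check of the mapping
  expect_identical(theta, 1)
})

test_that("allele-count generator plants recoverable AAF differences", {
  cfg <- sim_config(seed = 34, n_sites = 500, frac_ase = 1, daaf = 0.8,
                    depth_mean = 50)
  al <- simulate_allele_counts(cfg)
  design <- sim_design(cfg)
  aaf <- delta_aaf_test(al$sites, design)
  planted <- al$truth$aaf_case - al$truth$aaf_ctrl
  expect_lt(mean(abs(aaf$daaf - planted)), 0.05)
  expect_lt(abs(mean(abs(aaf$daaf)) - 0.8), 0.05)
  # masked sites are flagged in truth and fall inside their mask class
  cfg2 <- small_cfg(seed = 35)
  al2 <- simulate_allele_counts(cfg2)
  ssr_sites <- al2$truth$mask_class == "ssr"
  expect_gt(sum(ssr_sites), 0)
  pos <- GenomicRanges::GRanges(al2$truth$chrom[ssr_sites],
                                IRanges::IRanges(al2$truth$pos[ssr_sites],
                                                 al2$truth$pos[ssr_sites]))
  expect_true(all(IRanges::overlapsAny(pos, al2$masks$ssr)))
})

test_that("transcript generator separates coding and noncoding ORF structure", {
  cfg <- sim_config(seed = 36, n_transcripts = 60, frac_noncoding = 0.5)
  tr <- simulate_transcript_sequences(cfg)
  orf <- vapply(tr$records$sequence, function(s) longest_orf(s)$length,
                integer(1))
  expect_true(all(orf[!tr$truth$is_noncoding] >= 300L))
  expect_true(all(orf[tr$truth$is_noncoding] < 300L))
  expect_true(all(!tr$records$rfam_hit[tr$truth$is_noncoding]))
  expect_true(all(!tr$records$pfam_hit[tr$truth$is_noncoding]))
  # truth covers every generated transcript (no orphans)
  expect_setequal(tr$truth$transcript_id, tr$records$transcript_id)
})

test_that("qPCR generator hits the closed-form Cq relations", {
  # fold change 1, no noise: RQ exactly 1 everywhere
  cfg0 <- sim_config(seed = 37, cq_sd = 0)
  qp0 <- simulate_qpcr(cfg0, fold_changes = c(GX = 1))
  res0 <- qpcr_analysis(qp0$cq)
  expect_equal(unname(res0$rq$rq), rep(1, 11), tolerance = 1e-12)
  # fold change 2 at E = 2, no noise: case target Cq exactly 1 below control
  qp2 <- simulate_qpcr(cfg0, fold_changes = c(GX = 2))
  cc <- collapse_technical(qp2$cq)
  tgt <- cc[cc$gene == "GX", ]
  dcq <- mean(tgt$cq_mean[tgt$group == "CTR"]) -
    mean(tgt$cq_mean[tgt$group == "PA-E"])
  expect_equal(dcq, 1, tolerance = 1e-12)
  # planted fold change recovered within 10% at Cq noise sd 0.1
  cfg1 <- sim_config(seed = 38, cq_sd = 0.1)
  qp1 <- simulate_qpcr(cfg1)
  res1 <- qpcr_analysis(qp1$cq)
  fc <- res1$summary$fold_change[match(qp1$truth$gene, res1$summary$gene)]
  expect_true(all(abs(fc / qp1$truth$fold_change - 1) < 0.1))
})
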