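test_that("event enumeration recognises the five geometries", {
  # two transcripts differing by one internal exon: exactly one SE event
  ev <- enumerate_events(toy_se_models())
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$type, "SE")
  expect_equal(ev$l_inc, 2L * 105L)
  expect_equal(ev$l_skip, 105L)
  # identical transcripts: nothing
  tx <- data.frame(transcript_id = c("t1", "t2"), gene_id = "g1",
                   chrom = "chr1", strand = "+", biotype = "unknown",
                   stringsAsFactors = FALSE)
  ex <- rbind(data.frame(transcript_id = "t1",
                         start = c(100L, 300L), end = c(200L, 400L)),
              data.frame(transcript_id = "t2",
                         start = c(100L, 300L), end = c(200L, 400L)))
  expect_equal(nrow(enumerate_events(transcript_models(tx, ex))), 0L)
  # single-transcript genes contribute nothing
  expect_equal(nrow(enumerate_events(
    transcript_models(tx[1, ], ex[ex$transcript_id == "t1", ]))), 0L)
})

test_that("retained introns and mutually exclusive exons are detected", {
  tx <- data.frame(transcript_id = c("t1", "t2"), gene_id = "g1",
                   chrom = "chr1", strand = "+", biotype = "unknown",
                   stringsAsFactors = FALSE)
  # RI: t1 splices 201..299, t2 retains it in one exon
  ex <- rbind(data.frame(transcript_id = "t1",
                         start = c(100L, 300L), end = c(200L, 400L)),
              data.frame(transcript_id = "t2", start = 100L, end = 400L))
  ev <- enumerate_events(transcript_models(tx, ex))
  expect_equal(ev$type, "RI")
  expect_equal(ev$inclusion_form, "201-299")
  # MXE: shared flanks, non-overlapping alternative middle exons
  ex2 <- rbind(data.frame(transcript_id = "t1",
                          start = c(100L, 300L, 700L),
                          end = c(200L, 380L, 800L)),
               data.frame(transcript_id = "t2",
                          start = c(100L, 450L, 700L),
                          end = c(200L, 530L, 800L)))
  ev2 <- enumerate_events(transcript_models(tx, ex2))
  expect_equal(ev2$type, "MXE")
  expect_equal(ev2$inclusion_form, "300-380") # 5'-proximal exon on +
})

test_that("alternative splice-site typing is strand-aware", {
  # donor shift on the plus strand: A5SS
  tx <- data.frame(transcript_id = c("t1", "t2"), gene_id = "g1",
                   chrom = "chr1", strand = "+", biotype = "unknown",
                   stringsAsFactors = FALSE)
  ex <- rbind(data.frame(transcript_id = "t1",
                         start = c(100L, 500L), end = c(230L, 600L)),
              data.frame(transcript_id = "t2",
                         start = c(100L, 500L), end = c(200L, 600L)))
  ev <- enumerate_events(transcript_models(tx, ex))
  expect_equal(ev$type, "A5SS")
  # oracle: reverse-complement the locus (mirror all coordinates, flip
  # strand); the same biological event must keep its type
  L <- 1000L
  mirror <- function(d) {
    out <- d
    out$start <- L + 1L - d$end
    out$end <- L + 1L - d$start
    out
  }
  tx_m <- tx; tx_m$strand <- "-"
  ev_m <- enumerate_events(transcript_models(tx_m, mirror(ex)))
  expect_equal(ev_m$type, "A5SS")
  # and an acceptor shift mirrors to A3SS on both strands
  ex3 <- rbind(data.frame(transcript_id = "t1",
                          start = c(100L, 450L), end = c(200L, 600L)),
               data.frame(transcript_id = "t2",
                          start = c(100L, 500L), end = c(200L, 600L)))
  expect_equal(enumerate_events(transcript_models(tx, ex3))$type, "A3SS")
  ev3m <- enumerate_events(transcript_models(tx_m, mirror(ex3)))
  expect_equal(ev3m$type, "A3SS")
})

test_that("PSI follows its length-normalised closed form", {
  expect_equal(compute_psi(10, 0, 105, 105), 1)
  expect_equal(compute_psi(7, 7, 105, 105), 0.5)
  expect_equal(compute_psi(30, 10, 2, 1), 0.6) # (30/2)/(30/2 + 10/1)
  expect_true(is.na(compute_psi(0, 0, 105, 105)))
})

test_that("the pooled binomial LRT behaves on degenerate and planted cases", {
  design <- toy_design()
  events <- data.frame(event_id = "e1", gene_id = "g1", type = "SE",
                       chrom = ".", strand = "+", inclusion_form = ".",
                       skipping_form = ".", l_inc = 210L, l_skip = 105L,
                       stringsAsFactors = FALSE)
  # identical counts in every sample: LRT = 0, p = 1
  j <- data.frame(event_id = "e1", sample_id = design$sample_id,
                  inclusion = 40L, skipping = 20L)
  das <- das_test(j, events, design)
  expect_equal(das$lrt, 0, tolerance = 1e-12)
  expect_equal(das$pvalue, 1, tolerance = 1e-12)
  expect_equal(das$dpsi, 0, tolerance = 1e-12)
  # significant p but tiny dPSI: not DAS (dual threshold)
  j2 <- data.frame(event_id = "e1", sample_id = design$sample_id,
                   inclusion = c(rep(5300L, 6), rep(5000L, 5)),
                   skipping = c(rep(4700L, 6), rep(5000L, 5)))
  das2 <- das_test(j2, events, design)
  expect_lt(das2$padj, 0.01)
  expect_lt(abs(das2$dpsi), 0.1)
  expect_false(das2$is_das)
  # below-coverage events get NA p and are excluded from BH
  j3 <- data.frame(event_id = "e1", sample_id = design$sample_id,
                   inclusion = c(1L, rep(0L, 10)), skipping = 0L)
  das3 <- das_test(j3, events, design)
  expect_true(is.na(das3$pvalue))
  expect_true(is.na(das3$padj))
})

test_that("swapping group labels negates dPSI exactly", {
  cfg <- small_cfg(seed = 61)
  jx <- simulate_junctions(cfg)
  design <- sim_design(cfg)
  das1 <- das_test(jx$junctions, jx$events, design)
  swapped <- sample_design(design$sample_id,
                           ifelse(design$group == "PA-E", "CTR", "PA-E"))
  das2 <- das_test(jx$junctions, jx$events, swapped)
  expect_equal(das2$dpsi, -das1$dpsi, tolerance = 1e-12)
  expect_equal(das2$pvalue, das1$pvalue, tolerance = 1e-12)
})

test_that("gene-level DASG summary counts genes per event type", {
  das <- data.frame(event_id = c("e1", "e2", "e3"),
                    gene_id = c("g1", "g1", "g2"),
                    type = c("SE", "RI", "SE"),
                    is_das = c(TRUE, TRUE, FALSE),
                    stringsAsFactors = FALSE)
  s <- summarize_dasg(das)
  expect_equal(nrow(s$genes), 1L) # only g1 has significant events
  expect_equal(s$genes$types, "RI,SE")
  expect_equal(unname(s$type_gene_counts[c("SE", "RI")]), c(1L, 1L))
  expect_equal(sum(s$type_event_counts), 2L)
  # empty input
  s0 <- summarize_dasg(das[das$is_das & FALSE, ])
  expect_equal(nrow(s0$genes), 0L)
  # DASG x DEG overlap is a plain set intersection
  expect_identical(intersect(s$genes$gene_id, c("g1", "g9")), "g1")
})
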