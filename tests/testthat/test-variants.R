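make_sites <- function(chrom, pos, ref, alt, refm, altm, design) {
  colnames(refm) <- colnames(altm) <- design$sample_id
  allele_sites(data.frame(chrom = chrom, pos = pos, id = ".",
                          ref = ref, alt = alt, stringsAsFactors = FALSE),
               refm, altm)
}

test_that("SNV calling applies the 10-read coverage and alt-support rules", {
  design <- toy_design()
  n_s <- nrow(design)
  # one sample at depth 9: rejected
  ref1 <- matrix(8L, 1, n_s); alt1 <- matrix(5L, 1, n_s)
  ref1[1, 3] <- 4L # depth 9 there
  x1 <- make_sites("c", 10L, "A", "G", ref1, alt1, design)
  expect_equal(n_sites(call_snvs(x1, design)), 0L)
  # depths fine but zero alt everywhere: rejected
  x2 <- make_sites("c", 10L, "A", "G", matrix(12L, 1, n_s),
                   matrix(0L, 1, n_s), design)
  expect_equal(n_sites(call_snvs(x2, design)), 0L)
  # depths >= 10 with alt 5/20 in one sample: retained
  ref3 <- matrix(12L, 1, n_s); alt3 <- matrix(0L, 1, n_s)
  ref3[1, 1] <- 15L; alt3[1, 1] <- 5L
  x3 <- make_sites("c", 10L, "A", "G", ref3, alt3, design)
  out <- call_snvs(x3, design)
  expect_equal(n_sites(out), 1L)
  expect_named(attr(out, "filter_counts"),
               c("input", "low_coverage", "no_alt_support", "retained"))
})

test_that("SSR detection matches threshold boundaries and the brute-force oracle", {
  # mono-repeat at exactly 12 copies is reported; 11 is not
  g12 <- c(s = paste0("GC", strrep("A", 12), "GC"))
  hit <- detect_ssrs(g12)
  expect_equal(length(hit), 1L)
  expect_equal(S4Vectors::mcols(hit)$motif, "A")
  expect_equal(length(detect_ssrs(c(s = paste0("GC", strrep("A", 11), "GC")))),
               0L)
  # AT x 5 is below the 6-repeat dimer threshold
  expect_equal(length(detect_ssrs(c(s = strrep("AT", 5)))), 0L)
  expect_equal(length(detect_ssrs(c(s = strrep("AT", 6)))), 1L)
  # random sequences: identical intervals to the independent enumerator
  set.seed(11)
  for (i in 1:60) {
    s <- paste(sample(c("A", "C", "G", "T"), 300,
                      TRUE, prob = c(0.4, 0.1, 0.1, 0.4)), collapse = "")
    # splice in a couple of arrays to make hits likely
    s <- paste0(substr(s, 1, 100), strrep("AG", sample(4:8, 1)),
                substr(s, 101, 200), strrep("T", sample(10:14, 1)),
                substr(s, 201, 300))
    got <- as.data.frame(detect_ssrs(c(chr = s)))
    want <- ssr_brute(s)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$motif, want$motif)
    }
  }
})

test_that("region-mask construction follows the stated definitions", {
  # two genes, opposite strands, TSSs 500 bp apart head-to-head
  tx <- data.frame(transcript_id = c("tA", "tB"),
                   gene_id = c("gA", "gB"), chrom = "c1",
                   strand = c("-", "+"), biotype = "protein_coding",
                   stringsAsFactors = FALSE)
  ex <- rbind(data.frame(transcript_id = "tA", start = 1000L, end = 1500L),
              data.frame(transcript_id = "tB", start = 2000L, end = 2600L))
  m <- build_region_mask(transcript_models(tx, ex), genome = NULL)
  expect_equal(length(m$bidirectional), 1L)
  expect_equal(GenomicRanges::start(m$bidirectional), 1500L)
  expect_equal(GenomicRanges::end(m$bidirectional), 2000L)
  # same-strand genes never produce a bidirectional interval
  tx2 <- tx; tx2$strand <- "+"
  m2 <- build_region_mask(transcript_models(tx2, ex), genome = NULL)
  expect_equal(length(m2$bidirectional), 0L)
  # a 50 bp intron produces two 10 bp flank intervals
  tx3 <- data.frame(transcript_id = "t", gene_id = "g", chrom = "c1",
                    strand = "+", biotype = "protein_coding",
                    stringsAsFactors = FALSE)
  ex3 <- data.frame(transcript_id = "t", start = c(100L, 251L),
                    end = c(200L, 300L)) # intron 201..250
  m3 <- build_region_mask(transcript_models(tx3, ex3), genome = NULL)
  expect_equal(GenomicRanges::start(m3$intron_flank), c(201L, 241L))
  expect_equal(GenomicRanges::end(m3$intron_flank), c(210L, 250L))
  # no pseudogene biotypes: empty pseudogene mask
  expect_equal(length(m3$pseudogene), 0L)
})

test_that("mask filtering is boundary-exact and order-invariant", {
  design <- toy_design(2, 2)
  n_s <- nrow(design)
  pos <- c(100L, 110L, 111L, 500L)
  x <- make_sites("c1", pos, "A", "G",
                  matrix(10L, 4, n_s), matrix(10L, 4, n_s), design)
  # BED [99, 110) covers 1-based 100..110: boundary site 111 survives
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines("c1\t99\t110", f)
  masks <- list(ssr = read_bed(f))
  kept <- filter_sites_by_mask(x, masks)
  expect_equal(kept$sites$pos, c(111L, 500L))
  # the surviving set does not depend on application order
  m2 <- list(a = masks$ssr[1], b = GenomicRanges::GRanges(
    "c1", IRanges::IRanges(495L, 505L)))
  k_ab <- filter_sites_by_mask(filter_sites_by_mask(x, m2["a"]), m2["b"])
  k_ba <- filter_sites_by_mask(filter_sites_by_mask(x, m2["b"]), m2["a"])
  k_joint <- filter_sites_by_mask(x, m2)
  expect_equal(k_ab$sites, k_ba$sites)
  expect_equal(k_ab$sites, k_joint$sites)
})

test_that("the dAAF test handles extreme, null and threshold cases", {
  design <- toy_design()
  nc <- sum(design$group == "PA-E"); nk <- sum(design$group == "CTR")
  # PA-E all-reference, CTR all-alternative: dAAF = -1
  ref <- cbind(matrix(10L, 1, nc), matrix(0L, 1, nk))
  alt <- cbind(matrix(0L, 1, nc), matrix(10L, 1, nk))
  x <- make_sites("c", 1L, "A", "G", ref, alt, design)
  r <- delta_aaf_test(x, design)
  expect_equal(r$daaf, -1)
  expect_true(r$is_significant)
  # identical pooled tables: p = 1, dAAF = 0
  x2 <- make_sites("c", 1L, "A", "G", matrix(10L, 1, 11), matrix(10L, 1, 11),
                   design)
  r2 <- delta_aaf_test(x2, design)
  expect_equal(r2$pvalue, 1)
  expect_equal(r2$daaf, 0)
  expect_false(r2$is_significant)
  # significance needs BOTH |dAAF| > 0.3 and FDR < 0.001 (strict)
  expect_true(abs(r$daaf) > 0.3 && r$fdr < 0.001)
})

test_that("final ASE selection enforces the replicate-spread rule", {
  base <- data.frame(chrom = "c", pos = 1:3, id = ".", ref = "A", alt = "G",
                     aaf_case = 0.8, aaf_ctrl = 0.2, daaf = 0.6,
                     sd_case = c(0, 0.3, 0), sd_ctrl = c(0.05, 0.05, 0),
                     pvalue = 1e-6, fdr = 1e-5,
                     is_significant = c(TRUE, TRUE, FALSE),
                     stringsAsFactors = FALSE)
  fin <- select_final_ases(base)
  # high-spread significant site dropped; non-significant never included
  expect_equal(fin$pos, 1L)
  # zero-spread sites rank first
  base$is_significant[3] <- TRUE
  fin2 <- select_final_ases(base)
  expect_equal(fin2$pos, c(3L, 1L))
})

cds_toy <- function() {
  # chrom: 9 nt lead-in, 30 nt CDS (10 codons), 20 nt tail
  cds <- "ATGGATGGATTTCCCAAAGGGTTTAAATAA"
  genome <- c(c1 = paste0("AAACCCGGG", cds, strrep("C", 20)))
  tx <- data.frame(transcript_id = "t1", gene_id = "g1", chrom = "c1",
                   strand = "+", biotype = "protein_coding",
                   cds_start = 10L, cds_end = 39L, stringsAsFactors = FALSE)
  ex <- data.frame(transcript_id = "t1", start = 10L, end = 39L)
  list(genome = genome, models = transcript_models(tx, ex))
}

test_that("codon-level consequence calls match the genetic code", {
  toy <- cds_toy()
  # codon 2 is GAT (pos 13-15); T>A at pos 15: GAT(D) -> GAA(E), missense
  s1 <- data.frame(chrom = "c1", pos = 15L, ref = "T", alt = "A")
  a1 <- annotate_consequence(s1, toy$models, toy$genome)
  expect_equal(a1$per_site$class, "missense")
  row <- a1$per_transcript
  expect_equal(row$ref_codon, "GAT"); expect_equal(row$alt_codon, "GAA")
  expect_equal(row$ref_aa, "D"); expect_equal(row$alt_aa, "E")
  # codon 3 is GGA (pos 16-18); A>G at pos 18: GGA(G) -> GGG(G), synonymous
  s2 <- data.frame(chrom = "c1", pos = 18L, ref = "A", alt = "G")
  a2 <- annotate_consequence(s2, toy$models, toy$genome)
  expect_equal(a2$per_site$class, "synonymous")
  # both match the translate-everything oracle
  tx_row <- toy$models$transcripts[1, ]
  ex <- toy$models$exons
  expect_equal(cds_consequence_brute(15L, "A", tx_row, ex, toy$genome[[1]]),
               "missense")
  expect_equal(cds_consequence_brute(18L, "G", tx_row, ex, toy$genome[[1]]),
               "synonymous")
})

test_that("non-CDS structural classes are assigned strand-aware", {
  toy <- cds_toy()
  # upstream of the plus-strand transcript span, within 5 kb
  up <- annotate_consequence(data.frame(chrom = "c1", pos = 5L,
                                        ref = "A", alt = "G"),
                             toy$models, toy$genome)
  expect_equal(up$per_site$class, "upstream")
  dn <- annotate_consequence(data.frame(chrom = "c1", pos = 50L,
                                        ref = "C", alt = "G"),
                             toy$models, toy$genome)
  expect_equal(dn$per_site$class, "downstream")
  # spliced transcript: intron and splice-acceptor positions
  tx <- data.frame(transcript_id = "t1", gene_id = "g1", chrom = "c1",
                   strand = "+", biotype = "unknown",
                   stringsAsFactors = FALSE)
  ex <- data.frame(transcript_id = "t1", start = c(10L, 100L),
                   end = c(50L, 150L)) # intron 51..99
  models <- transcript_models(tx, ex)
  genome <- c(c1 = strrep("A", 200))
  cls <- function(p) annotate_consequence(
    data.frame(chrom = "c1", pos = p, ref = "A", alt = "G"),
    models, genome)$per_site$class
  expect_equal(cls(70L), "intron")
  expect_equal(cls(98L), "splice_acceptor")
  expect_equal(cls(99L), "splice_acceptor")
  expect_equal(cls(51L), "intron")
  # minus strand: the acceptor flips to the genomic start of the intron
  tx_m <- tx; tx_m$strand <- "-"
  models_m <- transcript_models(tx_m, ex)
  cls_m <- function(p) annotate_consequence(
    data.frame(chrom = "c1", pos = p, ref = "A", alt = "G"),
    models_m, genome)$per_site$class
  expect_equal(cls_m(51L), "splice_acceptor")
  expect_equal(cls_m(52L), "splice_acceptor")
  expect_equal(cls_m(99L), "intron")
})

test_that("consequence calling is strand-symmetric and oracle-exact", {
  set.seed(13)
  cfg <- small_cfg(seed = 71)
  gm <- simulate_gene_models(cfg)
  tx <- gm$models$transcripts
  coding <- which(!is.na(tx$cds_start))
  n_checked <- 0L
  for (ti in coding) {
    exons <- paeomics:::exons_of(gm$models, tx$transcript_id[ti])
    cpos <- paeomics:::cds_positions(tx[ti, ], exons)
    pick <- sample(cpos, min(4L, length(cpos)))
    for (p in pick) {
      chrom <- tx$chrom[ti]
      refb <- substr(gm$genome[[chrom]], p, p)
      altb <- sample(setdiff(c("A", "C", "G", "T"), refb), 1)
      one <- transcript_models(tx[ti, ], exons)
      got <- annotate_consequence(
        data.frame(chrom = chrom, pos = p, ref = refb, alt = altb),
        one, gm$genome)$per_site$class
      want <- cds_consequence_brute(p, altb, tx[ti, ], exons,
                                    gm$genome[[chrom]])
      expect_equal(got, want)
      ## strand symmetry: mirror the chromosome and the model
      L <- nchar(gm$genome[[chrom]])
      g_rc <- c(x = as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(gm$genome[[chrom]]))))
      tx_m <- tx[ti, ]
      tx_m$chrom <- "x"
      tx_m$strand <- if (tx_m$strand == "+") "-" else "+"
      tx_m$cds_start <- L + 1L - tx[ti, ]$cds_end
      tx_m$cds_end <- L + 1L - tx[ti, ]$cds_start
      ex_m <- data.frame(transcript_id = exons$transcript_id,
                         start = L + 1L - exons$end,
                         end = L + 1L - exons$start)
      comp <- c(A = "T", C = "G", G = "C", T = "A")
      got_m <- annotate_consequence(
        data.frame(chrom = "x", pos = L + 1L - p,
                   ref = unname(comp[refb]), alt = unname(comp[altb])),
        transcript_models(tx_m, ex_m), g_rc)$per_site$class
      expect_equal(got_m, got)
      n_checked <- n_checked + 1L
    }
    if (n_checked >= 60L) break
  }
  expect_gte(n_checked, 40L)
})
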