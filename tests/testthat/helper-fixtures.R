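# Shared toy builders and independent brute-force oracles.

toy_design <- function(n_case = 6L, n_ctrl = 5L) {
  sample_design(c(paste0("PA-E", seq_len(n_case)),
                  paste0("CTR", seq_len(n_ctrl))),
                c(rep("PA-E", n_case), rep("CTR", n_ctrl)))
}

# one gene, two isoforms differing by an internal (cassette) exon
toy_se_models <- function(strand = "+") {
  tx <- data.frame(
    transcript_id = c("t1", "t2"), gene_id = "g1", chrom = "chr1",
    strand = strand, biotype = "protein_coding",
    cds_start = NA_integer_, cds_end = NA_integer_,
    stringsAsFactors = FALSE)
  ex <- rbind(
    data.frame(transcript_id = "t1", start = c(100L, 300L, 500L),
               end = c(200L, 380L, 600L)),
    data.frame(transcript_id = "t2", start = c(100L, 500L),
               end = c(200L, 600L)))
  transcript_models(tx, ex)
}

# independent SSR enumerator: naive per-position period extension
ssr_brute <- function(seq, min_repeats = c(12L, 6L, 4L, 3L, 3L, 3L)) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(ch)
  res <- list()
  for (k in 1:6) {
    i <- 1L
    while (i + k <= n) {
      if (ch[i] == "N" || ch[i] != ch[i + k]) { i <- i + 1L; next }
      # left-maximality
      if (i > 1L && i + k - 1L < n && ch[i - 1L] == ch[i - 1L + k] &&
          ch[i - 1L] != "N") { i <- i + 1L; next }
      e <- i + k
      while (e < n && ch[e + 1L] == ch[e + 1L - k] && ch[e + 1L - k] != "N")
        e <- e + 1L
      width <- e - i + 1L
      reps <- width %/% k
      motif <- paste(ch[i:(i + k - 1L)], collapse = "")
      prim <- TRUE
      for (d in seq_len(k - 1L)) {
        if (k %% d != 0L) next
        if (paste(rep(substr(motif, 1L, d), k %/% d), collapse = "") == motif)
          prim <- FALSE
      }
      if (reps >= min_repeats[k] && prim)
        res[[length(res) + 1L]] <- data.frame(start = i, end = e, k = k,
                                              motif = motif)
      i <- i + 1L
    }
  }
  if (!length(res)) return(data.frame(start = integer(0), end = integer(0),
                                      k = integer(0), motif = character(0)))
  out <- unique(do.call(rbind, res))
  out[order(out$start, out$k), , drop = FALSE]
}

# hand-rolled BH step-up, independent of stats::p.adjust
bh_brute <- function(p) {
  ok <- !is.na(p)
  m <- sum(ok)
  out <- rep(NA_real_, length(p))
  if (m == 0L) return(out)
  o <- order(p[ok])
  ps <- p[ok][o]
  adj <- ps * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  tmp <- numeric(m)
  tmp[o] <- adj
  out[ok] <- tmp
  out
}

# translate-everything consequence oracle for CDS substitutions: rebuild
# the full spliced CDS for the reference and mutated genome and compare
# complete protein sequences
cds_consequence_brute <- function(pos, alt, tx_row, exons, chrom_seq) {
  splice_cds <- function(seqstr) {
    segs <- character(0)
    for (i in seq_len(nrow(exons))) {
      s <- max(exons$start[i], tx_row$cds_start)
      e <- min(exons$end[i], tx_row$cds_end)
      if (s <= e) segs <- c(segs, substring(seqstr, s, e))
    }
    s <- paste(segs, collapse = "")
    if (tx_row$strand == "-")
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    s
  }
  mut <- paste0(substring(chrom_seq, 1, pos - 1L), alt,
                substring(chrom_seq, pos + 1L, nchar(chrom_seq)))
  ref_prot <- as.character(Biostrings::translate(
    Biostrings::DNAString(splice_cds(chrom_seq)), no.init.codon = TRUE))
  alt_prot <- as.character(Biostrings::translate(
    Biostrings::DNAString(splice_cds(mut)), no.init.codon = TRUE))
  if (identical(ref_prot, alt_prot)) "synonymous" else "missense"
}

sim_paths <- function(dir) {
  list(design = file.path(dir, "design.tsv"),
       counts = file.path(dir, "counts.tsv"),
       gene_lengths = file.path(dir, "gene_lengths.tsv"),
       models = file.path(dir, "models.gtf"),
       genome = file.path(dir, "genome.fa"),
       transcripts = file.path(dir, "transcripts.fa"),
       tx_meta = file.path(dir, "tx_meta.tsv"),
       events = file.path(dir, "events.tsv"),
       junctions = file.path(dir, "junctions.tsv"),
       vcf = file.path(dir, "sites.vcf"),
       annotation = file.path(dir, "annotation_map.tsv"),
       cq = file.path(dir, "cq.tsv"))
}

small_cfg <- function(seed = 3L, ...) {
  sim_config(seed = seed, n_genes = 300L, n_events = 40L, n_sites = 300L,
             n_transcripts = 40L, n_model_genes = 40L, n_links = 10L, ...)
}
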