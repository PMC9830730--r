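#' Simulate a genome with gene models
#'
#' Lays out genes (alternating strands, occasional tight head-to-head
#' pairs so that bidirectional-promoter regions exist) on composition-
#' random chromosome sequence, 50 genes per chromosome. Most genes carry
#' one transcript; some carry a second isoform derived by skipping an
#' internal exon or shifting a splice site, so that event enumeration
#' finds work to do. Protein-coding transcripts get a CDS spanning their
#' middle exonic stretch (length a multiple of 3); a fraction of genes is
#' tagged `pseudogene` or `lncRNA`. A few perfect tandem-repeat arrays
#' are injected into intergenic space so the SSR mask class is non-empty.
#'
#' @param cfg A [sim_config]; uses `n_model_genes`.
#' @return list with `genome` (named character vector) and `models`
#'   (a [transcript_models]).
#' @export
simulate_gene_models <- function(cfg = sim_config()) {
  stage_seed(cfg, "genome")
  base_p <- hexamer_background()$base_p
  n_genes <- cfg$n_model_genes
  per_chrom <- 50L
  n_chrom <- ceiling(n_genes / per_chrom)
  tx_rows <- list(); ex_rows <- list()
  chrom_seqs <- character(n_chrom)
  names(chrom_seqs) <- paste0("chr", seq_len(n_chrom))
  ssr_specs <- list(c("A", 15L), c("AT", 10L), c("CAG", 6L),
                    c("ACGT", 5L), c("AC", 12L))
  g <- 0L
  for (ch in seq_len(n_chrom)) {
    cursor <- 2000L
    gene_iv <- list()
    n_here <- min(per_chrom, n_genes - g)
    for (k in seq_len(n_here)) {
      g <- g + 1L
      gid <- sprintf("G%04d", g)
      strand <- if (k %% 2L == 0L) "-" else "+"
      biotype <- sample(c("protein_coding", "lncRNA", "pseudogene"),
                        1L, prob = c(0.8, 0.1, 0.1))
      n_ex <- sample(2:4, 1L)
      ex_len <- sample(150:300, n_ex, TRUE)
      in_len <- sample(60:300, max(n_ex - 1L, 0L), TRUE)
      starts <- integer(n_ex); ends <- integer(n_ex)
      p <- cursor
      for (e in seq_len(n_ex)) {
        starts[e] <- p
        ends[e] <- p + ex_len[e] - 1L
        p <- ends[e] + 1L + (if (e < n_ex) in_len[e] else 0L)
      }
      span_end <- ends[n_ex]
      tid <- paste0(gid, ".t1")
      cds <- c(NA_integer_, NA_integer_)
      if (biotype == "protein_coding") {
        # CDS spanning the exonic interior, trimmed to whole codons
        epos <- unlist(mapply(seq, starts, ends, SIMPLIFY = FALSE))
        lo <- 31L; hi <- length(epos) - 30L
        n_cds <- ((hi - lo + 1L) %/% 3L) * 3L
        if (n_cds >= 6L) cds <- c(epos[lo], epos[lo + n_cds - 1L])
      }
      tx_rows[[length(tx_rows) + 1L]] <- data.frame(
        transcript_id = tid, gene_id = gid, chrom = names(chrom_seqs)[ch],
        strand = strand, biotype = biotype,
        cds_start = cds[1], cds_end = cds[2], stringsAsFactors = FALSE)
      ex_rows[[length(ex_rows) + 1L]] <- data.frame(
        transcript_id = tid, start = starts, end = ends,
        stringsAsFactors = FALSE)
      ## second isoform: exon skip (SE) or donor shift (A5SS family)
      if (stats::runif(1) < 0.4) {
        tid2 <- paste0(gid, ".t2")
        if (n_ex >= 3L) {
          s2 <- starts[-2L]; e2 <- ends[-2L]
        } else {
          shift <- min(30L, in_len[1] - 10L)
          s2 <- starts; e2 <- ends
          e2[1] <- e2[1] + shift
        }
        tx_rows[[length(tx_rows) + 1L]] <- data.frame(
          transcript_id = tid2, gene_id = gid,
          chrom = names(chrom_seqs)[ch], strand = strand, biotype = biotype,
          cds_start = NA_integer_, cds_end = NA_integer_,
          stringsAsFactors = FALSE)
        ex_rows[[length(ex_rows) + 1L]] <- data.frame(
          transcript_id = tid2, start = s2, end = e2,
          stringsAsFactors = FALSE)
      }
      gene_iv[[k]] <- c(cursor, span_end)
      # occasional tight gap after a minus-strand gene: the next (plus)
      # gene then sits head-to-head within the bidirectional window
      gap <- if (strand == "-" && k %% 4L == 0L) sample(300:800, 1L)
             else sample(1500:3000, 1L)
      cursor <- span_end + gap
    }
    chrom_len <- cursor + 2000L
    seq_chars <- sample(names(base_p), chrom_len, TRUE, prob = base_p)
    ## inject SSR arrays into intergenic space
    spans <- do.call(rbind, gene_iv)
    free_from <- spans[, 2]
    for (q in seq_along(ssr_specs)) {
      anchor <- free_from[min(q * 7L, nrow(spans))] + 100L
      motif <- strsplit(ssr_specs[[q]][1], "")[[1]]
      reps <- as.integer(ssr_specs[[q]][2])
      arr <- rep(motif, reps)
      if (anchor + length(arr) < chrom_len)
        seq_chars[anchor:(anchor + length(arr) - 1L)] <- arr
    }
    chrom_seqs[ch] <- paste(seq_chars, collapse = "")
  }
  models <- transcript_models(do.call(rbind, tx_rows),
                              do.call(rbind, ex_rows))
  list(genome = chrom_seqs, models = models)
}

#' Write a complete synthetic input bundle
#'
#' Runs every generator stage under the configured seed and writes the
#' exact file formats the pipeline readers consume (GTF, FASTA, VCF with
#' AD, BED masks, TSV tables) plus the planted truth (TSV per stage and
#' a JSON summary). The same seed yields a byte-identical bundle.
#'
#' @param cfg A [sim_config].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a named list with the generated objects, truth and
#'   file paths.
#' @export
simulate_bundle <- function(cfg = sim_config(), outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(outdir, paste0(...))
  gm <- simulate_gene_models(cfg)
  cnt <- simulate_counts(cfg)
  jx <- simulate_junctions(cfg, gene_ids = cnt$truth$gene_id)
  masks <- build_region_mask(gm$models, gm$genome)
  al <- simulate_allele_counts(cfg, masks = masks, genome = gm$genome)
  tr <- simulate_transcript_sequences(cfg)
  ## map transcripts to host genes: lncRNA transcripts on lnc-tagged genes
  stage_seed(cfg, "maps")
  lnc_genes <- cnt$truth$gene_id[cnt$truth$is_lnc]
  cod_genes <- cnt$truth$gene_id[!cnt$truth$is_lnc]
  is_nc <- tr$truth$is_noncoding
  tx2gene <- character(nrow(tr$records))
  tx2gene[is_nc] <- sample(lnc_genes, sum(is_nc), replace = TRUE)
  tx2gene[!is_nc] <- sample(cod_genes, sum(!is_nc), replace = TRUE)
  tx_meta <- cbind(tr$records[, c("transcript_id", "exon_count",
                                  "rfam_hit", "pfam_hit")],
                   gene_id = tx2gene)
  ## qPCR targets: planted-DE genes with their true fold change
  de_idx <- which(cnt$truth$is_de & !cnt$truth$is_lnc)
  qsel <- utils::head(de_idx, cfg$n_qpcr_genes)
  fc <- stats::setNames(2^cnt$truth$log2fc[qsel], cnt$truth$gene_id[qsel])
  qp <- simulate_qpcr(cfg, fold_changes = fc)
  ## annotation maps with terms enriched for planted DE genes
  map <- simulate_annotation_map(cnt$truth)
  ## gene lengths: exonic length where modelled, random otherwise
  len <- stats::setNames(sample(500:5000, cfg$n_genes, TRUE),
                         cnt$truth$gene_id)
  mod_len <- gene_exonic_length(gm$models)
  len[names(mod_len)] <- mod_len
  ## write everything
  write_fasta(gm$genome, p("genome.fa"))
  write_gtf(gm$models, p("models.gtf"))
  write_counts(cnt$counts, p("counts.tsv"))
  utils::write.table(data.frame(sample_id = cnt$design$sample_id,
                                group = cnt$design$group),
                     p("design.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(gene_id = names(len), length = unname(len)),
                     p("gene_lengths.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_fasta(stats::setNames(tr$records$sequence,
                              tr$records$transcript_id), p("transcripts.fa"))
  utils::write.table(tx_meta, p("tx_meta.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_splice_events(jx$events, p("events.tsv"))
  write_junction_counts(jx$junctions, p("junctions.tsv"))
  write_allele_sites(al$sites, p("sites.vcf"))
  for (cls in names(masks)) write_bed(masks[[cls]], p("mask_", cls, ".bed"))
  write_annotation_map(map, p("annotation_map.tsv"))
  write_cq_table(qp$cq, p("cq.tsv"))
  ## truth
  utils::write.table(cnt$truth, p("truth_genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(jx$truth, p("truth_events.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(al$truth, p("truth_sites.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cbind(tr$truth, gene_id = tx2gene),
                     p("truth_transcripts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(qp$truth, p("truth_qpcr.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(cnt$links))
    utils::write.table(cnt$links, p("truth_links.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(seed = cfg$seed, n_genes = cfg$n_genes,
         n_de = sum(cnt$truth$is_de), n_events = cfg$n_events,
         n_das = sum(jx$truth$is_das), n_sites = cfg$n_sites,
         n_ase = sum(al$truth$is_ase),
         n_transcripts = cfg$n_transcripts,
         n_noncoding = sum(tr$truth$is_noncoding)),
    p("truth.json"), auto_unbox = TRUE)
  invisible(list(genome = gm$genome, models = gm$models, counts = cnt,
                 junctions = jx, alleles = al, transcripts = tr,
                 qpcr = qp, map = map, masks = masks, outdir = outdir))
}

simulate_annotation_map <- function(gene_truth) {
  genes <- gene_truth$gene_id
  de_genes <- gene_truth$gene_id[gene_truth$is_de]
  spec <- list(BP = 20L, CC = 10L, MF = 5L, KEGG = 10L, HP = 5L)
  rows <- list()
  for (ns in names(spec)) {
    for (t in seq_len(spec[[ns]])) {
      size <- sample(10:50, 1L)
      tid <- sprintf("%s:%04d", ns, t)
      tname <- paste0(tolower(ns), " term ", t)
      if (t <= 2L && length(de_genes) >= size %/% 2L) {
        # planted enriched terms: half the members are DE genes
        members <- c(sample(de_genes, size %/% 2L),
                     sample(genes, size - size %/% 2L))
      } else {
        members <- sample(genes, size)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        namespace = ns, term_id = tid, term_name = tname,
        gene_id = unique(members), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("annotation_map", "data.frame")
  out
}
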