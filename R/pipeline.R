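#' Read a sample-design TSV
#'
#' Two columns: `sample_id`, `group` (PA-E / CTR).
#'
#' @param path TSV path.
#' @return A [sample_design].
#' @export
read_design <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(tab)))
    stop("design TSV needs columns sample_id, group")
  sample_design(tab$sample_id, tab$group)
}

pipeline_inputs <- c("design", "counts", "gene_lengths", "models", "genome",
                     "transcripts", "tx_meta", "events", "junctions", "vcf",
                     "annotation", "cq")

#' Run the full downstream pipeline
#'
#' Chains every analysis stage on file inputs and writes one TSV per
#' result plus a JSON run manifest (thresholds, seed, per-stage record
#' counts). Stages: differential expression (NB Wald + BH), FPKM
#' expression classes, lncRNA identification / DELs / trans network,
#' PSI differential splicing and DASG summary, the dAAF allele-specific-
#' expression cascade with region masks and consequence annotation,
#' functional enrichment of the DEG and DASG sets, and Pfaffl qPCR
#' validation. Any stage failure aborts with the stage name and cause;
#' all input paths are checked before any stage runs.
#'
#' @param config A [pipeline_config] whose `paths` list names:
#'   `design`, `counts`, `gene_lengths`, `models` (GTF), `genome`
#'   (FASTA), `transcripts` (FASTA), `tx_meta`, `events`, `junctions`,
#'   `vcf`, `annotation`, `cq`.
#' @return Invisibly, a named list with every stage's result tables.
#' @export
run_pipeline <- function(config) {
  paths <- config$paths
  missing_keys <- setdiff(pipeline_inputs, names(paths))
  if (length(missing_keys))
    stop("config$paths missing entries: ",
         paste(missing_keys, collapse = ", "))
  absent <- !vapply(paths[pipeline_inputs], file.exists, logical(1))
  if (any(absent))
    stop("missing input path(s): ",
         paste(unlist(paths[pipeline_inputs][absent]), collapse = ", "))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$outdir, f)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  set.seed(config$seed)
  log_counts <- list()
  ## -- inputs ----------------------------------------------------------
  design <- stage("read", read_design(paths$design))
  counts <- stage("read", read_counts(paths$counts, design))
  lengths_tab <- stage("read", utils::read.delim(paths$gene_lengths))
  lengths <- stats::setNames(lengths_tab$length, lengths_tab$gene_id)
  models <- stage("read", read_gtf(paths$models))
  genome <- stage("read", read_fasta(paths$genome))
  tx_seq <- stage("read", read_fasta(paths$transcripts))
  tx_meta <- stage("read", utils::read.delim(paths$tx_meta))
  events <- stage("read", read_splice_events(paths$events))
  junctions <- stage("read", read_junction_counts(paths$junctions))
  sites <- stage("read", read_allele_sites(paths$vcf, config$multiallelic))
  amap <- stage("read", read_annotation_map(paths$annotation))
  cq <- stage("read", read_cq_table(paths$cq))
  ## -- differential expression -----------------------------------------
  de <- stage("de", de_test(counts, design, padj_max = config$deg_padj))
  deg <- de[de$is_deg & !is.na(de$is_deg), ]
  fpkm <- stage("de", compute_fpkm(counts, lengths))
  log_counts$genes <- nrow(de); log_counts$deg <- nrow(deg)
  log_counts$deg_up <- sum(deg$direction == "up")
  log_counts$deg_down <- sum(deg$direction == "down")
  ## -- lncRNA ------------------------------------------------------------
  lnc <- stage("lncrna", {
    records <- data.frame(transcript_id = tx_meta$transcript_id,
                          sequence = unname(tx_seq[tx_meta$transcript_id]),
                          exon_count = tx_meta$exon_count,
                          rfam_hit = tx_meta$rfam_hit,
                          pfam_hit = tx_meta$pfam_hit,
                          stringsAsFactors = FALSE)
    identify_lncrnas(records)
  })
  tx2gene <- stats::setNames(tx_meta$gene_id, tx_meta$transcript_id)
  dels <- stage("lncrna", detect_dels(lnc, de, tx2gene))
  links <- stage("lncrna", {
    sf <- size_factors(counts)
    expr <- normalized_log_expr(counts, sf)
    lnc_genes <- unique(dels$gene_id)
    deg_genes <- setdiff(deg$gene_id, lnc_genes)
    if (length(lnc_genes) && length(deg_genes))
      suppressWarnings(
        trans_network(expr[lnc_genes, , drop = FALSE],
                      expr[deg_genes, , drop = FALSE],
                      r_min = config$link_r, p_max = config$link_p))
    else data.frame(lnc_id = character(0), gene_id = character(0),
                    r = numeric(0), p = numeric(0), sign = character(0))
  })
  log_counts$lncrna <- length(lnc); log_counts$dels <- nrow(dels)
  log_counts$trans_links <- nrow(links)
  ## -- splicing ----------------------------------------------------------
  das <- stage("splice", das_test(junctions, events, design,
                                  padj_max = config$das_padj,
                                  dpsi_min = config$das_dpsi))
  dasg <- stage("splice", summarize_dasg(das))
  log_counts$events_tested <- sum(!is.na(das$pvalue))
  log_counts$das_events <- sum(das$is_das)
  log_counts$dasg <- nrow(dasg$genes)
  ## -- allele-specific expression ---------------------------------------
  ase_res <- stage("ase", {
    snvs <- call_snvs(sites, design, min_coverage = config$min_coverage)
    masks <- build_region_mask(models, genome)
    kept <- filter_sites_by_mask(snvs, masks)
    aaf <- delta_aaf_test(kept, design, daaf_min = config$ase_daaf,
                          fdr_max = config$ase_fdr)
    final <- select_final_ases(aaf, sd_max = config$ase_sd_max)
    list(snvs = snvs, kept = kept, aaf = aaf, final = final, masks = masks)
  })
  cons <- stage("ase", {
    sig <- ase_res$aaf[ase_res$aaf$is_significant, , drop = FALSE]
    annotate_consequence(sig, models, genome)
  })
  log_counts$sites_input <- n_sites(sites)
  log_counts$sites_covered <- n_sites(ase_res$snvs)
  log_counts$sites_unmasked <- n_sites(ase_res$kept)
  log_counts$ase_significant <- sum(ase_res$aaf$is_significant)
  log_counts$ase_final <- nrow(ase_res$final)
  ## -- enrichment ---------------------------------------------------------
  enr_deg <- stage("enrich", fisher_enrichment(deg$gene_id, amap,
                                               fdr_max = config$enrich_fdr))
  enr_dasg <- stage("enrich", fisher_enrichment(dasg$genes$gene_id, amap,
                                                fdr_max = config$enrich_fdr))
  enr_deg$z_trend <- vapply(strsplit(enr_deg$genes, ","), trend_zscore,
                            numeric(1), de = de)
  log_counts$enriched_terms_deg <- sum(enr_deg$significant)
  ## -- qPCR --------------------------------------------------------------
  qp <- stage("qpcr", qpcr_analysis(cq))
  ## -- write --------------------------------------------------------------
  wt <- function(x, f) utils::write.table(x, out(f), sep = "\t",
                                          quote = FALSE, row.names = FALSE)
  wt(de, "deg_all.tsv"); wt(deg, "deg.tsv"); wt(fpkm, "fpkm.tsv")
  wt(data.frame(transcript_id = lnc), "lncrna.tsv")
  wt(dels, "dels.tsv"); wt(links, "trans_links.tsv")
  wt(das, "das_events.tsv"); wt(dasg$genes, "dasg.tsv")
  wt(ase_res$aaf, "ase_all.tsv")
  wt(ase_res$aaf[ase_res$aaf$is_significant, ], "ase_significant.tsv")
  wt(ase_res$final, "ase_final.tsv")
  wt(cons$per_site, "consequences.tsv")
  wt(enr_deg, "enrichment_deg.tsv"); wt(enr_dasg, "enrichment_dasg.tsv")
  wt(qp$summary, "qpcr_summary.tsv"); wt(qp$rq, "qpcr_rq.tsv")
  manifest <- list(
    package = "paeomics",
    version = as.character(utils::packageVersion("paeomics")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    thresholds = config[c("deg_padj", "das_padj", "das_dpsi", "ase_daaf",
                          "ase_fdr", "ase_sd_max", "min_coverage",
                          "link_r", "link_p", "enrich_fdr")],
    record_counts = log_counts)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(list(de = de, deg = deg, fpkm = fpkm, lncrna = lnc, dels = dels,
                 links = links, das = das, dasg = dasg, ase = ase_res,
                 consequences = cons, enrichment_deg = enr_deg,
                 enrichment_dasg = enr_dasg, qpcr = qp,
                 manifest = manifest))
}
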