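#' Read gene models from a GTF file
#'
#' Loads exon (and, when present, CDS) rows and assembles one
#' [transcript_models] record per transcript. GTF coordinates are 1-based
#' inclusive and are kept as such internally. Exon rows arriving out of
#' order are sorted on load; a transcript whose id recurs on more than one
#' chromosome or strand is rejected, as are transcripts with no exon rows.
#'
#' @param path Path to a GTF file.
#' @return A [transcript_models] object.
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  check_gtf_attributes(path)
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  keep <- md$type %in% c("exon", "CDS")
  gr <- gr[keep]
  md <- S4Vectors::mcols(gr)
  if (length(gr) == 0L) stop("no exon rows in ", path)
  tab <- data.frame(
    type = as.character(md$type),
    transcript_id = as.character(md$transcript_id),
    gene_id = as.character(md$gene_id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    biotype = if (!is.null(md$transcript_biotype))
      as.character(md$transcript_biotype) else "unknown",
    stringsAsFactors = FALSE)
  if (anyNA(tab$transcript_id))
    stop("GTF rows without transcript_id attribute")
  ex <- tab[tab$type == "exon", , drop = FALSE]
  if (nrow(ex) == 0L) stop("no exon rows in ", path)
  info <- unique(ex[, c("transcript_id", "gene_id", "chrom", "strand",
                        "biotype")])
  dup <- info$transcript_id[duplicated(info$transcript_id)]
  if (length(dup))
    stop("transcript_id on multiple chromosomes/strands: ",
         paste(unique(dup), collapse = ", "))
  cds <- tab[tab$type == "CDS", , drop = FALSE]
  if (nrow(cds)) {
    cs <- tapply(cds$start, cds$transcript_id, min)
    ce <- tapply(cds$end, cds$transcript_id, max)
    info$cds_start <- as.integer(cs[info$transcript_id])
    info$cds_end <- as.integer(ce[info$transcript_id])
  }
  transcript_models(info,
                    ex[, c("transcript_id", "start", "end"), drop = FALSE])
}

# Light pre-scan so attribute problems are reported with a line number;
# rtracklayer's own parse errors do not carry one.
check_gtf_attributes <- function(path) {
  lines <- readLines(path)
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 9L)
      stop("malformed GTF record (fewer than 9 fields) at line ", i)
    if (f[3] %in% c("exon", "CDS") && !grepl('transcript_id "', f[9], fixed = TRUE))
      stop("malformed attribute field (no transcript_id) at line ", i)
  }
  invisible(TRUE)
}

#' Write gene models to a GTF file
#'
#' Emits one exon row per exon and, for coding transcripts, CDS rows
#' clipped to the exon structure, in a form [read_gtf()] round-trips.
#'
#' @param models A [transcript_models] object.
#' @param path Output path.
#' @export
write_gtf <- function(models, path) {
  tx <- models$transcripts
  rows <- list()
  for (i in seq_len(nrow(tx))) {
    e <- exons_of(models, tx$transcript_id[i])
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = tx$chrom[i], type = "exon", start = e$start, end = e$end,
      strand = tx$strand[i], gene_id = tx$gene_id[i],
      transcript_id = tx$transcript_id[i], biotype = tx$biotype[i],
      phase = NA_integer_, stringsAsFactors = FALSE)
    if (!is.na(tx$cds_start[i])) {
      keep <- e$end >= tx$cds_start[i] & e$start <= tx$cds_end[i]
      ce <- e[keep, , drop = FALSE]
      ce$start <- pmax(ce$start, tx$cds_start[i])
      ce$end <- pmin(ce$end, tx$cds_end[i])
      # phase: bases to skip before the first whole codon of the segment,
      # accumulated in transcription order
      ord <- if (tx$strand[i] == "+") seq_len(nrow(ce)) else rev(seq_len(nrow(ce)))
      w <- ce$end - ce$start + 1L
      cum <- cumsum(c(0L, w[ord][-length(ord)]))
      phase <- integer(nrow(ce))
      phase[ord] <- (3L - cum %% 3L) %% 3L
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = tx$chrom[i], type = "CDS", start = ce$start, end = ce$end,
        strand = tx$strand[i], gene_id = tx$gene_id[i],
        transcript_id = tx$transcript_id[i], biotype = tx$biotype[i],
        phase = phase, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = tab$chrom,
    ranges = IRanges::IRanges(tab$start, tab$end),
    strand = tab$strand)
  S4Vectors::mcols(gr)$source <- "paeomics"
  S4Vectors::mcols(gr)$type <- tab$type
  S4Vectors::mcols(gr)$phase <- tab$phase
  S4Vectors::mcols(gr)$gene_id <- tab$gene_id
  S4Vectors::mcols(gr)$transcript_id <- tab$transcript_id
  S4Vectors::mcols(gr)$transcript_biotype <- tab$biotype
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read/write genome FASTA
#'
#' @param path FASTA path.
#' @return `read_fasta()`: named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(x)), sub("\\s.*$", "", names(x)))
}

#' @rdname read_fasta
#' @param sequences Named character vector of sequences.
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path)
  invisible(path)
}
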