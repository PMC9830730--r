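#' Transcript model set
#'
#' Container for gene/transcript models: one row per transcript plus an exon
#' table. Coordinates are 1-based inclusive genomic positions (the GTF/VCF
#' convention used throughout the package); BED output is converted to
#' 0-based half-open at the I/O boundary only.
#'
#' @param transcripts `data.frame` with columns `transcript_id`, `gene_id`,
#'   `chrom`, `strand` (`"+"`/`"-"`), `biotype` (e.g. `"protein_coding"`,
#'   `"lncRNA"`, `"pseudogene"`, `"unknown"`), and optional `cds_start`,
#'   `cds_end` (genomic span of the coding region, `NA` for non-coding).
#' @param exons `data.frame` with columns `transcript_id`, `start`, `end`.
#' @return An object of class `transcript_models`.
#' @export
transcript_models <- function(transcripts, exons) {
  need_tx <- c("transcript_id", "gene_id", "chrom", "strand", "biotype")
  if (!all(need_tx %in% names(transcripts)))
    stop("'transcripts' must have columns: ", paste(need_tx, collapse = ", "))
  if (!all(c("transcript_id", "start", "end") %in% names(exons)))
    stop("'exons' must have columns transcript_id, start, end")
  if (is.null(transcripts$cds_start)) transcripts$cds_start <- NA_integer_
  if (is.null(transcripts$cds_end)) transcripts$cds_end <- NA_integer_
  if (anyDuplicated(transcripts$transcript_id))
    stop("duplicate transcript_id: ",
         paste(unique(transcripts$transcript_id[
           duplicated(transcripts$transcript_id)]), collapse = ", "))
  if (!all(transcripts$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  orphan <- setdiff(exons$transcript_id, transcripts$transcript_id)
  if (length(orphan))
    stop("exon rows for unknown transcripts: ", paste(orphan, collapse = ", "))
  empty <- setdiff(transcripts$transcript_id, exons$transcript_id)
  if (length(empty))
    stop("transcripts without exon rows rejected: ",
         paste(empty, collapse = ", "))
  if (any(exons$start > exons$end))
    stop("exon with start > end")
  # sort exons by (transcript, start); forbid within-transcript overlap
  exons <- exons[order(match(exons$transcript_id, transcripts$transcript_id),
                       exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  by_tx <- split(seq_len(nrow(exons)), exons$transcript_id)
  for (idx in by_tx) {
    if (length(idx) > 1L &&
        any(exons$start[idx][-1] <= exons$end[idx][-length(idx)]))
      stop("overlapping exons in transcript ", exons$transcript_id[idx[1]])
  }
  rownames(transcripts) <- NULL
  out <- list(transcripts = transcripts, exons = exons)
  class(out) <- "transcript_models"
  out
}

#' @export
print.transcript_models <- function(x, ...) {
  cat("transcript_models: ", nrow(x$transcripts), " transcripts, ",
      length(unique(x$transcripts$gene_id)), " genes, ",
      nrow(x$exons), " exons\n", sep = "")
  invisible(x)
}

#' Number of transcripts
#' @param x A `transcript_models` object.
#' @export
n_transcripts <- function(x) nrow(x$transcripts)

exons_of <- function(models, transcript_id) {
  e <- models$exons[models$exons$transcript_id == transcript_id, , drop = FALSE]
  e[order(e$start), , drop = FALSE]
}

#' Exonic (union) length per gene
#'
#' Length of the union of all exons of all transcripts of a gene; the
#' denominator of FPKM.
#'
#' @param models A `transcript_models` object.
#' @return Named integer vector, one entry per gene.
#' @export
gene_exonic_length <- function(models) {
  tx2gene <- stats::setNames(models$transcripts$gene_id,
                             models$transcripts$transcript_id)
  gr <- GenomicRanges::GRanges(
    seqnames = models$transcripts$chrom[match(models$exons$transcript_id,
                                              models$transcripts$transcript_id)],
    ranges = IRanges::IRanges(models$exons$start, models$exons$end))
  byg <- split(gr, tx2gene[models$exons$transcript_id])
  len <- vapply(byg, function(g) sum(IRanges::width(GenomicRanges::reduce(g))),
                integer(1))
  len
}

#' Spliced transcript sequence from the genome
#'
#' Concatenates exon sequences in transcription order; minus-strand
#' transcripts are reverse-complemented.
#'
#' @param models A `transcript_models` object.
#' @param genome Named character vector of uppercase chromosome sequences
#'   (or a [Biostrings::DNAStringSet]).
#' @param transcript_ids Transcripts to extract (default all).
#' @return Named character vector of spliced sequences.
#' @export
spliced_sequence <- function(models, genome, transcript_ids = NULL) {
  genome <- as_genome(genome)
  tx <- models$transcripts
  if (!is.null(transcript_ids)) tx <- tx[tx$transcript_id %in% transcript_ids, ]
  out <- character(nrow(tx))
  for (i in seq_len(nrow(tx))) {
    e <- exons_of(models, tx$transcript_id[i])
    chrom <- genome[[tx$chrom[i]]]
    s <- paste(substring(chrom, e$start, e$end), collapse = "")
    if (tx$strand[i] == "-") s <- revcomp(s)
    out[i] <- s
  }
  stats::setNames(out, tx$transcript_id)
}

as_genome <- function(genome) {
  if (methods::is(genome, "DNAStringSet"))
    genome <- stats::setNames(as.character(genome), names(genome))
  if (is.null(names(genome)) || anyDuplicated(names(genome)))
    stop("genome must be a named sequence set with unique names")
  if (any(nchar(genome) == 0L)) stop("zero-length chromosome sequence")
  genome
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}
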