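# Transcription-ordered genomic positions of a transcript's CDS.
cds_positions <- function(tx_row, exons) {
  if (is.na(tx_row$cds_start)) return(integer(0))
  segs <- list()
  for (i in seq_len(nrow(exons))) {
    s <- max(exons$start[i], tx_row$cds_start)
    e <- min(exons$end[i], tx_row$cds_end)
    if (s <= e) segs[[length(segs) + 1L]] <- s:e
  }
  pos <- unlist(segs)
  if (tx_row$strand == "-") pos <- rev(pos)
  pos
}

comp_base <- function(b) c(A = "T", C = "G", G = "C", T = "A", N = "N")[b]

translate_codon <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  unname(gc[codon])
}

severity_order <- c("splice_acceptor", "missense", "synonymous",
                    "five_prime_utr", "three_prime_utr", "intron",
                    "upstream", "downstream")

# Classify one site against one transcript; returns NULL when the site is
# unrelated to the transcript (or exonic in a non-coding transcript, which
# falls outside the eight reported classes).
classify_site_tx <- function(pos, alt, tx_row, exons, chrom_chars,
                             window = 5000L) {
  span_s <- min(exons$start); span_e <- max(exons$end)
  strand <- tx_row$strand
  base <- list(transcript_id = tx_row$transcript_id, class = NA_character_,
               ref_codon = NA_character_, alt_codon = NA_character_,
               ref_aa = NA_character_, alt_aa = NA_character_)
  if (pos < span_s - window || pos > span_e + window) return(NULL)
  if (pos < span_s) {
    base$class <- if (strand == "+") "upstream" else "downstream"
    return(base)
  }
  if (pos > span_e) {
    base$class <- if (strand == "+") "downstream" else "upstream"
    return(base)
  }
  exon_hit <- any(exons$start <= pos & exons$end >= pos)
  if (!exon_hit) {
    # splice acceptor: last 2 intronic bases before the next exon in
    # transcription order
    for (i in seq_len(nrow(exons) - 1L)) {
      iL <- exons$end[i] + 1L; iR <- exons$start[i + 1L] - 1L
      if (pos < iL || pos > iR) next
      acc <- if (strand == "+") c(iR - 1L, iR) else c(iL, iL + 1L)
      base$class <- if (pos %in% acc) "splice_acceptor" else "intron"
      return(base)
    }
    base$class <- "intron"
    return(base)
  }
  ## exonic
  if (is.na(tx_row$cds_start)) return(NULL) # non-coding exon: outside classes
  if (pos < tx_row$cds_start) {
    base$class <- if (strand == "+") "five_prime_utr" else "three_prime_utr"
    return(base)
  }
  if (pos > tx_row$cds_end) {
    base$class <- if (strand == "+") "three_prime_utr" else "five_prime_utr"
    return(base)
  }
  cpos <- cds_positions(tx_row, exons)
  i <- match(pos, cpos)
  if (is.na(i)) { # inside the CDS genomic span but within a UTR-side exon gap
    base$class <- "intron"
    return(base)
  }
  ci <- (i - 1L) %/% 3L
  idx <- ci * 3L + 1:3
  if (max(idx) > length(cpos)) return(NULL) # incomplete trailing codon
  ref_codon <- chrom_chars[cpos[idx]]
  alt_codon <- ref_codon
  alt_codon[which(cpos[idx] == pos)] <- alt
  if (strand == "-") {
    ref_codon <- comp_base(ref_codon)
    alt_codon <- comp_base(alt_codon)
  }
  rc <- paste(ref_codon, collapse = ""); ac <- paste(alt_codon, collapse = "")
  ra <- translate_codon(rc); aa <- translate_codon(ac)
  base$class <- if (identical(ra, aa)) "synonymous" else "missense"
  base$ref_codon <- rc; base$alt_codon <- ac
  base$ref_aa <- ra; base$alt_aa <- aa
  base
}

#' Variant consequence annotation
#'
#' Annotates each site against every transcript within 5 kb (strand-aware
#' upstream/downstream), assigning one of the eight reported classes:
#' upstream, 5' UTR, missense, synonymous, intron, splice acceptor
#' (last 2 intronic bases before an exon), 3' UTR, downstream. CDS
#' substitutions carry ref/alt codons and amino acids under the standard
#' genetic code (reverse-complemented on the minus strand). Per site the
#' most severe class is reported with severity
#' splice_acceptor > missense > synonymous > 5'UTR > 3'UTR > intron >
#' upstream > downstream; sites not within 5 kb of any transcript are
#' labelled `intergenic` and excluded from the eight-class tally.
#'
#' @param sites data.frame with columns `chrom`, `pos`, `ref`, `alt` (an
#'   [allele_sites] object is also accepted).
#' @param models A [transcript_models] object.
#' @param genome Named sequence set (required for CDS classes).
#' @param window Upstream/downstream window, default 5000 bp.
#' @return list with `per_transcript` (one row per site-transcript
#'   annotation) and `per_site` (most severe class per site).
#' @export
annotate_consequence <- function(sites, models, genome, window = 5000L) {
  if (inherits(sites, "allele_sites")) sites <- sites$sites
  genome <- as_genome(genome)
  tx <- models$transcripts
  ex_by_tx <- lapply(tx$transcript_id, function(id) exons_of(models, id))
  names(ex_by_tx) <- tx$transcript_id
  chrom_chars <- lapply(genome, function(s) strsplit(s, "", fixed = TRUE)[[1]])
  per_tx <- list()
  per_site <- character(nrow(sites))
  sev <- stats::setNames(seq_along(severity_order), severity_order)
  for (si in seq_len(nrow(sites))) {
    pos <- sites$pos[si]; chrom <- sites$chrom[si]; alt <- sites$alt[si]
    best <- NA_character_
    on_chrom <- which(tx$chrom == chrom)
    for (ti in on_chrom) {
      ann <- classify_site_tx(pos, alt, tx[ti, ], ex_by_tx[[ti]],
                              chrom_chars[[chrom]], window)
      if (is.null(ann)) next
      per_tx[[length(per_tx) + 1L]] <- data.frame(
        chrom = chrom, pos = pos, ref = sites$ref[si], alt = alt,
        transcript_id = ann$transcript_id, class = ann$class,
        ref_codon = ann$ref_codon, alt_codon = ann$alt_codon,
        ref_aa = ann$ref_aa, alt_aa = ann$alt_aa,
        stringsAsFactors = FALSE)
      if (is.na(best) || sev[ann$class] < sev[best]) best <- ann$class
    }
    per_site[si] <- if (is.na(best)) "intergenic" else best
  }
  per_tx_df <- if (length(per_tx)) do.call(rbind, per_tx) else
    data.frame(chrom = character(0), pos = integer(0), ref = character(0),
               alt = character(0), transcript_id = character(0),
               class = character(0), ref_codon = character(0),
               alt_codon = character(0), ref_aa = character(0),
               alt_aa = character(0))
  list(per_transcript = per_tx_df,
       per_site = cbind(sites[, c("chrom", "pos", "ref", "alt")],
                        data.frame(class = per_site,
                                   stringsAsFactors = FALSE)))
}

#' Consequence class proportions
#'
#' Percentage of sites in each of the eight annotation classes, over
#' sites with a non-intergenic annotation.
#'
#' @param per_site The `per_site` table from [annotate_consequence()].
#' @return Named numeric vector of percentages summing to 100.
#' @export
class_proportions <- function(per_site) {
  keep <- per_site$class != "intergenic"
  cls <- factor(per_site$class[keep], levels = severity_order)
  stats::setNames(100 * as.vector(table(cls)) / max(sum(keep), 1L),
                  severity_order)
}
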