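#' SNV coverage and alt-support filter
#'
#' Retains sites with total read depth (ref + alt) of at least
#' `min_coverage` (default 10 reads) in every sample of both groups, and
#' with alternative-allele support (alt count >= 2 and alt fraction
#' >= 0.05) in at least one sample. Per-filter removal tallies are
#' attached as attribute `filter_counts`.
#'
#' @param x An [allele_sites] object.
#' @param design A [sample_design] (all design samples must be columns
#'   of `x`).
#' @param min_coverage Minimum per-sample depth.
#' @param min_alt,min_alt_frac Alt-support rule.
#' @return Filtered [allele_sites].
#' @export
call_snvs <- function(x, design, min_coverage = 10L, min_alt = 2L,
                      min_alt_frac = 0.05) {
  if (!all(design$sample_id %in% colnames(x$ref)))
    stop("design samples missing from allele counts")
  ref <- x$ref[, design$sample_id, drop = FALSE]
  alt <- x$alt[, design$sample_id, drop = FALSE]
  depth <- ref + alt
  cov_ok <- rowSums(depth >= min_coverage) == ncol(depth)
  frac <- ifelse(depth > 0, alt / depth, 0)
  alt_ok <- rowSums(alt >= min_alt & frac >= min_alt_frac) >= 1L
  keep <- cov_ok & alt_ok
  out <- subset_sites(x, keep)
  attr(out, "filter_counts") <- c(input = n_sites(x),
                                  low_coverage = sum(!cov_ok),
                                  no_alt_support = sum(cov_ok & !alt_ok),
                                  retained = sum(keep))
  out
}

#' Detect simple sequence repeats
#'
#' Perfect tandem repeats with motif length 1-6 and minimum repeat counts
#' 12, 6, 4, 3, 3, 3 respectively; each reported interval is maximal
#' (non-extendable) for its period, partial trailing repeats included.
#' Motifs that are themselves repetitions of a shorter unit are skipped
#' (their array is reported at the primitive period). Positions involving
#' N never match.
#'
#' @param genome Named character vector of chromosome sequences (or
#'   `DNAStringSet`).
#' @param min_repeats Integer vector of length 6: minimum (complete)
#'   repeat count per motif length.
#' @return A [GenomicRanges::GRanges] with metadata columns
#'   `motif_length`, `motif`, `n_repeats`.
#' @export
detect_ssrs <- function(genome, min_repeats = c(12L, 6L, 4L, 3L, 3L, 3L)) {
  genome <- as_genome(genome)
  stopifnot(length(min_repeats) == 6L)
  hits <- list()
  for (chrom in names(genome)) {
    s <- genome[[chrom]]
    n <- nchar(s)
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    for (k in 1:6) {
      if (n < k * min_repeats[k]) next
      m <- ch[seq_len(n - k)] == ch[seq_len(n - k) + k] &
        ch[seq_len(n - k)] != "N"
      r <- rle(m)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      run <- which(r$values & r$lengths >= k * (min_repeats[k] - 1L))
      for (j in run) {
        i0 <- starts[j]; L <- r$lengths[j]
        motif <- substr(s, i0, i0 + k - 1L)
        if (!is_primitive_motif(motif)) next
        hits[[length(hits) + 1L]] <- data.frame(
          chrom = chrom, start = i0, end = i0 + L + k - 1L,
          motif_length = k, motif = motif,
          n_repeats = (L + k) %/% k, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits))
    return(GenomicRanges::GRanges(motif_length = integer(0),
                                  motif = character(0),
                                  n_repeats = integer(0)))
  tab <- unique(do.call(rbind, hits))
  gr <- GenomicRanges::GRanges(tab$chrom,
                               IRanges::IRanges(tab$start, tab$end))
  S4Vectors::mcols(gr)$motif_length <- tab$motif_length
  S4Vectors::mcols(gr)$motif <- tab$motif
  S4Vectors::mcols(gr)$n_repeats <- tab$n_repeats
  sort(gr)
}

is_primitive_motif <- function(motif) {
  k <- nchar(motif)
  if (k == 1L) return(TRUE)
  for (d in seq_len(k - 1L)) {
    if (k %% d != 0L) next
    unit <- substr(motif, 1L, d)
    if (paste(rep(unit, k %/% d), collapse = "") == motif) return(FALSE)
  }
  TRUE
}

gene_spans <- function(models) {
  tx <- models$transcripts
  ex <- models$exons
  chrom <- tx$chrom[match(ex$transcript_id, tx$transcript_id)]
  gene <- tx$gene_id[match(ex$transcript_id, tx$transcript_id)]
  strand <- tx$strand[match(ex$transcript_id, tx$transcript_id)]
  agg <- data.frame(gene = gene, chrom = chrom, strand = strand,
                    start = ex$start, end = ex$end)
  sp <- do.call(rbind, lapply(split(agg, agg$gene), function(g)
    data.frame(gene_id = g$gene[1], chrom = g$chrom[1], strand = g$strand[1],
               start = min(g$start), end = max(g$end),
               stringsAsFactors = FALSE)))
  rownames(sp) <- NULL
  sp
}

#' Build the region-mask set
#'
#' The four mask classes removed before allele-frequency testing:
#' \describe{
#'   \item{bidirectional}{loci where genes on opposite strands overlap
#'     (the overlap interval) or have transcription start sites within
#'     `tss_window` bp head-to-head (the interval between the two TSSs).}
#'   \item{intron_flank}{the first and last `flank` bp of every intron.}
#'   \item{ssr}{simple sequence repeats from [detect_ssrs()].}
#'   \item{pseudogene}{spans of transcripts with a pseudogene biotype.}
#' }
#'
#' @param models A [transcript_models] object.
#' @param genome Named sequence set (only needed for the SSR class; may
#'   be `NULL` to skip it).
#' @param tss_window Head-to-head TSS distance, default 1000 bp.
#' @param flank Intron flank width, default 10 bp.
#' @return Named list of `GRanges`, one per class.
#' @export
build_region_mask <- function(models, genome = NULL, tss_window = 1000L,
                              flank = 10L) {
  sp <- gene_spans(models)
  ## bidirectional
  bid <- list()
  if (nrow(sp) > 1L) {
    for (i in seq_len(nrow(sp) - 1L)) for (j in (i + 1L):nrow(sp)) {
      if (sp$chrom[i] != sp$chrom[j] || sp$strand[i] == sp$strand[j]) next
      ov_s <- max(sp$start[i], sp$start[j])
      ov_e <- min(sp$end[i], sp$end[j])
      if (ov_s <= ov_e) {
        bid[[length(bid) + 1L]] <- c(sp$chrom[i], ov_s, ov_e)
        next
      }
      # head-to-head (divergent): minus-strand gene left of plus-strand gene
      minus <- if (sp$strand[i] == "-") i else j
      plus <- if (sp$strand[i] == "+") i else j
      tss_minus <- sp$end[minus]   # TSS of a minus-strand gene
      tss_plus <- sp$start[plus]
      if (tss_minus < tss_plus && tss_plus - tss_minus <= tss_window)
        bid[[length(bid) + 1L]] <- c(sp$chrom[i], tss_minus, tss_plus)
    }
  }
  bid_gr <- if (length(bid)) {
    m <- do.call(rbind, bid)
    GenomicRanges::reduce(GenomicRanges::GRanges(
      m[, 1], IRanges::IRanges(as.integer(m[, 2]), as.integer(m[, 3]))))
  } else GenomicRanges::GRanges()
  ## intron flanks
  fl <- list()
  tx <- models$transcripts
  for (i in seq_len(nrow(tx))) {
    e <- exons_of(models, tx$transcript_id[i])
    if (nrow(e) < 2L) next
    is_ <- e$end[-nrow(e)] + 1L
    ie_ <- e$start[-1] - 1L
    for (q in seq_along(is_)) {
      w <- ie_[q] - is_[q] + 1L
      if (w <= 0L) next
      f <- min(flank, w)
      fl[[length(fl) + 1L]] <- c(tx$chrom[i], is_[q], is_[q] + f - 1L)
      fl[[length(fl) + 1L]] <- c(tx$chrom[i], ie_[q] - f + 1L, ie_[q])
    }
  }
  fl_gr <- if (length(fl)) {
    m <- do.call(rbind, fl)
    GenomicRanges::reduce(GenomicRanges::GRanges(
      m[, 1], IRanges::IRanges(as.integer(m[, 2]), as.integer(m[, 3]))))
  } else GenomicRanges::GRanges()
  ## ssr + pseudogene
  ssr_gr <- if (is.null(genome)) GenomicRanges::GRanges() else
    GenomicRanges::reduce(detect_ssrs(genome))
  ps <- grepl("pseudogene", tx$biotype)
  ps_gr <- if (any(ps)) {
    ids <- tx$transcript_id[ps]
    e <- models$exons[models$exons$transcript_id %in% ids, , drop = FALSE]
    chrom <- tx$chrom[match(e$transcript_id, tx$transcript_id)]
    GenomicRanges::reduce(GenomicRanges::GRanges(
      chrom, IRanges::IRanges(e$start, e$end)))
  } else GenomicRanges::GRanges()
  list(bidirectional = bid_gr, intron_flank = fl_gr, ssr = ssr_gr,
       pseudogene = ps_gr)
}

#' Remove allele sites falling in any mask class
#'
#' A site is removed iff its position lies within any interval of any
#' mask class (1-based inclusive); removal tallies per class are attached
#' as attribute `mask_counts`. The surviving set does not depend on the
#' order in which classes are applied.
#'
#' @param x An [allele_sites] object.
#' @param masks Named list of `GRanges` (from [build_region_mask()] or
#'   [read_bed()]).
#' @return Filtered [allele_sites].
#' @export
filter_sites_by_mask <- function(x, masks) {
  pos <- GenomicRanges::GRanges(x$sites$chrom,
                                IRanges::IRanges(x$sites$pos, x$sites$pos))
  in_class <- vapply(masks, function(m)
    IRanges::overlapsAny(pos, m), logical(nrow(x$sites)))
  if (is.null(dim(in_class))) in_class <- matrix(in_class, nrow = 1L)
  hit <- rowSums(in_class) > 0
  out <- subset_sites(x, !hit)
  attr(out, "mask_counts") <- c(colSums(in_class), removed = sum(hit))
  out
}

#' Group allele-frequency comparison (dAAF test)
#'
#' Per site: the alternative-allele fraction AAF = alt/(alt+ref) per
#' sample; dAAF is the difference of unweighted group means (case minus
#' control; a pooled-count variant is available). Significance comes from
#' a two-sided Fisher's exact test on the 2x2 table of ref/alt counts
#' pooled within each group, BH-corrected across testable sites. A site
#' is significant when |dAAF| > `daaf_min` (0.3) and FDR < `fdr_max`
#' (0.001), both strict.
#'
#' @param x An [allele_sites] object.
#' @param design A [sample_design].
#' @param daaf_min,fdr_max Dual significance thresholds.
#' @param aaf `"mean"` (default): dAAF from per-sample AAF means;
#'   `"pooled"`: from pooled-count fractions.
#' @param method `"fisher"` (default) or `"chisq"`.
#' @return data.frame with per-group AAF means and SDs, `daaf`, `pvalue`,
#'   `fdr`, `is_significant`.
#' @export
delta_aaf_test <- function(x, design, daaf_min = 0.3, fdr_max = 0.001,
                           aaf = c("mean", "pooled"),
                           method = c("fisher", "chisq")) {
  aaf <- match.arg(aaf); method <- match.arg(method)
  case <- case_samples(design); ctrl <- control_samples(design)
  refC <- x$ref[, case, drop = FALSE]; altC <- x$alt[, case, drop = FALSE]
  refK <- x$ref[, ctrl, drop = FALSE]; altK <- x$alt[, ctrl, drop = FALSE]
  dC <- refC + altC; dK <- refK + altK
  aafC <- ifelse(dC > 0, altC / dC, NA_real_)
  aafK <- ifelse(dK > 0, altK / dK, NA_real_)
  mC <- rowMeans(aafC, na.rm = TRUE); mK <- rowMeans(aafK, na.rm = TRUE)
  sdC <- apply(aafC, 1L, stats::sd, na.rm = TRUE)
  sdK <- apply(aafK, 1L, stats::sd, na.rm = TRUE)
  if (aaf == "mean") {
    daaf <- mC - mK
  } else {
    daaf <- rowSums(altC) / pmax(rowSums(dC), 1) -
      rowSums(altK) / pmax(rowSums(dK), 1)
  }
  n <- nrow(x$sites)
  pval <- rep(NA_real_, n)
  testable <- rowSums(dC) > 0 & rowSums(dK) > 0
  RC <- rowSums(refC); AC <- rowSums(altC)
  RK <- rowSums(refK); AK <- rowSums(altK)
  for (i in which(testable)) {
    tab <- matrix(c(RC[i], AC[i], RK[i], AK[i]), nrow = 2)
    pval[i] <- if (method == "fisher")
      stats::fisher.test(tab)$p.value
    else
      suppressWarnings(stats::chisq.test(tab)$p.value)
  }
  fdr <- benjamini_hochberg(pval)
  sig <- !is.na(fdr) & abs(daaf) > daaf_min & fdr < fdr_max
  cbind(x$sites,
        data.frame(aaf_case = mC, aaf_ctrl = mK, daaf = daaf,
                   sd_case = sdC, sd_ctrl = sdK,
                   pvalue = pval, fdr = fdr, is_significant = sig,
                   stringsAsFactors = FALSE))
}

#' Final allele-specific-expression selection
#'
#' Among significant sites, retains those whose within-group standard
#' deviation of per-sample AAF is at most `sd_max` (default 0.1) in both
#' groups - the smallest-replicate-spread rule - and ranks them by the
#' larger of the two SDs, ascending.
#'
#' @param ase Result of [delta_aaf_test()].
#' @param sd_max Within-group SD ceiling.
#' @return The final ASE subset, ranked.
#' @export
select_final_ases <- function(ase, sd_max = 0.1) {
  keep <- ase$is_significant &
    !is.na(ase$sd_case) & !is.na(ase$sd_ctrl) &
    ase$sd_case <= sd_max & ase$sd_ctrl <= sd_max
  out <- ase[keep, , drop = FALSE]
  out[order(pmax(out$sd_case, out$sd_ctrl)), , drop = FALSE]
}
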