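# Junction representation: a splice junction of a transcript is the pair
# (end of left exon, start of right exon) in genomic coordinates.
tx_junctions <- function(exons) {
  if (nrow(exons) < 2L) return(matrix(numeric(0), ncol = 2))
  cbind(exons$end[-nrow(exons)], exons$start[-1])
}

# number of read start positions that span one junction with the required
# anchor overhang, for 120 bp trimmed reads
junction_positions <- function(read_len = 120L, anchor = 8L) {
  read_len - 2L * anchor + 1L
}

#' Enumerate alternative-splicing events from transcript models
#'
#' Pairwise comparison of the transcripts of each gene, emitting the five
#' canonical event geometries: skipped exon (SE), retained intron (RI),
#' alternative 5'/3' splice site (A5SS/A3SS, assigned relative to the
#' transcript direction, so strand-aware) and mutually exclusive exons
#' (MXE). Each distinct event (by coordinate tuple) is emitted once.
#' Effective lengths count junction-spanning read positions (120 bp reads,
#' 8 nt anchor; 105 positions per junction).
#'
#' @param models A [transcript_models] object.
#' @param read_len,anchor Read length and minimum junction overhang used
#'   for the effective lengths.
#' @return data.frame of events (`event_id`, `gene_id`, `type`, `chrom`,
#'   `strand`, `inclusion_form`, `skipping_form`, `l_inc`, `l_skip`).
#' @export
enumerate_events <- function(models, read_len = 120L, anchor = 8L) {
  u <- junction_positions(read_len, anchor)
  tx <- models$transcripts
  out <- list()
  seen <- character(0)
  emit <- function(gene, type, chrom, strand, inc, skp, l_inc, l_skip) {
    key <- paste(gene, type, inc, skp, sep = "|")
    if (key %in% seen) return(invisible())
    seen <<- c(seen, key)
    out[[length(out) + 1L]] <<- data.frame(
      gene_id = gene, type = type, chrom = chrom, strand = strand,
      inclusion_form = inc, skipping_form = skp,
      l_inc = l_inc, l_skip = l_skip, stringsAsFactors = FALSE)
  }
  seg <- function(s, e) paste0(s, "-", e)
  for (gene in unique(tx$gene_id)) {
    ids <- tx$transcript_id[tx$gene_id == gene]
    if (length(ids) < 2L) next
    ex <- lapply(ids, function(id) exons_of(models, id))
    jn <- lapply(ex, tx_junctions)
    strand <- tx$strand[match(ids[1], tx$transcript_id)]
    chrom <- tx$chrom[match(ids[1], tx$transcript_id)]
    has_junc <- function(j, L, R) any(j[, 1] == L & j[, 2] == R)
    for (a in seq_along(ids)) for (b in seq_along(ids)) {
      if (a == b) next
      e1 <- ex[[a]]; j1 <- jn[[a]]; j2 <- jn[[b]]; e2 <- ex[[b]]
      ## SE: cassette exon in a, skipped junction in b
      if (nrow(e1) >= 3L) {
        for (i in 2:(nrow(e1) - 1L)) {
          L <- e1$end[i - 1L]; R <- e1$start[i + 1L]
          if (has_junc(j2, L, R))
            emit(gene, "SE", chrom, strand,
                 paste(seg(e1$start[i], e1$end[i]), sep = ","),
                 paste0(L, "^", R),
                 2L * u, u)
        }
      }
      ## RI: junction in a, covering exon in b with matching outer bounds
      if (nrow(j1) > 0L) {
        for (i in seq_len(nrow(j1))) {
          L <- j1[i, 1]; R <- j1[i, 2]
          s1 <- e1$start[i]; e1end <- e1$end[i + 1L]
          cover <- any(e2$start == s1 & e2$end == e1end)
          if (cover)
            emit(gene, "RI", chrom, strand,
                 seg(L + 1L, R - 1L), paste0(L, "^", R), 2L * u, u)
        }
      }
      ## A5SS/A3SS and MXE need junction-level comparison
      if (nrow(j1) > 0L && nrow(j2) > 0L) {
        for (i in seq_len(nrow(j1))) for (k in seq_len(nrow(j2))) {
          L1 <- j1[i, 1]; R1 <- j1[i, 2]; L2 <- j2[k, 1]; R2 <- j2[k, 2]
          if (R1 == R2 && L1 != L2) {
            # shared genomic-right junction edge, alternative left edge;
            # left exons must overlap (same splice-site family)
            x1 <- e1[e1$end == L1, , drop = FALSE]
            x2 <- e2[e2$end == L2, , drop = FALSE]
            if (nrow(x1) && nrow(x2) &&
                x1$start[1] <= x2$end[1] && x2$start[1] <= x1$end[1]) {
              type <- if (strand == "+") "A5SS" else "A3SS"
              inc <- seg(min(L1, L2) + 1L, max(L1, L2))
              emit(gene, type, chrom, strand,
                   inc, paste0(min(L1, L2), "^", R1), u, u)
            }
          }
          if (L1 == L2 && R1 != R2) {
            x1 <- e1[e1$start == R1, , drop = FALSE]
            x2 <- e2[e2$start == R2, , drop = FALSE]
            if (nrow(x1) && nrow(x2) &&
                x1$start[1] <= x2$end[1] && x2$start[1] <= x1$end[1]) {
              type <- if (strand == "+") "A3SS" else "A5SS"
              inc <- seg(min(R1, R2), max(R1, R2) - 1L)
              emit(gene, type, chrom, strand,
                   inc, paste0(L1, "^", max(R1, R2)), u, u)
            }
          }
        }
      }
      ## MXE: shared flanks, two non-overlapping middle exons
      if (nrow(e1) >= 3L && nrow(e2) >= 3L) {
        for (i in 2:(nrow(e1) - 1L)) for (k in 2:(nrow(e2) - 1L)) {
          upL <- e1$end[i - 1L]; dnR <- e1$start[i + 1L]
          if (e2$end[k - 1L] != upL || e2$start[k + 1L] != dnR) next
          A <- c(e1$start[i], e1$end[i]); B <- c(e2$start[k], e2$end[k])
          if (A[2] >= B[1] && B[2] >= A[1]) next # must not overlap
          if (A[1] > B[1]) next                  # emit once, A left of B
          # exon closer to the transcript 5' end is the inclusion form
          inc_exon <- if (strand == "+") A else B
          alt_exon <- if (strand == "+") B else A
          emit(gene, "MXE", chrom, strand,
               seg(inc_exon[1], inc_exon[2]), seg(alt_exon[1], alt_exon[2]),
               2L * u, 2L * u)
        }
      }
    }
  }
  if (!length(out))
    return(data.frame(event_id = character(0), gene_id = character(0),
                      type = character(0), chrom = character(0),
                      strand = character(0), inclusion_form = character(0),
                      skipping_form = character(0), l_inc = integer(0),
                      l_skip = integer(0)))
  tab <- do.call(rbind, out)
  tab <- cbind(event_id = sprintf("EV%05d", seq_len(nrow(tab))), tab,
               stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  tab
}

#' Percent spliced-in
#'
#' Length-normalised inclusion fraction
#' \eqn{\psi = (I/l_I) / (I/l_I + S/l_S)}; `NA` when no reads support
#' either form.
#'
#' @param inclusion,skipping Junction read counts (vectorised).
#' @param l_inc,l_skip Effective lengths of the two forms.
#' @return Numeric PSI in \[0, 1\] or `NA`.
#' @export
compute_psi <- function(inclusion, skipping, l_inc, l_skip) {
  ni <- inclusion / l_inc
  ns <- skipping / l_skip
  psi <- ni / (ni + ns)
  psi[inclusion + skipping == 0] <- NA_real_
  psi
}

#' Differential alternative splicing test
#'
#' Per event, a binomial likelihood-ratio test comparing one shared
#' length-adjusted inclusion probability across all samples (H0) against
#' one per group (H1), with replicate junction counts pooled within each
#' group; the statistic is referred to chi-square with 1 df. Because the
#' length adjustment is a monotone reparameterisation of the binomial
#' proportion, the LRT is computed on the raw inclusion/skipping counts.
#' dPSI is the difference of group means of per-sample PSI (case minus
#' control, NA samples dropped). Events are flagged DAS when the
#' BH-adjusted p-value is below `padj_max` (default 0.01) and |dPSI|
#' exceeds `dpsi_min` (default 0.1).
#'
#' @param junctions Long data.frame `event_id, sample_id, inclusion,
#'   skipping` (one row per event and sample).
#' @param events Event table from [enumerate_events()] or
#'   [read_splice_events()] (needs `event_id`, `gene_id`, `l_inc`,
#'   `l_skip`, `type`).
#' @param design A [sample_design].
#' @param min_coverage An event is testable when each group has at least
#'   one sample with `inclusion + skipping >=` this value.
#' @param padj_max,dpsi_min The dual DAS thresholds.
#' @return data.frame with per-event PSI means, dPSI, LRT statistic,
#'   p-value, BH-adjusted p-value and `is_das`.
#' @export
das_test <- function(junctions, events, design, min_coverage = 5L,
                     padj_max = 0.01, dpsi_min = 0.1) {
  ev <- events[match(unique(junctions$event_id), events$event_id), ,
               drop = FALSE]
  if (anyNA(ev$event_id)) stop("junction counts for unknown event ids")
  case <- case_samples(design); ctrl <- control_samples(design)
  n_ev <- nrow(ev)
  psi_case <- psi_ctrl <- lrt <- pval <- rep(NA_real_, n_ev)
  jl <- split(junctions, junctions$event_id)
  ll <- function(i, s) {
    n <- i + s
    if (n == 0) return(0)
    th <- i / n
    (if (i > 0) i * log(th) else 0) + (if (s > 0) s * log(1 - th) else 0)
  }
  for (e in seq_len(n_ev)) {
    j <- jl[[ev$event_id[e]]]
    iC <- j$inclusion[match(case, j$sample_id)]
    sC <- j$skipping[match(case, j$sample_id)]
    iK <- j$inclusion[match(ctrl, j$sample_id)]
    sK <- j$skipping[match(ctrl, j$sample_id)]
    iC[is.na(iC)] <- 0L; sC[is.na(sC)] <- 0L
    iK[is.na(iK)] <- 0L; sK[is.na(sK)] <- 0L
    pc <- compute_psi(iC, sC, ev$l_inc[e], ev$l_skip[e])
    pk <- compute_psi(iK, sK, ev$l_inc[e], ev$l_skip[e])
    psi_case[e] <- mean(pc, na.rm = TRUE)
    psi_ctrl[e] <- mean(pk, na.rm = TRUE)
    if (!any(iC + sC >= min_coverage) || !any(iK + sK >= min_coverage))
      next # untestable: p stays NA, excluded from BH m
    IA <- sum(iC); SA <- sum(sC); IB <- sum(iK); SB <- sum(sK)
    stat <- 2 * (ll(IA, SA) + ll(IB, SB) - ll(IA + IB, SA + SB))
    lrt[e] <- max(stat, 0)
    pval[e] <- stats::pchisq(lrt[e], df = 1, lower.tail = FALSE)
  }
  padj <- benjamini_hochberg(pval)
  dpsi <- psi_case - psi_ctrl
  is_das <- !is.na(padj) & padj < padj_max & abs(dpsi) > dpsi_min
  data.frame(event_id = ev$event_id, gene_id = ev$gene_id, type = ev$type,
             psi_case = psi_case, psi_ctrl = psi_ctrl, dpsi = dpsi,
             lrt = lrt, pvalue = pval, padj = padj, is_das = is_das,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Gene-level differential-splicing summary
#'
#' A DASG is a gene with at least one significant event. Per-type counts
#' are computed over significant events; a gene contributes to every type
#' in which it has a significant event.
#'
#' @param das Result of [das_test()].
#' @return list with `genes` (data.frame `gene_id`, `n_sig_events`,
#'   `types`), `type_gene_counts` and `type_event_counts` (named integer
#'   vectors over the five types).
#' @export
summarize_dasg <- function(das) {
  types <- c("SE", "RI", "A3SS", "A5SS", "MXE")
  sig <- das[das$is_das, , drop = FALSE]
  if (!nrow(sig)) {
    z <- stats::setNames(integer(5), types)
    return(list(genes = data.frame(gene_id = character(0),
                                   n_sig_events = integer(0),
                                   types = character(0)),
                type_gene_counts = z, type_event_counts = z))
  }
  genes <- do.call(rbind, lapply(split(sig, sig$gene_id), function(g)
    data.frame(gene_id = g$gene_id[1], n_sig_events = nrow(g),
               types = paste(sort(unique(g$type)), collapse = ","),
               stringsAsFactors = FALSE)))
  rownames(genes) <- NULL
  tgc <- vapply(types, function(t)
    length(unique(sig$gene_id[sig$type == t])), integer(1))
  tec <- vapply(types, function(t) sum(sig$type == t), integer(1))
  list(genes = genes, type_gene_counts = tgc, type_event_counts = tec)
}
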