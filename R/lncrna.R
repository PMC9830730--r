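#' Longest open reading frame
#'
#' Scans the three forward frames for ATG..stop ORFs (stop codon included
#' in the length); ties on length are broken in favour of the 5'-most
#' start. Sequences without an in-frame ATG..stop pair have ORF length 0.
#'
#' @param sequence Uppercase DNA string (A/C/G/T/N).
#' @return list with `start`, `end` (1-based, NA if none) and `length` (nt).
#' @export
longest_orf <- function(sequence) {
  check_dna(sequence)
  n <- nchar(sequence)
  best <- list(start = NA_integer_, end = NA_integer_, length = 0L)
  if (n < 6L) return(best)
  for (f in 0:2) {
    starts <- seq.int(f + 1L, n - 2L, 3L)
    codons <- substring(sequence, starts, starts + 2L)
    atg <- which(codons == "ATG")
    stp <- which(codons %in% c("TAA", "TAG", "TGA"))
    if (!length(atg) || !length(stp)) next
    # first stop at or after each ATG
    nxt <- stp[findInterval(atg - 1L, stp) + 1L]
    ok <- !is.na(nxt)
    if (!any(ok)) next
    len <- (nxt[ok] - atg[ok] + 1L) * 3L
    s <- starts[atg[ok]]
    e <- starts[nxt[ok]] + 2L
    # drop nested ORFs sharing a stop: keep 5'-most ATG per stop
    first <- !duplicated(nxt[ok])
    len <- len[first]; s <- s[first]; e <- e[first]
    cand <- order(-len, s)[1]
    if (len[cand] > best$length ||
        (len[cand] == best$length && !is.na(best$start) && s[cand] < best$start))
      best <- list(start = s[cand], end = e[cand], length = len[cand])
  }
  best
}

check_dna <- function(sequence) {
  if (length(sequence) != 1L || !is.character(sequence))
    stop("sequence must be a single character string")
  if (grepl("[^ACGTN]", sequence))
    stop("sequence contains symbols outside A/C/G/T/N")
  invisible(TRUE)
}

# Fickett TESTCODE statistic: position (periodicity) and composition
# parameters per base, mapped through the classic probability tables.
fickett_tables <- function() {
  list(
    pos_prob = rbind(
      A = c(0.94, 0.68, 0.84, 0.93, 0.58, 0.68, 0.45, 0.34, 0.20, 0.22),
      C = c(0.80, 0.70, 0.70, 0.81, 0.66, 0.48, 0.51, 0.33, 0.30, 0.23),
      G = c(0.90, 0.88, 0.74, 0.64, 0.53, 0.48, 0.27, 0.16, 0.08, 0.08),
      T = c(0.97, 0.97, 0.91, 0.68, 0.69, 0.44, 0.54, 0.20, 0.09, 0.09)),
    pos_weight = c(A = 0.26, C = 0.18, G = 0.31, T = 0.33),
    pos_cut = c(1.9, 1.8, 1.7, 1.6, 1.5, 1.4, 1.3, 1.2, 1.1, 0),
    cont_prob = rbind(
      A = c(0.28, 0.49, 0.44, 0.55, 0.62, 0.49, 0.67, 0.65, 0.81, 0.21),
      C = c(0.82, 0.64, 0.51, 0.64, 0.59, 0.59, 0.43, 0.44, 0.39, 0.31),
      G = c(0.40, 0.54, 0.47, 0.64, 0.64, 0.73, 0.41, 0.41, 0.33, 0.29),
      T = c(0.28, 0.24, 0.39, 0.40, 0.55, 0.75, 0.56, 0.69, 0.51, 0.58)),
    cont_weight = c(A = 0.11, C = 0.12, G = 0.15, T = 0.14),
    cont_cut = c(0.33, 0.31, 0.29, 0.27, 0.25, 0.23, 0.21, 0.19, 0.17, 0))
}

#' Fickett coding-potential score
#'
#' The classic TESTCODE statistic combining 3-periodicity and base
#' composition; higher values indicate protein-coding character.
#'
#' @param sequence Uppercase DNA string.
#' @return Numeric score (roughly 0.2-1.3).
#' @export
fickett_score <- function(sequence) {
  check_dna(sequence)
  tb <- fickett_tables()
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(chars)
  phase <- (seq_len(n) - 1L) %% 3L
  score <- 0
  for (b in c("A", "C", "G", "T")) {
    cnt <- vapply(0:2, function(p) sum(chars == b & phase == p), numeric(1))
    pos_par <- max(cnt) / (min(cnt) + 1)
    cont_par <- sum(cnt) / n
    pi <- which(pos_par >= tb$pos_cut)[1]
    ci <- which(cont_par >= tb$cont_cut)[1]
    score <- score + tb$pos_prob[b, pi] * tb$pos_weight[b] +
      tb$cont_prob[b, ci] * tb$cont_weight[b]
  }
  score
}

#' Hexamer usage background tables
#'
#' In-frame hexamer (dicodon) log-usage ratio background derived
#' analytically from a codon-usage model: the coding background assigns a
#' hexamer the product of its two codon probabilities (stop codons carry
#' a small nuisance mass), the noncoding background the product of the
#' marginal base frequencies implied by the same codon model. These are
#' the shipped defaults and match the synthetic generator's codon model.
#'
#' @param codon_weights Named numeric vector of sense-codon weights
#'   (defaults to the package codon-usage model, [codon_usage()]).
#' @param stop_mass Probability mass given to each stop codon.
#' @return list with `log_ratio`, a named vector over all 4096 hexamers.
#' @export
hexamer_background <- function(codon_weights = codon_usage(),
                               stop_mass = 1e-4) {
  stops <- c("TAA", "TAG", "TGA")
  p <- codon_weights / sum(codon_weights) * (1 - 3 * stop_mass)
  p[stops] <- stop_mass
  codons <- names(p)
  # marginal base composition of the codon model
  base_p <- c(A = 0, C = 0, G = 0, T = 0)
  for (i in 1:3) {
    b <- substr(codons, i, i)
    base_p <- base_p + vapply(names(base_p),
                              function(x) sum(p[b == x]), numeric(1)) / 3
  }
  hex <- as.vector(outer(codons, codons, paste0))
  pc <- as.vector(outer(unname(p), unname(p)))
  chars <- strsplit(hex, "", fixed = TRUE)
  pn <- vapply(chars, function(h) prod(base_p[h]), numeric(1))
  list(log_ratio = stats::setNames(log(pc / pn), hex), base_p = base_p)
}

#' Mean in-frame hexamer log-ratio
#'
#' Average of the coding/noncoding hexamer log-usage ratio over
#' consecutive in-frame hexamers, read in the frame of the longest ORF
#' (frame 1 when the sequence has no ORF). Positive values indicate
#' coding-like dicodon usage.
#'
#' @param sequence Uppercase DNA string.
#' @param background Tables from [hexamer_background()].
#' @return Numeric score.
#' @export
hexamer_score <- function(sequence, background = hexamer_background()) {
  check_dna(sequence)
  n <- nchar(sequence)
  if (n < 6L) return(NA_real_)
  orf <- longest_orf(sequence)
  frame <- if (orf$length > 0) (orf$start - 1L) %% 3L else 0L
  starts <- seq.int(frame + 1L, n - 5L, 3L)
  hx <- substring(sequence, starts, starts + 5L)
  lr <- background$log_ratio[hx]
  mean(lr, na.rm = TRUE) # hexamers containing N are skipped
}

#' Three-scorer coding-potential assessment
#'
#' Emulates the three-method coding-potential consensus with internal
#' scorers: (i) ORF rule - coding if the longest ORF is >= 300 nt and
#' covers >= 30% of the transcript; (ii) Fickett rule - coding if the
#' TESTCODE score reaches 0.95; (iii) hexamer rule - coding if the mean
#' in-frame hexamer log-ratio is positive. Verdicts are defined for
#' sequences of at least 200 nt.
#'
#' @param sequence Uppercase DNA string (>= 200 nt).
#' @param background Hexamer background tables.
#' @return list with scores and a logical vector `coding_verdict` of
#'   length 3 (`orf`, `fickett`, `hexamer`).
#' @export
coding_potential <- function(sequence, background = hexamer_background()) {
  check_dna(sequence)
  if (nchar(sequence) < 200L)
    stop("coding-potential verdicts are defined for sequences >= 200 nt")
  orf <- longest_orf(sequence)
  cov <- orf$length / nchar(sequence)
  fk <- fickett_score(sequence)
  hx <- hexamer_score(sequence, background)
  list(orf_length = orf$length, orf_coverage = cov,
       fickett_score = fk, hexamer_score = hx,
       coding_verdict = c(orf = orf$length >= 300L && cov >= 0.3,
                          fickett = fk >= 0.95,
                          hexamer = is.finite(hx) && hx > 0))
}

#' Identify lncRNAs by the consensus rule
#'
#' A transcript is kept as lncRNA iff it is longer than 200 nt, has at
#' least two exons, carries no Rfam and no Pfam homology flag, and all
#' three coding-potential scorers call it noncoding.
#'
#' @param records data.frame with columns `transcript_id`, `sequence`,
#'   `exon_count`, `rfam_hit`, `pfam_hit`.
#' @param background Hexamer background tables.
#' @return Character vector of lncRNA transcript ids.
#' @export
identify_lncrnas <- function(records, background = hexamer_background()) {
  need <- c("transcript_id", "sequence", "exon_count", "rfam_hit", "pfam_hit")
  if (!all(need %in% names(records)))
    stop("records need columns: ", paste(need, collapse = ", "))
  keep <- logical(nrow(records))
  for (i in seq_len(nrow(records))) {
    if (nchar(records$sequence[i]) <= 200L) next
    if (records$exon_count[i] < 2L) next
    if (isTRUE(records$rfam_hit[i]) || isTRUE(records$pfam_hit[i])) next
    cp <- coding_potential(records$sequence[i], background)
    keep[i] <- !any(cp$coding_verdict)
  }
  records$transcript_id[keep]
}

#' Differentially expressed lncRNAs
#'
#' Intersects the identified lncRNA set with the DEG calls: a lncRNA is a
#' DEL iff its (host) gene is flagged `is_deg` (BH-adjusted p < 0.05,
#' strictly).
#'
#' @param lnc_ids Character vector of lncRNA transcript ids.
#' @param de DE result table from [de_test()].
#' @param tx2gene Optional named vector mapping transcript id to gene id;
#'   when missing, transcript ids are matched to `gene_id` directly.
#' @return data.frame of DELs with their DE statistics.
#' @export
detect_dels <- function(lnc_ids, de, tx2gene = NULL) {
  if (!length(lnc_ids))
    return(cbind(data.frame(transcript_id = character(0)),
                 de[0, , drop = FALSE]))
  gene <- if (is.null(tx2gene)) lnc_ids else unname(tx2gene[lnc_ids])
  idx <- match(gene, de$gene_id)
  keep <- !is.na(idx) & de$is_deg[idx]
  out <- cbind(data.frame(transcript_id = lnc_ids[keep],
                          stringsAsFactors = FALSE),
               de[idx[keep], , drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Log-normalised expression
#'
#' `log2(count / size_factor + 1)`, the scale on which lncRNA-mRNA
#' correlations are computed.
#'
#' @param counts Integer matrix, genes x samples.
#' @param sf Size factors (computed when missing).
#' @return Numeric matrix.
#' @export
normalized_log_expr <- function(counts, sf = size_factors(counts)) {
  log2(sweep(as.matrix(counts), 2L, sf, "/") + 1)
}

#' Trans lncRNA-mRNA correlation network
#'
#' Pearson correlation across samples for every DEL x DEG pair on the
#' log-normalised scale; a regulatory link is retained when |r| exceeds
#' `r_min` (default 0.9) and the correlation t-test (n-2 df) gives
#' p < `p_max`. Zero-variance profiles are skipped with a warning.
#'
#' @param lnc_expr,gene_expr Numeric matrices (features x samples) on the
#'   log-normalised scale, with identical sample columns.
#' @param r_min,p_max Link retention thresholds.
#' @return Edge-list data.frame `lnc_id, gene_id, r, p, sign`.
#' @export
trans_network <- function(lnc_expr, gene_expr, r_min = 0.9, p_max = 0.05) {
  lnc_expr <- as.matrix(lnc_expr); gene_expr <- as.matrix(gene_expr)
  if (ncol(lnc_expr) != ncol(gene_expr))
    stop("sample columns differ between the two expression matrices")
  n <- ncol(lnc_expr)
  if (n < 3L) stop("need at least 3 samples for correlation testing")
  v1 <- apply(lnc_expr, 1L, stats::var)
  v2 <- apply(gene_expr, 1L, stats::var)
  if (any(v1 == 0) || any(v2 == 0))
    warning("zero-variance profiles skipped: ",
            sum(v1 == 0), " lncRNA(s), ", sum(v2 == 0), " gene(s)")
  lnc_expr <- lnc_expr[v1 > 0, , drop = FALSE]
  gene_expr <- gene_expr[v2 > 0, , drop = FALSE]
  if (!nrow(lnc_expr) || !nrow(gene_expr))
    return(data.frame(lnc_id = character(0), gene_id = character(0),
                      r = numeric(0), p = numeric(0), sign = character(0)))
  cc <- stats::cor(t(lnc_expr), t(gene_expr))
  tt <- cc * sqrt((n - 2) / pmax(1 - cc^2, 1e-300))
  pp <- 2 * stats::pt(-abs(tt), df = n - 2)
  hit <- which(abs(cc) > r_min & pp < p_max, arr.ind = TRUE)
  out <- data.frame(
    lnc_id = rownames(lnc_expr)[hit[, 1]],
    gene_id = rownames(gene_expr)[hit[, 2]],
    r = cc[hit], p = pp[hit],
    sign = ifelse(cc[hit] > 0, "positive", "negative"),
    stringsAsFactors = FALSE)
  out[order(out$lnc_id, out$gene_id), , drop = FALSE]
}
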