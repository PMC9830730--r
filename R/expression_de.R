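#' Median-of-ratios size factors
#'
#' Per-library normalisation factors computed as the median, over genes
#' with positive counts in every library, of the ratio of each count to
#' the gene's geometric mean across libraries.
#'
#' @param counts Integer matrix, genes x samples.
#' @return Positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos))
    stop("no gene has positive counts in every sample; ",
         "filter the matrix to expressed genes first")
  lc <- log(counts[pos, , drop = FALSE])
  gm <- rowMeans(lc)
  s <- apply(lc, 2L, function(col) exp(stats::median(col - gm)))
  if (any(!is.finite(s)) || any(s <= 0)) stop("non-positive size factor")
  s
}

#' Per-gene NB dispersion estimates
#'
#' Method-of-moments dispersion on size-factor-normalised counts,
#' shrunk halfway toward a fitted mean-dispersion trend
#' \eqn{\alpha_{tr}(\mu) = a_0 + a_1/\mu} (ordinary least squares over
#' genes with a positive raw estimate). Estimates are floored at 1e-8;
#' all-zero genes get `NA` and are excluded from testing downstream.
#'
#' @param counts Integer matrix, genes x samples.
#' @param sf Size factors from [size_factors()].
#' @param floor Lower bound on the returned dispersion.
#' @return Numeric vector of dispersions (NA for all-zero genes).
#' @export
estimate_dispersion <- function(counts, sf = size_factors(counts),
                                floor = 1e-8) {
  counts <- as.matrix(counts)
  norm <- sweep(counts, 2L, sf, "/")
  mu <- rowMeans(norm)
  v <- apply(norm, 1L, stats::var)
  raw <- (v - mu) / mu^2
  raw[mu == 0] <- NA_real_
  raw <- pmax(raw, floor)
  use <- !is.na(raw) & raw > floor & mu > 0
  if (sum(use) >= 10L) {
    fit <- stats::lm.fit(cbind(1, 1 / mu[use]), raw[use])
    a <- fit$coefficients
    trend <- pmax(a[1] + a[2] / mu, floor)
  } else {
    trend <- rep(stats::median(raw, na.rm = TRUE), length(raw))
  }
  out <- pmax(floor, 0.5 * raw + 0.5 * trend)
  out[is.na(raw)] <- NA_real_
  unname(out)
}

# Vectorised per-group NB mean fit on the log scale.
# Returns list(logq, info): MLE of log group concentration q (counts have
# mean s_j * q) and the observed Fisher information for log q.
fit_group_mean <- function(y, s, alpha, n_iter = 25L, tol = 1e-10) {
  q <- pmax(rowSums(y) / sum(s), 1e-8)
  logq <- log(q)
  for (it in seq_len(n_iter)) {
    mu <- exp(logq) %o% s
    w <- 1 + alpha * mu
    score <- rowSums((y - mu) / w)
    info <- rowSums(mu / w)
    step <- score / pmax(info, 1e-12)
    step <- pmin(pmax(step, -5), 5)
    logq <- logq + step
    if (max(abs(step)) < tol) break
  }
  mu <- exp(logq) %o% s
  list(logq = logq, info = rowSums(mu / (1 + alpha * mu)))
}

#' Negative-binomial Wald test for differential expression
#'
#' Fits, per gene, a two-group NB model with library size factors as
#' offsets and gene-wise dispersions, then Wald-tests the log2 fold change
#' (case over control; PA-E over CTR under the default design labels).
#' P-values are BH-adjusted over the tested genes; a gene is flagged DEG
#' when the adjusted p-value falls below `padj_max` (default 0.05).
#'
#' @param counts Integer matrix, genes x samples (column names must match
#'   the design sample ids).
#' @param design A [sample_design].
#' @param dispersions Optional per-gene dispersions; computed with
#'   [estimate_dispersion()] when missing.
#' @param sf Optional size factors; computed when missing.
#' @param padj_max DEG threshold on the BH-adjusted p-value.
#' @return data.frame with columns `gene_id`, `base_mean`, `log2fc`, `se`,
#'   `stat`, `pvalue`, `padj`, `is_deg`, `direction`.
#' @export
de_test <- function(counts, design, dispersions = NULL, sf = NULL,
                    padj_max = 0.05) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts))) stop("counts must have sample column names")
  if (!all(design$sample_id %in% colnames(counts)))
    stop("design samples missing from counts")
  counts <- counts[, design$sample_id, drop = FALSE]
  if (is.null(sf)) sf <- size_factors(counts)
  if (is.null(dispersions)) dispersions <- estimate_dispersion(counts, sf)
  ic <- design$group == attr(design, "case")
  yA <- counts[, ic, drop = FALSE]; sA <- sf[ic]
  yB <- counts[, !ic, drop = FALSE]; sB <- sf[!ic]
  norm <- sweep(counts, 2L, sf, "/")
  base_mean <- rowMeans(norm)
  n_genes <- nrow(counts)
  log2fc <- se <- stat <- pvalue <- rep(NA_real_, n_genes)
  alpha <- ifelse(is.na(dispersions), 0, dispersions)
  testable <- !is.na(dispersions) & rowSums(yA) > 0 & rowSums(yB) > 0
  if (any(testable)) {
    fA <- fit_group_mean(yA[testable, , drop = FALSE], sA, alpha[testable])
    fB <- fit_group_mean(yB[testable, , drop = FALSE], sB, alpha[testable])
    l2 <- (fA$logq - fB$logq) / log(2)
    s2 <- sqrt(1 / fA$info + 1 / fB$info) / log(2)
    z <- l2 / s2
    log2fc[testable] <- l2
    se[testable] <- s2
    stat[testable] <- z
    pvalue[testable] <- 2 * stats::pnorm(-abs(z))
  }
  padj <- benjamini_hochberg(pvalue)
  is_deg <- !is.na(padj) & padj < padj_max
  direction <- ifelse(is.na(log2fc), NA_character_,
                      ifelse(log2fc > 0, "up", "down"))
  data.frame(gene_id = rownames(counts), base_mean = base_mean,
             log2fc = log2fc, se = se, stat = stat, pvalue = pvalue,
             padj = padj, is_deg = is_deg, direction = direction,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH step-up with missing p-values excluded from the number of
#' tests and returned as `NA` (delegates to [stats::p.adjust()], which
#' implements exactly this convention).
#'
#' @param pvalues Numeric vector, possibly with NAs.
#' @return Adjusted p-values, same length and order.
#' @export
benjamini_hochberg <- function(pvalues) {
  stats::p.adjust(pvalues, method = "BH")
}

#' FPKM and expression classes
#'
#' Fragments per kilobase of exonic gene model per million mapped reads:
#' \eqn{FPKM_{gj} = 10^9 k_{gj} / (L_g N_j)} with \eqn{L_g} the gene's
#' exonic union length and \eqn{N_j} the library's mapped total. Genes
#' are binned by the FPKM sum over all libraries: high if > 100, medium
#' if > 10, otherwise low (strict inequalities).
#'
#' @param counts Integer matrix, genes x samples.
#' @param lengths Named vector of exonic lengths in bp (e.g. from
#'   [gene_exonic_length()]); must cover all genes in `counts`.
#' @return data.frame with per-sample FPKM columns, `fpkm_sum` and `class`.
#' @export
compute_fpkm <- function(counts, lengths) {
  counts <- as.matrix(counts)
  lengths <- lengths[rownames(counts)]
  if (anyNA(lengths)) stop("missing exonic length for some genes")
  if (any(lengths <= 0)) stop("zero-length gene model")
  totals <- colSums(counts)
  fpkm <- counts * 1e9 / outer(as.numeric(lengths), as.numeric(totals))
  fs <- rowSums(fpkm)
  cls <- ifelse(fs > 100, "high", ifelse(fs > 10, "medium", "low"))
  out <- data.frame(gene_id = rownames(counts), fpkm,
                    fpkm_sum = fs, class = cls,
                    row.names = NULL, check.names = FALSE,
                    stringsAsFactors = FALSE)
  out
}
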