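#' Collapse technical qPCR replicates
#'
#' Arithmetic mean Cq per biological sample after dropping technical
#' replicates more than one cycle from the replicate median; fewer than
#' two surviving replicates yield `NA` with a warning.
#'
#' @param cq Long Cq table (`gene, sample_id, group, replicate, cq`).
#' @param max_dev Outlier rule: |Cq - median| greater than this many
#'   cycles drops the replicate.
#' @return data.frame `gene, sample_id, group, cq_mean, cq_sd, n_reps`.
#' @export
collapse_technical <- function(cq, max_dev = 1) {
  key <- interaction(cq$gene, cq$sample_id, drop = TRUE)
  rows <- lapply(split(cq, key), function(g) {
    keep <- abs(g$cq - stats::median(g$cq)) <= max_dev
    vals <- g$cq[keep]
    if (length(vals) < 2L) {
      warning("fewer than 2 surviving technical replicates for ",
              g$gene[1], "/", g$sample_id[1])
      m <- NA_real_; s <- NA_real_
    } else {
      m <- mean(vals); s <- stats::sd(vals)
    }
    data.frame(gene = g$gene[1], sample_id = g$sample_id[1],
               group = g$group[1], cq_mean = m, cq_sd = s,
               n_reps = sum(keep), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pfaffl relative quantification
#'
#' Efficiency-corrected relative expression
#' \deqn{RQ = E_t^{\Delta Cq_t} / E_{ref}^{\Delta Cq_{ref}}}
#' with \eqn{\Delta Cq = \bar{Cq}_{control} - Cq_{sample}}. With two
#' reference genes the reference term is the geometric mean of the two
#' per-reference ratios. The mean control RQ is 1 by construction when
#' replicates are noise-free. With all efficiencies equal to 2 the value
#' coincides with the classic \eqn{2^{-\Delta\Delta Cq}}.
#'
#' @param target_cq Named numeric vector of per-sample mean Cq for the
#'   target gene.
#' @param ref_cq List of named numeric vectors, one per reference gene
#'   (e.g. ACTB and GAPDH).
#' @param control_samples Sample ids forming the control group.
#' @param e_target Amplification efficiency of the target (default 2).
#' @param e_refs Efficiencies of the reference genes (recycled).
#' @return Named numeric vector of per-sample RQ.
#' @export
pfaffl_rq <- function(target_cq, ref_cq, control_samples, e_target = 2,
                      e_refs = 2) {
  if (!is.list(ref_cq)) ref_cq <- list(ref_cq)
  e_refs <- rep_len(e_refs, length(ref_cq))
  stopifnot(e_target > 1, all(e_refs > 1))
  ctrl <- intersect(control_samples, names(target_cq))
  if (!length(ctrl)) stop("no control samples found in target Cq vector")
  d_t <- mean(target_cq[ctrl]) - target_cq
  num <- e_target^d_t
  ref_ratio <- rep(1, length(target_cq))
  for (i in seq_along(ref_cq)) {
    r <- ref_cq[[i]][names(target_cq)]
    if (anyNA(r)) {
      ref_ratio[is.na(r)] <- NA_real_
      r[is.na(r)] <- 0
    }
    d_r <- mean(ref_cq[[i]][ctrl]) - r
    ref_ratio <- ref_ratio * e_refs[i]^d_r
  }
  ref_ratio <- ref_ratio^(1 / length(ref_cq)) # geometric mean of ratios
  stats::setNames(num / ref_ratio, names(target_cq))
}

#' Two-tailed t-test on RQ with significance stars
#'
#' Student's t-test (two-tailed) between case and control RQ values,
#' on the log2 scale by default (variance stabilisation); star classes
#' follow the printed thresholds: p < 0.0332 (*), < 0.0021 (**),
#' < 0.0002 (***), < 0.0001 (****), otherwise ns.
#'
#' @param case_rq,control_rq Numeric RQ vectors.
#' @param log_scale Test log2(RQ) (default) or raw RQ.
#' @return list with `p`, `stars`, `fold_change` (mean case RQ over mean
#'   control RQ).
#' @export
test_rq <- function(case_rq, control_rq, log_scale = TRUE) {
  a <- case_rq[!is.na(case_rq)]; b <- control_rq[!is.na(control_rq)]
  if (length(a) < 2L || length(b) < 2L)
    return(list(p = NA_real_, stars = "ns", fold_change = mean(a) / mean(b)))
  x <- if (log_scale) log2(a) else a
  y <- if (log_scale) log2(b) else b
  p <- if (stats::sd(c(x, y)) == 0) 1 else stats::t.test(x, y)$p.value
  list(p = p, stars = star_class(p), fold_change = mean(a) / mean(b))
}

#' @rdname test_rq
#' @param p A p-value.
#' @export
star_class <- function(p) {
  if (is.na(p)) return("ns")
  if (p < 0.0001) "****"
  else if (p < 0.0002) "***"
  else if (p < 0.0021) "**"
  else if (p < 0.0332) "*"
  else "ns"
}

#' Full qPCR validation analysis
#'
#' Collapses technical replicates, computes Pfaffl RQ per gene against
#' the reference genes, and t-tests case vs control.
#'
#' @param cq Long Cq table.
#' @param reference_genes Character vector of reference gene names
#'   (default ACTB and GAPDH).
#' @param efficiencies Named per-gene amplification efficiencies
#'   (default 2 for all).
#' @param control_group Label of the control group in the table.
#' @return list with `rq` (per-gene, per-sample RQ) and `summary`
#'   (per-gene fold change, p, stars).
#' @export
qpcr_analysis <- function(cq, reference_genes = c("ACTB", "GAPDH"),
                          efficiencies = NULL, control_group = "CTR") {
  coll <- collapse_technical(cq)
  genes <- setdiff(unique(coll$gene), reference_genes)
  missing_refs <- setdiff(reference_genes, unique(coll$gene))
  if (length(missing_refs))
    stop("reference gene(s) absent from Cq table: ",
         paste(missing_refs, collapse = ", "))
  get_cq <- function(g) {
    s <- coll[coll$gene == g, ]
    stats::setNames(s$cq_mean, s$sample_id)
  }
  samples <- unique(coll$sample_id)
  groups <- coll$group[match(samples, coll$sample_id)]
  ctrl_samples <- samples[groups == control_group]
  refs <- lapply(reference_genes, get_cq)
  eff <- function(g) if (!is.null(efficiencies) && g %in% names(efficiencies))
    efficiencies[[g]] else 2
  rq_rows <- list(); summ <- list()
  for (g in genes) {
    rq <- pfaffl_rq(get_cq(g), refs, ctrl_samples, e_target = eff(g),
                    e_refs = vapply(reference_genes, eff, numeric(1)))
    grp <- groups[match(names(rq), samples)]
    tst <- test_rq(rq[grp != control_group], rq[grp == control_group])
    rq_rows[[g]] <- data.frame(gene = g, sample_id = names(rq),
                               group = grp, rq = unname(rq),
                               stringsAsFactors = FALSE)
    summ[[g]] <- data.frame(
      gene = g, fold_change = tst$fold_change,
      rq_case_mean = mean(rq[grp != control_group], na.rm = TRUE),
      rq_case_sd = stats::sd(rq[grp != control_group], na.rm = TRUE),
      rq_ctrl_mean = mean(rq[grp == control_group], na.rm = TRUE),
      rq_ctrl_sd = stats::sd(rq[grp == control_group], na.rm = TRUE),
      p = tst$p, stars = tst$stars, stringsAsFactors = FALSE)
  }
  list(rq = do.call(rbind, c(rq_rows, list(make.row.names = FALSE))),
       summary = do.call(rbind, c(summ, list(make.row.names = FALSE))))
}
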