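#' Over-representation analysis
#'
#' One-sided hypergeometric (Fisher's exact) enrichment of a query gene
#' set against a term-to-gene map: per term, the upper-tail probability
#' \eqn{P(X \ge k)} of drawing `k` or more term genes in a query of size
#' `n` from a universe of `N` genes containing `K` term genes. The
#' universe is the set of genes with at least one annotation in the
#' namespace. BH correction is applied within each namespace; a term is
#' significant at FDR < `fdr_max` (default 0.05).
#'
#' @param query Character vector of gene ids.
#' @param map An annotation map (see [read_annotation_map()]).
#' @param universe Optional explicit universe; default: annotated genes
#'   per namespace.
#' @param fdr_max Significance threshold.
#' @return data.frame with `namespace`, `term_id`, `term_name`, `k`, `n`,
#'   `K`, `N`, `pvalue`, `fdr`, `significant`, and the term's overlapping
#'   genes as a comma-joined string.
#' @export
fisher_enrichment <- function(query, map, universe = NULL, fdr_max = 0.05) {
  query <- unique(query)
  if (!length(query))
    return(data.frame(namespace = character(0), term_id = character(0),
                      term_name = character(0), k = integer(0),
                      n = integer(0), K = integer(0), N = integer(0),
                      pvalue = numeric(0), fdr = numeric(0),
                      significant = logical(0), genes = character(0)))
  out <- list()
  for (ns in unique(map$namespace)) {
    sub <- map[map$namespace == ns, , drop = FALSE]
    uni <- if (is.null(universe)) unique(sub$gene_id) else unique(universe)
    q <- intersect(query, uni)
    n <- length(q)
    terms <- unique(sub$term_id)
    rows <- lapply(terms, function(t) {
      tg <- unique(sub$gene_id[sub$term_id == t])
      K <- length(tg)
      hits <- intersect(q, tg)
      k <- length(hits)
      p <- stats::phyper(k - 1, K, length(uni) - K, n, lower.tail = FALSE)
      data.frame(namespace = ns, term_id = t,
                 term_name = sub$term_name[match(t, sub$term_id)],
                 k = k, n = n, K = K, N = length(uni),
                 pvalue = p, genes = paste(sort(hits), collapse = ","),
                 stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    tab$fdr <- benjamini_hochberg(tab$pvalue)
    out[[ns]] <- tab
  }
  res <- do.call(rbind, out)
  res$significant <- res$fdr < fdr_max
  rownames(res) <- NULL
  res[order(res$namespace, res$pvalue), c("namespace", "term_id",
                                          "term_name", "k", "n", "K", "N",
                                          "pvalue", "fdr", "significant",
                                          "genes")]
}

#' Expression-trend z-score of an enriched term
#'
#' \eqn{z = (n_{up} - n_{down})/\sqrt{n_{up} + n_{down}}} over the term's
#' differentially expressed genes: the overall increasing or decreasing
#' impact of the contrast on the functional term. `NA` when the term has
#' no DE genes.
#'
#' @param term_genes Character vector of the term's overlapping DE genes.
#' @param de DE result table from [de_test()].
#' @return Numeric z-score.
#' @export
trend_zscore <- function(term_genes, de) {
  dir <- de$direction[match(term_genes, de$gene_id)]
  up <- sum(dir == "up", na.rm = TRUE)
  down <- sum(dir == "down", na.rm = TRUE)
  k <- up + down
  if (k == 0) return(NA_real_)
  (up - down) / sqrt(k)
}

#' Phenotype-signature membership report
#'
#' Intersects a DEG list with selected phenotype-ontology terms (e.g.
#' cardiovascular-system terms of the HP namespace), one row per
#' gene-term membership with the gene's DE direction.
#'
#' @param deg_ids Character vector of DEG ids.
#' @param map Annotation map containing the namespace of interest.
#' @param term_ids Terms to report.
#' @param de Optional DE table to annotate direction.
#' @return data.frame `term_id, term_name, gene_id, direction`.
#' @export
signature_report <- function(deg_ids, map, term_ids, de = NULL) {
  sub <- map[map$term_id %in% term_ids, , drop = FALSE]
  sub <- sub[sub$gene_id %in% deg_ids, , drop = FALSE]
  out <- data.frame(term_id = sub$term_id, term_name = sub$term_name,
                    gene_id = sub$gene_id, stringsAsFactors = FALSE)
  out$direction <- if (is.null(de)) rep(NA_character_, nrow(out)) else
    de$direction[match(out$gene_id, de$gene_id)]
  rownames(out) <- NULL
  out[order(out$term_id, out$gene_id), , drop = FALSE]
}
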