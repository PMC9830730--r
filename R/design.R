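#' Two-group sample design
#'
#' Describes which RNA-seq libraries belong to the embolism-affected
#' pulmonary-artery group (PA-E) and which to the control group (CTR).
#' All group-contrast statistics in the package (log2 fold change,
#' \eqn{\Delta}PSI, \eqn{\Delta}AAF, qPCR fold change) are signed as
#' case minus control.
#'
#' @param sample_id Character vector of unique library identifiers.
#' @param group Character vector, one label per sample; every label must be
#'   `case` or `control`.
#' @param case,control The two group labels. Defaults follow the study
#'   vocabulary: `"PA-E"` and `"CTR"`.
#' @return A `data.frame` of class `sample_design` with columns `sample_id`
#'   and `group`, and attributes `case` / `control`.
#' @examples
#' sample_design(c("PA-E1", "PA-E2", "CTR1", "CTR2"),
#'               c("PA-E", "PA-E", "CTR", "CTR"))
#' @export
sample_design <- function(sample_id, group, case = "PA-E", control = "CTR") {
  sample_id <- as.character(sample_id)
  group <- as.character(group)
  if (length(sample_id) != length(group))
    stop("'sample_id' and 'group' must have equal length")
  if (anyDuplicated(sample_id))
    stop("duplicated sample ids: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  bad <- setdiff(unique(group), c(case, control))
  if (length(bad))
    stop("group labels must be '", case, "' or '", control, "'; found: ",
         paste(bad, collapse = ", "))
  if (sum(group == case) < 2L || sum(group == control) < 2L)
    stop("each group needs at least 2 samples")
  out <- data.frame(sample_id = sample_id, group = group,
                    stringsAsFactors = FALSE)
  attr(out, "case") <- case
  attr(out, "control") <- control
  class(out) <- c("sample_design", "data.frame")
  out
}

#' @export
print.sample_design <- function(x, ...) {
  cat("sample_design: ", sum(x$group == attr(x, "case")), " ",
      attr(x, "case"), " vs ", sum(x$group == attr(x, "control")), " ",
      attr(x, "control"), "\n", sep = "")
  print.data.frame(x, ...)
  invisible(x)
}

case_samples <- function(design) design$sample_id[design$group == attr(design, "case")]
control_samples <- function(design) design$sample_id[design$group == attr(design, "control")]

#' Pipeline configuration
#'
#' Collects input paths and decision thresholds for [run_pipeline()]. All
#' thresholds default to the values used throughout the analysis: DEG at
#' BH-adjusted p < 0.05; differential splicing at adjusted p < 0.01 and
#' |dPSI| > 0.1; allele-specific expression at |dAAF| > 0.3 and FDR < 0.001
#' with minimum per-sample coverage of 10 reads and a final within-group
#' AAF standard-deviation cut of 0.1; trans lncRNA-mRNA links at |r| > 0.9
#' (p < 0.05); enrichment at FDR < 0.05.
#'
#' @param paths Named list of input file paths (see [run_pipeline()]).
#' @param outdir Output directory for result tables and the run manifest.
#' @param seed Integer seed recorded in the manifest and used by any
#'   stochastic stage.
#' @param deg_padj,das_padj,das_dpsi,ase_daaf,ase_fdr,ase_sd_max,min_coverage,
#'   link_r,link_p,enrich_fdr Decision thresholds, as above.
#' @param multiallelic `"reject"` (default) or `"split"` for multiallelic
#'   VCF records.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(paths = list(), outdir = tempfile("paeomics_run_"),
                            seed = 1L,
                            deg_padj = 0.05,
                            das_padj = 0.01, das_dpsi = 0.1,
                            ase_daaf = 0.3, ase_fdr = 0.001, ase_sd_max = 0.1,
                            min_coverage = 10L,
                            link_r = 0.9, link_p = 0.05,
                            enrich_fdr = 0.05,
                            multiallelic = c("reject", "split")) {
  stopifnot(deg_padj > 0, deg_padj <= 1, das_padj > 0, das_dpsi >= 0,
            ase_daaf >= 0, ase_fdr > 0, ase_sd_max >= 0, min_coverage >= 0,
            link_r >= 0, link_r <= 1)
  cfg <- list(paths = paths, outdir = outdir, seed = as.integer(seed),
              deg_padj = deg_padj, das_padj = das_padj, das_dpsi = das_dpsi,
              ase_daaf = ase_daaf, ase_fdr = ase_fdr, ase_sd_max = ase_sd_max,
              min_coverage = as.integer(min_coverage),
              link_r = link_r, link_p = link_p, enrich_fdr = enrich_fdr,
              multiallelic = match.arg(multiallelic))
  class(cfg) <- "pipeline_config"
  cfg
}
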