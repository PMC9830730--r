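#' Per-site, per-sample allele counts
#'
#' @param sites data.frame with columns `chrom`, `pos` (1-based), `id`
#'   (known "rs"-style id or `.`), `ref`, `alt` (single bases, ref != alt).
#' @param ref_counts,alt_counts Integer matrices (sites x samples) of
#'   reference / alternative read depths; column names are sample ids.
#' @return Object of class `allele_sites`.
#' @export
allele_sites <- function(sites, ref_counts, alt_counts) {
  need <- c("chrom", "pos", "id", "ref", "alt")
  if (!all(need %in% names(sites)))
    stop("'sites' needs columns: ", paste(need, collapse = ", "))
  if (nrow(sites) != nrow(ref_counts) || nrow(sites) != nrow(alt_counts))
    stop("count matrices must have one row per site")
  if (!identical(colnames(ref_counts), colnames(alt_counts)))
    stop("ref/alt sample columns differ")
  if (any(ref_counts < 0) || any(alt_counts < 0)) stop("negative allele count")
  if (any(sites$ref == sites$alt)) stop("ref == alt at some site")
  rownames(sites) <- NULL
  out <- list(sites = sites,
              ref = as.matrix(ref_counts), alt = as.matrix(alt_counts))
  class(out) <- "allele_sites"
  out
}

#' @export
print.allele_sites <- function(x, ...) {
  cat("allele_sites: ", nrow(x$sites), " sites x ", ncol(x$ref),
      " samples\n", sep = "")
  invisible(x)
}

n_sites <- function(x) nrow(x$sites)

subset_sites <- function(x, i) {
  allele_sites(x$sites[i, , drop = FALSE],
               x$ref[i, , drop = FALSE], x$alt[i, , drop = FALSE])
}

#' Read per-sample allele depths from a VCF
#'
#' Intake for the allele-specific-expression cascade: a VCF v4.2 whose
#' genotype FORMAT carries `AD` (ref,alt read depths per sample). Only
#' biallelic single-nucleotide records are analysed: indel records are
#' skipped (tallied in attribute `n_skipped_indel`) and multiallelic
#' records are either rejected with an error (default, matching the
#' biallelic-substitution analysis) or split into one record per
#' alternative allele.
#'
#' @param path VCF path (plain text).
#' @param multiallelic `"reject"` or `"split"`.
#' @return An [allele_sites] object.
#' @export
read_allele_sites <- function(path, multiallelic = c("reject", "split")) {
  multiallelic <- match.arg(multiallelic)
  if (!file.exists(path)) stop("no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) # single-record VCFs come back as a bare vector
    fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0L) stop("empty VCF: ", path)
  if (!any(grepl("AD", v@gt[, "FORMAT"])))
    stop("AD field missing from VCF FORMAT")
  ad <- vcfR::extract.gt(v, element = "AD")
  if (is.null(ad) || all(is.na(ad))) stop("AD field missing from VCF FORMAT")
  chrom <- fix[, "CHROM"]; pos <- as.integer(fix[, "POS"])
  id <- fix[, "ID"]; ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  id[is.na(id)] <- "."
  multi <- grepl(",", alt, fixed = TRUE)
  if (any(multi) && multiallelic == "reject")
    stop("multiallelic record(s) at ",
         paste(utils::head(paste0(chrom[multi], ":", pos[multi]), 5),
               collapse = ", "),
         "; rerun with multiallelic = 'split' to keep them")
  rows <- list(); refm <- list(); altm <- list()
  n_indel <- 0L
  samples <- colnames(ad)
  for (i in seq_along(pos)) {
    alts <- strsplit(alt[i], ",", fixed = TRUE)[[1]]
    depths <- lapply(strsplit(ad[i, ], ",", fixed = TRUE), as.integer)
    for (k in seq_along(alts)) {
      if (nchar(ref[i]) != 1L || nchar(alts[k]) != 1L) {
        n_indel <- n_indel + 1L
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chrom[i], pos = pos[i], id = id[i], ref = ref[i],
        alt = alts[k], stringsAsFactors = FALSE)
      refm[[length(refm) + 1L]] <- vapply(depths, `[`, integer(1), 1L)
      altm[[length(altm) + 1L]] <- vapply(depths, `[`, integer(1), k + 1L)
    }
  }
  if (!length(rows)) stop("no biallelic SNV records in ", path)
  sites <- do.call(rbind, rows)
  refc <- do.call(rbind, refm); altc <- do.call(rbind, altm)
  colnames(refc) <- colnames(altc) <- samples
  out <- allele_sites(sites, refc, altc)
  attr(out, "n_skipped_indel") <- n_indel
  out
}

#' Write allele counts as a VCF with per-sample AD
#'
#' @param x An [allele_sites] object.
#' @param path Output path.
#' @export
write_allele_sites <- function(x, path) {
  samples <- colnames(x$ref)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=paeomics",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")), con)
  gt <- matrix(paste(x$ref, x$alt, sep = ","), nrow = nrow(x$sites))
  body <- apply(cbind(x$sites$chrom, x$sites$pos, x$sites$id, x$sites$ref,
                      x$sites$alt, ".", "PASS", ".", "AD", gt),
                1L, paste, collapse = "\t")
  writeLines(body, con)
  invisible(path)
}
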