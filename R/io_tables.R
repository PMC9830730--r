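#' Read a gene count matrix
#'
#' Reads a TSV with a `gene_id` column followed by one column per library,
#' checks it against the sample design, and returns an integer matrix
#' (genes x samples) ordered as in the design. Columns not named in the
#' design are dropped with a warning; a design sample absent from the
#' header, a negative, missing or non-integer cell are errors.
#'
#' @param path TSV path.
#' @param design A [sample_design].
#' @return Integer matrix with the design attached as attribute `design`.
#' @export
read_counts <- function(path, design) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"gene_id" %in% names(tab)) stop("counts TSV needs a 'gene_id' column")
  missing <- setdiff(design$sample_id, names(tab))
  if (length(missing))
    stop("samples in design absent from counts header: ",
         paste(missing, collapse = ", "))
  extra <- setdiff(names(tab), c("gene_id", design$sample_id))
  if (length(extra))
    warning("dropping columns not in design: ", paste(extra, collapse = ", "))
  m <- as.matrix(tab[, design$sample_id, drop = FALSE])
  if (anyNA(m)) stop("missing cell in count matrix")
  if (any(m < 0)) stop("negative count in matrix")
  if (any(m != round(m))) stop("non-integer count in matrix")
  storage.mode(m) <- "integer"
  rownames(m) <- tab$gene_id
  attr(m, "design") <- design
  m
}

#' @rdname read_counts
#' @param counts Integer matrix, genes x samples.
#' @export
write_counts <- function(counts, path) {
  out <- data.frame(gene_id = rownames(counts), counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write splice-event definitions and junction counts
#'
#' Events are stored as a TSV with one row per event (id, gene, type,
#' effective lengths and the inclusion/skipping coordinate tuples encoded
#' as `start-end` segments joined by `,`). Junction counts are a long TSV
#' `event_id, sample_id, inclusion, skipping`.
#'
#' @param path TSV path.
#' @return `read_splice_events()`: data.frame of events;
#'   `read_junction_counts()`: data.frame of counts.
#' @export
read_splice_events <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("event_id", "gene_id", "type", "chrom", "strand",
            "inclusion_form", "skipping_form", "l_inc", "l_skip")
  if (!all(need %in% names(tab)))
    stop("events TSV needs columns: ", paste(need, collapse = ", "))
  if (!all(tab$type %in% c("SE", "RI", "A3SS", "A5SS", "MXE")))
    stop("unknown event type")
  if (any(tab$l_inc < 1) || any(tab$l_skip < 1))
    stop("effective lengths must be >= 1")
  tab
}

#' @rdname read_splice_events
#' @param events Event data.frame.
#' @export
write_splice_events <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname read_splice_events
#' @export
read_junction_counts <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("event_id", "sample_id", "inclusion", "skipping")
  if (!all(need %in% names(tab)))
    stop("junction TSV needs columns: ", paste(need, collapse = ", "))
  if (any(tab$inclusion < 0) || any(tab$skipping < 0))
    stop("negative junction count")
  tab
}

#' @rdname read_splice_events
#' @param junctions Junction-count data.frame.
#' @export
write_junction_counts <- function(junctions, path) {
  utils::write.table(junctions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a term-to-gene annotation map
#'
#' Long TSV with columns `namespace` (BP/CC/MF/KEGG/HP), `term_id`,
#' `term_name`, `gene_id`; one row per term-gene assignment.
#'
#' @param path TSV path.
#' @return data.frame of class `annotation_map`.
#' @export
read_annotation_map <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("namespace", "term_id", "term_name", "gene_id")
  if (!all(need %in% names(tab)))
    stop("annotation map needs columns: ", paste(need, collapse = ", "))
  class(tab) <- c("annotation_map", "data.frame")
  tab
}

#' @rdname read_annotation_map
#' @param map Annotation map data.frame.
#' @export
write_annotation_map <- function(map, path) {
  utils::write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a qPCR Cq table
#'
#' Long TSV with columns `gene`, `sample_id`, `group`, `replicate`, `cq`;
#' four technical replicates per biological sample are expected.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_cq_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "sample_id", "group", "replicate", "cq")
  if (!all(need %in% names(tab)))
    stop("Cq table needs columns: ", paste(need, collapse = ", "))
  if (any(tab$cq <= 0)) stop("Cq values must be positive")
  tab
}

#' @rdname read_cq_table
#' @param cq Cq data.frame.
#' @export
write_cq_table <- function(cq, path) {
  utils::write.table(cq, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write region masks as BED
#'
#' BED files are 0-based half-open; conversion to the package-internal
#' 1-based inclusive convention happens here and only here, and is
#' bijective on valid intervals.
#'
#' @param path BED path.
#' @return `read_bed()`: a [GenomicRanges::GRanges].
#' @export
read_bed <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 3L) stop("BED needs at least 3 columns")
  GenomicRanges::GRanges(seqnames = tab[[1]],
                         ranges = IRanges::IRanges(tab[[2]] + 1L, tab[[3]]))
}

#' @rdname read_bed
#' @param gr A `GRanges` of 1-based inclusive intervals.
#' @export
write_bed <- function(gr, path) {
  tab <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
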