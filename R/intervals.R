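#' Genomic intervals and transcript models
#'
#' All coordinates inside the package are 0-based half-open; the GTF readers
#' and writers convert at the boundary. Strand is one of `"+"`, `"-"`, or
#' `"*"` (unknown).
#'
#' @name intervals
NULL

#' Construct a genomic interval
#'
#' @param chrom sequence (chromosome/scaffold) name, non-empty.
#' @param start 0-based inclusive start.
#' @param end 0-based exclusive end; must exceed `start`.
#' @param strand `"+"`, `"-"` or `"*"`.
#' @return a `genomic_interval` list.
#' @export
genomic_interval <- function(chrom, start, end, strand = "*") {
  stopifnot(is.character(chrom), nzchar(chrom))
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || start >= end) {
    stop("invalid interval: require 0 <= start < end, got [", start, ", ", end, ")")
  }
  if (!strand %in% c("+", "-", "*")) stop("strand must be one of '+', '-', '*'")
  structure(list(chrom = chrom, start = start, end = end, strand = strand),
            class = "genomic_interval")
}

interval_width <- function(x) x$end - x$start

#' Construct a transcript model
#'
#' A transcript is an ordered set of non-overlapping exons on one chromosome
#' and strand, plus a locus class code (`I`, `U`, `X`, `OTHER`, `REFERENCE`)
#' and a source tag.
#'
#' @param id unique transcript identifier.
#' @param chrom chromosome name.
#' @param strand `"+"`, `"-"` or `"*"`.
#' @param exons two-column matrix (or data.frame) of 0-based half-open
#'   `start`, `end` pairs; will be sorted by start.
#' @param class_code locus class code.
#' @param source free-text provenance tag (assembler or reference).
#' @param gene_id optional gene identifier (defaults to `id`).
#' @return a `transcript` object.
#' @export
transcript <- function(id, chrom, strand, exons,
                       class_code = "OTHER", source = "unknown",
                       gene_id = id) {
  exons <- as.matrix(exons)
  if (ncol(exons) != 2L) stop("exons must have two columns (start, end)")
  storage.mode(exons) <- "integer"
  colnames(exons) <- c("start", "end")
  exons <- exons[order(exons[, "start"]), , drop = FALSE]
  if (any(exons[, "end"] <= exons[, "start"]) || any(exons[, "start"] < 0L)) {
    stop("transcript ", id, ": invalid exon coordinates")
  }
  if (nrow(exons) > 1L &&
      any(exons[-1L, "start"] < exons[-nrow(exons), "end"])) {
    stop("transcript ", id, ": overlapping exons")
  }
  if (!strand %in% c("+", "-", "*")) stop("strand must be one of '+', '-', '*'")
  structure(list(id = id, gene_id = gene_id, chrom = chrom, strand = strand,
                 exons = exons, class_code = class_code, source = source),
            class = "transcript")
}

#' Spliced (mature) length of a transcript
#'
#' @param tx a `transcript`.
#' @return total exonic length in nucleotides.
#' @export
spliced_length <- function(tx) {
  sum(tx$exons[, "end"] - tx$exons[, "start"])
}

#' Genomic span of a transcript
#'
#' @param tx a `transcript`.
#' @return a `genomic_interval` covering first exon start to last exon end.
#' @export
transcript_span <- function(tx) {
  genomic_interval(tx$chrom, min(tx$exons[, "start"]), max(tx$exons[, "end"]),
                   tx$strand)
}

#' @export
print.transcript <- function(x, ...) {
  cat(sprintf("<transcript %s> %s:%d-%d(%s) %d exon(s), %d nt, class=%s, source=%s\n",
              x$id, x$chrom, min(x$exons[, "start"]), max(x$exons[, "end"]),
              x$strand, nrow(x$exons), spliced_length(x), x$class_code,
              x$source))
  invisible(x)
}

# exonic overlap length (nt) between two transcripts; 0 if different chrom
exonic_overlap_length <- function(a, b) {
  if (a$chrom != b$chrom) return(0L)
  ia <- IRanges::IRanges(start = a$exons[, "start"] + 1L, end = a$exons[, "end"])
  ib <- IRanges::IRanges(start = b$exons[, "start"] + 1L, end = b$exons[, "end"])
  ov <- IRanges::intersect(ia, ib)
  sum(IRanges::width(ov))
}

# strands compatible for dual-assembler support: equal, or either unknown
strands_compatible <- function(s1, s2) s1 == "*" || s2 == "*" || s1 == s2
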