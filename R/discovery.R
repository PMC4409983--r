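#' Transcript discovery cascade
#'
#' The front end of the pipeline mirrors a dual-assembler identification
#' flow: keep transcripts supported by both assemblers, assign a locus class
#' code against the reference annotation (I = intronic, U = intergenic,
#' X = exonic overlap on the opposite strand), apply the 200-nt length
#' cutoff, and flag likely complementary-strand duplicate calls among
#' single-exon transcripts.
#'
#' @name discovery
NULL

#' Intersect two assembler transcript sets
#'
#' A transcript from `set_a` is retained iff some transcript in `set_b` has
#' at least `min_overlap` nt of exonic overlap on the same chromosome and a
#' compatible strand (equal strands, or either unknown). Optionally a
#' reciprocal-fraction rule can be required instead.
#'
#' @param set_a,set_b lists of `transcript` objects on the same genome.
#' @param min_overlap minimum exonic overlap in nt (default 1).
#' @param reciprocal_frac if non-NULL, additionally require that the overlap
#'   covers at least this fraction of both transcripts' exonic lengths.
#' @return the retained subset of `set_a`, each transcript flagged
#'   `supported_by_both = TRUE`.
#' @export
intersect_assemblies <- function(set_a, set_b, min_overlap = 1L,
                                 reciprocal_frac = NULL) {
  if (!length(set_a) || !length(set_b)) return(list())
  keep <- vapply(set_a, function(a) {
    for (b in set_b) {
      if (a$chrom != b$chrom) next
      if (!strands_compatible(a$strand, b$strand)) next
      ov <- exonic_overlap_length(a, b)
      if (ov >= min_overlap) {
        if (is.null(reciprocal_frac)) return(TRUE)
        if (ov >= reciprocal_frac * spliced_length(a) &&
            ov >= reciprocal_frac * spliced_length(b)) return(TRUE)
      }
    }
    FALSE
  }, logical(1))
  out <- set_a[keep]
  lapply(out, function(t) { t$supported_by_both <- TRUE; t })
}

#' Assign a locus class code against a reference annotation
#'
#' Precedence: same-strand exonic overlap with a reference transcript gives
#' `OTHER` (a putative isoform, excluded downstream); opposite-strand exonic
#' overlap gives `X`; a span entirely inside one intron of a reference
#' transcript (either strand) gives `I`; no overlap with any reference span
#' gives `U`; any remaining partial span overlap gives `OTHER`.
#'
#' @param tx a `transcript`.
#' @param reference list of reference `transcript` objects.
#' @return single character class code.
#' @export
assign_class_code <- function(tx, reference) {
  span <- transcript_span(tx)
  any_span_overlap <- FALSE
  intronic <- FALSE
  antisense_exonic <- FALSE
  for (ref in reference) {
    if (ref$chrom != tx$chrom) next
    rspan_start <- min(ref$exons[, "start"]); rspan_end <- max(ref$exons[, "end"])
    if (rspan_start < span$end && rspan_end > span$start) any_span_overlap <- TRUE
    ov <- exonic_overlap_length(tx, ref)
    if (ov > 0L) {
      # unknown strand on either side: the overlap cannot be called
      # antisense with confidence, so it falls to OTHER (isoform-like)
      if (tx$strand == "*" || ref$strand == "*" || tx$strand == ref$strand) {
        return("OTHER")
      }
      antisense_exonic <- TRUE
      next
    }
    # intron containment: span inside a gap between consecutive exons
    if (nrow(ref$exons) > 1L && rspan_start <= span$start && rspan_end >= span$end) {
      for (j in seq_len(nrow(ref$exons) - 1L)) {
        if (span$start >= ref$exons[j, "end"] &&
            span$end <= ref$exons[j + 1L, "start"]) {
          intronic <- TRUE
          break
        }
      }
    }
  }
  if (antisense_exonic) return("X")
  if (intronic) return("I")
  if (!any_span_overlap) return("U")
  "OTHER"
}

#' Apply the minimum-length cutoff
#'
#' Retains transcripts whose spliced length is at least `min_len`
#' (boundary inclusive; a 200-nt transcript passes the default cutoff).
#'
#' @param transcripts list of `transcript` objects.
#' @param min_len minimum spliced length in nt (default 200).
#' @return the retained subset, flagged `passed_length = TRUE`.
#' @export
length_filter <- function(transcripts, min_len = 200L) {
  keep <- vapply(transcripts, function(t) spliced_length(t) >= min_len,
                 logical(1))
  lapply(transcripts[keep], function(t) { t$passed_length <- TRUE; t })
}

#' Detect complementary-strand duplicate gene calls
#'
#' Single-exon transcripts on the same chromosome and opposite strands are
#' reported as a duplicate pair when their overlap covers at least
#' `min_frac` of their combined (union) span. This targets the failure mode
#' where an unstranded single-exon call is emitted once per strand.
#'
#' @param transcripts list of `transcript` objects.
#' @param min_frac minimum overlap/union-span fraction (default 0.5).
#' @return data.frame with columns `id1`, `id2`, `overlap`, `union_span`,
#'   `fraction`; zero rows when no pair qualifies.
#' @export
find_duplicate_complements <- function(transcripts, min_frac = 0.5) {
  single <- Filter(function(t) nrow(t$exons) == 1L && t$strand %in% c("+", "-"),
                   transcripts)
  out <- list()
  n <- length(single)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      a <- single[[i]]; b <- single[[j]]
      if (a$chrom != b$chrom || a$strand == b$strand) next
      s1 <- a$exons[1, "start"]; e1 <- a$exons[1, "end"]
      s2 <- b$exons[1, "start"]; e2 <- b$exons[1, "end"]
      ov <- max(0L, min(e1, e2) - max(s1, s2))
      un <- max(e1, e2) - min(s1, s2)
      if (un > 0L && ov / un >= min_frac) {
        out[[length(out) + 1L]] <- data.frame(
          id1 = min(a$id, b$id), id2 = max(a$id, b$id),
          overlap = ov, union_span = un, fraction = ov / un)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(id1 = character(0), id2 = character(0),
                      overlap = integer(0), union_span = integer(0),
                      fraction = numeric(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$id1, res$id2), , drop = FALSE]
}

#' One-directional gene-set overlap comparison
#'
#' A gene in `set_a` is matched when some gene in `set_b` covers at least
#' `min_frac` of its exonic length (fraction measured on the `set_a` gene).
#'
#' @param set_a,set_b lists of `transcript` objects.
#' @param min_frac minimum covered fraction of the `set_a` gene (default 0.5).
#' @return character vector of matched `set_a` ids.
#' @export
compare_gene_sets <- function(set_a, set_b, min_frac = 0.5) {
  matched <- vapply(set_a, function(a) {
    len_a <- spliced_length(a)
    for (b in set_b) {
      if (exonic_overlap_length(a, b) >= min_frac * len_a) return(TRUE)
    }
    FALSE
  }, logical(1))
  vapply(set_a[matched], `[[`, "", "id")
}

#' Fragments per kilobase of exonic length per million mapped fragments
#'
#' @param fragment_count non-negative fragment count for the gene.
#' @param exonic_length exonic length in nt (> 0).
#' @param total_mapped total mapped fragments in the library (> 0).
#' @return FPKM value `count * 1e9 / (exonic_length * total_mapped)`.
#' @export
compute_fpkm <- function(fragment_count, exonic_length, total_mapped) {
  if (any(exonic_length <= 0)) stop("exonic_length must be positive")
  if (any(total_mapped <= 0)) stop("total_mapped must be positive")
  if (any(fragment_count < 0)) stop("fragment_count must be non-negative")
  fragment_count * 1e9 / (exonic_length * total_mapped)
}

#' Per-class exon-count summary
#'
#' @param transcripts list of `transcript` objects carrying class labels in
#'   `class_code` (or a supplied `labels` vector).
#' @param labels optional character vector of class labels, parallel to
#'   `transcripts`; defaults to the class codes.
#' @return list with `means` (named numeric; NA for empty classes) and
#'   `histogram` (data.frame class/exons/count).
#' @export
exon_count_summary <- function(transcripts, labels = NULL) {
  if (is.null(labels)) labels <- vapply(transcripts, `[[`, "", "class_code")
  counts <- vapply(transcripts, function(t) nrow(t$exons), 0L)
  classes <- sort(unique(labels))
  means <- setNames(vapply(classes, function(cl) {
    v <- counts[labels == cl]
    if (!length(v)) NA_real_ else mean(v)
  }, 0), classes)
  hist <- as.data.frame(table(class = labels, exons = counts),
                        stringsAsFactors = FALSE)
  hist <- hist[hist$Freq > 0L, ]
  names(hist)[3] <- "count"
  hist$exons <- as.integer(hist$exons)
  list(means = means, histogram = hist[order(hist$class, hist$exons), ])
}
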