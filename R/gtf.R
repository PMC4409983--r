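#' Read transcript models from a GTF file
#'
#' Parses `exon` features (and, when present, `CDS` features, retained in the
#' `cds` field) into [transcript()] objects. GTF coordinates are 1-based
#' inclusive and are converted to the package-internal 0-based half-open
#' convention. Strand `"."` maps to unknown (`"*"`). A light line-level
#' parser is used so that malformed input can be reported with its line
#' number, which `rtracklayer`-style importers do not surface.
#'
#' @param path path to a GTF file.
#' @param feature feature types to keep (default `exon`).
#' @return named list of `transcript` objects (names are transcript ids),
#'   each with an extra `cds` matrix attribute when CDS lines are present.
#' @export
read_gtf <- function(path, feature = c("exon", "CDS")) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (!length(idx)) return(structure(list(), names = character(0)))
  rec <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 9L) {
      stop("malformed GTF line ", i, " in ", path, ": expected 9 tab-separated fields, got ",
           length(f))
    }
    start <- suppressWarnings(as.integer(f[4])); end <- suppressWarnings(as.integer(f[5]))
    if (is.na(start) || is.na(end) || start < 1L || end < start) {
      stop("malformed GTF line ", i, " in ", path, ": bad coordinates '", f[4], "-", f[5], "'")
    }
    attrs <- f[9]
    tid <- sub('.*transcript_id "([^"]+)".*', "\\1", attrs)
    gid <- sub('.*gene_id "([^"]+)".*', "\\1", attrs)
    if (identical(tid, attrs)) stop("malformed GTF line ", i, " in ", path,
                                    ": missing transcript_id attribute")
    if (identical(gid, attrs)) gid <- tid
    cc <- if (grepl('class_code "', attrs, fixed = TRUE)) {
      sub('.*class_code "([^"]+)".*', "\\1", attrs)
    } else NA_character_
    rec[[k]] <- list(chrom = f[1], source = f[2], type = f[3],
                     start = start - 1L, end = end,
                     strand = if (f[7] %in% c("+", "-")) f[7] else "*",
                     tid = tid, gid = gid, class_code = cc, line = i)
  }
  type <- vapply(rec, `[[`, "", "type")
  rec <- rec[type %in% feature]
  if (!length(rec)) return(structure(list(), names = character(0)))
  tids <- vapply(rec, `[[`, "", "tid")
  out <- list()
  for (tid in unique(tids)) {
    rr <- rec[tids == tid]
    ty <- vapply(rr, `[[`, "", "type")
    ex <- rr[ty == "exon"]
    if (!length(ex)) ex <- rr            # CDS-only entries still form a model
    chrom <- unique(vapply(ex, `[[`, "", "chrom"))
    strand <- unique(vapply(ex, `[[`, "", "strand"))
    if (length(chrom) != 1L || length(strand) != 1L) {
      stop("transcript ", tid, ": exons on multiple chromosomes or strands")
    }
    exons <- cbind(start = vapply(ex, `[[`, 0L, "start"),
                   end = vapply(ex, `[[`, 0L, "end"))
    cc <- vapply(ex, `[[`, "", "class_code")
    cc <- cc[!is.na(cc)]
    tx <- tryCatch(
      transcript(tid, chrom, strand, exons,
                 class_code = if (length(cc)) cc[1] else "OTHER",
                 source = ex[[1]]$source, gene_id = ex[[1]]$gid),
      error = function(e) stop("GTF ", path, " near line ", ex[[1]]$line, ": ",
                               conditionMessage(e), call. = FALSE))
    cds <- rr[ty == "CDS"]
    if (length(cds)) {
      cm <- cbind(start = vapply(cds, `[[`, 0L, "start"),
                  end = vapply(cds, `[[`, 0L, "end"))
      tx$cds <- cm[order(cm[, "start"]), , drop = FALSE]
    }
    out[[tid]] <- tx
  }
  out
}

#' Write transcript models to a GTF file
#'
#' Emits one `exon` feature per exon (plus `CDS` features when the transcript
#' carries a `cds` matrix), converting back to 1-based inclusive coordinates.
#' Output ordering is deterministic: (chrom, span start, transcript id).
#' Unknown strand is written as `"."`.
#'
#' @param transcripts list of `transcript` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(transcripts, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# GTF emitted by lncevo; 1-based inclusive coordinates", con)
  if (!length(transcripts)) return(invisible(path))
  ord <- order(vapply(transcripts, `[[`, "", "chrom"),
               vapply(transcripts, function(t) min(t$exons[, "start"]), 0L),
               vapply(transcripts, `[[`, "", "id"))
  for (tx in transcripts[ord]) {
    strand <- if (tx$strand == "*") "." else tx$strand
    attrs <- sprintf('gene_id "%s"; transcript_id "%s"; class_code "%s";',
                     tx$gene_id, tx$id, tx$class_code)
    for (j in seq_len(nrow(tx$exons))) {
      writeLines(paste(tx$chrom, tx$source, "exon",
                       tx$exons[j, "start"] + 1L, tx$exons[j, "end"],
                       ".", strand, ".", attrs, sep = "\t"), con)
    }
    if (!is.null(tx$cds)) {
      for (j in seq_len(nrow(tx$cds))) {
        writeLines(paste(tx$chrom, tx$source, "CDS",
                         tx$cds[j, "start"] + 1L, tx$cds[j, "end"],
                         ".", strand, "0", attrs, sep = "\t"), con)
      }
    }
  }
  invisible(path)
}

#' Read a genome FASTA
#'
#' @param path FASTA path.
#' @return a named character vector of uppercase chromosome sequences.
#' @export
read_genome <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' Write a genome FASTA
#'
#' @param genome named character vector of chromosome sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Read a rooted species tree with branch lengths
#'
#' @param path Newick file path.
#' @return an `ape::phylo` tree.
#' @export
read_species_tree <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr$edge.length)) stop("species tree must carry branch lengths")
  if (any(tr$edge.length < 0)) stop("negative branch lengths in species tree")
  if (anyDuplicated(tr$tip.label)) stop("duplicate leaf names in species tree")
  tr
}

#' Extract the spliced transcript sequence from a genome
#'
#' Exon substrings are concatenated and, for minus-strand transcripts,
#' reverse-complemented so the result reads 5' to 3' in transcript
#' orientation. Unknown strand is treated as plus.
#'
#' @param genome named character vector of chromosome sequences.
#' @param tx a `transcript`.
#' @return nucleotide string.
#' @export
spliced_sequence <- function(genome, tx) {
  chrom_seq <- genome[[tx$chrom]]
  if (is.null(chrom_seq)) stop("chromosome not in genome: ", tx$chrom)
  if (max(tx$exons[, "end"]) > nchar(chrom_seq)) {
    stop("transcript ", tx$id, " extends beyond end of ", tx$chrom)
  }
  parts <- substring(chrom_seq, tx$exons[, "start"] + 1L, tx$exons[, "end"])
  s <- paste(parts, collapse = "")
  if (tx$strand == "-") revcomp(s) else s
}
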