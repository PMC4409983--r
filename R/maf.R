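#' Multiple-alignment (MAF) store and region extraction
#'
#' A minimal indexed reader for the UCSC MAF dialect produced by MULTIZ-style
#' whole-genome aligners. Blocks are held in memory and queried by reference
#' coordinates; no R package on the stack parses MAF, so the parser lives
#' here. Species names are taken as the part of the `s`-line source before
#' the first `.` (the remainder is the source chromosome).
#'
#' @name maf
NULL

parse_maf_src <- function(src) {
  dot <- regexpr(".", src, fixed = TRUE)
  if (dot > 0) {
    list(species = substr(src, 1L, dot - 1L),
         chrom = substr(src, dot + 1L, nchar(src)))
  } else {
    list(species = src, chrom = src)
  }
}

#' Read a MAF file into an indexed alignment store
#'
#' @param path MAF path.
#' @param reference_species name of the reference species; every retained
#'   block must contain it exactly once, on the plus strand, with reference
#'   starts strictly increasing per chromosome. Blocks missing the reference
#'   are skipped with a warning and counted.
#' @return a `maf_store` with components `reference`, `blocks` and an
#'   interval index; query with [extract_region_alignment()].
#' @export
read_maf <- function(path, reference_species) {
  if (!file.exists(path)) stop("MAF file not found: ", path)
  lines <- readLines(path)
  blocks <- list()
  skipped <- 0L
  cur <- NULL
  flush_block <- function(cur) {
    if (is.null(cur) || !length(cur$src)) return(invisible(NULL))
    sp <- vapply(cur$src, function(s) parse_maf_src(s)$species, "")
    nref <- sum(sp == reference_species)
    if (nref != 1L) {
      skipped <<- skipped + 1L
      warning("MAF block at line ", cur$line, " has ", nref,
              " rows for reference species '", reference_species, "'; skipped")
      return(invisible(NULL))
    }
    w <- nchar(cur$text)
    if (length(unique(w)) != 1L) {
      stop("MAF block at line ", cur$line, ": inconsistent row lengths")
    }
    ri <- which(sp == reference_species)
    if (cur$strand[ri] != "+") {
      stop("MAF block at line ", cur$line, ": reference row must be on + strand")
    }
    blk <- list(species = sp,
                chrom = vapply(cur$src, function(s) parse_maf_src(s)$chrom, ""),
                start = cur$start, size = cur$size, strand = cur$strand,
                src_size = cur$src_size, text = toupper(cur$text),
                ref_row = ri)
    blocks[[length(blocks) + 1L]] <<- blk
    invisible(NULL)
  }
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (grepl("^a( |$)", ln)) {
      flush_block(cur)
      cur <- list(line = i, src = character(0), start = integer(0),
                  size = integer(0), strand = character(0),
                  src_size = integer(0), text = character(0))
    } else if (grepl("^s ", ln)) {
      if (is.null(cur)) stop("MAF line ", i, ": 's' line outside a block")
      f <- strsplit(trimws(ln), "\\s+")[[1]]
      if (length(f) != 7L) stop("MAF line ", i, ": expected 7 fields on s line")
      cur$src <- c(cur$src, f[2])
      cur$start <- c(cur$start, as.integer(f[3]))
      cur$size <- c(cur$size, as.integer(f[4]))
      cur$strand <- c(cur$strand, f[5])
      cur$src_size <- c(cur$src_size, as.integer(f[6]))
      cur$text <- c(cur$text, f[7])
    }
    # other line types (##maf, i/e/q lines, blanks) are ignored
  }
  flush_block(cur)
  if (length(blocks)) {
    chrom <- vapply(blocks, function(b) b$chrom[b$ref_row], "")
    rstart <- vapply(blocks, function(b) b$start[b$ref_row], 0L)
    rend <- rstart + vapply(blocks, function(b) b$size[b$ref_row], 0L)
    for (ch in unique(chrom)) {
      s <- rstart[chrom == ch]
      if (is.unsorted(s, strictly = TRUE)) {
        stop("reference starts not strictly increasing on ", ch)
      }
    }
    index <- data.frame(chrom = chrom, start = rstart, end = rend,
                        block = seq_along(blocks))
  } else {
    index <- data.frame(chrom = character(0), start = integer(0),
                        end = integer(0), block = integer(0))
  }
  structure(list(reference = reference_species, blocks = blocks,
                 index = index, skipped = skipped),
            class = "maf_store")
}

#' @export
print.maf_store <- function(x, ...) {
  cat(sprintf("<maf_store> reference=%s, %d block(s), %d skipped\n",
              x$reference, length(x$blocks), x$skipped))
  invisible(x)
}

#' Query MAF blocks overlapping a reference interval
#'
#' @param store a `maf_store`.
#' @param interval a `genomic_interval` on the reference assembly.
#' @return list of blocks (possibly empty), in reference order.
#' @export
maf_query <- function(store, interval) {
  idx <- store$index
  hit <- idx$chrom == interval$chrom & idx$start < interval$end &
    idx$end > interval$start
  store$blocks[idx$block[hit]]
}

#' Extract a reference-anchored region alignment
#'
#' Returns one gap-padded row per requested species over the reference
#' interval. Columns are restricted to reference positions: insertion
#' columns (gap in the reference row) are dropped and counted. Species
#' absent from every overlapping block get an all-gap row. Reference
#' positions covered by no block are filled from `genome` when supplied,
#' otherwise with `N`; non-reference rows carry gaps there. Minus-strand
#' rows need no re-orientation: MAF block text is printed column-aligned to
#' the reference, which is the reference orientation by construction.
#'
#' @param store a `maf_store`.
#' @param interval a `genomic_interval` on the reference assembly.
#' @param species_list species to report (reference always included first).
#' @param genome optional genome (named character vector) to fill uncovered
#'   reference positions.
#' @return a `region_alignment`: list with `reference`, `interval`, `rows`
#'   (named character vector, equal widths), and `dropped_columns`.
#' @export
extract_region_alignment <- function(store, interval, species_list = NULL,
                                     genome = NULL) {
  if (!is.null(genome)) {
    chrom_seq <- genome[[interval$chrom]]
    if (!is.null(chrom_seq) && interval$end > nchar(chrom_seq)) {
      stop("interval [", interval$start, ",", interval$end,
           ") off end of chromosome ", interval$chrom)
    }
  }
  if (is.null(species_list)) {
    species_list <- unique(unlist(lapply(store$blocks, `[[`, "species")))
  }
  species_list <- unique(c(store$reference, species_list))
  w <- interval_width(interval)
  mat <- matrix("-", nrow = length(species_list), ncol = w,
                dimnames = list(species_list, NULL))
  if (is.null(genome)) {
    mat[store$reference, ] <- "N"
  } else {
    mat[store$reference, ] <-
      str_chars(substr(genome[[interval$chrom]], interval$start + 1L,
                       interval$end))
  }
  dropped <- 0L
  for (blk in maf_query(store, interval)) {
    ref_chars <- str_chars(blk$text[blk$ref_row])
    is_base <- ref_chars != "-"
    refpos <- blk$start[blk$ref_row] + cumsum(is_base) - 1L  # valid where is_base
    inwin <- is_base & refpos >= interval$start & refpos < interval$end
    if (!any(inwin)) next
    wi <- which(inwin)
    dropped <- dropped + sum(!is_base[wi[1]:wi[length(wi)]])
    cols <- refpos[inwin] - interval$start + 1L
    for (r in seq_along(blk$species)) {
      sp <- blk$species[r]
      if (!sp %in% species_list) next
      mat[sp, cols] <- str_chars(blk$text[r])[inwin]
    }
  }
  rows <- apply(mat, 1L, paste, collapse = "")
  structure(list(reference = store$reference, interval = interval,
                 rows = rows, dropped_columns = dropped),
            class = "region_alignment")
}

#' Spliced (exon-concatenated) alignment of a transcript
#'
#' Per-exon region alignments are concatenated in transcript orientation;
#' for minus-strand transcripts every row is reverse-complemented and exon
#' order reversed, so row 1 (reference) equals [spliced_sequence()] up to
#' uncovered positions.
#'
#' @param store a `maf_store`.
#' @param tx a `transcript` on the reference assembly.
#' @param species_list species to report.
#' @param genome optional genome for uncovered reference positions.
#' @return a `region_alignment` whose interval is the transcript span.
#' @export
spliced_region_alignment <- function(store, tx, species_list = NULL,
                                     genome = NULL) {
  if (is.null(species_list)) {
    species_list <- unique(unlist(lapply(store$blocks, `[[`, "species")))
  }
  species_list <- unique(c(store$reference, species_list))
  parts <- lapply(seq_len(nrow(tx$exons)), function(j) {
    extract_region_alignment(store,
      genomic_interval(tx$chrom, tx$exons[j, "start"], tx$exons[j, "end"],
                       tx$strand),
      species_list, genome)
  })
  rows_list <- lapply(parts, function(p) p$rows[species_list])
  if (tx$strand == "-") {
    rows_list <- rev(lapply(rows_list, function(r) vapply(r, revcomp, "")))
  }
  rows <- vapply(species_list, function(sp) {
    paste(vapply(rows_list, `[[`, "", sp), collapse = "")
  }, "")
  structure(list(reference = store$reference, interval = transcript_span(tx),
                 rows = rows,
                 dropped_columns = sum(vapply(parts, `[[`, 0L, "dropped_columns"))),
            class = "region_alignment")
}

#' Write alignment blocks as MAF
#'
#' @param blocks list of blocks in the internal format (as in a
#'   `maf_store`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_maf <- function(blocks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##maf version=1 scoring=none", con)
  for (blk in blocks) {
    writeLines("a score=0.0", con)
    src <- paste0(blk$species, ".", blk$chrom)
    for (r in seq_along(blk$species)) {
      writeLines(sprintf("s %s %d %d %s %d %s", src[r], blk$start[r],
                         blk$size[r], blk$strand[r], blk$src_size[r],
                         blk$text[r]), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

# convenience: number of rows / columns of a region_alignment
alignment_ncol <- function(ra) nchar(ra$rows[[1]])
alignment_matrix <- function(ra) {
  do.call(rbind, lapply(ra$rows, str_chars))
}
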