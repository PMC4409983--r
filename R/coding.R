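#' Coding-potential scoring and transcript classification
#'
#' Protein-coding potential is measured as a phylogenetic likelihood ratio:
#' the alignment of a candidate region is scored under an MG94xHKY codon
#' model (purifying selection on amino acids) versus the neutral HKY model
#' fitted on four-fold degenerate sites, and reported in decibans,
#' `10*log10(L_coding / L_noncoding)`, so a score of +10 means the region is
#' ten times more likely under the coding model. This is a defined,
#' desk-scale surrogate for empirical codon-substitution-frequency scoring;
#' the +/-10 deciban classification thresholds carry over.
#'
#' @name coding_potential
NULL

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Scan a spliced sequence for open reading frames in six frames
#'
#' Frames 0-2 scan the sequence as given; frames 3-5 scan its reverse
#' complement (offsets are reported on the scanned orientation). For every
#' frame each maximal ATG-to-stop ORF is reported (first ATG after the
#' previous stop), along with ATG-anchored stretches running off the 3' end
#' (`has_stop = FALSE`) and the maximal stop-free stretch
#' (`has_start = FALSE`). Codons containing `N` translate as unknown: they
#' neither start nor terminate an ORF.
#'
#' @param sequence nucleotide string over `A,C,G,T,N`.
#' @return data.frame with columns `frame` (0-5), `start`, `end` (0-based
#'   half-open nt offsets on the scanned orientation), `n_codons`,
#'   `peptide_length` (amino acids, terminal stop excluded), `has_start`,
#'   `has_stop`.
#' @export
scan_orfs <- function(sequence) {
  empty <- data.frame(frame = integer(0), start = integer(0), end = integer(0),
                      n_codons = integer(0), peptide_length = integer(0),
                      has_start = logical(0), has_stop = logical(0))
  sequence <- toupper(sequence)
  if (nchar(sequence) < 3L) return(empty)
  out <- list()
  for (fr in 0:5) {
    s <- if (fr < 3L) sequence else revcomp(sequence)
    off <- fr %% 3L
    n_cod <- (nchar(s) - off) %/% 3L
    if (n_cod < 1L) next
    starts <- off + 3L * (seq_len(n_cod) - 1L)
    codons <- substring(s, starts + 1L, starts + 3L)
    is_stop <- codons %in% STOP_CODONS
    is_atg <- codons == "ATG"
    # segment boundaries between stops
    seg_start <- 1L
    add_orf <- function(ci, cj, has_stop) {
      # codons ci..cj inclusive (cj includes the stop when has_stop)
      st <- starts[ci]; en <- starts[cj] + 3L
      ncods <- cj - ci + 1L
      out[[length(out) + 1L]] <<- data.frame(
        frame = fr, start = st, end = en, n_codons = ncods,
        peptide_length = ncods - as.integer(has_stop),
        has_start = is_atg[ci], has_stop = has_stop)
    }
    for (ci in seq_len(n_cod)) {
      if (is_stop[ci]) {
        seg <- seg_start:ci
        atg <- seg[is_atg[seg]]
        if (length(atg)) add_orf(atg[1L], ci, TRUE)
        # maximal stop-free stretch candidate (excluding the stop codon)
        if (ci > seg_start) {
          out[[length(out) + 1L]] <- data.frame(
            frame = fr, start = starts[seg_start], end = starts[ci - 1L] + 3L,
            n_codons = ci - seg_start, peptide_length = ci - seg_start,
            has_start = is_atg[seg_start], has_stop = FALSE)
        }
        seg_start <- ci + 1L
      }
    }
    if (seg_start <= n_cod) {
      seg <- seg_start:n_cod
      atg <- seg[is_atg[seg]]
      if (length(atg) && atg[1L] > seg_start) add_orf(atg[1L], n_cod, FALSE)
      out[[length(out) + 1L]] <- data.frame(
        frame = fr, start = starts[seg_start], end = starts[n_cod] + 3L,
        n_codons = n_cod - seg_start + 1L,
        peptide_length = n_cod - seg_start + 1L,
        has_start = is_atg[seg_start], has_stop = FALSE)
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- unique(res)
  rownames(res) <- NULL
  res[order(res$frame, res$start, res$end), , drop = FALSE]
}

#' Maximal ATG-anchored peptide length of a transcript sequence
#'
#' @param sequence spliced nucleotide string.
#' @return list with `peptide_length` (aa; 0 when no ATG-anchored ORF) and
#'   `orf` (the best ORF row, or NULL).
#' @export
max_orf_peptide <- function(sequence) {
  orfs <- scan_orfs(sequence)
  cand <- orfs[orfs$has_start, , drop = FALSE]
  if (!nrow(cand)) return(list(peptide_length = 0L, orf = NULL))
  best <- cand[which.max(cand$peptide_length), , drop = FALSE]
  list(peptide_length = best$peptide_length[1L], orf = best)
}

#' Fraction of a transcript covered by an ORF
#'
#' @param orf one row of [scan_orfs()] output (or NULL).
#' @param spliced_length transcript spliced length in nt (> 0).
#' @return ORF nucleotide length (stop included) divided by spliced length;
#'   0 when `orf` is NULL.
#' @export
orf_fraction <- function(orf, spliced_length) {
  if (spliced_length <= 0) stop("spliced_length must be positive")
  if (is.null(orf) || !nrow(orf)) return(0)
  (orf$end[1L] - orf$start[1L]) / spliced_length
}

# ---- neutral model ---------------------------------------------------------

# two-base prefixes whose third position is four-fold degenerate
fourfold_prefixes <- function() {
  ct <- codon_table()
  pre <- unique(substr(ct$codons, 1, 2))
  pre[vapply(pre, function(p) {
    aa <- ct$aa[paste0(p, DNA_BASES)]
    !any(aa == "*") && length(unique(aa)) == 1L
  }, logical(1))]
}

#' Neutral substitution model bound to a species tree
#'
#' @param tree rooted `ape::phylo` with branch lengths.
#' @param pi base frequencies.
#' @param kappa transition/transversion ratio.
#' @param scale tree scale factor (all branch lengths multiplied by it).
#' @return a `neutral_model`.
#' @export
neutral_model <- function(tree, pi = c(0.25, 0.25, 0.25, 0.25), kappa = 2,
                          scale = 1) {
  if (scale <= 0) stop("scale must be positive")
  structure(list(model = hky_model(pi, kappa), tree = tree, pi = pi / sum(pi),
                 kappa = kappa, scale = scale),
            class = "neutral_model")
}

#' @export
print.neutral_model <- function(x, ...) {
  cat(sprintf("<neutral_model> HKY85 kappa=%.3f scale=%.3f on %d-leaf tree%s\n",
              x$kappa, x$scale, length(x$tree$tip.label),
              if (!is.null(x$n_columns)) sprintf(" (fit on %d 4-fold sites)",
                                                 x$n_columns) else ""))
  invisible(x)
}

#' Fit the neutral model on four-fold degenerate sites
#'
#' Third-codon-position alignment columns of four-fold degenerate codons
#' (identified on the reference CDS annotation) are pooled; base frequencies
#' are set empirically and `(kappa, scale)` maximize the HKY pruning
#' likelihood, with branch-length proportions of the input tree preserved.
#'
#' @param store a `maf_store`.
#' @param reference list of reference `transcript` objects carrying `cds`
#'   matrices (as produced by [read_gtf()] on an annotation with CDS lines).
#' @param tree rooted species tree (`ape::phylo`).
#' @param genome optional genome for uncovered reference positions.
#' @param min_columns minimum usable four-fold columns (default 100).
#' @return a fitted `neutral_model` with `n_columns` recorded.
#' @export
fit_neutral_model <- function(store, reference, tree, genome = NULL,
                              min_columns = 100L) {
  pre4 <- fourfold_prefixes()
  cols <- list()
  for (tx in reference) {
    if (is.null(tx$cds)) next
    cds_tx <- transcript(paste0(tx$id, ".cds"), tx$chrom, tx$strand, tx$cds,
                         class_code = "REFERENCE", source = tx$source)
    sra <- spliced_region_alignment(store, cds_tx,
                                    species_list = tree$tip.label, genome)
    mat <- alignment_matrix(sra)
    ref <- mat[sra$reference, ]
    n_cod <- length(ref) %/% 3L
    if (n_cod < 1L) next
    for (k in seq_len(n_cod)) {
      i <- 3L * (k - 1L) + 1L
      cod <- paste0(ref[i], ref[i + 1L], ref[i + 2L])
      if (substr(cod, 1, 2) %in% pre4 && !grepl("[^ACGT]", cod)) {
        cols[[length(cols) + 1L]] <- mat[, i + 2L]
      }
    }
  }
  if (length(cols) < min_columns) {
    stop("too few four-fold degenerate columns for neutral fit: ",
         length(cols), " < ", min_columns)
  }
  M <- do.call(cbind, cols)
  sp <- rownames(M)
  tip_states <- matrix(NA_integer_, length(tree$tip.label), ncol(M),
                       dimnames = list(tree$tip.label, NULL))
  for (s in intersect(sp, tree$tip.label)) {
    tip_states[s, ] <- encode_nuc(M[s, ])
  }
  tab <- table(factor(M[!is.na(match(rownames(M), tree$tip.label)), ],
                      levels = DNA_BASES))
  pi <- as.numeric(tab) + 1      # add-one smoothing keeps frequencies positive
  pi <- pi / sum(pi)
  nll <- function(par) {
    kappa <- exp(par[1]); scale <- exp(par[2])
    -prune_loglik(hky_model(pi, kappa), tree, tip_states,
                  rate_scale = scale)$total
  }
  fit <- optim(c(log(2), log(1)), nll, method = "Nelder-Mead",
               control = list(reltol = 1e-10, maxit = 500))
  nm <- neutral_model(tree, pi, exp(fit$par[1]), exp(fit$par[2]))
  nm$n_columns <- ncol(M)
  nm$loglik <- -fit$value
  nm
}

#' Coding model sharing parameters with a fitted neutral model
#'
#' The codon model's branch lengths are the neutral (per-site) branch
#' lengths times `bl_mult`, chosen so that third positions of four-fold
#' degenerate codons evolve at exactly the neutral rate. This anchors the
#' two models on the same synonymous clock: the likelihood ratio then
#' responds to codon structure, not to an arbitrary overall rate offset.
#' (Under `omega = 1` the multiplier is close to 3, the naive
#' sites-per-codon factor.)
#'
#' @param neutral a `neutral_model`.
#' @param omega nonsynonymous/synonymous rate ratio (default 0.2, the
#'   purifying-selection alternative against which regions are scored).
#' @return a `coding_model` (MG94xHKY bound to the same scaled tree) with
#'   `bl_mult` recorded.
#' @export
coding_model <- function(neutral, omega = 0.2) {
  m <- mg94_model(neutral$pi, neutral$kappa, omega)
  structure(list(model = m, tree = neutral$tree, scale = neutral$scale,
                 omega = omega, bl_mult = codon_bl_mult(m)),
            class = "coding_model")
}

# branch-length multiplier equating the codon model's four-fold
# third-position rate with the neutral per-site rate of 1
codon_bl_mult <- function(m) {
  ct <- codon_table()
  pre <- substr(m$states, 1, 2)
  in4 <- pre %in% fourfold_prefixes()
  pi4 <- m$pi[in4] / sum(m$pi[in4])
  idx4 <- which(in4)
  r3 <- 0
  for (k in seq_along(idx4)) {
    i <- idx4[k]
    js <- which(pre == pre[i])
    js <- js[js != i]
    r3 <- r3 + pi4[k] * sum(m$Q[i, js])
  }
  1 / r3
}

# ---- the score -------------------------------------------------------------

revcomp_alignment_rows <- function(rows) {
  vapply(rows, revcomp, "")
}

#' Phylogenetic coding-potential score of an aligned region
#'
#' Scores one reading frame of a reference-anchored alignment as
#' `10*log10(L_coding / L_noncoding)` decibans. Codon likelihoods use
#' Felsenstein pruning over the 61 sense codons with branch lengths
#' `bl_mult * scale * tree` (synonymous-rate-matched, see
#' [coding_model()]); the non-coding likelihood
#' is the neutral HKY likelihood of the same columns. Species codons
#' containing gaps, `N`, or a stop are treated as missing data; codons whose
#' reference codon is a stop contribute 0 decibans (they are excluded from
#' both likelihoods and flagged in the profile).
#'
#' @param ra a `region_alignment` (insertion columns already dropped).
#' @param frame 0-5; frames 3-5 score the reverse complement.
#' @param neutral a `neutral_model`.
#' @param coding a `coding_model`.
#' @return a `coding_score`: list with `total_decibans`, `per_codon`
#'   (decibans, 0 at reference-stop codons), `codon_starts` (offsets on the
#'   scanned orientation), `frame`, `n_codons`, `informative`.
#' @export
coding_score <- function(ra, frame, neutral, coding) {
  rows <- ra$rows
  if (frame >= 3L) rows <- revcomp_alignment_rows(rows)
  off <- frame %% 3L
  mat <- do.call(rbind, lapply(rows, str_chars))
  ref_name <- ra$reference
  keep <- mat[ref_name, ] != "-"
  mat <- mat[, keep, drop = FALSE]
  n_cod <- (ncol(mat) - off) %/% 3L
  if (n_cod < 1L) stop("region too short in frame ", frame, " (< 1 codon)")
  starts <- off + 3L * (seq_len(n_cod) - 1L)
  tree <- neutral$tree
  tips <- tree$tip.label
  unmatched <- setdiff(rownames(mat), tips)
  if (length(unmatched)) {
    warning("alignment rows not in tree dropped: ",
            paste(unmatched, collapse = ", "))
  }
  sp <- intersect(tips, rownames(mat))
  codon_states <- matrix(NA_integer_, length(tips), n_cod,
                         dimnames = list(tips, NULL))
  nuc_states <- matrix(NA_integer_, length(tips), 3L * n_cod,
                       dimnames = list(tips, NULL))
  ref_stop <- logical(n_cod)
  for (k in seq_len(n_cod)) {
    i <- starts[k] + 1L
    cods <- paste0(mat[sp, i], mat[sp, i + 1L], mat[sp, i + 2L])
    names(cods) <- sp
    ref_stop[k] <- cods[ref_name] %in% STOP_CODONS
    codon_states[sp, k] <- encode_codons(cods)
    for (p in 0:2) nuc_states[sp, 3L * (k - 1L) + p + 1L] <-
        encode_nuc(mat[sp, i + p])
  }
  informative <- FALSE
  others <- setdiff(sp, ref_name)
  if (length(others)) {
    informative <- any(!is.na(codon_states[others, , drop = FALSE]))
  }
  per_codon <- numeric(n_cod)
  if (!informative) {
    warning("no informative species in alignment; coding score set to 0")
  } else {
    use <- which(!ref_stop)
    if (length(use)) {
      llc <- prune_loglik(coding$model, tree,
                          codon_states[, use, drop = FALSE],
                          rate_scale = coding$bl_mult * coding$scale)$per_column
      nuc_cols <- as.vector(vapply(use, function(k) 3L * (k - 1L) + 1:3,
                                   integer(3)))
      lln_site <- prune_loglik(neutral$model, tree,
                               nuc_states[, nuc_cols, drop = FALSE],
                               rate_scale = neutral$scale)$per_column
      lln <- colSums(matrix(lln_site, nrow = 3L))
      per_codon[use] <- 10 * (llc - lln) / log(10)
    }
  }
  structure(list(total_decibans = sum(per_codon), per_codon = per_codon,
                 codon_starts = starts, frame = frame, n_codons = n_cod,
                 ref_stop = ref_stop, informative = informative),
            class = "coding_score")
}

#' @export
print.coding_score <- function(x, ...) {
  cat(sprintf("<coding_score> frame %d: %.2f decibans over %d codons\n",
              x$frame, x$total_decibans, x$n_codons))
  invisible(x)
}

slice_alignment <- function(ra, start, end, reverse = FALSE) {
  # reverse-frame offsets are measured on the reverse complement, so the
  # rows must be reverse-complemented before slicing
  rows <- ra$rows
  if (reverse) rows <- revcomp_alignment_rows(rows)
  rows <- vapply(rows, function(r) substr(r, start + 1L, end), "")
  structure(list(reference = ra$reference, interval = ra$interval,
                 rows = rows, dropped_columns = ra$dropped_columns),
            class = "region_alignment")
}

#' Per-codon score profiles over a transcript region (six frames)
#'
#' The scanned region is the transcript span plus `flank` bp each side,
#' clipped to the chromosome; all six frames are profiled, suitable for
#' browser-track export via [write_bedgraph_track()].
#'
#' @param tx a `transcript`.
#' @param store a `maf_store`.
#' @param neutral,coding fitted models.
#' @param flank flanking bases (default 50).
#' @param genome optional genome; also provides the chromosome length for
#'   clipping.
#' @return list of six `coding_score` objects (frames 0-5) plus the scanned
#'   interval as attribute `interval`.
#' @export
score_per_codon <- function(tx, store, neutral, coding, flank = 50L,
                            genome = NULL) {
  span <- transcript_span(tx)
  lo <- max(0L, span$start - flank)
  hi <- span$end + flank
  if (!is.null(genome) && !is.null(genome[[tx$chrom]])) {
    hi <- min(hi, nchar(genome[[tx$chrom]]))
  }
  region <- genomic_interval(tx$chrom, lo, hi, tx$strand)
  ra <- extract_region_alignment(store, region, neutral$tree$tip.label, genome)
  profiles <- lapply(0:5, function(fr) coding_score(ra, fr, neutral, coding))
  attr(profiles, "interval") <- region
  profiles
}

#' Best-frame coding score per exon
#'
#' @param tx a `transcript`.
#' @param store a `maf_store`.
#' @param neutral,coding fitted models.
#' @param genome optional genome.
#' @return data.frame with one row per exon: `exon`, `start`, `end`,
#'   `best_frame`, `score`, `flagged` (TRUE when the exon is shorter than
#'   one codon and scored 0).
#' @export
score_per_exon <- function(tx, store, neutral, coding, genome = NULL) {
  res <- lapply(seq_len(nrow(tx$exons)), function(j) {
    s <- tx$exons[j, "start"]; e <- tx$exons[j, "end"]
    if (e - s < 3L) {
      return(data.frame(exon = j, start = s, end = e, best_frame = NA_integer_,
                        score = 0, flagged = TRUE))
    }
    ra <- extract_region_alignment(store,
                                   genomic_interval(tx$chrom, s, e, tx$strand),
                                   neutral$tree$tip.label, genome)
    scores <- vapply(0:5, function(fr) {
      coding_score(ra, fr, neutral, coding)$total_decibans
    }, 0)
    data.frame(exon = j, start = s, end = e,
               best_frame = which.max(scores) - 1L, score = max(scores),
               flagged = FALSE)
  })
  do.call(rbind, res)
}

#' Best start-to-stop ORF score of a transcript
#'
#' ORFs are enumerated on the spliced sequence in six frames; each
#' ATG-to-stop ORF is scored on its spliced sub-alignment and the best is
#' returned. When no complete ORF exists, the maximal stop-free stretch is
#' scored instead and flagged `no_start_codon`.
#'
#' @param tx a `transcript`.
#' @param store a `maf_store`.
#' @param neutral,coding fitted models.
#' @param genome optional genome.
#' @return list with `orf` (the chosen ORF row), `score` (a `coding_score`),
#'   `peptide_length`, and `no_start_codon` flag.
#' @export
score_per_gene <- function(tx, store, neutral, coding, genome = NULL) {
  sra <- spliced_region_alignment(store, tx, neutral$tree$tip.label, genome)
  seq <- gsub("-", "", sra$rows[[sra$reference]])
  orfs <- scan_orfs(seq)
  cand <- orfs[orfs$has_start & orfs$has_stop, , drop = FALSE]
  no_start <- FALSE
  if (!nrow(cand)) {
    no_start <- TRUE
    cand <- orfs[orfs$n_codons >= 2L, , drop = FALSE]
    if (!nrow(cand)) cand <- orfs
  }
  if (!nrow(cand)) {
    return(list(orf = NULL, score = NULL, peptide_length = 0L,
                no_start_codon = TRUE))
  }
  best <- NULL; best_score <- NULL
  for (r in seq_len(nrow(cand))) {
    o <- cand[r, ]
    sc <- tryCatch(
      coding_score(slice_alignment(sra, o$start, o$end, reverse = o$frame >= 3L),
                   0L, neutral, coding),
      error = function(e) NULL)
    if (is.null(sc)) next
    if (is.null(best_score) || sc$total_decibans > best_score$total_decibans) {
      best <- o; best_score <- sc
    }
  }
  list(orf = best, score = best_score,
       peptide_length = if (is.null(best)) 0L else best$peptide_length,
       no_start_codon = no_start)
}

#' Classification evidence for one transcript
#'
#' Builds the evidence tuple the cascade consumes. All three ORF-derived
#' values describe the same candidate: the maximal ATG-anchored ORF
#' (greatest peptide length over the six frames). Its spliced
#' sub-alignment is scored under the coding/neutral likelihood ratio.
#' Scoring the maximal ORF — rather than the best-scoring one — avoids the
#' upward bias of maximizing a noisy score over the many short spurious
#' ORFs of a non-coding transcript; [score_per_gene()] still provides the
#' best-scoring-ORF view.
#'
#' @param tx a `transcript`.
#' @param store a `maf_store`.
#' @param neutral,coding fitted models.
#' @param genome optional genome.
#' @return list with `peptide_length`, `orf_fraction`, `score_decibans`,
#'   and `orf` (NULL when no ATG-anchored ORF exists; the maximal
#'   stop-free stretch is then scored instead).
#' @export
transcript_evidence <- function(tx, store, neutral, coding, genome = NULL) {
  sra <- spliced_region_alignment(store, tx, neutral$tree$tip.label, genome)
  seq <- gsub("-", "", sra$rows[[sra$reference]])
  mo <- max_orf_peptide(seq)
  o <- mo$orf
  if (is.null(o)) {
    orfs <- scan_orfs(seq)
    o <- if (nrow(orfs)) orfs[which.max(orfs$n_codons), , drop = FALSE] else
      NULL
  }
  score <- 0
  if (!is.null(o) && o$end - o$start >= 3L) {
    sc <- tryCatch(
      coding_score(slice_alignment(sra, o$start, o$end,
                                   reverse = o$frame >= 3L),
                   0L, neutral, coding),
      error = function(e) NULL)
    if (!is.null(sc)) score <- sc$total_decibans
  }
  list(peptide_length = mo$peptide_length,
       orf_fraction = orf_fraction(mo$orf, spliced_length(tx)),
       score_decibans = score, orf = mo$orf)
}

# note: slicing a minus-frame ORF reverse-complements the spliced alignment,
# which mirrors scoring the transcript's opposite strand; strand symmetry is
# exercised in the test suite.

#' Default classification thresholds
#'
#' @return named list of the printed cascade thresholds: coding requires
#'   peptide > 100 aa and score > +10 db; lncRNA requires peptide < 50 aa,
#'   ORF fraction < 0.35, score < -10 db, and no protein domain.
#' @export
default_thresholds <- function() {
  list(coding_min_peptide = 100, coding_min_score = 10,
       lnc_max_peptide = 50, lnc_max_orf_fraction = 0.35,
       lnc_max_score = -10)
}

#' Classify a transcript as coding, lncRNA, or ambiguous
#'
#' All inequalities are strict, so boundary cases (exactly 100 or 50 aa,
#' exactly +/-10 db) fall to `AMBIGUOUS`.
#'
#' @param evidence list with `peptide_length` (aa), `orf_fraction`,
#'   `score_decibans`, `has_domain`.
#' @param thresholds as [default_thresholds()].
#' @return a `classification` list with `label` (`CODING`, `LNCRNA`,
#'   `AMBIGUOUS`) and the evidence.
#' @export
classify_transcript <- function(evidence, thresholds = default_thresholds()) {
  if (is.null(evidence$has_domain)) {
    warning("no domain evidence supplied; assuming has_domain = FALSE")
    evidence$has_domain <- FALSE
  }
  label <- "AMBIGUOUS"
  if (evidence$peptide_length > thresholds$coding_min_peptide &&
      evidence$score_decibans > thresholds$coding_min_score) {
    label <- "CODING"
  } else if (evidence$peptide_length < thresholds$lnc_max_peptide &&
             evidence$orf_fraction < thresholds$lnc_max_orf_fraction &&
             evidence$score_decibans < thresholds$lnc_max_score &&
             !isTRUE(evidence$has_domain)) {
    label <- "LNCRNA"
  }
  structure(list(label = label, evidence = evidence), class = "classification")
}

#' Look up protein-domain evidence for a transcript
#'
#' @param transcript_id id to query.
#' @param domain_table data.frame with columns `transcript_id`, `domain_id`,
#'   `e_value` (externally produced HMM hits), or NULL.
#' @param max_evalue e-value cutoff at or below which a hit counts
#'   (default 1e-5).
#' @return TRUE iff at least one qualifying hit exists; FALSE for absent ids
#'   or a NULL/empty table.
#' @export
domain_lookup <- function(transcript_id, domain_table, max_evalue = 1e-5) {
  if (is.null(domain_table) || !nrow(domain_table)) return(FALSE)
  hits <- domain_table[domain_table$transcript_id == transcript_id, ,
                       drop = FALSE]
  any(hits$e_value <= max_evalue)
}

#' Write a per-codon score profile as bedGraph
#'
#' @param profile output of [score_per_codon()].
#' @param frame which frame's profile to export (0-5).
#' @param chrom chromosome name.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph_track <- function(profile, frame, chrom, path) {
  iv <- attr(profile, "interval")
  p <- profile[[frame + 1L]]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("track type=bedGraph name=coding_potential_frame%d", frame),
             con)
  if (frame < 3L) {
    starts <- iv$start + p$codon_starts
  } else {
    width <- interval_width(iv)
    starts <- iv$start + width - (p$codon_starts + 3L)
  }
  for (k in seq_along(starts)) {
    writeLines(sprintf("%s\t%d\t%d\t%.4f", chrom, starts[k], starts[k] + 3L,
                       p$per_codon[k]), con)
  }
  invisible(path)
}
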