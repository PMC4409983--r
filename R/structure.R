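#' Conserved RNA secondary-structure screen
#'
#' A defined surrogate for SVM-based structure screens: windows of a gene's
#' alignment are scored by combining (i) the mean minimum-free-energy
#' z-score of the rows against mononucleotide shuffles and (ii) a structure
#' conservation index (consensus folding energy over mean individual
#' energy), through a logistic map onto [0, 1]. Windows scoring above 0.5
#' are called high-confidence and merged into structure loci. Folding is a
#' maximum-score nested-pairing dynamic program with pair scores GC=3,
#' AU=2, GU=1 and a minimum loop of 3 unpaired positions; energy is the
#' negated pair-score sum (dimensionless).
#'
#' @name structure_conservation
NULL

encode_rna <- function(sequence) {
  chars <- str_chars(toupper(chartr("U", "T", sequence)))
  code <- match(chars, DNA_BASES) - 1L
  code[is.na(code)] <- -1L
  code
}

#' Fold a sequence into its maximum-score nested structure
#'
#' @param sequence nucleotide string over `A,C,G,T,U,N`.
#' @param min_loop minimum unpaired positions between a pair (j - i > 3 by
#'   default).
#' @return a `secondary_structure`: list with `pairs` (two-column matrix of
#'   0-based positions i < j), `dotbracket`, `n_pairs`, `energy`
#'   (= -score). Sequences shorter than 5 nt fold to the empty structure.
#' @export
fold <- function(sequence, min_loop = 3L) {
  n <- nchar(sequence)
  if (n < 5L) {
    return(structure(list(pairs = matrix(integer(0), 0, 2),
                          dotbracket = strrep(".", n), n_pairs = 0L,
                          energy = 0),
                     class = "secondary_structure"))
  }
  res <- .fold_full_cpp(encode_rna(sequence), as.integer(min_loop))
  make_structure(res, n)
}

make_structure <- function(res, n) {
  pairs <- res$pairs
  db <- rep(".", n)
  if (nrow(pairs)) {
    db[pairs[, 1] + 1L] <- "("
    db[pairs[, 2] + 1L] <- ")"
  }
  structure(list(pairs = pairs, dotbracket = paste(db, collapse = ""),
                 n_pairs = nrow(pairs), energy = -res$score),
            class = "secondary_structure")
}

#' @export
print.secondary_structure <- function(x, ...) {
  cat(sprintf("<secondary_structure> %d pair(s), energy %.1f\n%s\n",
              x$n_pairs, x$energy, x$dotbracket))
  invisible(x)
}

#' Fold energy only (fast path)
#'
#' @param sequence nucleotide string.
#' @param min_loop minimum loop size.
#' @return scalar energy (<= 0).
#' @export
fold_energy <- function(sequence, min_loop = 3L) {
  if (nchar(sequence) < 5L) return(0)
  -.fold_score_cpp(encode_rna(sequence), as.integer(min_loop))
}

#' Consensus fold of an alignment
#'
#' Column-pair scores are the mean nucleotide pair score over rows (a gapped
#' row contributes 0) plus a covariation bonus of `covar_bonus` for every
#' pair of rows showing a compensatory double substitution that preserves
#' pairability; rows whose two characters are bases but cannot pair
#' contribute `-mismatch_penalty` instead of 0, so unrelated-but-foldable
#' rows do not accumulate spurious consensus structure (without the
#' penalty the structure conservation index saturates near 1 for any
#' foldable alignment). All-gap columns are dropped first. With a single
#' row this falls back to [fold()] with a warning.
#'
#' @param ra a `region_alignment` (or named character vector of gapped
#'   rows).
#' @param min_loop minimum loop size.
#' @param covar_bonus covariation bonus per compensatory row pair
#'   (default 1).
#' @param mismatch_penalty penalty per row that cannot pair at a column
#'   pair (default 3, the strongest pair score).
#' @return list with `structure` (a `secondary_structure` on the kept
#'   columns, `column_map` giving original column indices) and
#'   `consensus_energy`.
#' @export
consensus_fold <- function(ra, min_loop = 3L, covar_bonus = 1,
                           mismatch_penalty = 3) {
  rows <- if (inherits(ra, "region_alignment")) ra$rows else ra
  codes <- do.call(rbind, lapply(rows, encode_rna))
  keep <- colSums(codes >= 0L) > 0L
  codes <- codes[, keep, drop = FALSE]
  n <- ncol(codes)
  if (nrow(codes) < 2L) {
    warning("consensus_fold needs >= 2 rows; falling back to single-row fold")
    s <- fold(paste(DNA_BASES[codes[1, ] + 1L], collapse = ""), min_loop)
    return(list(structure = s, consensus_energy = s$energy,
                column_map = which(keep)))
  }
  if (n < 5L) {
    s <- structure(list(pairs = matrix(integer(0), 0, 2),
                        dotbracket = strrep(".", n), n_pairs = 0L, energy = 0),
                   class = "secondary_structure")
    return(list(structure = s, consensus_energy = 0, column_map = which(keep)))
  }
  S <- .consensus_matrix_cpp(codes, covar_bonus, mismatch_penalty)
  res <- .nussinov_matrix_cpp(S, as.integer(min_loop))
  s <- make_structure(res, n)
  list(structure = s, consensus_energy = -res$score, column_map = which(keep))
}

#' Minimum-free-energy z-score against mononucleotide shuffles
#'
#' @param sequence nucleotide string.
#' @param n_shuffles number of shuffles (>= 30; default 100).
#' @param seed RNG seed for the shuffles (restored afterwards).
#' @param min_loop minimum loop size.
#' @return `z = (E_obs - mean(E_shuffled)) / sd(E_shuffled)`; 0 when the
#'   shuffle energies are constant.
#' @export
mfe_zscore <- function(sequence, n_shuffles = 100L, seed = NULL,
                       min_loop = 3L) {
  if (n_shuffles < 30L) stop("n_shuffles must be >= 30")
  codes <- encode_rna(sequence)
  codes <- codes[codes >= 0L]
  if (length(codes) < 5L) return(0)
  e_obs <- -.fold_score_cpp(codes, as.integer(min_loop))
  e_sh <- with_seed(seed, {
    vapply(seq_len(n_shuffles), function(k) {
      -.fold_score_cpp(sample(codes), as.integer(min_loop))
    }, 0)
  })
  s <- sd(e_sh)
  if (s == 0) return(0)
  (e_obs - mean(e_sh)) / s
}

#' Structure conservation index of an alignment
#'
#' @param ra a `region_alignment` with >= 2 rows.
#' @param min_loop minimum loop size.
#' @return `consensus_energy / mean(individual fold energies)`; 0 when the
#'   mean individual energy is 0 (nothing folds).
#' @export
sci <- function(ra, min_loop = 3L) {
  rows <- if (inherits(ra, "region_alignment")) ra$rows else ra
  indiv <- vapply(rows, function(r) fold_energy(gsub("-", "", r), min_loop), 0)
  m <- mean(indiv)
  if (m == 0) return(0)
  cf <- consensus_fold(ra, min_loop)
  cf$consensus_energy / m
}

#' Default structure-score weights
#' @return list(w0, w1, w2) of the logistic combination
#'   `combined = logistic(w0 + w1 * (-mean_z) + w2 * sci)`.
#' @export
default_structure_weights <- function() list(w0 = -4, w1 = 1.5, w2 = 3)

#' Combined structure-conservation score of an alignment window
#'
#' `combined = logistic(w0 + w1 * (-mean_z) + w2 * sci)` with positive
#' `w1`, `w2`, so the score is monotone in folding stability and in
#' cross-species structure agreement. Windows scoring above 0.5 are
#' high-confidence.
#'
#' @param ra a `region_alignment` window (recommended width 40-200 nt).
#' @param weights list(w0, w1, w2); see [default_structure_weights()] and
#'   [calibrate_score_weights()].
#' @param n_shuffles shuffles per row for the z-score.
#' @param seed RNG seed.
#' @param min_loop minimum loop size.
#' @return a `structure_score`: list with `mean_z`, `sci`, `combined`,
#'   `high_confidence`. Degenerate (all-gap) windows score 0.
#' @export
structure_score <- function(ra, weights = default_structure_weights(),
                            n_shuffles = 100L, seed = NULL, min_loop = 3L) {
  rows <- if (inherits(ra, "region_alignment")) ra$rows else ra
  ungapped <- vapply(rows, function(r) gsub("-", "", r), "")
  usable <- nchar(ungapped) >= 5L
  if (!any(usable)) {
    return(structure(list(mean_z = 0, sci = 0, combined = 0,
                          high_confidence = FALSE),
                     class = "structure_score"))
  }
  zs <- vapply(seq_along(rows)[usable], function(i) {
    mfe_zscore(ungapped[i], n_shuffles,
               seed = if (is.null(seed)) NULL else derive_seed(seed, i),
               min_loop = min_loop)
  }, 0)
  mean_z <- mean(zs)
  s <- if (sum(usable) >= 2L) sci(rows[usable], min_loop) else 0
  combined <- plogis(weights$w0 + weights$w1 * (-mean_z) + weights$w2 * s)
  structure(list(mean_z = mean_z, sci = s, combined = combined,
                 high_confidence = combined > 0.5),
            class = "structure_score")
}

#' @export
print.structure_score <- function(x, ...) {
  cat(sprintf("<structure_score> mean_z=%.2f sci=%.2f combined=%.3f%s\n",
              x$mean_z, x$sci, x$combined,
              if (x$high_confidence) " [high confidence]" else ""))
  invisible(x)
}

#' Calibrate structure-score weights on labeled windows
#'
#' Fits a logistic regression of the window labels on `(-mean_z, sci)`;
#' typically run on synthetic conserved-hairpin windows versus shuffled
#' controls.
#'
#' @param alignments list of `region_alignment` windows.
#' @param labels logical vector (TRUE = structured).
#' @param n_shuffles,seed,min_loop passed through to feature computation.
#' @return list(w0, w1, w2) usable as `weights` in [structure_score()].
#' @export
calibrate_score_weights <- function(alignments, labels, n_shuffles = 100L,
                                    seed = NULL, min_loop = 3L) {
  feats <- do.call(rbind, lapply(seq_along(alignments), function(i) {
    ss <- structure_score(alignments[[i]], n_shuffles = n_shuffles,
                          seed = if (is.null(seed)) NULL else derive_seed(seed, i),
                          min_loop = min_loop)
    c(negz = -ss$mean_z, sci = ss$sci)
  }))
  df <- data.frame(y = as.integer(labels), negz = feats[, "negz"],
                   sci = feats[, "sci"])
  fit <- suppressWarnings(glm(y ~ negz + sci, family = binomial(), data = df))
  co <- coef(fit)
  co[is.na(co)] <- 0
  list(w0 = unname(co[1]), w1 = unname(co[2]), w2 = unname(co[3]))
}

#' Scan a gene for high-confidence structure loci
#'
#' Sliding windows over the gene span are scored; overlapping
#' high-confidence windows are merged into maximal loci (union of
#' intervals, locus score = best window score).
#'
#' @param gene a `transcript`.
#' @param store a `maf_store`.
#' @param species_list species rows to use.
#' @param window,step window size and stride in nt (defaults 120/40).
#' @param threshold high-confidence cutoff on the combined score.
#' @param weights,n_shuffles,seed,min_loop scoring parameters.
#' @param genome optional genome.
#' @return list of `structure_locus` objects: `interval`, `score` (best
#'   window `structure_score`), `n_windows`, `clipped` flag.
#' @export
scan_windows <- function(gene, store, species_list, window = 120L,
                         step = 40L, threshold = 0.5,
                         weights = default_structure_weights(),
                         n_shuffles = 100L, seed = NULL, min_loop = 3L,
                         genome = NULL) {
  span <- transcript_span(gene)
  w <- interval_width(span)
  clipped <- w < window
  starts <- if (clipped) span$start else
    seq(span$start, span$end - window, by = step)
  hits <- list()
  for (k in seq_along(starts)) {
    s <- starts[k]; e <- min(span$end, s + window)
    ra <- extract_region_alignment(store, genomic_interval(gene$chrom, s, e,
                                                           gene$strand),
                                   species_list, genome)
    ss <- structure_score(ra, weights, n_shuffles,
                          seed = if (is.null(seed)) NULL else derive_seed(seed, k),
                          min_loop = min_loop)
    if (ss$combined > threshold) {
      hits[[length(hits) + 1L]] <- list(start = s, end = e, score = ss)
    }
  }
  if (!length(hits)) return(list())
  # merge overlapping confident windows into maximal loci
  hs <- vapply(hits, `[[`, 0L, "start")
  he <- vapply(hits, `[[`, 0L, "end")
  ord <- order(hs)
  loci <- list()
  cur_s <- hs[ord[1]]; cur_e <- he[ord[1]]
  cur_best <- hits[[ord[1]]]$score; cur_n <- 1L
  flush <- function() {
    loci[[length(loci) + 1L]] <<- structure(
      list(interval = genomic_interval(gene$chrom, cur_s, cur_e, gene$strand),
           score = cur_best, n_windows = cur_n, clipped = clipped,
           gene_id = gene$id),
      class = "structure_locus")
  }
  for (k in ord[-1]) {
    if (hs[k] <= cur_e) {
      cur_e <- max(cur_e, he[k]); cur_n <- cur_n + 1L
      if (hits[[k]]$score$combined > cur_best$combined) cur_best <- hits[[k]]$score
    } else {
      flush()
      cur_s <- hs[k]; cur_e <- he[k]; cur_best <- hits[[k]]$score; cur_n <- 1L
    }
  }
  flush()
  loci
}

#' Per-species retention of a structure locus
#'
#' A species retains a locus when it is alignable over the locus interval
#' (non-gap coverage at least `min_cov`) and the two-row
#' (reference + species) sub-alignment still scores above `threshold`.
#'
#' @param locus a `structure_locus`.
#' @param store a `maf_store`.
#' @param species species name.
#' @param threshold combined-score cutoff (default 0.5).
#' @param weights,n_shuffles,seed,min_loop scoring parameters.
#' @param min_cov alignability threshold.
#' @param genome optional genome.
#' @return TRUE iff the species retains the structure.
#' @export
species_structure_presence <- function(locus, store, species, threshold = 0.5,
                                       weights = default_structure_weights(),
                                       n_shuffles = 100L, seed = NULL,
                                       min_loop = 3L, min_cov = 0.10,
                                       genome = NULL) {
  iv <- locus$interval
  ra <- extract_region_alignment(store, iv, species, genome)
  sp_row <- ra$rows[[species]]
  if (is.null(sp_row)) return(FALSE)
  cov <- mean(str_chars(sp_row) != "-")
  if (cov < min_cov) return(FALSE)
  two <- ra$rows[c(ra$reference, species)]
  ss <- structure_score(two, weights, n_shuffles, seed = seed,
                        min_loop = min_loop)
  ss$combined > threshold
}

#' Divergence-rate regression and ANCOVA slope comparison
#'
#' Ordinary least squares of retained count against root age per group
#' (conserved genomic regions vs conserved structures), and an ANCOVA
#' F-test of the age-by-group interaction (`count ~ age * group`, 1 and
#' n - 4 degrees of freedom) for equality of slopes.
#'
#' @param points_regions,points_structures data.frames with columns
#'   `species`, `root_age`, `count` (>= 3 rows each).
#' @return list with per-group `slope`, `intercept`, the `ancova_p` for the
#'   interaction, and the fitted models.
#' @export
divergence_regression <- function(points_regions, points_structures) {
  for (df in list(points_regions, points_structures)) {
    if (nrow(df) < 3L) stop("need >= 3 points per group")
    if (length(unique(df$root_age)) < 2L) {
      stop("degenerate design: root ages are constant within a group")
    }
  }
  fr <- lm(count ~ root_age, data = points_regions)
  fs <- lm(count ~ root_age, data = points_structures)
  all_df <- rbind(transform(points_regions, group = "regions"),
                  transform(points_structures, group = "structures"))
  all_df$group <- factor(all_df$group, levels = c("regions", "structures"))
  full <- lm(count ~ root_age * group, data = all_df)
  reduced <- lm(count ~ root_age + group, data = all_df)
  an <- anova(reduced, full)
  p <- an[2, "Pr(>F)"]
  # an (essentially) exact equal-slope fit carries no evidence against H0;
  # guard against 0/0 F ratios from numerically zero residuals
  rss_scale <- max(1, sum(all_df$count^2))
  if (is.na(p) || an[1, "RSS"] < 1e-9 * rss_scale) p <- 1
  list(regions = list(slope = unname(coef(fr)[2]),
                      intercept = unname(coef(fr)[1])),
       structures = list(slope = unname(coef(fs)[2]),
                         intercept = unname(coef(fs)[1])),
       ancova_p = p, n = nrow(all_df), model = full)
}

#' Write structure loci as BED
#'
#' Score column is the combined score scaled by 1000 and capped at 1000.
#'
#' @param loci list of `structure_locus` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure_bed <- function(loci, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (lc in loci) {
    iv <- lc$interval
    writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t%s", iv$chrom, iv$start, iv$end,
                       lc$gene_id, min(1000L, round(1000 * lc$score$combined)),
                       if (iv$strand == "*") "." else iv$strand), con)
  }
  invisible(path)
}
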