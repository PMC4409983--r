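#' Sequence conservation: alignability and rate-scaling tests
#'
#' Conservation of a gene is tested by asking whether its alignment evolves
#' slower than the neutral expectation: under H0 all branch lengths carry
#' the neutral scale (rate multiplier r = 1), under H1 a single multiplier
#' r in (0, 1] shrinks them. The likelihood-ratio statistic is compared to
#' the boundary mixture 0.5*chi-square(1) + 0.5*point-mass(0), the standard
#' null for a parameter tested at the edge of its space. This is a per-gene
#' surrogate for per-base conservation scoring: columns are pooled over the
#' gene and one p-value is reported per gene.
#'
#' @name conservation
NULL

#' Alignable presence of one species over a gene
#'
#' @param gene a `transcript` on the reference assembly.
#' @param store a `maf_store`.
#' @param species species name.
#' @param min_cov minimum fraction of exonic reference positions at which
#'   the species row is a non-gap nucleotide (default 0.10, boundary
#'   inclusive).
#' @param genome optional genome.
#' @return list with `present` (logical) and `coverage` in [0,1].
#' @export
alignable_presence <- function(gene, store, species, min_cov = 0.10,
                               genome = NULL) {
  sra <- spliced_region_alignment(store, gene, species_list = species, genome)
  row <- sra$rows[[species]]
  if (is.null(row)) return(list(present = FALSE, coverage = 0))
  chars <- str_chars(row)
  cov <- mean(chars != "-")
  list(present = cov >= min_cov, coverage = cov)
}

#' Presence/absence matrix across species, with per-class percentages
#'
#' @param genes list of `transcript` objects carrying class labels.
#' @param store a `maf_store`.
#' @param species_list species columns to report.
#' @param labels optional class labels parallel to `genes` (defaults to the
#'   transcripts' `class_code`).
#' @param min_cov alignable-coverage threshold passed to
#'   [alignable_presence()].
#' @param genome optional genome.
#' @return list with `present` (logical gene x species matrix), `coverage`
#'   (numeric matrix), and `class_percent` (data.frame class x species
#'   percentage of present genes; NA for empty classes).
#' @export
presence_matrix <- function(genes, store, species_list, labels = NULL,
                            min_cov = 0.10, genome = NULL) {
  if (is.null(labels)) labels <- vapply(genes, `[[`, "", "class_code")
  ids <- vapply(genes, `[[`, "", "id")
  pres <- matrix(FALSE, length(genes), length(species_list),
                 dimnames = list(ids, species_list))
  cov <- matrix(0, length(genes), length(species_list),
                dimnames = list(ids, species_list))
  for (i in seq_along(genes)) {
    sra <- spliced_region_alignment(store, genes[[i]], species_list, genome)
    for (sp in species_list) {
      c_sp <- mean(str_chars(sra$rows[[sp]]) != "-")
      cov[i, sp] <- c_sp
      pres[i, sp] <- c_sp >= min_cov
    }
  }
  classes <- sort(unique(labels))
  pct <- do.call(rbind, lapply(classes, function(cl) {
    rows <- pres[labels == cl, , drop = FALSE]
    if (!nrow(rows)) return(rep(NA_real_, length(species_list)))
    100 * colMeans(rows)
  }))
  pct <- data.frame(class = classes, pct, check.names = FALSE)
  colnames(pct) <- c("class", species_list)
  list(present = pres, coverage = cov, class_percent = pct)
}

#' Phylogenetic likelihood of a region alignment at a given rate scale
#'
#' Thin wrapper over [prune_loglik()]: encodes the alignment rows as
#' nucleotide states (gaps and ambiguity codes are missing data) and
#' multiplies every branch length by `rate_scale` on top of the neutral
#' model's own scale.
#'
#' @param ra a `region_alignment`.
#' @param neutral a `neutral_model` (carries tree, HKY parameters, scale).
#' @param rate_scale positive rate multiplier.
#' @return total log-likelihood.
#' @export
felsenstein_likelihood <- function(ra, neutral, rate_scale = 1) {
  if (rate_scale <= 0) stop("rate_scale must be positive")
  ts <- encode_alignment_nuc(ra, neutral$tree)
  prune_loglik(neutral$model, neutral$tree, ts,
               rate_scale = rate_scale * neutral$scale)$total
}

# encode region_alignment rows as tip-state matrix over tree tips
encode_alignment_nuc <- function(ra, tree) {
  tips <- tree$tip.label
  C <- alignment_ncol(ra)
  ts <- matrix(NA_integer_, length(tips), C, dimnames = list(tips, NULL))
  for (sp in intersect(tips, names(ra$rows))) {
    ts[sp, ] <- encode_nuc(str_chars(ra$rows[[sp]]))
  }
  ts
}

#' Per-gene conservation likelihood-ratio test
#'
#' Tests H0: r = 1 against H1: r free in (0, 1] over the gene's spliced
#' alignment. The MLE of r is found by bounded 1-D maximization (tolerance
#' 1e-6); the statistic `Lambda = 2 (lnL1 - lnL0)` is clipped at 0 and the
#' p-value is `0.5 * P(chi-square_1 >= Lambda)` for positive Lambda, 1
#' otherwise (one-sided boundary mixture).
#'
#' @param gene a `transcript`.
#' @param store a `maf_store`.
#' @param neutral a fitted `neutral_model`.
#' @param genome optional genome.
#' @return a `conservation_result`: list with `id`, `r_hat`, `lambda`,
#'   `p_value`, `neg_log10_p`, `n_columns`, `testable`.
#' @export
conservation_test <- function(gene, store, neutral, genome = NULL) {
  sra <- spliced_region_alignment(store, gene, neutral$tree$tip.label, genome)
  conservation_lrt(sra, neutral, id = gene$id)
}

#' Rate-scaling LRT on a region alignment
#'
#' The computational core of [conservation_test()], usable directly on any
#' `region_alignment` (or named row list).
#'
#' @param ra a `region_alignment` or named character vector of rows; the
#'   reference row is `ra$reference` or `"ref"`.
#' @param neutral a `neutral_model`.
#' @param id label for the result.
#' @return a `conservation_result`.
#' @export
conservation_lrt <- function(ra, neutral, id = "region") {
  if (!inherits(ra, "region_alignment")) {
    ra <- structure(list(reference = if ("ref" %in% names(ra)) "ref" else
                           names(ra)[1],
                         rows = ra, dropped_columns = 0L),
                    class = "region_alignment")
  }
  ts <- encode_alignment_nuc(ra, neutral$tree)
  others <- setdiff(rownames(ts), ra$reference)
  usable <- colSums(!is.na(ts[others, , drop = FALSE])) > 0L
  if (!any(usable)) {
    return(structure(list(id = id, r_hat = NA_real_, lambda = NA_real_,
                          p_value = NA_real_, neg_log10_p = NA_real_,
                          n_columns = 0L, testable = FALSE),
                     class = "conservation_result"))
  }
  ts <- ts[, usable, drop = FALSE]
  ll <- function(r) prune_loglik(neutral$model, neutral$tree, ts,
                                 rate_scale = r * neutral$scale)$total
  opt <- optimize(ll, interval = c(1e-6, 1), maximum = TRUE, tol = 1e-6)
  l0 <- ll(1)
  lambda <- max(0, 2 * (opt$objective - l0))
  p <- if (lambda > 0) 0.5 * pchisq(lambda, df = 1, lower.tail = FALSE) else 1
  structure(list(id = id, r_hat = opt$maximum, lambda = lambda,
                 p_value = p, neg_log10_p = -log10(p),
                 n_columns = ncol(ts), testable = TRUE),
            class = "conservation_result")
}

#' @export
print.conservation_result <- function(x, ...) {
  cat(sprintf("<conservation_result %s> r_hat=%.3f Lambda=%.3f p=%.3g (-log10 p=%.2f)\n",
              x$id, x$r_hat, x$lambda, x$p_value, x$neg_log10_p))
  invisible(x)
}

#' Compare conservation between gene classes
#'
#' For every pair of classes, a two-sided Mann-Whitney U test (normal
#' approximation with tie correction) compares the `-log10 p` conservation
#' scores; per-class means with t-based 95% confidence intervals are
#' reported alongside.
#'
#' @param results_by_class named list: class label -> numeric vector of
#'   `-log10 p` values.
#' @return list with `class_summary` (data.frame class, n, mean, ci_lo,
#'   ci_hi) and `pairwise` (data.frame class1, class2, U, p_value,
#'   testable).
#' @export
class_conservation_compare <- function(results_by_class) {
  classes <- names(results_by_class)
  summ <- do.call(rbind, lapply(classes, function(cl) {
    v <- results_by_class[[cl]]
    n <- length(v)
    if (n >= 2L) {
      m <- mean(v); se <- sd(v) / sqrt(n)
      hw <- qt(0.975, df = n - 1L) * se
      data.frame(class = cl, n = n, mean = m, ci_lo = m - hw, ci_hi = m + hw)
    } else {
      data.frame(class = cl, n = n, mean = if (n) mean(v) else NA_real_,
                 ci_lo = NA_real_, ci_hi = NA_real_)
    }
  }))
  pw <- list()
  if (length(classes) >= 2L) {
    for (i in seq_len(length(classes) - 1L)) for (j in (i + 1L):length(classes)) {
      x <- results_by_class[[classes[i]]]; y <- results_by_class[[classes[j]]]
      if (length(x) < 2L || length(y) < 2L) {
        pw[[length(pw) + 1L]] <- data.frame(class1 = classes[i],
                                            class2 = classes[j],
                                            U = NA_real_, p_value = NA_real_,
                                            testable = FALSE)
        next
      }
      wt <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = FALSE))
      pw[[length(pw) + 1L]] <- data.frame(class1 = classes[i],
                                          class2 = classes[j],
                                          U = unname(wt$statistic),
                                          p_value = wt$p.value,
                                          testable = TRUE)
    }
  }
  list(class_summary = summ,
       pairwise = if (length(pw)) do.call(rbind, pw) else
         data.frame(class1 = character(0), class2 = character(0),
                    U = numeric(0), p_value = numeric(0),
                    testable = logical(0)))
}
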