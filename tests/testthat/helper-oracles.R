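# Independent oracles used by the property and acceptance tests. These are
# deliberately naive (enumeration / brute force) and share no code with the
# implementation paths they check.

# -- six-frame ORF scan by direct codon walking ------------------------------
# returns the ATG-to-stop ORFs (first ATG after the previous stop, stop
# included) per frame, as a data.frame(frame, start, end)
oracle_orfs <- function(sequence) {
  sequence <- toupper(sequence)
  stops <- c("TAA", "TAG", "TGA")
  out <- list()
  for (fr in 0:5) {
    s <- if (fr < 3) sequence else {
      paste(rev(chartr("ACGT", "TGCA",
                       strsplit(sequence, "")[[1]])), collapse = "")
    }
    off <- fr %% 3
    n <- (nchar(s) - off) %/% 3
    if (n < 1) next
    codons <- substring(s, off + 3 * (0:(n - 1)) + 1, off + 3 * (0:(n - 1)) + 3)
    prev_stop <- 0
    for (ci in seq_len(n)) {
      if (codons[ci] %in% stops) {
        seg <- (prev_stop + 1):ci
        atgs <- seg[codons[seg] == "ATG"]
        atgs <- atgs[atgs < ci]
        if (length(atgs)) {
          a <- atgs[1]
          out[[length(out) + 1]] <- data.frame(
            frame = fr, start = off + 3 * (a - 1), end = off + 3 * ci,
            peptide = ci - a)
        }
        prev_stop <- ci
      }
    }
  }
  if (!length(out)) {
    return(data.frame(frame = integer(0), start = integer(0),
                      end = integer(0), peptide = integer(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$frame, res$start), ]
}

# -- phylogenetic likelihood by summation over ancestral states --------------
# model: a subst_model; tree: ape phylo; tips_col: named state vector (may
# contain NA = missing). Sums P(data, ancestors) over every assignment of
# internal-node states.
oracle_tree_loglik <- function(model, tree, tips_col, rate_scale = 1) {
  tr <- ape::reorder.phylo(tree, "postorder")
  E <- tr$edge
  bl <- tr$edge.length * rate_scale
  ntip <- length(tr$tip.label)
  nn <- tr$Nnode
  S <- length(model$states)
  Ps <- lapply(seq_len(nrow(E)), function(k) prob_matrix(model, bl[k]))
  tipstates <- tips_col[tr$tip.label]
  grid <- as.matrix(expand.grid(rep(list(seq_len(S)), nn)))
  tot <- 0
  for (g in seq_len(nrow(grid))) {
    # likelihood of one full ancestral assignment, marginalizing missing tips
    asn <- grid[g, ]
    p <- model$pi[asn[1]]          # root is node ntip+1, first internal
    for (k in seq_len(nrow(E))) {
      par_state <- asn[E[k, 1] - ntip]
      child <- E[k, 2]
      if (child <= ntip) {
        st <- tipstates[child]
        p <- p * if (is.na(st)) 1 else Ps[[k]][par_state, st]
      } else {
        p <- p * Ps[[k]][par_state, asn[child - ntip]]
      }
      if (p == 0) break
    }
    tot <- tot + p
  }
  unname(log(tot))
}

# -- exhaustive nested-structure enumeration ---------------------------------
# materializes every nested pairing (min_loop constraint) of a coded
# sequence and returns the maximum total pair score
oracle_fold_score <- function(sequence, min_loop = 3) {
  code <- match(strsplit(toupper(chartr("U", "T", sequence)), "")[[1]],
                c("A", "C", "G", "T"))
  code[is.na(code)] <- -1
  ps <- function(a, b) {
    if (a < 0 || b < 0) return(0)
    key <- paste(sort(c(a, b)), collapse = "")
    switch(key, "23" = 3, "14" = 2, "34" = 1, 0)
  }
  n <- length(code)
  # all_pairsets(i, j): list of pair matrices achievable on [i, j]
  all_pairsets <- function(i, j) {
    if (i >= j) return(list(matrix(numeric(0), 0, 2)))
    res <- list()
    # i unpaired
    for (m in all_pairsets(i + 1, j)) res[[length(res) + 1]] <- m
    ks <- if (i + min_loop + 1 > j) integer(0) else (i + min_loop + 1):j
    for (k in ks) {
      if (ps(code[i], code[k]) <= 0) next
      left <- all_pairsets(i + 1, k - 1)
      right <- all_pairsets(k + 1, j)
      for (lm in left) for (rm in right) {
        res[[length(res) + 1]] <- rbind(c(i, k), lm, rm)
      }
    }
    res
  }
  if (n < 2) return(0)
  best <- 0
  for (m in all_pairsets(1, n)) {
    if (!nrow(m)) next
    sc <- sum(apply(m, 1, function(p) ps(code[p[1]], code[p[2]])))
    if (sc > best) best <- sc
  }
  best
}

# -- O(n^2) duplicate-complement oracle --------------------------------------
oracle_duplicates <- function(df, min_frac = 0.5) {
  # df: id, chrom, strand, start, end (single-exon intervals)
  hits <- list()
  n <- nrow(df)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    a <- df[i, ]; b <- df[j, ]
    if (a$chrom != b$chrom || a$strand == b$strand) next
    ov <- max(0, min(a$end, b$end) - max(a$start, b$start))
    un <- max(a$end, b$end) - min(a$start, b$start)
    if (un > 0 && ov / un >= min_frac) {
      hits[[length(hits) + 1]] <- sort(c(a$id, b$id))
    }
  }
  if (!length(hits)) return(character(0))
  sort(vapply(hits, paste, "", collapse = "|"))
}

# -- Mann-Whitney U by direct rank counting ----------------------------------
oracle_mann_whitney_u <- function(x, y) {
  sum(vapply(x, function(xi) sum(xi > y) + 0.5 * sum(xi == y), 0))
}
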