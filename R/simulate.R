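#' Seeded synthetic-data generators
#'
#' Every input the pipeline consumes can be generated at desk scale with
#' recorded ground truth: a reference genome with planted multi-exon genes,
#' two noisy pseudo-assembler transcript-call sets, a multi-species
#' whole-genome alignment evolved under neutral, purifying-codon and
#' compensatory structured-RNA processes (exact matrix-exponential
#' transitions, no indels, so alignment columns equal reference positions),
#' and lineage-specific loss of alignability by gapping species out of
#' chosen genes. All generators are deterministic under a fixed seed.
#'
#' @name synthetic_data
NULL

#' Default 8-species ladder tree
#'
#' A ladder of six ingroup species above the reference plus two outgroups,
#' emulating a shallow-to-deep divergence gradient (sibling complex through
#' distant congeners). Branch lengths are substitutions/site.
#'
#' @return list with `tree` (`ape::phylo`, reference tip `ref`) and
#'   `root_ages` (named vector, million years to the MRCA with the
#'   reference).
#' @export
default_species_tree <- function() {
  nwk <- paste0("(((((((ref:0.02,sp1:0.02):0.03,sp2:0.05):0.05,sp3:0.10):0.10,",
                "sp4:0.20):0.15,sp5:0.35):0.20,sp6:0.55):0.20,sp7:0.75);")
  tree <- ape::read.tree(text = nwk)
  ages <- c(sp1 = 0.5, sp2 = 2, sp3 = 10, sp4 = 25, sp5 = 50, sp6 = 80,
            sp7 = 100)
  list(tree = tree, root_ages = ages)
}

sample_dna <- function(n, pi) {
  paste(sample(DNA_BASES, n, replace = TRUE, prob = pi), collapse = "")
}

gc_to_pi <- function(gc) {
  c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
}

random_cds <- function(n_codons, pi) {
  ct <- codon_table()
  sense <- ct$sense
  w <- vapply(sense, function(cod) {
    prod(pi[match(str_chars(cod), DNA_BASES)])
  }, 0)
  inner <- sample(sense, n_codons - 2L, replace = TRUE, prob = w)
  paste0("ATG", paste(inner, collapse = ""), "TAA")
}

#' Generate a toy genome with planted reference genes
#'
#' The background is i.i.d. sequence at the requested GC content; reference
#' genes are multi-exon (three coding exons separated by introns), on
#' alternating strands, non-overlapping, with full-length CDS (ATG to stop)
#' written into the exons so four-fold degenerate sites can be extracted.
#'
#' @param n_chrom number of chromosomes.
#' @param length chromosome length in nt (>= 10000).
#' @param gc GC content in (0, 1).
#' @param seed RNG seed.
#' @param n_genes reference genes per chromosome.
#' @param fasta_path,gtf_path optional output paths; written when given.
#' @return list with `genome` (named character vector) and `genes` (list of
#'   `transcript` objects with `cds`).
#' @export
generate_genome <- function(n_chrom = 1L, length = 1e5, gc = 0.5, seed = 1L,
                            n_genes = 8L, fasta_path = NULL,
                            gtf_path = NULL) {
  if (length < 1e4) stop("chromosome length must be >= 10 kb")
  if (gc <= 0 || gc >= 1) stop("gc must be in (0, 1)")
  pi <- gc_to_pi(gc)
  with_seed(seed, {
    genome <- character(n_chrom)
    names(genome) <- paste0("chr", seq_len(n_chrom))
    genes <- list()
    for (ci in seq_len(n_chrom)) {
      chrom <- names(genome)[ci]
      seq <- sample_dna(length, pi)
      spacing <- floor(length / (n_genes + 1L))
      for (g in seq_len(n_genes)) {
        gene <- plant_gene_layout(spacing * g, exon_lens = c(210L, 180L, 210L),
                                  intron_len = 400L)
        strand <- if (g %% 2L == 0L) "-" else "+"
        cds <- random_cds(sum(gene$exon_lens) / 3L, pi)
        seq <- write_cds_into(seq, gene$exons, strand, cds)
        id <- sprintf("%s_refgene%02d", chrom, g)
        tx <- transcript(id, chrom, strand, gene$exons,
                         class_code = "REFERENCE", source = "reference")
        tx$cds <- tx$exons
        genes[[id]] <- tx
      }
      genome[ci] <- seq
    }
    if (!is.null(fasta_path)) write_genome(genome, fasta_path)
    if (!is.null(gtf_path)) write_gtf(genes, gtf_path)
    list(genome = genome, genes = genes)
  })
}

plant_gene_layout <- function(start, exon_lens, intron_len) {
  exons <- matrix(0L, length(exon_lens), 2L,
                  dimnames = list(NULL, c("start", "end")))
  cur <- as.integer(start)
  for (j in seq_along(exon_lens)) {
    exons[j, ] <- c(cur, cur + exon_lens[j])
    cur <- cur + exon_lens[j] + intron_len
  }
  list(exons = exons, exon_lens = exon_lens,
       span = c(exons[1, 1], exons[nrow(exons), 2]))
}

# write a spliced CDS (given 5'->3' on `strand`) into exon intervals of seq
write_cds_into <- function(seq, exons, strand, cds) {
  genomic <- if (strand == "-") revcomp(cds) else cds
  off <- 0L
  for (j in seq_len(nrow(exons))) {
    w <- exons[j, "end"] - exons[j, "start"]
    substr(seq, exons[j, "start"] + 1L, exons[j, "end"]) <-
      substr(genomic, off + 1L, off + w)
    off <- off + w
  }
  seq
}

#' Simulate a multi-species alignment block under a named process
#'
#' Model specs: `list(type = "neutral", kappa, pi, scale)`;
#' `"conserved"` adds `r` (rate multiplier < 1); `"coding"` adds `omega`
#' (length must be a multiple of 3; branch lengths are
#' synonymous-rate-matched as in [coding_model()]); `"structured"` adds
#' `pairs` (two-column 1-based position matrix), `compensatory_prob` and
#' `decay_rate` — paired positions substitute jointly (preserving
#' pairability) with probability `compensatory_prob`, and the whole
#' structure is lost on a branch with probability
#' `1 - exp(-decay_rate * branch_length)`, after which all positions evolve
#' neutrally; an optional `protect_tip` names a tip whose root path never
#' loses the structure (reference-anchored structures).
#'
#' @param tree rooted `ape::phylo`.
#' @param model_spec model specification list (see above).
#' @param length alignment length in nt.
#' @param seed RNG seed (NULL = use current stream).
#' @return list with `rows` (named ungapped character vector, one per tip)
#'   and `truth` (spec echo plus, for structured mode, per-tip
#'   `structure_present` flags).
#' @export
simulate_alignment <- function(tree, model_spec, length, seed = NULL) {
  with_seed(seed, simulate_alignment_impl(tree, model_spec, length))
}

simulate_alignment_impl <- function(tree, spec, length) {
  kappa <- spec$kappa %||% 3
  pi <- spec$pi %||% rep(0.25, 4)
  scale <- spec$scale %||% 1
  type <- spec$type
  if (type %in% c("neutral", "conserved")) {
    r <- if (type == "conserved") spec$r else 1
    if (scale == 0 || r == 0) {
      root <- sample.int(4L, length, replace = TRUE, prob = pi)
      rows <- setNames(rep(paste(DNA_BASES[root], collapse = ""),
                           length(tree$tip.label)), tree$tip.label)
      return(list(rows = rows, truth = spec))
    }
    m <- hky_model(pi, kappa)
    sim <- simulate_states(m, tree, length, rate_scale = scale * r)
    rows <- apply(sim$tips, 1L, function(s) paste(DNA_BASES[s], collapse = ""))
    return(list(rows = rows, truth = spec))
  }
  if (type == "coding") {
    if (length %% 3L != 0L) stop("coding length must be a multiple of 3")
    m <- mg94_model(pi, kappa, spec$omega %||% 0.1)
    sim <- simulate_states(m, tree, length %/% 3L,
                           rate_scale = scale * codon_bl_mult(m))
    sense <- codon_table()$sense
    rows <- apply(sim$tips, 1L, function(s) paste(sense[s], collapse = ""))
    return(list(rows = rows, truth = spec))
  }
  if (type == "structured") {
    return(simulate_structured(tree, spec, length))
  }
  stop("unknown model_spec type: ", type)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

PAIRABLE <- matrix(c("G", "C", "C", "G", "A", "T", "T", "A", "G", "T",
                     "T", "G"), ncol = 2, byrow = TRUE)

# compensatory structured-RNA simulation: joint evolution of paired
# positions while the structure survives; neutral HKY afterwards. When
# `protect_tip` is set, branches on the root-to-that-tip path never lose
# the structure (reference-anchored structures are present in the
# reference by construction).
simulate_structured <- function(tree, spec, length) {
  pairs <- spec$pairs
  comp <- spec$compensatory_prob %||% 0.9
  decay <- spec$decay_rate %||% 1.5
  pair_rate <- spec$pair_rate %||% 1
  kappa <- spec$kappa %||% 3
  pi <- spec$pi %||% rep(0.25, 4)
  scale <- spec$scale %||% 1
  m <- hky_model(pi, kappa)
  paired_idx <- as.vector(pairs)
  if (anyDuplicated(paired_idx)) stop("positions may appear in at most one pair")
  unpaired_idx <- setdiff(seq_len(length), paired_idx)
  root <- character(length)
  root[unpaired_idx] <- sample(DNA_BASES, length(unpaired_idx), replace = TRUE,
                               prob = pi)
  for (k in seq_len(nrow(pairs))) {
    pp <- PAIRABLE[sample.int(nrow(PAIRABLE), 1L), ]
    root[pairs[k, 1]] <- pp[1]; root[pairs[k, 2]] <- pp[2]
  }
  ti <- tree_info(tree)
  protected_nodes <- integer(0)
  if (!is.null(spec$protect_tip) && spec$protect_tip %in% ti$tips) {
    node <- which(ti$tips == spec$protect_tip)
    repeat {
      protected_nodes <- c(protected_nodes, node)
      k <- which(ti$edge[, 2L] == node)
      if (!length(k)) break
      node <- ti$edge[k, 1L]
    }
  }
  nodes <- vector("list", ti$ntip + ti$nnode)
  present <- logical(ti$ntip + ti$nnode)
  nodes[[ti$root]] <- root
  present[ti$root] <- TRUE
  evolve_hky <- function(seqv, idx, bl) {
    if (!length(idx) || bl <= 0) return(seqv)
    P <- prob_matrix(m, bl)
    st <- match(seqv[idx], DNA_BASES)
    out <- st
    for (s in 1:4) {
      w <- which(st == s)
      if (length(w)) out[w] <- sample.int(4L, length(w), replace = TRUE,
                                          prob = P[s, ])
    }
    seqv[idx] <- DNA_BASES[out]
    seqv
  }
  for (k in rev(seq_len(nrow(ti$edge)))) {
    parent <- ti$edge[k, 1L]; child <- ti$edge[k, 2L]
    bl <- ti$lengths[k] * scale
    seqv <- nodes[[parent]]
    child_present <- present[parent] &&
      (child %in% protected_nodes ||
         stats::runif(1) >= (1 - exp(-decay * ti$lengths[k])))
    if (child_present) {
      seqv <- evolve_hky(seqv, unpaired_idx, bl)
      p_sub <- 1 - exp(-pair_rate * bl)
      for (p in seq_len(nrow(pairs))) {
        if (stats::runif(1) < p_sub) {
          i <- pairs[p, 1]; j <- pairs[p, 2]
          if (stats::runif(1) < comp) {
            cur <- nrow(PAIRABLE) + 1L
            repeat {
              cand <- sample.int(nrow(PAIRABLE), 1L)
              if (!(PAIRABLE[cand, 1] == seqv[i] &&
                    PAIRABLE[cand, 2] == seqv[j])) break
            }
            seqv[i] <- PAIRABLE[cand, 1]; seqv[j] <- PAIRABLE[cand, 2]
          } else {
            side <- if (stats::runif(1) < 0.5) i else j
            seqv[side] <- sample(setdiff(DNA_BASES, seqv[side]), 1L)
          }
        }
      }
    } else {
      seqv <- evolve_hky(seqv, seq_len(length), bl)
    }
    nodes[[child]] <- seqv
    present[child] <- child_present
  }
  rows <- vapply(seq_len(ti$ntip), function(i) paste(nodes[[i]], collapse = ""),
                 "")
  names(rows) <- ti$tips
  truth <- spec
  truth$structure_present <- setNames(present[seq_len(ti$ntip)], ti$tips)
  list(rows = rows, truth = truth)
}

#' Labeled synthetic windows for structure-score calibration
#'
#' Positives are conserved hairpin families (compensatory evolution, no
#' structure decay). Negatives come in two flavours: `"shuffled"` rows
#' (each row independently mononucleotide-shuffled, destroying both
#' folding stability and shared structure) and `"aligned"` neutral windows
#' (phylogenetically correlated rows with no planted structure) — the
#' latter is the realistic null a genomic window scan faces, since related
#' rows share residual consensus signal that shuffles do not. Used to fit
#' [calibrate_score_weights()] for a given tree.
#'
#' @param tree rooted `ape::phylo`.
#' @param n_pos,n_neg window counts per class (for `neg = "both"`, `n_neg`
#'   of each flavour).
#' @param window window length (nt).
#' @param stem,loop hairpin geometry of the positives.
#' @param kappa,pi nucleotide model parameters.
#' @param seed RNG seed.
#' @param neg negative-control flavour: `"shuffled"`, `"aligned"`, or
#'   `"both"`.
#' @return list with `alignments` (row lists) and `labels` (logical).
#' @export
synthetic_structure_windows <- function(tree, n_pos = 30L, n_neg = 30L,
                                        window = 120L, stem = 25L,
                                        loop = 5L, kappa = 3,
                                        pi = rep(0.25, 4), seed = 1L,
                                        neg = c("shuffled", "aligned",
                                                "both")) {
  neg <- match.arg(neg)
  pairs <- hairpin_pairs(window, stem, loop)
  with_seed(seed, {
    pos <- lapply(seq_len(n_pos), function(k) {
      as.list(simulate_alignment_impl(
        tree, list(type = "structured", pairs = pairs,
                   compensatory_prob = 0.9, decay_rate = 0,
                   kappa = kappa, pi = pi), window)$rows)
    })
    neutral_window <- function() {
      as.list(simulate_alignment_impl(
        tree, list(type = "neutral", kappa = kappa, pi = pi), window)$rows)
    }
    negs <- list()
    if (neg %in% c("shuffled", "both")) {
      negs <- c(negs, lapply(seq_len(n_neg), function(k) {
        lapply(neutral_window(), function(r) {
          paste(sample(str_chars(r)), collapse = "")
        })
      }))
    }
    if (neg %in% c("aligned", "both")) {
      negs <- c(negs, lapply(seq_len(n_neg), function(k) neutral_window()))
    }
    list(alignments = c(pos, negs),
         labels = rep(c(TRUE, FALSE), c(n_pos, length(negs))))
  })
}

# a centered hairpin pairing for a window of given length: `stem` pairs
# with a loop of `loop` unpaired positions
hairpin_pairs <- function(window, stem = 25L, loop = 5L) {
  need <- 2L * stem + loop
  if (need > window) stop("window too short for requested stem")
  off <- (window - need) %/% 2L
  cbind(off + seq_len(stem), off + need + 1L - seq_len(stem))
}

#' Generate two noisy pseudo-assembler transcript-call sets
#'
#' Each planted transcript is dropped independently per assembler with
#' `drop_prob`, its outer boundaries are jittered with Gaussian noise of sd
#' `jitter_sd` (clamped so transcripts stay valid), and `n_spurious` random
#' intergenic single-exon calls are added per assembler. Transcript ids are
#' preserved so calls can be matched back to the truth table.
#'
#' @param planted list of `transcript` objects (the true novel set).
#' @param noise list with `drop_prob` (length-2), `jitter_sd`,
#'   `n_spurious`, and for spurious placement `genome_length` and `chrom`.
#' @param seed RNG seed.
#' @return list with `set_a`, `set_b` (lists of transcripts) and `truth`
#'   (data.frame id, in_a, in_b, spurious).
#' @export
generate_assembler_calls <- function(planted,
                                     noise = list(drop_prob = c(0.05, 0.05),
                                                  jitter_sd = 3,
                                                  n_spurious = 3L,
                                                  genome_length = 2e5,
                                                  chrom = "chr1"),
                                     seed = 1L) {
  with_seed(seed, {
    jitter_tx <- function(tx, tag) {
      sd <- noise$jitter_sd %||% 0
      if (sd > 0) {
        ex <- tx$exons
        d1 <- round(stats::rnorm(1, 0, sd)); d2 <- round(stats::rnorm(1, 0, sd))
        ex[1, "start"] <- max(0L, ex[1, "start"] + as.integer(d1))
        ex[nrow(ex), "end"] <- ex[nrow(ex), "end"] + as.integer(d2)
        if (ex[1, "start"] >= ex[1, "end"]) ex[1, "start"] <- ex[1, "end"] - 1L
        if (nrow(ex) > 1L && ex[1, "end"] > ex[2, "start"]) {
          ex[1, "end"] <- ex[2, "start"] - 1L
        }
        tx2 <- transcript(tx$id, tx$chrom, tx$strand, ex,
                          class_code = tx$class_code, source = tag,
                          gene_id = tx$gene_id)
        return(tx2)
      }
      tx$source <- tag
      tx
    }
    make_set <- function(tag, drop_p, n_spur) {
      kept <- list()
      dropped <- character(0)
      for (tx in planted) {
        if (stats::runif(1) < drop_p) {
          dropped <- c(dropped, tx$id)
        } else {
          kept[[tx$id]] <- jitter_tx(tx, tag)
        }
      }
      spur <- list()
      for (k in seq_len(n_spur)) {
        len <- 250L
        s <- as.integer(floor(stats::runif(1, 0, noise$genome_length - len)))
        id <- sprintf("spurious_%s_%d", tag, k)
        spur[[id]] <- transcript(id, noise$chrom,
                                 sample(c("+", "-"), 1L),
                                 cbind(s, s + len), class_code = "OTHER",
                                 source = tag)
      }
      list(kept = kept, dropped = dropped, spur = spur)
    }
    dp <- noise$drop_prob %||% c(0, 0)
    a <- make_set("asmA", dp[1], noise$n_spurious %||% 0L)
    b <- make_set("asmB", dp[2], noise$n_spurious %||% 0L)
    ids <- vapply(planted, `[[`, "", "id")
    truth <- data.frame(id = c(ids, names(a$spur), names(b$spur)),
                        in_a = c(!ids %in% a$dropped,
                                 rep(c(TRUE, FALSE), c(length(a$spur),
                                                       length(b$spur)))),
                        in_b = c(!ids %in% b$dropped,
                                 rep(c(FALSE, TRUE), c(length(a$spur),
                                                       length(b$spur)))),
                        spurious = c(rep(FALSE, length(ids)),
                                     rep(TRUE, length(a$spur) + length(b$spur))))
    list(set_a = c(a$kept, a$spur), set_b = c(b$kept, b$spur), truth = truth)
  })
}

#' Default configuration of the synthetic study
#'
#' The stated world: an 8-species ladder tree, a 200 kb chromosome, 12
#' reference protein-coding genes (the four-fold-site substrate), and 60
#' planted novel transcripts — 15 coding (MG94, omega = 0.1), 15 structured
#' lncRNAs (compensatory hairpin windows), 15 unstructured neutral lncRNAs
#' and 15 neutral transcripts with a mid-length ORF that the cascade must
#' leave ambiguous — plus planted single-exon complementary-strand
#' duplicate pairs and lineage-specific alignability loss on a quarter of
#' the novel genes.
#'
#' @return named list of generator parameters.
#' @export
study_config <- function() {
  list(chrom = "chr1", genome_length = 2e5, gc = 0.45, kappa = 3,
       n_ref_genes = 12L, ref_exon_lens = c(210L, 180L, 210L),
       ref_intron_len = 500L, ref_omega = 0.05,
       n_coding = 15L, coding_cds_codons = 150L, coding_utr = 45L,
       coding_omega = 0.1,
       n_lnc_structured = 15L, n_lnc_unstructured = 15L, n_ambiguous = 15L,
       lnc_len = 480L, amb_len = 510L, amb_orf_codons = 70L,
       structure_window = 120L, structure_stem = 25L, structure_loop = 5L,
       compensatory_prob = 0.9, decay_rate = 1.5,
       n_intronic = 5L, n_antisense = 4L,
       n_duplicate_pairs = 4L, duplicate_len = 260L,
       ablation_frac = 0.25,
       drop_prob = c(0.05, 0.05), jitter_sd = 3, n_spurious = 3L,
       max_lnc_peptide = 45L, maf_block = 1000L)
}

#' Generate a complete synthetic study bundle
#'
#' One call yields every input the pipeline consumes — genome FASTA,
#' reference GTF (exons + CDS), two assembler GTFs, MAF alignment, Newick
#' tree, root-age TSV, domain TSV — plus a truth record (also serialized as
#' JSON) naming each planted transcript's generating class, the ablation
#' table, and per-structure retention. Deterministic under `seed`.
#'
#' @param config as [study_config()]; partial lists are completed with
#'   defaults.
#' @param seed master RNG seed.
#' @param out_dir output directory (created if needed).
#' @return list with `paths` (named file paths), `truth`, `tree`,
#'   `root_ages`, `genome`, and `planted` (the true novel transcripts).
#' @export
generate_study <- function(config = study_config(), seed = 1L,
                           out_dir = tempfile("lncevo_study_")) {
  cfg <- utils::modifyList(study_config(), config)
  bad <- c(if (cfg$genome_length < 5e4) "genome_length (< 50 kb)",
           if (cfg$lnc_len < 300L) "lnc_len (< 300)",
           if (cfg$structure_window > cfg$lnc_len) "structure_window > lnc_len")
  if (length(bad)) stop("inconsistent config: ", paste(bad, collapse = ", "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  st <- default_species_tree()
  tree <- st$tree
  tips <- tree$tip.label
  pi <- gc_to_pi(cfg$gc)
  with_seed(seed, build_study(cfg, tree, st$root_ages, pi, out_dir))
}

# the actual study assembly; runs inside with_seed()
build_study <- function(cfg, tree, root_ages, pi, out_dir) {
  tips <- tree$tip.label
  neutral_spec <- list(type = "neutral", kappa = cfg$kappa, pi = pi, scale = 1)
  env <- new.env()
  env$rows <- setNames(rep(list(character(0)), length(tips)), tips)
  env$cursor <- 0L
  env$planted <- list()
  env$truth_tx <- list()
  env$structures <- list()
  env$ref_genes <- list()
  env$lnc_id <- 0L

  append_rows <- function(seg_rows) {
    for (sp in tips) env$rows[[sp]] <- c(env$rows[[sp]], seg_rows[[sp]])
    invisible(NULL)
  }
  advance <- function(len) env$cursor <- env$cursor + as.integer(len)
  emit_neutral <- function(len) {
    if (len <= 0L) return(invisible(NULL))
    seg <- simulate_alignment_impl(tree, neutral_spec, len)
    append_rows(seg$rows)
    advance(len)
  }
  gap_len <- function() 400L + sample.int(400L, 1L)
  next_lnc_id <- function() {
    env$lnc_id <- env$lnc_id + 1L
    sprintf("novel_lnc%02d", env$lnc_id)
  }
  ref_row_tail <- function(from) {
    # reference-row sequence emitted so far, from 0-based position `from`
    substring(paste(env$rows[["ref"]], collapse = ""), from + 1L)
  }
  register <- function(id, strand, start, end, locus_class, class, extra = list()) {
    env$planted[[id]] <- transcript(id, cfg$chrom, strand,
                                    cbind(start, end), class_code = locus_class,
                                    source = "planted")
    env$truth_tx[[id]] <- c(list(id = id, class = class,
                                 locus_class = locus_class), extra)
  }

  # rejection-sample a neutral segment until the reference row (prefixed
  # with fixed context already emitted, when given) keeps every
  # ATG-anchored ORF at or below the lncRNA peptide bound
  simulate_lnc_segment <- function(len, prefix = "") {
    for (attempt in 1:300) {
      seg <- simulate_alignment_impl(tree, neutral_spec, len)
      if (max_orf_peptide(paste0(prefix, seg$rows[["ref"]]))$peptide_length <=
          cfg$max_lnc_peptide) {
        return(seg)
      }
    }
    stop("could not satisfy lncRNA ORF constraint after 300 attempts")
  }

  # ---- reference genes (purifying CDS; neutral introns), hosting the
  # planted intronic and antisense lncRNAs
  emit_ref_gene <- function(g, with_intronic, with_antisense) {
    emit_neutral(gap_len())
    strand <- if (g %% 2L == 0L) "-" else "+"
    ex_lens <- cfg$ref_exon_lens
    cds_len <- sum(ex_lens)
    seg <- simulate_alignment_impl(tree,
      list(type = "coding", kappa = cfg$kappa, pi = pi, scale = 1,
           omega = cfg$ref_omega), cds_len)
    spliced <- vapply(seg$rows[tips], function(s) {
      substr(s, 1L, 3L) <- "ATG"
      substr(s, cds_len - 2L, cds_len) <- "TAA"
      s
    }, "")
    # genomic orientation: minus-strand genes carry the reverse complement
    genomic_cds <- if (strand == "-") vapply(spliced, revcomp, "") else spliced
    off <- c(0L, cumsum(ex_lens))
    gene_start <- env$cursor
    exons <- matrix(0L, length(ex_lens), 2L,
                    dimnames = list(NULL, c("start", "end")))
    for (j in seq_along(ex_lens)) {
      exons[j, ] <- c(env$cursor, env$cursor + ex_lens[j])
      append_rows(lapply(genomic_cds,
                         function(s) substr(s, off[j] + 1L, off[j + 1L])))
      advance(ex_lens[j])
      if (j < length(ex_lens)) {
        if (with_intronic && j == 1L) {
          pad <- 25L
          lnc_len_i <- cfg$ref_intron_len - 2L * pad
          emit_neutral(pad)
          lstart <- env$cursor
          append_rows(simulate_lnc_segment(lnc_len_i)$rows)
          advance(lnc_len_i)
          emit_neutral(pad)
          id <- next_lnc_id()
          register(id, sample(c("+", "-"), 1L), lstart, lstart + lnc_len_i,
                   "I", "lncRNA_unstructured",
                   list(host = sprintf("refgene%02d", g)))
        } else {
          emit_neutral(cfg$ref_intron_len)
        }
      }
    }
    gene_id <- sprintf("refgene%02d", g)
    tx <- transcript(gene_id, cfg$chrom, strand, exons,
                     class_code = "REFERENCE", source = "reference")
    tx$cds <- tx$exons
    env$ref_genes[[gene_id]] <- tx
    if (with_antisense) {
      # antisense lncRNA: overlaps the last 60 nt of the gene's final exon
      # on the opposite strand and extends into downstream intergenic space
      ov <- 60L
      ext <- cfg$lnc_len - ov
      xstart <- env$cursor - ov
      seg2 <- NULL
      for (attempt in 1:300) {
        cand <- simulate_alignment_impl(tree, neutral_spec, ext)
        refseq <- paste0(ref_row_tail(xstart), cand$rows[["ref"]])
        if (max_orf_peptide(refseq)$peptide_length <= cfg$max_lnc_peptide) {
          seg2 <- cand
          break
        }
      }
      if (is.null(seg2)) stop("antisense ORF constraint not satisfiable")
      append_rows(seg2$rows)
      advance(ext)
      id <- next_lnc_id()
      register(id, if (strand == "+") "-" else "+", xstart,
               xstart + cfg$lnc_len, "X", "lncRNA_unstructured",
               list(host = gene_id))
    }
  }

  # ---- intergenic novel transcripts
  emit_coding_tx <- function(id) {
    emit_neutral(gap_len())
    utr <- cfg$coding_utr
    emit_neutral(utr)
    tstart <- env$cursor - utr
    cds_len <- 3L * cfg$coding_cds_codons
    seg <- simulate_alignment_impl(tree,
      list(type = "coding", kappa = cfg$kappa, pi = pi, scale = 1,
           omega = cfg$coding_omega), cds_len)
    append_rows(lapply(seg$rows[tips], function(s) {
      substr(s, 1L, 3L) <- "ATG"
      substr(s, cds_len - 2L, cds_len) <- "TAA"
      s
    }))
    advance(cds_len)
    emit_neutral(utr)
    register(id, "+", tstart, env$cursor, "U", "coding",
             list(cds = c(tstart + utr, tstart + utr + cds_len)))
  }

  emit_structured_lnc <- function(id) {
    emit_neutral(gap_len())
    tstart <- env$cursor
    win <- cfg$structure_window
    flank1 <- (cfg$lnc_len - win) %/% 2L
    flank2 <- cfg$lnc_len - win - flank1
    pairs <- hairpin_pairs(win, cfg$structure_stem, cfg$structure_loop)
    f1 <- sw <- f2 <- NULL
    for (attempt in 1:300) {
      f1 <- simulate_alignment_impl(tree, neutral_spec, flank1)
      sw <- simulate_alignment_impl(tree,
        list(type = "structured", pairs = pairs,
             compensatory_prob = cfg$compensatory_prob,
             decay_rate = cfg$decay_rate, kappa = cfg$kappa, pi = pi,
             scale = 1, protect_tip = "ref"), win)
      f2 <- simulate_alignment_impl(tree, neutral_spec, flank2)
      refseq <- paste0(f1$rows[["ref"]], sw$rows[["ref"]], f2$rows[["ref"]])
      if (max_orf_peptide(refseq)$peptide_length <= cfg$max_lnc_peptide) break
      if (attempt == 300) stop("structured lncRNA ORF constraint failed")
    }
    seg_rows <- setNames(lapply(tips, function(sp) {
      paste0(f1$rows[[sp]], sw$rows[[sp]], f2$rows[[sp]])
    }), tips)
    append_rows(seg_rows)
    advance(cfg$lnc_len)
    register(id, "+", tstart, env$cursor, "U", "lncRNA_structured")
    env$structures[[id]] <- list(
      gene_id = id,
      window = c(tstart + flank1, tstart + flank1 + win),
      present = sw$truth$structure_present)
  }

  emit_plain_lnc <- function(id) {
    emit_neutral(gap_len())
    tstart <- env$cursor
    append_rows(simulate_lnc_segment(cfg$lnc_len)$rows)
    advance(cfg$lnc_len)
    register(id, sample(c("+", "-"), 1L), tstart, env$cursor, "U",
             "lncRNA_unstructured")
  }

  emit_ambiguous_tx <- function(id) {
    emit_neutral(gap_len())
    tstart <- env$cursor
    # the reference row must keep a mid-length ORF (between the lncRNA and
    # coding peptide bounds) so the transcript stays AMBIGUOUS
    seg <- NULL
    for (attempt in 1:500) {
      cand <- simulate_alignment_impl(tree, neutral_spec, cfg$amb_len)
      pl <- max_orf_peptide(cand$rows[["ref"]])$peptide_length
      if (pl >= 55L && pl <= 95L) {
        seg <- cand
        break
      }
    }
    if (is.null(seg)) stop("ambiguous ORF constraint failed")
    append_rows(seg$rows)
    advance(cfg$amb_len)
    register(id, "+", tstart, env$cursor, "U", "ambiguous")
  }

  emit_duplicate_pair <- function(k) {
    emit_neutral(gap_len())
    tstart <- env$cursor
    append_rows(simulate_alignment_impl(tree, neutral_spec,
                                        cfg$duplicate_len)$rows)
    advance(cfg$duplicate_len)
    id1 <- sprintf("novel_dup%02da", k)
    id2 <- sprintf("novel_dup%02db", k)
    register(id1, "+", tstart, env$cursor, "U", "duplicate_pair",
             list(partner = id2))
    register(id2, "-", tstart, env$cursor, "U", "duplicate_pair",
             list(partner = id1))
  }

  n_intronic <- min(cfg$n_intronic, cfg$n_ref_genes)
  n_antisense <- min(cfg$n_antisense, cfg$n_ref_genes)
  for (g in seq_len(cfg$n_ref_genes)) {
    emit_ref_gene(g, with_intronic = g <= n_intronic,
                  with_antisense = g <= n_antisense)
  }
  for (k in seq_len(cfg$n_coding)) emit_coding_tx(sprintf("novel_cod%02d", k))
  for (k in seq_len(cfg$n_lnc_structured)) {
    emit_structured_lnc(sprintf("novel_str%02d", k))
  }
  n_plain <- cfg$n_lnc_unstructured - n_intronic - n_antisense
  for (k in seq_len(max(0L, n_plain))) emit_plain_lnc(next_lnc_id())
  for (k in seq_len(cfg$n_ambiguous)) emit_ambiguous_tx(sprintf("novel_amb%02d", k))
  for (k in seq_len(cfg$n_duplicate_pairs)) emit_duplicate_pair(k)
  if (env$cursor > cfg$genome_length) {
    stop("layout overflow: planted features need ", env$cursor,
         " nt but genome_length is ", cfg$genome_length)
  }
  emit_neutral(cfg$genome_length - env$cursor)

  aln <- vapply(env$rows, function(x) paste(x, collapse = ""), "")
  stopifnot(all(nchar(aln) == cfg$genome_length))

  # ---- lineage-specific ablation: species from a sampled depth outward
  # lose alignability over whole novel genes
  depth_order <- setdiff(tips, "ref")
  ablation <- list()
  novel_ids <- names(env$planted)
  n_ablate <- ceiling(cfg$ablation_frac * length(novel_ids))
  ablate_ids <- sort(sample(novel_ids, n_ablate))
  spans <- lapply(env$planted, transcript_span)
  for (id in ablate_ids) {
    k <- sample(2:(length(depth_order) - 1L), 1L)
    lost <- depth_order[k:length(depth_order)]
    span <- spans[[id]]
    for (sp in lost) {
      substr(aln[[sp]], span$start + 1L, span$end) <-
        strrep("-", interval_width(span))
    }
    # gapping a region ablates every transcript over it: credit co-located
    # transcripts (complementary-strand duplicate partners) in the truth too
    for (id2 in novel_ids) {
      s2 <- spans[[id2]]
      if (s2$start < span$end && s2$end > span$start) {
        ablation[[id2]] <- sort(union(ablation[[id2]], lost))
      }
    }
  }

  # ---- write outputs
  genome <- setNames(aln[["ref"]], cfg$chrom)
  calls <- generate_assembler_calls(
    env$planted,
    noise = list(drop_prob = cfg$drop_prob, jitter_sd = cfg$jitter_sd,
                 n_spurious = cfg$n_spurious,
                 genome_length = cfg$genome_length, chrom = cfg$chrom),
    seed = sample.int(2^30, 1L))
  domains <- data.frame(transcript_id = character(0),
                        domain_id = character(0), e_value = numeric(0))
  cod_ids <- names(Filter(function(t) t$class == "coding", env$truth_tx))
  if (length(cod_ids) >= 3L) {
    hit_ids <- cod_ids[seq_len(min(5L, length(cod_ids)))]
    domains <- data.frame(transcript_id = hit_ids,
                          domain_id = sprintf("PF%05d", seq_along(hit_ids)),
                          e_value = 1e-10)
  }
  paths <- list(genome = file.path(out_dir, "genome.fa"),
                reference_gtf = file.path(out_dir, "reference.gtf"),
                assembler_a = file.path(out_dir, "assembler_a.gtf"),
                assembler_b = file.path(out_dir, "assembler_b.gtf"),
                maf = file.path(out_dir, "alignment.maf"),
                tree = file.path(out_dir, "tree.nwk"),
                root_ages = file.path(out_dir, "root_ages.tsv"),
                domains = file.path(out_dir, "domains.tsv"),
                truth = file.path(out_dir, "truth.json"))
  write_genome(genome, paths$genome)
  write_gtf(env$ref_genes, paths$reference_gtf)
  write_gtf(calls$set_a, paths$assembler_a)
  write_gtf(calls$set_b, paths$assembler_b)
  write_maf(alignment_to_blocks(aln, cfg$chrom, "ref", cfg$maf_block),
            paths$maf)
  ape::write.tree(tree, paths$tree)
  write.table(data.frame(species = names(root_ages), age_mya = root_ages),
              paths$root_ages, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(domains, paths$domains, sep = "\t", quote = FALSE,
              row.names = FALSE)
  truth <- list(transcripts = env$truth_tx, ablation = ablation,
                structures = env$structures, assembler = calls$truth,
                config = cfg)
  jsonlite::write_json(truth_to_json(truth), paths$truth, auto_unbox = TRUE,
                       pretty = TRUE)
  list(paths = paths, truth = truth, tree = tree, root_ages = root_ages,
       genome = genome, planted = env$planted,
       reference_genes = env$ref_genes)
}

truth_to_json <- function(truth) {
  truth$structures <- lapply(truth$structures, function(s) {
    s$present <- as.list(s$present)
    s
  })
  truth
}

# chunk a gapped per-species alignment (no insertion columns) into MAF
# blocks; all-gap rows are omitted from a block, and per-species ungapped
# offsets are tracked for the s-line coordinates
alignment_to_blocks <- function(aln, chrom, reference, block_size) {
  L <- nchar(aln[[reference]])
  species <- names(aln)
  src_size <- vapply(aln, function(s) sum(str_chars(s) != "-"), 0L)
  offset <- setNames(integer(length(species)), species)
  blocks <- list()
  starts <- seq(0L, L - 1L, by = block_size)
  for (s in starts) {
    e <- min(L, s + block_size)
    texts <- vapply(aln, function(x) substr(x, s + 1L, e), "")
    ungap <- vapply(texts, function(x) sum(str_chars(x) != "-"), 0L)
    keep <- ungap > 0L
    blocks[[length(blocks) + 1L]] <- list(
      species = species[keep], chrom = rep(chrom, sum(keep)),
      start = unname(offset[keep]), size = unname(ungap[keep]),
      strand = rep("+", sum(keep)), src_size = unname(src_size[keep]),
      text = unname(texts[keep]),
      ref_row = which(species[keep] == reference))
    offset <- offset + ungap
  }
  blocks
}
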