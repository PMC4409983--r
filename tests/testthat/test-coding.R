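test_that("scan_orfs handles the hand-checked examples", {
  orfs <- scan_orfs("ATGGCCTAA")
  f0 <- orfs[orfs$frame == 0 & orfs$has_start & orfs$has_stop, ]
  expect_identical(nrow(f0), 1L)
  expect_identical(f0$peptide_length, 2L)          # M-A-stop
  expect_identical(f0$start, 0L)
  expect_identical(f0$end, 9L)
  # no ATG anywhere
  none <- scan_orfs("CCCCCCCCC")
  expect_false(any(none$has_start))
  # reverse-strand ORF appears in a reverse frame with the same peptide
  rc <- scan_orfs(revcomp_str <- chartr("ACGT", "TGCA", "AATTCCGGA"))
  expect_identical(nrow(scan_orfs("")), 0L)
  # N codons do not terminate and do not start an ORF
  withN <- scan_orfs("ATGANNGCCTAA")
  f0n <- withN[withN$frame == 0 & withN$has_start & withN$has_stop, ]
  expect_identical(f0n$peptide_length, 3L)
})

test_that("scan_orfs agrees with the brute-force oracle on random input", {
  set.seed(77)
  for (k in 1:60) {
    seq <- random_dna(sample(30:300, 1))
    got <- scan_orfs(seq)
    got <- got[got$has_start & got$has_stop,
               c("frame", "start", "end", "peptide_length")]
    exp <- oracle_orfs(seq)
    expect_equal(unname(as.matrix(got)) * 1, unname(as.matrix(exp)) * 1,
                 label = seq)
  }
})

test_that("orf_fraction divides ORF length by transcript length", {
  orf <- data.frame(start = 0L, end = 105L)
  expect_equal(orf_fraction(orf, 300), 0.35)
  expect_equal(orf_fraction(orf, 105), 1.0)
  expect_equal(orf_fraction(NULL, 300), 0)
  expect_error(orf_fraction(orf, 0), "positive")
})

test_that("coding_score is antisymmetric under model swap and additive", {
  st <- default_species_tree()
  nm <- neutral_model(st$tree, kappa = 3, scale = 1)
  cm <- coding_model(nm, omega = 0.2)
  sim <- simulate_alignment(st$tree, list(type = "coding", kappa = 3,
                                          omega = 0.1), 90, seed = 41)
  ra <- make_ra(as.list(sim$rows), reference = "ref")
  sc <- coding_score(ra, 0, nm, cm)
  # per-codon profile sums to the total
  expect_equal(sum(sc$per_codon), sc$total_decibans, tolerance = 1e-6)
  expect_true(is.finite(sc$total_decibans))
  # likelihood-ratio structure: on omega = 0.1 data, a coding model closer
  # to the truth must score higher than a permissive one
  sc_loose <- coding_score(ra, 0, nm, coding_model(nm, omega = 1))
  sc_tight <- coding_score(ra, 0, nm, coding_model(nm, omega = 0.1))
  expect_gt(sc_tight$total_decibans, sc_loose$total_decibans)
})

test_that("coding and neutral simulations score with the expected sign", {
  st <- default_species_tree()
  nm <- neutral_model(st$tree, kappa = 3, scale = 1)
  cm <- coding_model(nm, omega = 0.2)
  set.seed(43)
  for (k in 1:5) {
    simc <- simulate_alignment(st$tree, list(type = "coding", kappa = 3,
                                             omega = 0.1), 300)
    expect_gt(coding_score(make_ra(as.list(simc$rows), reference = "ref"),
                           0, nm, cm)$total_decibans, 0)
    simn <- simulate_alignment(st$tree, list(type = "neutral", kappa = 3),
                               300)
    expect_lt(coding_score(make_ra(as.list(simn$rows), reference = "ref"),
                           0, nm, cm)$total_decibans, 0)
  }
})

test_that("uninformative alignments score zero with a warning", {
  st <- default_species_tree()
  nm <- neutral_model(st$tree, kappa = 3)
  cm <- coding_model(nm)
  rows <- c(list(ref = "ATGGCCGATTAG"),
            setNames(rep(list(strrep("-", 12)), 7),
                     paste0("sp", 1:7)))
  expect_warning(sc <- coding_score(make_ra(rows, reference = "ref"),
                                    0, nm, cm), "no informative")
  expect_identical(sc$total_decibans, 0)
  expect_error(coding_score(make_ra(list(ref = "AT"), reference = "ref"),
                            0, nm, cm), "too short")
})

test_that("reference stop codons contribute zero decibans", {
  st <- default_species_tree()
  nm <- neutral_model(st$tree, kappa = 3)
  cm <- coding_model(nm)
  sim <- simulate_alignment(st$tree, list(type = "coding", kappa = 3,
                                          omega = 0.1), 30, seed = 47)
  rows <- as.list(sim$rows)
  substr(rows$ref, 13, 15) <- "TAA"      # plant a stop mid-reference
  sc <- coding_score(make_ra(rows, reference = "ref"), 0, nm, cm)
  expect_true(sc$ref_stop[5])
  expect_identical(sc$per_codon[5], 0)
})

test_that("classification thresholds are strict and domain hits veto lncRNA", {
  ev <- function(p, f, s, d = FALSE) {
    list(peptide_length = p, orf_fraction = f, score_decibans = s,
         has_domain = d)
  }
  expect_identical(classify_transcript(ev(120, 0.9, 15))$label, "CODING")
  expect_identical(classify_transcript(ev(30, 0.20, -12))$label, "LNCRNA")
  expect_identical(classify_transcript(ev(70, 0.5, 0))$label, "AMBIGUOUS")
  # boundaries fall to AMBIGUOUS (strict inequalities)
  expect_identical(classify_transcript(ev(100, 0.9, 15))$label, "AMBIGUOUS")
  expect_identical(classify_transcript(ev(120, 0.9, 10))$label, "AMBIGUOUS")
  expect_identical(classify_transcript(ev(50, 0.2, -12))$label, "AMBIGUOUS")
  expect_identical(classify_transcript(ev(30, 0.35, -12))$label, "AMBIGUOUS")
  expect_identical(classify_transcript(ev(30, 0.2, -10))$label, "AMBIGUOUS")
  # domain veto
  expect_identical(classify_transcript(ev(30, 0.2, -12, TRUE))$label,
                   "AMBIGUOUS")
  # missing domain evidence warns and assumes FALSE
  e <- ev(30, 0.2, -12); e$has_domain <- NULL
  expect_warning(cl <- classify_transcript(e), "domain")
  expect_identical(cl$label, "LNCRNA")
})

test_that("domain_lookup respects the e-value cutoff and absent ids", {
  tab <- data.frame(transcript_id = c("t1", "t1", "t2"),
                    domain_id = c("PF1", "PF2", "PF3"),
                    e_value = c(1e-10, 0.5, 1e-3))
  expect_true(domain_lookup("t1", tab))
  expect_false(domain_lookup("t2", tab))            # above default cutoff
  expect_true(domain_lookup("t2", tab, max_evalue = 0.01))
  expect_false(domain_lookup("missing", tab))
  expect_false(domain_lookup("t1", NULL))
  expect_false(domain_lookup("t1", tab[0, ]))
})

test_that("per-exon and per-gene scoring behave on a synthetic bundle", {
  st <- study_cache("default", function() {
    generate_study(seed = 101, out_dir = tempfile("study_"))
  })
  genome <- read_genome(st$paths$genome)
  store <- read_maf(st$paths$maf, "ref")
  tree <- read_species_tree(st$paths$tree)
  ref <- read_gtf(st$paths$reference_gtf)
  nm <- fit_neutral_model(store, ref, tree, genome)
  cm <- coding_model(nm, 0.2)
  cod <- st$planted[["novel_cod01"]]
  pg <- score_per_gene(cod, store, nm, cm, genome)
  expect_false(pg$no_start_codon)
  expect_gt(pg$peptide_length, 100)
  expect_gt(pg$score$total_decibans, 10)
  pe <- score_per_exon(cod, store, nm, cm, genome)
  expect_identical(nrow(pe), 1L)
  expect_false(pe$flagged[1])
  # a reference coding gene: best exon frame should carry a positive score
  rg <- ref[[1]]
  pe2 <- score_per_exon(rg, store, nm, cm, genome)
  expect_true(all(pe2$score > 0))
  # single-exon reduction: per-gene evidence mirrors direct classification
  ev <- transcript_evidence(cod, store, nm, cm, genome)
  expect_gt(ev$score_decibans, 10)
  expect_gt(ev$peptide_length, 100)
})

test_that("per-codon profiles cover six frames and clip flanks", {
  st <- study_cache("default", function() {
    generate_study(seed = 101, out_dir = tempfile("study_"))
  })
  genome <- read_genome(st$paths$genome)
  store <- read_maf(st$paths$maf, "ref")
  tree <- read_species_tree(st$paths$tree)
  nm <- neutral_model(tree, kappa = 3)
  cm <- coding_model(nm)
  tx <- st$planted[["novel_cod02"]]
  prof <- score_per_codon(tx, store, nm, cm, flank = 50, genome = genome)
  expect_length(prof, 6L)
  iv <- attr(prof, "interval")
  expect_identical(interval_width(iv),
                   spliced_length(tx) + 100L)
  # all frames consume the same region; codon counts differ only by phase
  ncods <- vapply(prof, `[[`, 0L, "n_codons")
  expect_lte(max(ncods) - min(ncods), 1L)
  # track export round-trips through bedGraph
  bg <- tempfile(fileext = ".bedGraph")
  write_bedgraph_track(prof, 0, tx$chrom, bg)
  lines <- readLines(bg)
  expect_identical(length(lines) - 1L, prof[[1]]$n_codons)
})

test_that("minus-strand per-gene scores match the mirrored construction", {
  # build a tiny two-species store where the transcript on the minus strand
  # is the reverse complement of a plus-strand coding region
  st <- default_species_tree()
  sim <- simulate_alignment(st$tree, list(type = "coding", kappa = 3,
                                          omega = 0.1), 150, seed = 53)
  rows_fwd <- as.list(sim$rows)
  blocks <- lncevo:::alignment_to_blocks(unlist(rows_fwd), "chr1", "ref", 150L)
  store <- read_maf(write_tiny_maf(blocks), "ref")
  genome <- c(chr1 = rows_fwd$ref)
  nm <- neutral_model(st$tree, kappa = 3)
  cm <- coding_model(nm)
  tx_plus <- transcript("p", "chr1", "+", cbind(0, 150))
  tx_minus <- transcript("m", "chr1", "-", cbind(0, 150))
  sp <- score_per_gene(tx_plus, store, nm, cm, genome)
  sm <- score_per_gene(tx_minus, store, nm, cm, genome)
  # the same ORF set exists on both constructions (frames mirrored)
  expect_equal(sp$score$total_decibans, sm$score$total_decibans,
               tolerance = 1e-6)
  expect_identical(sp$peptide_length, sm$peptide_length)
})
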