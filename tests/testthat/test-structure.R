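test_that("fold reproduces hand-enumerable structures", {
  s <- fold("AAAAAA")
  expect_identical(s$n_pairs, 0L)
  expect_identical(s$energy, 0)
  g <- fold("GAAAC")
  expect_identical(g$n_pairs, 1L)
  expect_identical(unname(g$pairs[1, ]), c(0L, 4L))
  expect_identical(g$energy, -3)
  h <- fold("GCGAAACGC")
  expect_identical(h$n_pairs, 3L)
  expect_setequal(paste(h$pairs[, 1], h$pairs[, 2]), c("0 8", "1 7", "2 6"))
  expect_identical(h$energy, -oracle_fold_score("GCGAAACGC"))
  # loop constraint: a pair needs j - i > 3
  expect_identical(fold("GAAC")$n_pairs, 0L)
  expect_identical(fold("GC")$n_pairs, 0L)      # below minimum length
})

test_that("fold equals exhaustive enumeration for short sequences", {
  set.seed(91)
  for (k in 1:40) {
    s <- random_dna(sample(5:14, 1))
    expect_identical(-fold(s)$energy, oracle_fold_score(s), label = s)
    expect_identical(-fold_energy(s), oracle_fold_score(s), label = s)
  }
})

test_that("fold traceback is deterministic and respects nesting", {
  set.seed(92)
  for (k in 1:20) {
    s <- random_dna(60)
    f1 <- fold(s); f2 <- fold(s)
    expect_identical(f1$pairs, f2$pairs)
    if (nrow(f1$pairs) >= 2) {
      # nested: no crossing pairs
      p <- f1$pairs
      for (i in seq_len(nrow(p) - 1)) for (j in (i + 1):nrow(p)) {
        a <- p[i, ]; b <- p[j, ]
        crossing <- (a[1] < b[1] & b[1] < a[2] & a[2] < b[2]) |
          (b[1] < a[1] & a[1] < b[2] & b[2] < a[2])
        expect_false(unname(crossing))
      }
    }
    # structure score equals sum of its own pair scores
    ps <- function(a, b) {
      key <- paste(sort(c(a, b)), collapse = "")
      switch(key, "CG" = 3, "AT" = 2, "GT" = 1, 0)
    }
    chars <- strsplit(s, "")[[1]]
    total <- sum(apply(f1$pairs, 1,
                       function(p2) ps(chars[p2[1] + 1], chars[p2[2] + 1])))
    expect_identical(-f1$energy, total)
  }
})

test_that("consensus_fold rewards compensatory substitutions", {
  # identical rows: consensus equals the single-row fold
  rows <- list(a = "GCGAAACGC", b = "GCGAAACGC")
  cf <- consensus_fold(rows)
  f <- fold("GCGAAACGC")
  expect_identical(cf$structure$pairs, f$pairs)
  # compensatory pair at (1, 7): CG in row a, AT in row b
  rows2 <- list(a = "GCGAAACGC", b = "GAGAAACTC")
  cf2 <- consensus_fold(rows2)
  expect_true(any(cf2$structure$pairs[, 1] == 1 &
                    cf2$structure$pairs[, 2] == 7))
  # the compensatory column pair scores mean + bonus = (3+2)/2 + 1 = 3.5
  codes <- rbind(lncevo:::encode_rna(rows2$a), lncevo:::encode_rna(rows2$b))
  S <- lncevo:::.consensus_matrix_cpp(codes, 1.0, 3.0)
  expect_equal(S[2, 8], 3.5)
  # single row falls back with a warning
  expect_warning(consensus_fold(list(a = "GCGAAACGC")), ">= 2 rows")
})

test_that("mfe_zscore flags stable hairpins and is seed-stable", {
  expect_equal(mfe_zscore("AAAAAAAAAAAAAA", seed = 1), 0)  # nothing folds
  z <- mfe_zscore("GGGGGAAAACCCCC", n_shuffles = 100, seed = 7)
  expect_lt(z, -1)
  expect_identical(mfe_zscore("GGGGGAAAACCCCC", n_shuffles = 100, seed = 7),
                   z)
  # sampling stability: two seeds agree within sampling error at n = 1000
  s <- paste0(random_dna(20), "GGGGGAAAACCCCC", random_dna(20))
  z1 <- mfe_zscore(s, n_shuffles = 1000, seed = 1)
  z2 <- mfe_zscore(s, n_shuffles = 1000, seed = 2)
  expect_lt(abs(z1 - z2), 0.5)
  expect_error(mfe_zscore("ACGT", n_shuffles = 10), ">= 30")
})

test_that("sci is 1 for identical rows and small for unrelated rows", {
  set.seed(93)
  row <- paste0("GGGGG", random_dna(30), "CCCCC")
  expect_equal(sci(list(a = row, b = row)), 1, tolerance = 1e-9)
  expect_equal(sci(list(a = "AAAAAAAA", b = "AAAAAAAA")), 0)  # nothing folds
  # independently shuffled rows share no structure: sci well below 1
  # (discrimination grows with row count; 8 rows is the pipeline regime)
  vals <- replicate(10, {
    rows <- lapply(1:8, function(i) {
      paste(sample(strsplit(row, "")[[1]]), collapse = "")
    })
    names(rows) <- paste0("r", 1:8)
    sci(rows)
  })
  expect_lt(mean(vals), 0.6)
})

test_that("structure_score combines z and sci through the logistic map", {
  # mean_z = 0, sci = 0 -> logistic(-4) ~ 0.018
  rows <- list(ref = strrep("A", 60), spA = strrep("A", 60))
  ss <- structure_score(rows, n_shuffles = 50, seed = 1)
  expect_equal(ss$combined, plogis(-4), tolerance = 1e-9)
  expect_false(ss$high_confidence)
  # degenerate window
  ss0 <- structure_score(list(ref = strrep("-", 50)), n_shuffles = 50)
  expect_identical(ss0$combined, 0)
  # monotonicity in weights: stronger structure evidence raises the score
  w <- default_structure_weights()
  expect_gt(w$w1, 0); expect_gt(w$w2, 0)
})

test_that("structure_score separates conserved hairpins from shuffles", {
  st <- default_species_tree()
  pairs <- lncevo:::hairpin_pairs(120L, 25L, 5L)
  set.seed(95)
  conserved <- replicate(12, {
    sim <- simulate_alignment(st$tree,
                              list(type = "structured", pairs = pairs,
                                   compensatory_prob = 0.9,
                                   decay_rate = 0, kappa = 3), 120)
    structure_score(as.list(sim$rows), n_shuffles = 50,
                    seed = sample.int(1e6, 1))$combined
  })
  controls <- replicate(12, {
    sim <- simulate_alignment(st$tree, list(type = "neutral", kappa = 3), 120)
    rows <- lapply(sim$rows, function(r) {
      paste(sample(strsplit(r, "")[[1]]), collapse = "")
    })
    structure_score(rows, n_shuffles = 50,
                    seed = sample.int(1e6, 1))$combined
  })
  # default (uncalibrated) weights: a clear score gap and few false calls;
  # the >=80% calibrated detection rate is asserted by the acceptance suite
  expect_gt(mean(conserved), mean(controls) + 0.3)
  expect_lte(mean(controls > 0.5), 0.2)
})

test_that("scan_windows merges overlapping confident windows into loci", {
  st <- study_cache("default", function() {
    generate_study(seed = 101, out_dir = tempfile("study_"))
  })
  store <- read_maf(st$paths$maf, "ref")
  genome <- read_genome(st$paths$genome)
  tree <- read_species_tree(st$paths$tree)
  # a structured lncRNA should yield at least one locus over its window
  sid <- names(st$truth$structures)[1]
  gene <- st$planted[[sid]]
  loci <- scan_windows(gene, store, tree$tip.label, n_shuffles = 50,
                       seed = 5, genome = genome)
  expect_gte(length(loci), 1L)
  # loci are maximal: no two overlap
  if (length(loci) >= 2) {
    ivs <- t(vapply(loci, function(l) c(l$interval$start, l$interval$end),
                    numeric(2)))
    ivs <- ivs[order(ivs[, 1]), , drop = FALSE]
    expect_true(all(ivs[-1, 1] >= ivs[-nrow(ivs), 2]))
  }
  # the locus covers the planted window midpoint
  win <- st$truth$structures[[sid]]$window
  mid <- mean(win)
  expect_true(any(vapply(loci, function(l) {
    l$interval$start <= mid && mid <= l$interval$end
  }, logical(1))))
  # an unstructured neutral gene yields no loci (seeded)
  plain <- st$planted[["novel_amb01"]]
  loci0 <- scan_windows(plain, store, tree$tip.label, n_shuffles = 50,
                        seed = 6, genome = genome)
  expect_length(loci0, 0L)
})

test_that("species_structure_presence needs alignability and structure", {
  # a species identical to the reference over a confident hairpin locus is
  # retained; an all-gap species is absent regardless of structure
  set.seed(99)
  hairpin <- paste0(random_dna(20), "GGCGCGGCGGGCCG", strrep("A", 6),
                    "CGGCCCGCCGCGCC", random_dna(20))
  rows <- c(ref = hairpin, spA = hairpin, spB = strrep("-", nchar(hairpin)))
  blocks <- lncevo:::alignment_to_blocks(rows, "chr1", "ref", 1000L)
  store0 <- read_maf(write_tiny_maf(blocks), "ref")
  locus0 <- structure(list(
    interval = genomic_interval("chr1", 0, nchar(hairpin), "+"),
    gene_id = "g"), class = "structure_locus")
  expect_true(species_structure_presence(locus0, store0, "spA",
                                         n_shuffles = 50, seed = 3))
  expect_false(species_structure_presence(locus0, store0, "spB",
                                          n_shuffles = 50, seed = 3))
  st <- study_cache("default", function() {
    generate_study(seed = 101, out_dir = tempfile("study_"))
  })
  store <- read_maf(st$paths$maf, "ref")
  genome <- read_genome(st$paths$genome)
  ab <- names(st$truth$ablation)
  # an ablated gene is absent regardless of structure
  abid <- intersect(names(st$truth$structures), ab)
  if (length(abid)) {
    tr2 <- st$truth$structures[[abid[1]]]
    lost_sp <- st$truth$ablation[[abid[1]]][1]
    locus2 <- structure(list(
      interval = genomic_interval("chr1", tr2$window[1], tr2$window[2], "+"),
      gene_id = abid[1]), class = "structure_locus")
    expect_false(species_structure_presence(locus2, store, lost_sp,
                                            n_shuffles = 50, seed = 3,
                                            genome = genome))
  }
})

test_that("divergence_regression fits slopes and the ANCOVA interaction", {
  # exact fit: y = 2x in both groups -> identical slopes, p ~ 1
  ages <- c(1, 5, 10, 25, 50)
  pr <- data.frame(species = letters[1:5], root_age = ages, count = 2 * ages)
  ps <- data.frame(species = letters[1:5], root_age = ages,
                   count = 2 * ages + 3)
  res <- divergence_regression(pr, ps)
  expect_equal(res$regions$slope, 2, tolerance = 1e-10)
  expect_equal(res$structures$slope, 2, tolerance = 1e-10)
  expect_gt(res$ancova_p, 0.99)
  # clearly different slopes with modest noise are detected
  set.seed(97)
  ps2 <- data.frame(species = letters[1:5], root_age = ages,
                    count = -3 * ages + 200 + rnorm(5, 0, 1))
  pr2 <- data.frame(species = letters[1:5], root_age = ages,
                    count = -0.5 * ages + 200 + rnorm(5, 0, 1))
  res2 <- divergence_regression(pr2, ps2)
  expect_lt(res2$ancova_p, 0.01)
  expect_lt(res2$structures$slope, res2$regions$slope)
  # degenerate designs error out with a named deficiency
  expect_error(divergence_regression(pr[1:2, ], ps), ">= 3")
  prc <- pr; prc$root_age <- 5
  expect_error(divergence_regression(prc, ps), "degenerate")
})

test_that("structure loci export as BED with capped scores", {
  locus <- structure(list(
    interval = genomic_interval("chr1", 100, 220, "+"),
    score = structure(list(mean_z = -3, sci = 0.9, combined = 0.87,
                           high_confidence = TRUE),
                      class = "structure_score"),
    n_windows = 2L, clipped = FALSE, gene_id = "g1"),
    class = "structure_locus")
  bed <- tempfile(fileext = ".bed")
  write_structure_bed(list(locus), bed)
  f <- strsplit(readLines(bed), "\t")[[1]]
  expect_identical(f[1:4], c("chr1", "100", "220", "g1"))
  expect_identical(f[5], "870")
})
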