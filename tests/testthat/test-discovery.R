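mk <- function(id, chrom, strand, ...) {
  transcript(id, chrom, strand, rbind(...))
}

test_that("intersect_assemblies requires compatible-strand exonic overlap", {
  a1 <- mk("a1", "chr1", "+", c(100, 300))
  a2 <- mk("a2", "chr1", "+", c(1000, 1200))
  a3 <- mk("a3", "chr1", "*", c(2000, 2200))
  b_same <- mk("b1", "chr1", "+", c(299, 500))      # 1-nt overlap with a1
  b_opp <- mk("b2", "chr1", "-", c(1000, 1200))
  b_unk <- mk("b3", "chr1", "-", c(2100, 2300))
  res <- intersect_assemblies(list(a1, a2, a3), list(b_same, b_opp, b_unk))
  ids <- vapply(res, `[[`, "", "id")
  expect_setequal(ids, c("a1", "a3"))    # opposite known strands do not count
  expect_true(all(vapply(res, `[[`, TRUE, "supported_by_both")))
  # identity and empty-set behavior
  expect_length(intersect_assemblies(list(a1, a2), list(a1, a2)), 2L)
  expect_length(intersect_assemblies(list(), list(a1)), 0L)
  expect_length(intersect_assemblies(list(a1), list()), 0L)
})

test_that("assign_class_code follows the OTHER > X > I > U precedence", {
  ref <- list(mk("r1", "chr1", "+", c(1000, 1200), c(1800, 2000)))
  # exonic overlap, same strand -> OTHER
  expect_identical(assign_class_code(mk("t", "chr1", "+", c(1100, 1300)), ref),
                   "OTHER")
  # exonic overlap, opposite strand -> X
  expect_identical(assign_class_code(mk("t", "chr1", "-", c(1100, 1300)), ref),
                   "X")
  # inside the intron, either strand -> I
  expect_identical(assign_class_code(mk("t", "chr1", "+", c(1300, 1500)), ref),
                   "I")
  expect_identical(assign_class_code(mk("t", "chr1", "-", c(1300, 1500)), ref),
                   "I")
  # far away -> U
  expect_identical(assign_class_code(mk("t", "chr1", "+", c(9000, 9200)), ref),
                   "U")
  # different chromosome -> U
  expect_identical(assign_class_code(mk("t", "chr2", "+", c(1100, 1300)), ref),
                   "U")
  # partial span overlap without exonic overlap -> OTHER
  expect_identical(assign_class_code(mk("t", "chr1", "+", c(1300, 2500)), ref),
                   "OTHER")
  # totality + determinism over random transcripts
  set.seed(11)
  for (k in 1:50) {
    s <- sample(0:3000, 1); tx <- mk("t", "chr1", sample(c("+", "-", "*"), 1),
                                     c(s, s + sample(50:500, 1)))
    c1 <- assign_class_code(tx, ref)
    expect_true(c1 %in% c("I", "U", "X", "OTHER"))
    expect_identical(assign_class_code(tx, ref), c1)
  }
})

test_that("length_filter keeps the 200-nt boundary inclusive", {
  t199 <- mk("t199", "chr1", "+", c(0, 199))
  t200 <- mk("t200", "chr1", "+", c(0, 100), c(150, 250))
  out <- length_filter(list(t199, t200))
  expect_identical(vapply(out, `[[`, "", "id"), "t200")
  expect_length(length_filter(list()), 0L)
})

test_that("find_duplicate_complements matches the brute-force oracle", {
  # hand-checked example: ratio 60/140 < 0.5 is not reported
  t1 <- mk("t1", "chr1", "+", c(0, 100))
  t2 <- mk("t2", "chr1", "-", c(40, 140))
  expect_identical(nrow(find_duplicate_complements(list(t1, t2))), 0L)
  t3 <- mk("t3", "chr1", "-", c(0, 100))
  pairs <- find_duplicate_complements(list(t1, t3))
  expect_identical(nrow(pairs), 1L)
  expect_equal(pairs$fraction, 1.0)
  # same strand never reported
  t4 <- mk("t4", "chr1", "+", c(0, 100))
  expect_identical(nrow(find_duplicate_complements(list(t1, t4))), 0L)
  # randomized equivalence with the O(n^2) oracle
  set.seed(5)
  n <- 200
  df <- data.frame(id = sprintf("x%03d", seq_len(n)),
                   chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
                   strand = sample(c("+", "-"), n, replace = TRUE),
                   start = sample(0:2000, n, replace = TRUE))
  df$end <- df$start + sample(50:300, n, replace = TRUE)
  txs <- lapply(seq_len(n), function(i) {
    mk(df$id[i], df$chrom[i], df$strand[i], c(df$start[i], df$end[i]))
  })
  got <- find_duplicate_complements(txs)
  got_keys <- sort(paste(got$id1, got$id2, sep = "|"))
  expect_identical(got_keys, oracle_duplicates(df))
})

test_that("compare_gene_sets uses one-directional 50% exonic coverage", {
  a <- mk("a", "chr1", "+", c(0, 300))
  b_half <- mk("b", "chr1", "+", c(150, 500))      # covers exactly 150/300
  expect_identical(compare_gene_sets(list(a), list(b_half)), "a")
  b_less <- mk("b", "chr1", "+", c(151, 500))
  expect_length(compare_gene_sets(list(a), list(b_less)), 0L)
  expect_identical(compare_gene_sets(list(a), list(a)), "a")
  expect_length(compare_gene_sets(list(a), list()), 0L)
})

test_that("compute_fpkm implements count * 1e9 / (len * lib)", {
  expect_equal(compute_fpkm(100, 1000, 1e7), 10)
  expect_equal(compute_fpkm(0, 1000, 1e7), 0)
  expect_equal(compute_fpkm(100, 1000, 2e7), 5)   # doubling library halves it
  expect_error(compute_fpkm(1, 0, 1e6), "exonic_length")
  expect_error(compute_fpkm(1, 100, 0), "total_mapped")
})

test_that("exon_count_summary reports per-class means and missing classes", {
  txs <- list(mk("a", "chr1", "+", c(0, 100)),
              mk("b", "chr1", "+", c(0, 100), c(200, 300)),
              mk("c", "chr1", "+", c(0, 100), c(200, 300), c(400, 500)))
  s <- exon_count_summary(txs, labels = c("L", "L", "L"))
  expect_equal(unname(s$means["L"]), 2.0)
  s2 <- exon_count_summary(txs, labels = c("L", "L", "C"))
  expect_equal(unname(s2$means["C"]), 3.0)
  s3 <- exon_count_summary(list(mk("a", "chr1", "+", c(0, 100))),
                           labels = "L")
  expect_equal(unname(s3$means["L"]), 1.0)
})

test_that("discovery cascade counts are monotone on a synthetic study", {
  st <- study_cache("default", function() {
    generate_study(seed = 101, out_dir = tempfile("study_"))
  })
  cfg <- pipeline_config(genome = st$paths$genome,
                         reference_gtf = st$paths$reference_gtf,
                         assembler_a = st$paths$assembler_a,
                         assembler_b = st$paths$assembler_b,
                         maf = st$paths$maf, tree = st$paths$tree,
                         out_dir = tempfile("out_"), seed = 1)
  d <- run_discover(cfg)
  counts <- d$stage_counts$count
  cascade <- counts[3:5]                    # supported -> class -> length
  expect_true(all(diff(cascade) <= 0))
  expect_lte(cascade[1], min(counts[1:2]))
  # planted duplicate pairs are recovered exactly
  truth <- st$truth$transcripts
  dup_ids <- names(Filter(function(t) t$class == "duplicate_pair", truth))
  surviving <- intersect(dup_ids, vapply(d$candidates, `[[`, "", "id"))
  exp_pairs <- unique(t(apply(cbind(surviving,
    vapply(truth[surviving], `[[`, "", "partner")), 1, sort)))
  exp_pairs <- exp_pairs[exp_pairs[, 1] %in% surviving &
                           exp_pairs[, 2] %in% surviving, , drop = FALSE]
  got <- find_duplicate_complements(d$candidates)
  expect_setequal(paste(got$id1, got$id2),
                  unique(paste(exp_pairs[, 1], exp_pairs[, 2])))
})
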