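test_that("generate_genome honors GC, plants clean genes, and is seeded", {
  g1 <- generate_genome(length = 1e5, gc = 0.5, seed = 13, n_genes = 4)
  g2 <- generate_genome(length = 1e5, gc = 0.5, seed = 13, n_genes = 4)
  expect_identical(g1$genome, g2$genome)              # byte determinism
  g3 <- generate_genome(length = 1e5, gc = 0.5, seed = 14, n_genes = 4)
  expect_false(identical(g1$genome, g3$genome))
  chars <- strsplit(g1$genome[["chr1"]], "")[[1]]
  gc_obs <- mean(chars %in% c("G", "C"))
  expect_lt(abs(gc_obs - 0.5), 0.02)                  # binomial bound
  # planted genes are non-overlapping and carry full-length ORFs
  spans <- t(vapply(g1$genes, function(t) {
    c(min(t$exons[, "start"]), max(t$exons[, "end"]))
  }, numeric(2)))
  spans <- spans[order(spans[, 1]), ]
  expect_true(all(spans[-1, 1] >= spans[-nrow(spans), 2]))
  for (tx in g1$genes) {
    cds <- spliced_sequence(g1$genome, tx)
    expect_identical(substr(cds, 1, 3), "ATG")
    expect_true(substr(cds, nchar(cds) - 2, nchar(cds)) %in%
                  c("TAA", "TAG", "TGA"))
    expect_identical(nchar(cds) %% 3L, 0L)
  }
  expect_error(generate_genome(length = 5000), ">= 10 kb")
  expect_error(generate_genome(length = 2e4, gc = 1.2), "gc")
})

test_that("simulate_alignment is deterministic and degenerate at scale 0", {
  tree <- tiny_tree(4)
  a <- simulate_alignment(tree, list(type = "neutral", kappa = 2), 100,
                          seed = 17)
  b <- simulate_alignment(tree, list(type = "neutral", kappa = 2), 100,
                          seed = 17)
  expect_identical(a$rows, b$rows)
  frozen <- simulate_alignment(tree, list(type = "neutral", kappa = 2,
                                          scale = 0), 50, seed = 18)
  expect_identical(length(unique(frozen$rows)), 1L)   # all rows = root
  cod <- simulate_alignment(tree, list(type = "coding", omega = 0.1,
                                       kappa = 2), 90, seed = 19)
  expect_identical(unique(nchar(cod$rows)), 90L)
  # coding rows contain no stop codons (MG94 state space)
  for (r in cod$rows) {
    cods <- substring(r, seq(1, 88, 3), seq(3, 90, 3))
    expect_false(any(cods %in% c("TAA", "TAG", "TGA")))
  }
  expect_error(simulate_alignment(tree, list(type = "coding"), 91, seed = 1),
               "multiple of 3")
  expect_error(simulate_alignment(tree, list(type = "nope"), 30, seed = 1),
               "unknown")
})

test_that("structured simulation keeps pairability and decays with depth", {
  st <- default_species_tree()
  pairs <- lncevo:::hairpin_pairs(120L, 20L, 5L)
  sim <- simulate_alignment(st$tree,
                            list(type = "structured", pairs = pairs,
                                 compensatory_prob = 1, decay_rate = 0,
                                 kappa = 3), 120, seed = 23)
  # with decay 0 and fully compensatory evolution, every species keeps
  # every stem pair pairable
  pairable <- function(a, b) {
    paste0(a, b) %in% c("GC", "CG", "AT", "TA", "GT", "TG")
  }
  for (sp in names(sim$rows)) {
    chars <- strsplit(sim$rows[[sp]], "")[[1]]
    ok <- apply(pairs, 1, function(p) pairable(chars[p[1]], chars[p[2]]))
    expect_true(all(ok), label = sp)
  }
  expect_true(all(unlist(sim$truth$structure_present)))
  # strong decay: distal species lose the structure more often than
  # near ones, and loss is inherited (monotone along the ladder)
  set.seed(29)
  pres <- replicate(40, {
    s <- simulate_alignment(st$tree,
                            list(type = "structured", pairs = pairs,
                                 compensatory_prob = 0.9, decay_rate = 3,
                                 kappa = 3, protect_tip = "ref"), 60,
                            seed = NULL)
    unlist(s$truth$structure_present)
  })
  expect_true(all(pres["ref", ]))           # reference lineage protected
  n_present <- colSums(pres)
  expect_lt(mean(n_present), 8)             # distal losses happen
  # retention declines with divergence depth on average
  rates <- rowMeans(pres)[c("sp1", "sp4", "sp7")]
  expect_true(rates["sp1"] >= rates["sp4"] && rates["sp4"] >= rates["sp7"])
})

test_that("generate_assembler_calls applies drop, jitter, and spurious noise", {
  planted <- lapply(1:20, function(k) {
    s <- 1000 * k
    transcript(sprintf("t%02d", k), "chr1", "+", cbind(s, s + 400),
               class_code = "U", source = "planted")
  })
  clean <- generate_assembler_calls(planted,
                                    noise = list(drop_prob = c(0, 0),
                                                 jitter_sd = 0,
                                                 n_spurious = 0L,
                                                 genome_length = 1e5,
                                                 chrom = "chr1"),
                                    seed = 31)
  expect_identical(length(clean$set_a), 20L)
  expect_identical(length(clean$set_b), 20L)
  expect_identical(clean$set_a$t01$exons, planted[[1]]$exons)
  # full drop on one side empties the intersection
  gone <- generate_assembler_calls(planted,
                                   noise = list(drop_prob = c(1, 0),
                                                jitter_sd = 0,
                                                n_spurious = 0L,
                                                genome_length = 1e5,
                                                chrom = "chr1"),
                                   seed = 31)
  expect_identical(length(gone$set_a), 0L)
  expect_length(intersect_assemblies(gone$set_a, gone$set_b), 0L)
  noisy <- generate_assembler_calls(planted,
                                    noise = list(drop_prob = c(0.3, 0.3),
                                                 jitter_sd = 4,
                                                 n_spurious = 5L,
                                                 genome_length = 1e5,
                                                 chrom = "chr1"),
                                    seed = 33)
  expect_identical(sum(noisy$truth$spurious), 10L)
  expect_identical(sum(!noisy$truth$in_a & !noisy$truth$spurious),
                   20L - sum(noisy$truth$in_a & !noisy$truth$spurious))
  # truth flags agree with set membership
  for (i in seq_len(nrow(noisy$truth))) {
    id <- noisy$truth$id[i]
    expect_identical(id %in% names(noisy$set_a), noisy$truth$in_a[i])
    expect_identical(id %in% names(noisy$set_b), noisy$truth$in_b[i])
  }
})

test_that("generate_study is deterministic and internally consistent", {
  st <- study_cache("default", function() {
    generate_study(seed = 101, out_dir = tempfile("study_"))
  })
  # reference genome equals the MAF reference rows
  genome <- read_genome(st$paths$genome)
  expect_identical(nchar(genome[["chr1"]]), 200000L)
  store <- read_maf(st$paths$maf, "ref")
  ra <- extract_region_alignment(store, genomic_interval("chr1", 0, 5000),
                                 character(0))
  expect_identical(unname(ra$rows[["ref"]]),
                   substr(genome[["chr1"]], 1, 5000))
  # every planted transcript has exactly one truth record
  expect_setequal(names(st$planted), names(st$truth$transcripts))
  # truth JSON reloads
  tr <- jsonlite::read_json(st$paths$truth)
  expect_setequal(names(tr$transcripts), names(st$planted))
  # byte determinism of the bundle
  st2 <- generate_study(seed = 101, out_dir = tempfile("study_"))
  for (f in c("genome", "reference_gtf", "assembler_a", "maf", "tree")) {
    expect_identical(readLines(st$paths[[f]]), readLines(st2$paths[[f]]),
                     label = f)
  }
  # planted class codes are recovered by assign_class_code
  reference <- read_gtf(st$paths$reference_gtf)
  for (id in names(st$planted)) {
    tx <- st$planted[[id]]
    expect_identical(assign_class_code(tx, reference),
                     st$truth$transcripts[[id]]$locus_class, label = id)
  }
})

test_that("calibration windows separate under the default tree", {
  st <- default_species_tree()
  w <- synthetic_structure_windows(st$tree, n_pos = 8, n_neg = 8, seed = 7)
  expect_length(w$alignments, 16L)
  weights <- calibrate_score_weights(w$alignments, w$labels,
                                     n_shuffles = 40, seed = 8)
  scores <- vapply(seq_along(w$alignments), function(i) {
    structure_score(w$alignments[[i]], weights, n_shuffles = 40,
                    seed = 100 + i)$combined
  }, 0)
  expect_gt(mean(scores[w$labels]), mean(scores[!w$labels]) + 0.3)
})
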