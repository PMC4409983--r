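#' Pipeline orchestration
#'
#' Stages mirror the discovery flow chart: `run_discover` (dual-assembler
#' support, class codes, length cutoff), `run_classify` (ORF + coding
#' potential + domains -> CODING / LNCRNA / AMBIGUOUS), `run_conserve`
#' (presence/absence and per-gene conservation tests), `run_structure`
#' (structure loci, per-species retention, divergence regression) and
#' `run_all`. Every report embeds the configuration echo, its hash, the
#' seed and the package version; no timestamps are written, so identical
#' configurations produce byte-identical reports.
#'
#' @name pipeline_cli
NULL

#' Build a pipeline configuration
#'
#' All thresholds default to the printed cascade values: 200-nt length
#' cutoff, 100/50-aa peptide bounds, 0.35 ORF fraction, +/-10 deciban score
#' bounds, 0.10 alignable coverage, 0.5 structure-score cutoff with 120/40
#' windows.
#'
#' @param genome,reference_gtf,assembler_a,assembler_b,maf,tree input paths.
#' @param root_ages,domains optional input paths (TSV).
#' @param out_dir output directory.
#' @param seed RNG seed used by stochastic stages (structure shuffles).
#' @param ... overrides for any default field.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(genome, reference_gtf, assembler_a, assembler_b,
                            maf, tree, root_ages = NULL, domains = NULL,
                            out_dir = "lncevo_out", seed = 1L, ...) {
  cfg <- list(genome = genome, reference_gtf = reference_gtf,
              assembler_a = assembler_a, assembler_b = assembler_b,
              maf = maf, tree = tree, root_ages = root_ages,
              domains = domains, out_dir = out_dir, seed = as.integer(seed),
              reference_species = "ref",
              min_len = 200L, min_overlap = 1L,
              coding_min_peptide = 100, coding_min_score = 10,
              lnc_max_peptide = 50, lnc_max_orf_fraction = 0.35,
              lnc_max_score = -10, omega = 0.2, domain_max_evalue = 1e-5,
              min_cov = 0.10, structure_threshold = 0.5,
              structure_window = 120L, structure_step = 40L,
              n_shuffles = 50L)
  over <- list(...)
  cfg[names(over)] <- over
  structure(cfg, class = "pipeline_config")
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, null = "null"),
             tmp)
  unname(tools::md5sum(tmp))
}

provenance <- function(cfg) {
  list(config = unclass(cfg), config_hash = config_hash(cfg),
       seed = cfg$seed,
       package_version = as.character(utils::packageVersion("lncevo")))
}

write_report <- function(obj, path) {
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

check_inputs <- function(cfg, fields) {
  for (f in fields) {
    p <- cfg[[f]]
    if (is.null(p) || !file.exists(p)) {
      stop("missing input for stage: ", f, " (", p %||% "NULL", ")")
    }
  }
}

#' Run the discovery cascade
#'
#' Intersects the two assembler sets, assigns class codes against the
#' reference annotation, keeps classes I/U/X, applies the length cutoff,
#' and reports per-stage counts plus the complementary-strand duplicate
#' pairs among the survivors.
#'
#' @param cfg a `pipeline_config`.
#' @return list with `candidates` (transcripts), `stage_counts`,
#'   `duplicates`, and output `paths`.
#' @export
run_discover <- function(cfg) {
  check_inputs(cfg, c("assembler_a", "assembler_b", "reference_gtf"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  set_a <- read_gtf(cfg$assembler_a)
  set_b <- read_gtf(cfg$assembler_b)
  reference <- read_gtf(cfg$reference_gtf)
  supported <- intersect_assemblies(set_a, set_b,
                                    min_overlap = cfg$min_overlap)
  coded <- lapply(supported, function(t) {
    t$class_code <- assign_class_code(t, reference)
    t
  })
  kept_class <- Filter(function(t) t$class_code %in% c("I", "U", "X"), coded)
  kept_len <- length_filter(kept_class, cfg$min_len)
  dup <- find_duplicate_complements(kept_len)
  stage_counts <- data.frame(
    stage = c("assembler_a", "assembler_b", "supported_by_both",
              "class_IUX", "length_filter"),
    count = c(length(set_a), length(set_b), length(supported),
              length(kept_class), length(kept_len)))
  paths <- list(candidates_gtf = file.path(cfg$out_dir, "candidates.gtf"),
                stage_counts = file.path(cfg$out_dir, "stage_counts.tsv"),
                duplicates = file.path(cfg$out_dir, "duplicate_pairs.tsv"),
                report = file.path(cfg$out_dir, "discover_report.json"))
  write_gtf(kept_len, paths$candidates_gtf)
  write.table(stage_counts, paths$stage_counts, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(dup, paths$duplicates, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_report(c(provenance(cfg),
                 list(stage_counts = stage_counts,
                      n_duplicate_pairs = nrow(dup))), paths$report)
  list(candidates = kept_len, stage_counts = stage_counts, duplicates = dup,
       paths = paths)
}

load_pipeline_inputs <- function(cfg) {
  check_inputs(cfg, c("genome", "reference_gtf", "maf", "tree"))
  list(genome = read_genome(cfg$genome),
       reference = read_gtf(cfg$reference_gtf),
       store = read_maf(cfg$maf, cfg$reference_species),
       tree = read_species_tree(cfg$tree))
}

#' Classify discovery candidates
#'
#' Fits (or reuses) the neutral model on four-fold degenerate sites of the
#' reference annotation, scores each candidate's best start-to-stop ORF
#' under the codon/neutral likelihood ratio, and applies the printed
#' thresholds together with the ORF statistics and optional domain hits.
#'
#' @param cfg a `pipeline_config`.
#' @param discovered optional result of [run_discover()] (re-read from disk
#'   otherwise).
#' @param inputs optional preloaded inputs (genome/reference/store/tree).
#' @return list with `table` (classification data.frame), `neutral`,
#'   `coding` models, and `paths`.
#' @export
run_classify <- function(cfg, discovered = NULL, inputs = NULL) {
  if (is.null(inputs)) inputs <- load_pipeline_inputs(cfg)
  if (is.null(discovered)) {
    cand_path <- file.path(cfg$out_dir, "candidates.gtf")
    if (!file.exists(cand_path)) stop("run_discover output not found: ",
                                      cand_path)
    candidates <- read_gtf(cand_path)
  } else {
    candidates <- discovered$candidates
  }
  domains <- if (!is.null(cfg$domains) && file.exists(cfg$domains)) {
    read.delim(cfg$domains, stringsAsFactors = FALSE)
  } else NULL
  neutral <- fit_neutral_model(inputs$store, inputs$reference, inputs$tree,
                               inputs$genome)
  coding <- coding_model(neutral, cfg$omega)
  rows <- lapply(candidates, function(tx) {
    ev <- transcript_evidence(tx, inputs$store, neutral, coding,
                              inputs$genome)
    evidence <- list(peptide_length = ev$peptide_length,
                     orf_fraction = ev$orf_fraction,
                     score_decibans = ev$score_decibans,
                     has_domain = domain_lookup(tx$id, domains,
                                                cfg$domain_max_evalue))
    score <- ev$score_decibans
    cls <- classify_transcript(evidence, list(
      coding_min_peptide = cfg$coding_min_peptide,
      coding_min_score = cfg$coding_min_score,
      lnc_max_peptide = cfg$lnc_max_peptide,
      lnc_max_orf_fraction = cfg$lnc_max_orf_fraction,
      lnc_max_score = cfg$lnc_max_score))
    data.frame(id = tx$id, class_code = tx$class_code,
               peptide_length = evidence$peptide_length,
               orf_fraction = round(evidence$orf_fraction, 4),
               score_decibans = round(score, 3),
               has_domain = evidence$has_domain, label = cls$label)
  })
  tab <- do.call(rbind, rows)
  paths <- list(classification = file.path(cfg$out_dir, "classification.tsv"),
                report = file.path(cfg$out_dir, "classify_report.json"))
  write.table(tab, paths$classification, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_report(c(provenance(cfg),
                 list(label_counts = as.list(table(tab$label)),
                      neutral_kappa = neutral$kappa,
                      neutral_scale = neutral$scale,
                      fourfold_columns = neutral$n_columns)),
               paths$report)
  list(table = tab, neutral = neutral, coding = coding, paths = paths)
}

#' Presence/absence and conservation stage
#'
#' @param cfg a `pipeline_config`.
#' @param classified optional result of [run_classify()].
#' @param inputs optional preloaded inputs.
#' @return list with `presence`, `conservation` (per-gene data.frame),
#'   `class_compare`, and `paths`.
#' @export
run_conserve <- function(cfg, classified = NULL, inputs = NULL) {
  if (is.null(inputs)) inputs <- load_pipeline_inputs(cfg)
  if (is.null(classified)) {
    cls_path <- file.path(cfg$out_dir, "classification.tsv")
    if (!file.exists(cls_path)) stop("run_classify output not found")
    tab <- read.delim(cls_path, stringsAsFactors = FALSE)
    neutral <- fit_neutral_model(inputs$store, inputs$reference, inputs$tree,
                                 inputs$genome)
  } else {
    tab <- classified$table
    neutral <- classified$neutral
  }
  candidates <- read_gtf(file.path(cfg$out_dir, "candidates.gtf"))
  candidates <- candidates[tab$id]
  labels <- setNames(tab$label, tab$id)
  species <- setdiff(inputs$tree$tip.label, cfg$reference_species)
  pm <- presence_matrix(candidates, inputs$store, species,
                        labels = unname(labels[names(candidates)]),
                        min_cov = cfg$min_cov, genome = inputs$genome)
  cons <- lapply(candidates, function(tx) {
    r <- conservation_test(tx, inputs$store, neutral, inputs$genome)
    data.frame(id = r$id, r_hat = r$r_hat, lambda = r$lambda,
               p_value = r$p_value, neg_log10_p = r$neg_log10_p,
               testable = r$testable)
  })
  cons <- do.call(rbind, cons)
  cons$label <- unname(labels[cons$id])
  by_class <- split(cons$neg_log10_p[cons$testable], cons$label[cons$testable])
  cmp <- if (length(by_class) >= 2L) class_conservation_compare(by_class) else
    NULL
  paths <- list(presence = file.path(cfg$out_dir, "presence_matrix.tsv"),
                class_percent = file.path(cfg$out_dir,
                                          "presence_class_percent.tsv"),
                conservation = file.path(cfg$out_dir, "conservation.tsv"),
                report = file.path(cfg$out_dir, "conserve_report.json"))
  write.table(data.frame(id = rownames(pm$present), pm$present,
                         check.names = FALSE),
              paths$presence, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(pm$class_percent, paths$class_percent, sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(cons, paths$conservation, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_report(c(provenance(cfg),
                 list(class_summary = if (!is.null(cmp)) cmp$class_summary,
                      pairwise = if (!is.null(cmp)) cmp$pairwise)),
               paths$report)
  list(presence = pm, conservation = cons, class_compare = cmp,
       neutral = neutral, paths = paths)
}

#' Structure screen and divergence regression stage
#'
#' Scans LNCRNA- and CODING-labelled candidates for high-confidence
#' structure loci, tabulates per-species retention, and (when a root-age
#' table is configured) regresses retained counts of conserved regions and
#' structures on divergence time with the ANCOVA slope test.
#'
#' @param cfg a `pipeline_config`.
#' @param conserved optional result of [run_conserve()].
#' @param inputs optional preloaded inputs.
#' @return list with `loci`, `species_counts`, `divergence`, `paths`.
#' @export
run_structure <- function(cfg, conserved = NULL, inputs = NULL) {
  if (is.null(inputs)) inputs <- load_pipeline_inputs(cfg)
  cls_path <- file.path(cfg$out_dir, "classification.tsv")
  if (!file.exists(cls_path)) stop("run_classify output not found")
  tab <- read.delim(cls_path, stringsAsFactors = FALSE)
  candidates <- read_gtf(file.path(cfg$out_dir, "candidates.gtf"))
  species <- setdiff(inputs$tree$tip.label, cfg$reference_species)
  scan_ids <- tab$id[tab$label %in% c("LNCRNA", "CODING")]
  lnc_ids <- tab$id[tab$label == "LNCRNA"]
  # calibrate the combined score on synthetic labeled windows under the
  # study tree (logistic refit of the z / SCI weights)
  train <- synthetic_structure_windows(inputs$tree, n_pos = 25L, n_neg = 15L,
                                       window = cfg$structure_window,
                                       seed = derive_seed(cfg$seed, 9901L),
                                       neg = "both")
  weights <- calibrate_score_weights(train$alignments, train$labels,
                                     n_shuffles = cfg$n_shuffles,
                                     seed = derive_seed(cfg$seed, 9902L))
  loci <- list()
  for (id in scan_ids) {
    gl <- scan_windows(candidates[[id]], inputs$store, inputs$tree$tip.label,
                       window = cfg$structure_window,
                       step = cfg$structure_step,
                       threshold = cfg$structure_threshold,
                       weights = weights,
                       n_shuffles = cfg$n_shuffles,
                       seed = derive_seed(cfg$seed, match(id, tab$id)),
                       genome = inputs$genome)
    loci <- c(loci, gl)
  }
  locus_genes <- vapply(loci, `[[`, "", "gene_id")
  lnc_loci <- loci[locus_genes %in% lnc_ids]
  # per-species retention of lncRNA structures and alignable lncRNA regions
  pres_struct <- setNames(integer(length(species)), species)
  for (k in seq_along(lnc_loci)) {
    for (sp in species) {
      ok <- species_structure_presence(lnc_loci[[k]], inputs$store, sp,
                                       threshold = cfg$structure_threshold,
                                       weights = weights,
                                       n_shuffles = cfg$n_shuffles,
                                       seed = derive_seed(cfg$seed, 7919L + k),
                                       min_cov = cfg$min_cov,
                                       genome = inputs$genome)
      if (ok) pres_struct[sp] <- pres_struct[sp] + 1L
    }
  }
  lnc_tx <- candidates[intersect(names(candidates), lnc_ids)]
  pres_region <- setNames(integer(length(species)), species)
  for (tx in lnc_tx) {
    for (sp in species) {
      ap <- alignable_presence(tx, inputs$store, sp, cfg$min_cov,
                               inputs$genome)
      if (ap$present) pres_region[sp] <- pres_region[sp] + 1L
    }
  }
  species_counts <- data.frame(species = species,
                               n_regions = unname(pres_region[species]),
                               n_structures = unname(pres_struct[species]))
  divergence <- NULL
  if (!is.null(cfg$root_ages) && file.exists(cfg$root_ages)) {
    ages <- read.delim(cfg$root_ages, stringsAsFactors = FALSE)
    m <- merge(species_counts, ages, by = "species")
    if (nrow(m) >= 3L) {
      pr <- data.frame(species = m$species, root_age = m$age_mya,
                       count = m$n_regions)
      ps <- data.frame(species = m$species, root_age = m$age_mya,
                       count = m$n_structures)
      divergence <- tryCatch(divergence_regression(pr, ps),
                             error = function(e) {
                               warning("divergence regression failed: ",
                                       conditionMessage(e))
                               NULL
                             })
    } else {
      warning("fewer than 3 species with root ages; regression skipped")
    }
  }
  paths <- list(loci_bed = file.path(cfg$out_dir, "structure_loci.bed"),
                species_counts = file.path(cfg$out_dir,
                                           "structure_species_counts.tsv"),
                report = file.path(cfg$out_dir, "structure_report.json"))
  write_structure_bed(loci, paths$loci_bed)
  write.table(species_counts, paths$species_counts, sep = "\t",
              quote = FALSE, row.names = FALSE)
  n_genes_with_loci <- length(unique(locus_genes))
  write_report(c(provenance(cfg),
                 list(n_loci = length(loci),
                      n_genes_with_loci = n_genes_with_loci,
                      calibrated_weights = weights,
                      species_counts = species_counts,
                      divergence = if (!is.null(divergence)) list(
                        slope_regions = divergence$regions$slope,
                        slope_structures = divergence$structures$slope,
                        ancova_p = divergence$ancova_p))),
               paths$report)
  list(loci = loci, species_counts = species_counts, divergence = divergence,
       paths = paths)
}

#' Conservation and structure stages together
#'
#' @param cfg a `pipeline_config`.
#' @param classified,inputs optional precomputed stage objects.
#' @return list with `conserve` and `structure` stage results.
#' @export
run_conserve_structure <- function(cfg, classified = NULL, inputs = NULL) {
  if (is.null(inputs)) inputs <- load_pipeline_inputs(cfg)
  conserve <- run_conserve(cfg, classified, inputs)
  structure <- run_structure(cfg, conserve, inputs)
  list(conserve = conserve, structure = structure)
}

#' Run the complete pipeline
#'
#' @param cfg a `pipeline_config`.
#' @return list with all stage results and a `summary` report path.
#' @export
run_all <- function(cfg) {
  inputs <- load_pipeline_inputs(cfg)
  discovered <- run_discover(cfg)
  classified <- run_classify(cfg, discovered, inputs)
  cs <- run_conserve_structure(cfg, classified, inputs)
  summary_path <- file.path(cfg$out_dir, "summary_report.json")
  write_report(c(provenance(cfg),
                 list(stage_counts = discovered$stage_counts,
                      label_counts = as.list(table(classified$table$label)),
                      n_structure_loci = length(cs$structure$loci))),
               summary_path)
  list(discover = discovered, classify = classified,
       conserve = cs$conserve, structure = cs$structure,
       summary = summary_path)
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `discover`, `classify`, `conserve`,
#' `structure`, `all`, `report`. `simulate` writes a synthetic study bundle
#' (`--seed` required); the analysis subcommands take `--config`, a JSON
#' file of [pipeline_config()] fields. `report` prints the summary report.
#'
#' @param args character vector of CLI arguments (default
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return exit status (0 on success), invisibly.
#' @export
lncevo_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: lncevo <simulate|discover|classify|conserve|structure|all|report>",
    "  simulate --seed <int> --out <dir>",
    "  <stage>  --config <config.json>", sep = "\n")
  if (!length(args)) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  opt <- list()
  i <- 2L
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    opt[[key]] <- if (i + 1L <= length(args)) args[i + 1L] else NA
    i <- i + 2L
  }
  status <- tryCatch({
    if (cmd == "simulate") {
      if (is.null(opt$seed)) stop("simulate requires --seed")
      out <- opt$out %||% "lncevo_study"
      res <- generate_study(seed = as.integer(opt$seed), out_dir = out)
      message("study written to ", out)
      0L
    } else if (cmd %in% c("discover", "classify", "conserve", "structure",
                          "all", "report")) {
      if (is.null(opt$config)) stop(cmd, " requires --config")
      cj <- jsonlite::read_json(opt$config, simplifyVector = TRUE)
      cfg <- do.call(pipeline_config, cj)
      switch(cmd,
             discover = run_discover(cfg),
             classify = run_classify(cfg),
             conserve = run_conserve(cfg),
             structure = run_structure(cfg),
             all = run_all(cfg),
             report = {
               p <- file.path(cfg$out_dir, "summary_report.json")
               if (!file.exists(p)) stop("no summary report at ", p)
               cat(readLines(p), sep = "\n")
             })
      0L
    } else {
      message(usage)
      1L
    }
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
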