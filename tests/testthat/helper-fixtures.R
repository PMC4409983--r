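# in-code fixtures shared across test files

tiny_tree <- function(n = 4) {
  txt <- switch(as.character(n),
                "2" = "(A:0.1,B:0.15);",
                "3" = "((A:0.1,B:0.12):0.05,C:0.2);",
                "4" = "((A:0.1,B:0.1):0.08,(C:0.15,D:0.05):0.1);",
                "5" = "(((A:0.1,B:0.1):0.05,C:0.12):0.08,(D:0.2,E:0.07):0.1);",
                stop("unsupported tiny tree size"))
  ape::read.tree(text = txt)
}

make_ra <- function(rows, reference = names(rows)[1], start = 0,
                    chrom = "chr1", strand = "+") {
  structure(list(reference = reference,
                 interval = genomic_interval(chrom, start,
                                             start + nchar(rows[[1]]), strand),
                 rows = rows, dropped_columns = 0L),
            class = "region_alignment")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# a one-chromosome genome + MAF store where sp2 differs by given rows;
# convenient for presence / extraction tests
write_tiny_maf <- function(blocks, path = tempfile(fileext = ".maf")) {
  write_maf(blocks, path)
  path
}

# study bundle shared by the heavier pipeline tests (generated once per run)
study_cache <- local({
  cache <- list()
  function(key, generator) {
    if (is.null(cache[[key]])) cache[[key]] <<- generator()
    cache[[key]]
  }
})
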