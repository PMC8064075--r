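# Shared fixtures, built in code (plus the two small extdata files).

toy_gtf_path <- function() {
  system.file("extdata", "toy_models.gtf", package = "chimerascape")
}

toy_models <- function() load_annotation(toy_gtf_path())

# deterministic random genome covering the toy annotation (chrT 1..1200)
toy_genome <- function(seed = 11L) {
  withr::with_seed(seed, {
    s <- paste(sample(c("A", "C", "G", "T"), 1200, replace = TRUE), collapse = "")
    Biostrings::DNAStringSet(c(chrT = s))
  })
}

# gene layout for adjacency / overlap / strand tests: single-exon, non-coding
# P1 -> P2 -> P3 consecutive on +, M1 on -, O1/O2 overlapping on +, Q1 on chrB
adjacency_gtf <- function(dir = tempdir()) {
  g <- function(chrom, id, start, end, strand) {
    at <- sprintf('gene_id "%s"; transcript_id "%s.t1"; gene_name "%s";', id, id, id)
    c(paste(chrom, "fix", "gene", start, end, ".", strand, ".",
            sprintf('gene_id "%s"; gene_name "%s";', id, id), sep = "\t"),
      paste(chrom, "fix", "exon", start, end, ".", strand, ".", at, sep = "\t"))
  }
  lines <- c(
    g("chrA", "P1", 1000, 1999, "+"), g("chrA", "P2", 3000, 3999, "+"),
    g("chrA", "P3", 5000, 5999, "+"), g("chrA", "M1", 7000, 7999, "-"),
    g("chrA", "O1", 9000, 9999, "+"), g("chrA", "O2", 9500, 10400, "+"),
    g("chrB", "Q1", 1000, 1999, "+")
  )
  path <- file.path(dir, "adjacency.gtf")
  writeLines(lines, path)
  path
}

adjacency_models <- function() load_annotation(adjacency_gtf())

# quick candidate-row builder
cand <- function(gene5, pos5, gene3, pos3,
                 chrom5 = "chrT", chrom3 = "chrT",
                 strand5 = "+", strand3 = "+", sample = "s1",
                 span_reads = 10, junc_reads = 5) {
  data.frame(sample = sample, gene5 = gene5, chrom5 = chrom5, strand5 = strand5,
             pos5 = pos5, gene3 = gene3, chrom3 = chrom3, strand3 = strand3,
             pos3 = pos3, span_reads = span_reads, junc_reads = junc_reads,
             stringsAsFactors = FALSE)
}

write_calls_tsv <- function(df, path) {
  write.table(df[, setdiff(names(df), "sample"), drop = FALSE], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# candidates keyed to a simulation's truth table
truth_as_calls <- function(truth, sample = "x") {
  cbind(sample = sample,
        truth[, c("gene5", "chrom5", "strand5", "pos5",
                  "gene3", "chrom3", "strand3", "pos3"), drop = FALSE])
}

# random class-label tables for filter-algebra / enrichment properties
random_annotated <- function(n) {
  data.frame(
    junction_class = sample(c("EE", "EM", "ME", "MM"), n, replace = TRUE),
    locus_class = sample(c("READ_THROUGH", "INTRA_OTHERS", "INTERCHR"), n, replace = TRUE),
    frame_class = sample(c("IN_FRAME", "FRAME_SHIFT", "NA", "BOTH"), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}
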