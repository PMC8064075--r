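mk_ct <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(sample = r[[1]], target = r[[2]], replicate = 1L,
               ct = as.numeric(r[[3]]), stringsAsFactors = FALSE)
  }))
}

test_that("ddct reproduces the textbook worked example and identities", {
  ct <- mk_ct(list("s", "FUS", 20), list("s", "GAPDH", 15),
              list("cal", "FUS", 22), list("cal", "GAPDH", 15))
  # dCt(sample) = 5, dCt(cal) = 7, ddCt = -2 -> 2^2 = 4
  expect_identical(ddct(ct, "FUS", "s", calibrator = "cal"), 4)
  # calibrator against itself is exactly 1
  expect_identical(ddct(ct, "FUS", "cal", calibrator = "cal"), 1)
  # ddCt of +1 halves expression
  ct2 <- mk_ct(list("s", "FUS", 21), list("s", "GAPDH", 15),
               list("cal", "FUS", 20), list("cal", "GAPDH", 15))
  expect_identical(ddct(ct2, "FUS", "s", calibrator = "cal"), 0.5)
  expect_error(ddct(ct[ct$target != "GAPDH", ], "FUS", "s", calibrator = "cal"),
               "GAPDH")
})

test_that("ddct averages replicates and is invariant to a global Ct shift", {
  withr::with_seed(53, {
    ct <- expand.grid(sample = c("a", "b"), target = c("FUS", "GAPDH"),
                      replicate = 1:3, stringsAsFactors = FALSE)
    ct$ct <- runif(nrow(ct), 15, 25)
    fc <- ddct(ct, "FUS", "b", calibrator = "a")
    shifted <- ct
    shifted$ct <- shifted$ct + 3.7
    expect_equal(ddct(shifted, "FUS", "b", calibrator = "a"), fc)
    # replicate mean, computed by hand
    m <- function(s, t) mean(ct$ct[ct$sample == s & ct$target == t])
    expect_equal(fc, 2^-((m("b", "FUS") - m("b", "GAPDH")) -
                         (m("a", "FUS") - m("a", "GAPDH"))))
  })
})

test_that("nuclear/cytoplasmic ratios come straight from the Ct difference", {
  ct <- data.frame(fraction = c("nuclear", "cytoplasmic"), target = "FUS",
                   replicate = 1L, ct = c(24, 24))
  expect_identical(nc_ratio(ct, "FUS"), 1)
  ct$ct <- c(22, 24)   # nuclear two cycles earlier -> 4x nuclear-enriched
  expect_identical(nc_ratio(ct, "FUS"), 4)
  expect_error(nc_ratio(ct[1, ], "FUS"), "cytoplasmic")
})

test_that("noise-free fractionation controls behave like MALAT1 and GAPDH", {
  tab <- simulate_nc_table(c(NUC_CTRL = 16, CYT_CTRL = 1 / 8, FUS = 1),
                           noise_sd = 0)
  expect_equal(nc_ratio(tab, "NUC_CTRL"), 16)
  expect_equal(nc_ratio(tab, "CYT_CTRL"), 1 / 8)
  expect_equal(nc_ratio(tab, "FUS"), 1)
})

test_that("junction sequences splice across exons on E sides", {
  m <- toy_models()
  genome <- toy_genome()
  chr <- as.character(genome[["chrT"]])
  # donor at 400 with k=120: last 20 bases of exon1 + all 100 of exon2
  f <- cand("GENEA", 400, "GENEB", 1001)
  expect_warning(js <- extract_junction_sequence(f, m, genome, k = 120),
                 "downstream")
  expect_equal(js$upstream, paste0(substr(chr, 181, 200), substr(chr, 301, 400)))
  # acceptor at 1001 with k=120: exon2 of GENEB spliced onward (100 bases,
  # then the transcript ends -> shorter, with a warning)
  expect_equal(substr(js$downstream, 1, 100), substr(chr, 1001, 1100))
  expect_equal(js$joined, paste0(js$upstream, js$downstream))
  expect_equal(js$junction_index, 120L)
})

test_that("mid-exon sides take the genomic path and respect strand", {
  m <- toy_models()
  genome <- toy_genome()
  chr <- as.character(genome[["chrT"]])
  js <- extract_junction_sequence(cand("GENEA", 150, "GENEB", 1050), m, genome, k = 10)
  expect_equal(js$upstream, substr(chr, 141, 150))
  expect_equal(js$downstream, substr(chr, 1050, 1059))
  expect_equal(nchar(extract_junction_sequence(
    cand("GENEA", 150, "GENEB", 1050), m, genome, k = 1)$joined), 2L)
  # minus-strand 5' partner: upstream is the reverse complement of the
  # genomic slice starting at the junction
  sim <- simulate_fusion_study(simulation_config(seed = 8))
  tr <- sim$truth
  mi <- which(tr$strand5 == "-" & tr$junction %in% c("ME", "MM"))[1]
  f <- truth_as_calls(tr[mi, ])
  js2 <- extract_junction_sequence(f, sim$models, sim$genome, k = 12)
  manual <- as.character(Biostrings::reverseComplement(
    Biostrings::subseq(sim$genome[[tr$chrom5[mi]]], tr$pos5[mi], tr$pos5[mi] + 11)))
  expect_equal(js2$upstream, manual)
})

test_that("E/E junction sequences match the simulated chimeric transcript", {
  sim <- simulate_fusion_study(simulation_config(seed = 9))
  tr <- sim$truth
  ee <- which(tr$junction == "EE")
  for (i in ee[1:5]) {
    js <- extract_junction_sequence(truth_as_calls(tr[i, ]), sim$models,
                                    sim$genome, k = 15)
    expect_equal(nchar(js$joined), 30L)
    expect_true(grepl(js$joined, tr$chimeric_seq[i], fixed = TRUE),
                label = paste("junction 15-mer pair inside chimeric transcript", i))
  }
})

test_that("junction FASTA export writes one record per fusion", {
  m <- toy_models()
  genome <- toy_genome()
  s <- extract_junction_sequence(cand("GENEA", 200, "GENEB", 1001), m, genome, k = 8)
  path <- withr::local_tempfile(fileext = ".fa")
  write_junction_fasta(list(`GENEA|GENEB|200|1001` = s), path)
  fa <- Biostrings::readDNAStringSet(path)
  expect_equal(length(fa), 1L)
  expect_equal(as.character(fa[[1]]), s$joined)
})
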