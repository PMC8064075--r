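mk_ann <- function(junctions, locus = "READ_THROUGH", frame = "NA") {
  data.frame(sample = "s1", junction_class = junctions,
             locus_class = rep_len(locus, length(junctions)),
             frame_class = rep_len(frame, length(junctions)),
             stringsAsFactors = FALSE)
}

test_that("landscape proportions are exact fractions of the stage total", {
  ann <- mk_ann(c(rep("EE", 4), rep("MM", 3), rep("ME", 2), "EM"))
  s <- summarize_landscape(ann, "s1", "all")
  expect_equal(s$n, 10L)
  expect_equal(unname(s$proportions$junction[c("EE", "MM", "ME", "EM")]),
               c(0.4, 0.3, 0.2, 0.1))
  expect_equal(sum(s$proportions$junction), 1, tolerance = 1e-12)
  expect_equal(sum(s$counts$locus), s$n)
  # after the M/M filter the E/E share rises to 4/7
  s2 <- summarize_landscape(filter_mm(ann), "s1", "non_mm")
  expect_equal(unname(s2$proportions$junction[["EE"]]), 4 / 7)
})

test_that("the non_mm stage refuses unfiltered input and empty stages are well-formed", {
  ann <- mk_ann(c("EE", "MM"))
  expect_error(summarize_landscape(ann, stage = "non_mm"), "filter_mm")
  s <- summarize_landscape(ann[0, ], "s1", "all")
  expect_equal(s$n, 0L)
  expect_null(s$proportions)
  expect_true(all(unlist(s$counts) == 0L))
})

test_that("counts are conserved across the filter and E/E can only enrich", {
  withr::with_seed(41, {
    for (i in 1:100) {
      ann <- random_annotated(sample(1:60, 1))
      filt <- filter_mm(ann)
      n_mm <- sum(ann$junction_class == "MM")
      expect_equal(nrow(filt), nrow(ann) - n_mm)
      expect_equal(filter_mm(filt), filt)
      if (n_mm >= 1 && any(ann$junction_class == "EE") && nrow(filt) > 0) {
        p_before <- mean(ann$junction_class == "EE")
        p_after <- mean(filt$junction_class == "EE")
        expect_gte(p_after, p_before)
      }
    }
  })
})

test_that("overlap decomposition matches brute-force set arithmetic", {
  sets <- list(
    a = rbind(cand("G1", 1, "G2", 2), cand("G3", 3, "G4", 4), cand("G5", 5, "G6", 6)),
    b = rbind(cand("G7", 7, "G8", 8), cand("G9", 9, "G10", 10)),
    c = cand("G11", 11, "G12", 12)
  )
  rep <- compute_overlap(sets, "junction")
  expect_equal(rep$union_size, 6L)
  expect_equal(unname(rep$regions[c("a&b", "a&c", "b&c", "a&b&c")]),
               rep(0L, 4))
  expect_equal(sum(rep$regions), rep$union_size)
  withr::with_seed(77, {
    for (i in 1:10) {
      pool <- lapply(1:12, function(j) cand(paste0("A", j), j, paste0("B", j), j + 100))
      ks <- lapply(1:3, function(j) do.call(rbind, sample(pool, sample(2:9, 1))))
      names(ks) <- c("x", "y", "z")
      got <- compute_overlap(ks, "junction")
      want <- brute_overlap(lapply(ks, function(df) unique(paste(df$gene5, df$gene3, df$pos5, df$pos3, sep = "|"))))
      expect_equal(got$regions[names(want)], want)
    }
  })
})

test_that("gene-pair identity collapses junction forms; junction identity keeps them", {
  form1 <- cand("RPH", 10, "OLA", 20)
  form2 <- cand("RPH", 10, "OLA", 35)   # second junction form of the same pair
  sets <- list(s1 = rbind(form1, form2), s2 = form1)
  expect_equal(compute_overlap(sets, "junction")$union_size, 2L)
  expect_equal(compute_overlap(sets, "gene_pair")$union_size, 1L)
  expect_equal(unname(compute_overlap(sets, "gene_pair")$regions[["s1&s2"]]), 1L)
  # shared singleton across three sets lands in the triple region
  sets3 <- list(p = rbind(cand("A", 1, "B", 2), form1),
                q = rbind(cand("C", 3, "D", 4), form1),
                r = form1)
  expect_equal(unname(compute_overlap(sets3, "gene_pair")$regions[["p&q&r"]]), 1L)
  expect_error(compute_overlap(sets["s1"]), "2-5 samples")
})

test_that("circos link export emits one 1-based link per known-chromosome fusion", {
  ann <- rbind(cand("GENEA", 200, "GENEB", 1001),
               cand("GENEA", 400, "GENEB", 1050, chrom3 = "chrU"),
               cand("GENEA", 150, "GENEB", 1090))
  ann$locus_class <- c("READ_THROUGH", "INTERCHR", "INTRA_OTHERS")
  out <- withr::local_tempfile(fileext = ".tsv")
  lens <- c(chrT = 2000)
  expect_warning(export_circos_links(ann, out, lens), "skipped 1")
  links <- read.delim(out, header = FALSE)
  expect_equal(nrow(links), 2L)
  expect_equal(links$V2, links$V3)              # single-base anchors
  expect_equal(links$V2, c(200, 150))
  expect_equal(links$V7, c("READ_THROUGH", "INTRA_OTHERS"))
  # interchromosomal link names two different chromosomes
  ann2 <- cand("GENEA", 200, "Q1", 1500, chrom3 = "chrB")
  ann2$locus_class <- "INTERCHR"
  export_circos_links(ann2, out, c(chrT = 2000, chrB = 3000))
  l2 <- read.delim(out, header = FALSE)
  expect_equal(c(l2$V1, l2$V4), c("chrT", "chrB"))
})

test_that("figure rendering produces non-empty files", {
  sim <- simulate_fusion_study(simulation_config(seed = 6))
  res <- annotate_all(truth_as_calls(sim$truth), sim$models)
  dir <- withr::local_tempdir()
  p1 <- plot_landscape(summarize_landscape(res$annotated, "x", "all"),
                       file.path(dir, "pies.png"))
  p2 <- plot_overlap(compute_overlap(sim$calls), file.path(dir, "venn.png"))
  p3 <- plot_overlap(compute_overlap(sim$calls[1:2]), file.path(dir, "venn2.png"))
  for (p in c(p1, p2, p3)) {
    expect_true(file.exists(p))
    expect_gt(file.size(p), 0)
  }
})
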