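# GENEA (tA1): exons 101-200, 301-400, 501-600; CDS 151-200, 301-400, 501-560
# GENEB (tB1): exons 801-900, 1001-1100; CDS 841-900, 1001-1090

test_that("junction classification composes E/M sides from gene edges", {
  m <- toy_models()
  expect_equal(classify_junction(cand("GENEA", 200, "GENEB", 1001), m)$value, "EE")
  expect_equal(classify_junction(cand("GENEA", 200, "GENEB", 1050), m)$value, "EM")
  expect_equal(classify_junction(cand("GENEA", 150, "GENEB", 1001), m)$value, "ME")
  expect_equal(classify_junction(cand("GENEA", 150, "GENEB", 1050), m)$value, "MM")
  # a donor edge is not an acceptor: 3' side landing on an exon *end* is M
  expect_equal(classify_junction(cand("GENEA", 200, "GENEB", 1100), m)$value, "EM")
  expect_error(classify_junction(cand("NOPE", 200, "GENEB", 1001), m),
               "unresolved partner: NOPE")
})

test_that("junction classification agrees with brute-force edge membership", {
  m <- toy_models()
  edges_a_donor <- c(200, 400, 600)
  edges_b_acceptor <- c(801, 1001)
  withr::with_seed(31, {
    for (i in 1:40) {
      p5 <- sample(101:600, 1)
      p3 <- sample(801:1100, 1)
      jc <- classify_junction(cand("GENEA", p5, "GENEB", p3), m)
      expect_equal(jc$side5, if (p5 %in% edges_a_donor) "E" else "M")
      expect_equal(jc$side3, if (p3 %in% edges_b_acceptor) "E" else "M")
      expect_equal(jc$value, paste0(jc$side5, jc$side3))
    }
  })
})

test_that("locus classification distinguishes the three configurations", {
  am <- adjacency_models()
  rt <- cand("P1", 1500, "P2", 3500, chrom5 = "chrA", chrom3 = "chrA")
  expect_equal(classify_locus(rt, am), "READ_THROUGH")
  # reversed transcription order demotes to INTRA_OTHERS
  rev <- cand("P2", 3500, "P1", 1500, chrom5 = "chrA", chrom3 = "chrA")
  expect_equal(classify_locus(rev, am), "INTRA_OTHERS")
  # one intervening same-strand gene
  skip1 <- cand("P1", 1500, "P3", 5500, chrom5 = "chrA", chrom3 = "chrA")
  expect_equal(classify_locus(skip1, am), "INTRA_OTHERS")
  expect_equal(classify_locus(skip1, am, max_intervening = 1), "READ_THROUGH")
  # opposite strands on one chromosome
  opp <- cand("P1", 1500, "M1", 7500, chrom5 = "chrA", chrom3 = "chrA",
              strand3 = "-")
  expect_equal(classify_locus(opp, am), "INTRA_OTHERS")
  # different chromosomes, either order
  inter <- cand("P1", 1500, "Q1", 1500, chrom5 = "chrA", chrom3 = "chrB")
  expect_equal(classify_locus(inter, am), "INTERCHR")
  swapped <- cand("Q1", 1500, "P1", 1500, chrom5 = "chrB", chrom3 = "chrA")
  expect_equal(classify_locus(swapped, am), "INTERCHR")
})

test_that("frame prediction applies the mod-3 rule over CDS coordinates", {
  m <- toy_models()
  # retained 5' CDS at donor 400: 50 + 100 = 150 (= 0 mod 3)
  # discarded 3' CDS at acceptor 1001: 60 (= 0 mod 3) -> in-frame
  f <- predict_frame(cand("GENEA", 400, "GENEB", 1001), m)
  expect_equal(f$value, "IN_FRAME")
  # one extra 3' base discarded (61 = 1 mod 3) -> shift
  expect_equal(predict_frame(cand("GENEA", 400, "GENEB", 1002), m)$value,
               "FRAME_SHIFT")
  # one fewer retained 5' base (149 = 2 mod 3) -> shift
  expect_equal(predict_frame(cand("GENEA", 399, "GENEB", 1001), m)$value,
               "FRAME_SHIFT")
  # junction in the 3' partner's 5'UTR: inert everywhere -> NA
  expect_equal(predict_frame(cand("GENEA", 400, "GENEB", 801), m)$value, "NA")
  # non-coding 3' parent (single-exon fixture genes carry no CDS) -> NA
  am <- adjacency_models()
  expect_equal(predict_frame(cand("P1", 1500, "P2", 3500, chrom5 = "chrA",
                                  chrom3 = "chrA"), am)$value, "NA")
  # only the coding isoform pair is evaluable; tA2 contributes no pairs
  expect_equal(nrow(f$pairs), 1L)
})

test_that("two 3' isoforms with CDS starts one base apart give BOTH", {
  dir <- withr::local_tempdir()
  lines <- c(readLines(toy_gtf_path()), c(
    "chrT\ttoy\tgene\t2001\t2400\t.\t+\t.\tgene_id \"GD\"; gene_name \"GENED\";",
    "chrT\ttoy\ttranscript\t2001\t2400\t.\t+\t.\tgene_id \"GD\"; transcript_id \"tD1\"; gene_name \"GENED\";",
    "chrT\ttoy\texon\t2001\t2400\t.\t+\t.\tgene_id \"GD\"; transcript_id \"tD1\"; gene_name \"GENED\";",
    "chrT\ttoy\tCDS\t2031\t2390\t.\t+\t0\tgene_id \"GD\"; transcript_id \"tD1\"; gene_name \"GENED\";",
    "chrT\ttoy\ttranscript\t2001\t2400\t.\t+\t.\tgene_id \"GD\"; transcript_id \"tD2\"; gene_name \"GENED\";",
    "chrT\ttoy\texon\t2001\t2400\t.\t+\t.\tgene_id \"GD\"; transcript_id \"tD2\"; gene_name \"GENED\";",
    "chrT\ttoy\tCDS\t2032\t2391\t.\t+\t0\tgene_id \"GD\"; transcript_id \"tD2\"; gene_name \"GENED\";"))
  path <- file.path(dir, "both.gtf")
  writeLines(lines, path)
  m <- load_annotation(path)
  # retained 150 (0 mod 3); tD1 discards 2100-2031+1-81=... position 2112:
  # tD1 discards 2112-2031 = 81 (0 mod 3, in-frame), tD2 discards 80 (shift)
  f <- predict_frame(cand("GENEA", 400, "GENED", 2112), m)
  expect_equal(f$value, "BOTH")
  expect_setequal(f$pairs$outcome, c("in_frame", "frame_shift"))
})

test_that("frame calls match the splice-and-translate oracle on the toy locus", {
  m <- toy_models()
  genome <- toy_genome()
  withr::with_seed(47, {
    picks <- data.frame(p5 = sample(380:420, 12, replace = TRUE),
                        p3 = sample(1001:1080, 12, replace = TRUE))
  })
  for (i in seq_len(nrow(picks))) {
    f <- predict_frame(cand("GENEA", picks$p5[i], "GENEB", picks$p3[i]), m)
    o <- oracle_frame(m, genome, "tA1", "tB1", picks$p5[i], picks$p3[i])
    if (is.na(o)) next
    expected <- switch(o, in_frame = "IN_FRAME", frame_shift = "FRAME_SHIFT", inert = "NA")
    expect_equal(f$value, expected,
                 label = sprintf("frame at (%d, %d)", picks$p5[i], picks$p3[i]))
  }
})

test_that("filter_mm removes exactly the M/M stratum and is idempotent", {
  withr::with_seed(13, df <- random_annotated(10))
  df$junction_class <- c(rep("MM", 4), rep("EE", 3), "EM", "ME", "EE")
  out <- filter_mm(df)
  expect_equal(nrow(out), 6L)
  expect_equal(filter_mm(out), out)
  no_mm <- df[df$junction_class != "MM", ]
  expect_equal(filter_mm(no_mm), no_mm, ignore_attr = TRUE)
  all_mm <- df[df$junction_class == "MM", ]
  expect_equal(nrow(filter_mm(all_mm)), 0L)
})

test_that("annotate_all quarantines unresolvable candidates and labels the rest", {
  m <- toy_models()
  batch <- rbind(cand("GENEA", 200, "GENEB", 1001),
                 cand("GENEA", 200, "GHOST", 1001),
                 cand("GENEA", 150, "GENEB", 1050))
  res <- annotate_all(batch, m)
  expect_equal(nrow(res$annotated), 2L)
  expect_equal(nrow(res$rejects), 1L)
  expect_match(res$rejects$reason, "unresolved partner: GHOST")
  expect_equal(res$annotated$junction_class, c("EE", "MM"))
  empty <- annotate_all(batch[0, ], m)
  expect_equal(nrow(empty$annotated), 0L)
  expect_equal(nrow(empty$rejects), 0L)
})

test_that("every resolvable fusion gets exactly one label per scheme", {
  sim <- simulate_fusion_study(simulation_config(seed = 4))
  res <- annotate_all(truth_as_calls(sim$truth), sim$models)
  a <- res$annotated
  expect_equal(nrow(res$rejects), 0L)
  expect_true(all(a$junction_class %in% c("EE", "EM", "ME", "MM")))
  expect_true(all(a$locus_class %in% c("READ_THROUGH", "INTRA_OTHERS", "INTERCHR")))
  expect_true(all(a$frame_class %in% c("IN_FRAME", "FRAME_SHIFT", "NA", "BOTH")))
  expect_equal(a$junction_class, paste0(a$junction_side5, a$junction_side3))
})

test_that("partner swap keeps INTERCHR but demotes a read-through pair", {
  sim <- simulate_fusion_study(simulation_config(seed = 4))
  tr <- sim$truth
  swap <- function(df) {
    cand(df$gene3, df$pos3, df$gene5, df$pos5,
         chrom5 = df$chrom3, chrom3 = df$chrom5,
         strand5 = df$strand3, strand3 = df$strand5)
  }
  ic <- tr[tr$locus == "INTERCHR", ][1, ]
  expect_equal(classify_locus(swap(ic), sim$models), "INTERCHR")
  rt <- tr[tr$locus == "READ_THROUGH", ][1, ]
  expect_equal(classify_locus(swap(rt), sim$models), "INTRA_OTHERS")
})
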