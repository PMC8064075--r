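# Independent splice-and-translate frame oracle.  Deliberately shares no code
# with the package's mod-3 arithmetic: it builds the chimeric mRNA, translates
# it in the 5' partner's reading frame, and asks whether the protein suffix
# encoded by the 3' partner's own frame reappears verbatim.

oracle_exons <- function(models, tid) {
  e <- models$exons[models$exons$transcript_id == tid, , drop = FALSE]
  e[order(e$start), , drop = FALSE]
}

oracle_splice <- function(models, genome, tid) {
  e <- oracle_exons(models, tid)
  s <- paste(vapply(seq_len(nrow(e)), function(i) {
    as.character(Biostrings::subseq(genome[[e$chrom[1L]]], e$start[i], e$end[i]))
  }, character(1L)), collapse = "")
  if (e$strand[1L] == "-") {
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }
  s
}

oracle_offset <- function(models, tid, pos) {
  e <- oracle_exons(models, tid)
  strand <- e$strand[1L]
  ord <- if (strand == "+") seq_len(nrow(e)) else rev(seq_len(nrow(e)))
  off <- 0L
  for (i in ord) {
    if (pos >= e$start[i] && pos <= e$end[i]) {
      return(off + if (strand == "+") pos - e$start[i] + 1L else e$end[i] - pos + 1L)
    }
    off <- off + e$end[i] - e$start[i] + 1L
  }
  NA_integer_
}

# first and last CDS base of a transcript, in spliced coordinates
oracle_cds_span <- function(models, tid) {
  cc <- models$cds[models$cds$transcript_id == tid, , drop = FALSE]
  if (nrow(cc) == 0L) return(NULL)
  strand <- cc$strand[1L]
  first_g <- if (strand == "+") min(cc$start) else max(cc$end)
  last_g <- if (strand == "+") max(cc$end) else min(cc$start)
  c(oracle_offset(models, tid, first_g), oracle_offset(models, tid, last_g))
}

# -> "in_frame" / "frame_shift" / "inert", or NA when the 3' stub is too
# short to decide by string comparison
oracle_frame <- function(models, genome, tid5, tid3, pos5, pos3) {
  o5 <- oracle_offset(models, tid5, pos5)
  o3 <- oracle_offset(models, tid3, pos3)
  if (is.na(o5) || is.na(o3)) return("inert")
  c5 <- oracle_cds_span(models, tid5)
  c3 <- oracle_cds_span(models, tid3)
  if (is.null(c5) || is.null(c3)) return("inert")
  if (o5 < c5[1L] || o5 > c5[2L]) return("inert")
  if (o3 < c3[1L] || o3 > c3[2L]) return("inert")
  s5 <- oracle_splice(models, genome, tid5)
  s3 <- oracle_splice(models, genome, tid3)
  chim <- paste0(substr(s5, 1L, o5), substr(s3, o3, nchar(s3)))
  chim_orf <- substr(chim, c5[1L], nchar(chim))
  chim_orf <- substr(chim_orf, 1L, 3L * (nchar(chim_orf) %/% 3L))
  prot_chim <- as.character(Biostrings::translate(Biostrings::DNAString(chim_orf), no.init.codon = TRUE))
  cds3 <- substr(s3, c3[1L], c3[2L])
  d <- o3 - c3[1L]                      # coding bases lost upstream of junction
  pad <- (3L - d %% 3L) %% 3L           # to the first intact 3'-frame codon
  tail3 <- substr(cds3, d + pad + 1L, nchar(cds3))
  tail3 <- substr(tail3, 1L, 3L * (nchar(tail3) %/% 3L))
  if (nchar(tail3) < 9L) return(NA_character_)
  tail3 <- substr(tail3, 1L, min(nchar(tail3), 30L))
  suffix3 <- as.character(Biostrings::translate(Biostrings::DNAString(tail3), no.init.codon = TRUE))
  if (grepl(suffix3, prot_chim, fixed = TRUE)) "in_frame" else "frame_shift"
}

# exact brute-force Venn decomposition for cross-checking compute_overlap()
brute_overlap <- function(key_sets) {
  samples <- names(key_sets)
  k <- length(samples)
  out <- integer(0L)
  for (m in seq_len(k)) {
    for (ss in asplit(utils::combn(samples, m), 2L)) {
      inside <- Reduce(intersect, key_sets[ss])
      outside <- unique(unlist(key_sets[setdiff(samples, ss)]))
      out[paste(ss, collapse = "&")] <- length(setdiff(inside, outside))
    }
  }
  out
}
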