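#' Relative expression by the 2^-ddCt method
#'
#' Standard relative quantification from qPCR cycle thresholds: replicate Ct
#' values are averaged (arithmetic mean), the reference target is subtracted
#' within each sample (dCt), the calibrator sample's dCt is subtracted
#' (ddCt), and the fold change is `2^-ddCt`.  The calibrator sample therefore
#' always returns exactly 1, and adding any constant to every Ct leaves all
#' fold changes unchanged.
#'
#' @param ct data.frame with columns `sample`, `target`, `replicate`, `ct`
#'   (cycle-threshold values, > 0).
#' @param target Target of interest (e.g. a chimeric RNA assay).
#' @param sample Sample whose expression is reported.
#' @param reference Internal-control target measured in every sample
#'   (default `"GAPDH"`).
#' @param calibrator Sample all fold changes are relative to.
#' @return Fold change (positive numeric scalar).
#' @export
ddct <- function(ct, target, sample, reference = "GAPDH", calibrator) {
  stopifnot(all(c("sample", "target", "replicate", "ct") %in% names(ct)))
  if (any(ct$ct <= 0)) chs_stop("Ct values must be positive")
  mean_ct <- function(s, t) {
    v <- ct$ct[ct$sample == s & ct$target == t]
    if (length(v) == 0L) {
      chs_stop("no Ct measurements for target '", t, "' in sample '", s, "'")
    }
    mean(v)
  }
  dct_s <- mean_ct(sample, target) - mean_ct(sample, reference)
  dct_c <- mean_ct(calibrator, target) - mean_ct(calibrator, reference)
  2^-(dct_s - dct_c)
}

#' Nuclear/cytoplasmic expression ratio from fractionation qPCR
#'
#' Returns `2^-(Ct_nuclear - Ct_cytoplasmic)` for a target measured in both
#' fractions of a fractionation experiment (replicates averaged).  Values
#' above 1 indicate nuclear enrichment.  No reference normalization is
#' applied: fractionation controls (a cytoplasm-biased mRNA such as GAPDH and
#' a nucleus-retained lncRNA such as MALAT1) are themselves fraction-biased,
#' so they are reported as companion ratios rather than divided out;
#' equal-input loading of the two fractions is assumed.
#'
#' @param ct data.frame with columns `fraction` (containing `"nuclear"` and
#'   `"cytoplasmic"`), `target`, `replicate`, `ct`.
#' @param target Target to evaluate.
#' @return Nuclear/cytoplasmic ratio (positive numeric scalar).
#' @export
nc_ratio <- function(ct, target) {
  stopifnot(all(c("fraction", "target", "ct") %in% names(ct)))
  mean_ct <- function(fr) {
    v <- ct$ct[ct$fraction == fr & ct$target == target]
    if (length(v) == 0L) {
      chs_stop("no Ct measurements for target '", target, "' in fraction '", fr, "'")
    }
    mean(v)
  }
  2^-(mean_ct("nuclear") - mean_ct("cytoplasmic"))
}

read_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet")) return(genome)
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    return(Biostrings::readDNAStringSet(genome))
  }
  chs_stop("genome must be a DNAStringSet or a FASTA path")
}

# full spliced (mature) sequence of one transcript, 5'->3'
spliced_transcript_seq <- function(models, genome, transcript_id) {
  e <- models$exons[models$exons$transcript_id == transcript_id, , drop = FALSE]
  e <- e[order(e$start), , drop = FALSE]
  chrom_seq <- genome[[e$chrom[1L]]]
  s <- do.call(Biostrings::xscat,
               lapply(seq_len(nrow(e)),
                      function(i) Biostrings::subseq(chrom_seq, e$start[i], e$end[i])))
  if (e$strand[1L] == "-") s <- Biostrings::reverseComplement(s)
  s
}

# spliced-transcript offset (1-based) of a genomic position, or NA if the
# position is not exonic in this transcript
tx_offset <- function(models, transcript_id, pos) {
  e <- tx_exons(models, transcript_id)
  off <- 0L
  for (i in seq_len(nrow(e))) {
    if (pos >= e$start[i] && pos <= e$end[i]) {
      within <- if (e$strand[i] == "+") pos - e$start[i] + 1L else e$end[i] - pos + 1L
      return(off + within)
    }
    off <- off + (e$end[i] - e$start[i] + 1L)
  }
  NA_integer_
}

#' Extract the transcript sequence flanking a fusion junction
#'
#' Produces the `k` transcribed bases ending at the 5'-side junction
#' coordinate and the `k` transcribed bases starting at the 3'-side
#' coordinate — the substrate for designing RT-PCR primers that anneal to the
#' parental genes and flank the junction.  When a side coincides with an
#' annotated exon boundary (an E side), the sequence follows the mature
#' (spliced) transcript of an isoform sharing that edge, matching the cDNA a
#' junction-spanning primer would read; otherwise the genomic path is used.
#' Sequences are reverse-complemented as needed so both halves read 5' to 3'
#' along the chimera.
#'
#' @param f One annotated fusion (one-row data.frame or named list).
#' @param models A `GeneModelSet`.
#' @param genome [Biostrings::DNAStringSet] or FASTA path.
#' @param k Bases to extract on each side (>= 1).
#' @return Object of class `junction_sequence`: list with `upstream`,
#'   `downstream`, `joined` (character), `k` and `junction_index` (length of
#'   the upstream half).  If fewer than `k` bases are available on a side the
#'   sequence is shortened with a warning.
#' @export
extract_junction_sequence <- function(f, models, genome, k = 25L) {
  stopifnot(k >= 1L)
  genome <- read_genome(genome)
  p <- resolve_pair(f, models)

  side_seq <- function(gene_id, chrom, pos, which_side) {
    g <- models$genes[models$genes$gene_id == gene_id, ]
    edge_side <- if (which_side == "up") "donor" else "acceptor"
    spliced <- gene_side_is_E(models, gene_id, pos, edge_side, 0L)
    if (spliced) {
      txs <- sort(models$transcripts$transcript_id[models$transcripts$gene_id == gene_id])
      for (tid in txs) {
        offs <- tx_offset(models, tid, pos)
        if (is.na(offs)) next
        ed <- exon_edge_table(models$exons[models$exons$transcript_id == tid, , drop = FALSE])
        if (!any(ed$side == edge_side & ed$coord == pos)) next
        full <- spliced_transcript_seq(models, genome, tid)
        if (which_side == "up") {
          lo <- max(1L, offs - k + 1L)
          if (offs - k + 1L < 1L) chs_warn("fewer than k bases upstream of junction")
          return(as.character(Biostrings::subseq(full, lo, offs)))
        } else {
          hi <- min(length(full), offs + k - 1L)
          if (offs + k - 1L > length(full)) chs_warn("fewer than k bases downstream of junction")
          return(as.character(Biostrings::subseq(full, offs, hi)))
        }
      }
    }
    # genomic path (mid-exon or intronic side)
    chrom_seq <- genome[[chrom]]
    strand <- g$strand
    take <- function(lo, hi, clip_msg) {
      if (lo < 1L || hi > length(chrom_seq)) {
        chs_warn(clip_msg)
        lo <- max(1L, lo); hi <- min(length(chrom_seq), hi)
      }
      Biostrings::subseq(chrom_seq, lo, hi)
    }
    if (which_side == "up") {
      s <- if (strand == "+") take(pos - k + 1L, pos, "upstream clipped at contig edge")
           else Biostrings::reverseComplement(take(pos, pos + k - 1L, "upstream clipped at contig edge"))
    } else {
      s <- if (strand == "+") take(pos, pos + k - 1L, "downstream clipped at contig edge")
           else Biostrings::reverseComplement(take(pos - k + 1L, pos, "downstream clipped at contig edge"))
    }
    as.character(s)
  }

  up <- side_seq(p$g5, f$chrom5, f$pos5, "up")
  down <- side_seq(p$g3, f$chrom3, f$pos3, "down")
  structure(list(upstream = up, downstream = down,
                 joined = paste0(up, down), k = as.integer(k),
                 junction_index = nchar(up)),
            class = "junction_sequence")
}

#' Write junction sequences as FASTA
#'
#' Headers encode the fusion identity (gene5|gene3|pos5|pos3) and `k`.
#'
#' @param seqs Named list of `junction_sequence` objects; names become the
#'   fusion identifiers.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_junction_fasta <- function(seqs, path) {
  lines <- unlist(lapply(names(seqs), function(nm) {
    s <- seqs[[nm]]
    c(sprintf(">%s k=%d junction=%d", nm, s$k, s$junction_index), s$joined)
  }))
  writeLines(lines, path)
  invisible(path)
}
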