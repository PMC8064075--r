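#' Resolve a caller partner symbol against the annotation
#'
#' Matches `gene_name` first, then `gene_id`.  When a symbol is ambiguous
#' (shared by several genes), the tie is broken by requiring the gene span to
#' contain the reported junction on the reported chromosome; anything still
#' ambiguous, or entirely absent, is unresolved.
#'
#' @param models A `GeneModelSet`.
#' @param symbol Partner symbol as reported by the caller.
#' @param chrom,pos Reported junction location used for disambiguation.
#' @return The matching `gene_id`, or `NA_character_` with attribute `reason`.
#' @export
resolve_gene <- function(models, symbol, chrom, pos) {
  g <- models$genes
  hits <- g[g$gene_name == symbol, , drop = FALSE]
  if (nrow(hits) == 0L) hits <- g[g$gene_id == symbol, , drop = FALSE]
  if (nrow(hits) == 0L) {
    return(structure(NA_character_, reason = paste0("unresolved partner: ", symbol)))
  }
  if (nrow(hits) > 1L) {
    hits <- hits[hits$chrom == chrom & hits$start <= pos & hits$end >= pos, , drop = FALSE]
    if (nrow(hits) != 1L) {
      return(structure(NA_character_,
                       reason = paste0("ambiguous partner: ", symbol)))
    }
  }
  hits$gene_id[1L]
}

resolve_pair <- function(c, models) {
  g5 <- resolve_gene(models, c$gene5, c$chrom5, c$pos5)
  if (is.na(g5)) chs_stop("cannot classify: ", attr(g5, "reason"))
  g3 <- resolve_gene(models, c$gene3, c$chrom3, c$pos3)
  if (is.na(g3)) chs_stop("cannot classify: ", attr(g3, "reason"))
  list(g5 = g5, g3 = g3)
}

# does pos match an edge of the given side among this gene's pooled edges?
gene_side_is_E <- function(models, gene_id, pos, side, tol) {
  ed <- gene_edges(models, gene_id)
  any(ed$side == side & abs(ed$coord - pos) <= tol)
}

#' Classify a fusion junction as E/E, E/M, M/E or M/M
#'
#' Each side of the junction is an "E" when it coincides (within `tol`) with a
#' known exon/intron boundary of its parental gene — the donor (exon 3' edge)
#' for the 5' side, the acceptor (exon 5' edge) for the 3' side — and an "M"
#' when it falls mid-exon (or anywhere else).  Edges are pooled across all
#' isoforms of the gene, so a junction matching any isoform's edge counts as E.
#'
#' @param c One fusion candidate (a one-row data.frame or named list).
#' @param models A `GeneModelSet`.
#' @param tol Boundary tolerance in bases (default 0, exact).
#' @return list with `value` (one of `"EE"`, `"EM"`, `"ME"`, `"MM"`), `side5`
#'   and `side3`.
#' @export
classify_junction <- function(c, models, tol = 0L) {
  p <- resolve_pair(c, models)
  side5 <- if (gene_side_is_E(models, p$g5, c$pos5, "donor", tol)) "E" else "M"
  side3 <- if (gene_side_is_E(models, p$g3, c$pos3, "acceptor", tol)) "E" else "M"
  list(value = paste0(side5, side3), side5 = side5, side3 = side3)
}

#' Classify the locus relationship of the parental genes
#'
#' `INTERCHR` when the partners lie on different chromosomes; `READ_THROUGH`
#' when they are same-strand neighbours with the 5' partner upstream in
#' transcription orientation and at most `max_intervening` same-strand genes
#' wholly between them (the cis-SAGe configuration); everything else on one
#' chromosome — non-neighbouring pairs, reversed order, opposite strands — is
#' `INTRA_OTHERS`.
#'
#' @inheritParams classify_junction
#' @param max_intervening Maximum intervening same-strand genes still counted
#'   as neighbouring (default 0, strict adjacency).
#' @return One of `"READ_THROUGH"`, `"INTRA_OTHERS"`, `"INTERCHR"`.
#' @export
classify_locus <- function(c, models, max_intervening = 0L) {
  p <- resolve_pair(c, models)
  if (c$chrom5 != c$chrom3) return("INTERCHR")
  a <- models$genes[models$genes$gene_id == p$g5, ]
  b <- models$genes[models$genes$gene_id == p$g3, ]
  if (a$gene_id == b$gene_id) return("INTRA_OTHERS")
  if (a$strand != b$strand) return("INTRA_OTHERS")
  upstream <- if (a$strand == "+") a$start < b$start else a$end > b$end
  if (!upstream) return("INTRA_OTHERS")
  if (intervening_genes(models, p$g5, p$g3) > max_intervening) return("INTRA_OTHERS")
  "READ_THROUGH"
}

# spliced CDS bases of transcript `tid` retained on the 5' side of a junction
# whose last retained base is `pos` (inclusive), or NA when `pos` is not a CDS
# base of that isoform (UTR, intron, or outside).
cds_retained_5p <- function(models, tid, pos) {
  cc <- tx_cds(models, tid)
  if (nrow(cc) == 0L) return(NA_integer_)
  inside <- any(cc$start <= pos & cc$end >= pos)
  if (!inside) return(NA_integer_)
  if (cc$strand[1L] == "+") {
    sum(pmax(0L, pmin(cc$end, pos) - cc$start + 1L))
  } else {
    sum(pmax(0L, cc$end - pmax(cc$start, pos) + 1L))
  }
}

# spliced CDS bases of transcript `tid` discarded strictly upstream of a
# junction whose first retained base is `pos`; NA when `pos` is not a CDS base.
cds_discarded_3p <- function(models, tid, pos) {
  cc <- tx_cds(models, tid)
  if (nrow(cc) == 0L) return(NA_integer_)
  inside <- any(cc$start <= pos & cc$end >= pos)
  if (!inside) return(NA_integer_)
  if (cc$strand[1L] == "+") {
    sum(pmax(0L, pmin(cc$end, pos - 1L) - cc$start + 1L))
  } else {
    sum(pmax(0L, cc$end - pmax(cc$start, pos + 1L) + 1L))
  }
}

#' Predict the reading-frame consequence of a fusion junction
#'
#' For every pair of coding isoforms (one of each parent) where both junction
#' bases fall inside the isoform's CDS, the chimera preserves the 3' partner's
#' reading frame exactly when the number of 5'-isoform coding bases retained
#' upstream of the junction and the number of 3'-isoform coding bases
#' discarded upstream of it agree modulo 3.  Pairs where a junction base falls
#' in a UTR or an intron of the isoform, or where a parent is non-coding, are
#' inert.  Aggregation across isoform pairs: all evaluable pairs in-frame
#' yields `IN_FRAME`; all shifted, `FRAME_SHIFT`; a mixture, `BOTH`
#' (isoform-dependent outcome); no evaluable pair, `"NA"` (no predicted frame
#' effect).  Mid-exon (M) junction sides are still evaluated when they land in
#' CDS, so M/M fusions are frame-classifiable.
#'
#' @inheritParams classify_junction
#' @return list with `value` (one of `"IN_FRAME"`, `"FRAME_SHIFT"`, `"NA"`,
#'   `"BOTH"`) and `pairs`, a data.frame of per-isoform-pair outcomes.
#' @export
predict_frame <- function(c, models, junction = NULL) {
  p <- resolve_pair(c, models)
  tx <- models$transcripts
  t5s <- tx$transcript_id[tx$gene_id == p$g5 & tx$coding]
  t3s <- tx$transcript_id[tx$gene_id == p$g3 & tx$coding]
  pairs <- data.frame(transcript5 = character(), transcript3 = character(),
                      outcome = character(), stringsAsFactors = FALSE)
  for (t5 in sort(t5s)) {
    r <- cds_retained_5p(models, t5, c$pos5)
    for (t3 in sort(t3s)) {
      d <- cds_discarded_3p(models, t3, c$pos3)
      outcome <- if (is.na(r) || is.na(d)) {
        "inert"
      } else if (r %% 3L == d %% 3L) "in_frame" else "frame_shift"
      pairs <- rbind(pairs, data.frame(transcript5 = t5, transcript3 = t3,
                                       outcome = outcome, stringsAsFactors = FALSE))
    }
  }
  ev <- pairs$outcome[pairs$outcome != "inert"]
  value <- if (length(ev) == 0L) {
    "NA"
  } else if (all(ev == "in_frame")) {
    "IN_FRAME"
  } else if (all(ev == "frame_shift")) {
    "FRAME_SHIFT"
  } else "BOTH"
  list(value = value, pairs = pairs)
}

#' Remove M/M-type fusions
#'
#' M/M junctions (neither side on a known exon boundary) validate at a much
#' lower rate and are excluded from downstream landscape summaries.  Input
#' order is preserved; the operation is idempotent.
#'
#' @param annotated data.frame with a `junction_class` column (from
#'   [annotate_all()]).
#' @return The non-M/M subset.
#' @export
filter_mm <- function(annotated) {
  stopifnot("junction_class" %in% names(annotated))
  out <- annotated[annotated$junction_class != "MM", , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate a batch of fusion candidates with all three class labels
#'
#' Applies [classify_junction()], [classify_locus()] and [predict_frame()] to
#' each candidate.  Candidates whose partner symbols cannot be resolved in the
#' annotation are quarantined in a rejects table with a reason, never silently
#' dropped and never aborting the batch.
#'
#' @param candidates data.frame of fusion candidates.
#' @param models A `GeneModelSet`.
#' @param tol Boundary tolerance passed to [classify_junction()].
#' @param max_intervening Passed to [classify_locus()].
#' @return list with `annotated` (candidates plus gene_id5/gene_id3,
#'   junction_side5/3, junction_class, locus_class, frame_class and
#'   frame_pairs as JSON) and `rejects` (failed rows plus `reason`).
#' @export
annotate_all <- function(candidates, models, tol = 0L, max_intervening = 0L) {
  ann_rows <- list()
  rej_rows <- list()
  for (i in seq_len(nrow(candidates))) {
    c <- candidates[i, , drop = FALSE]
    g5 <- resolve_gene(models, c$gene5, c$chrom5, c$pos5)
    g3 <- resolve_gene(models, c$gene3, c$chrom3, c$pos3)
    if (is.na(g5) || is.na(g3)) {
      c$reason <- paste(na.omit(c(attr(g5, "reason"), attr(g3, "reason"))),
                        collapse = "; ")
      rej_rows[[length(rej_rows) + 1L]] <- c
      next
    }
    j <- classify_junction(c, models, tol = tol)
    l <- classify_locus(c, models, max_intervening = max_intervening)
    f <- predict_frame(c, models)
    c$gene_id5 <- g5
    c$gene_id3 <- g3
    c$junction_side5 <- j$side5
    c$junction_side3 <- j$side3
    c$junction_class <- j$value
    c$locus_class <- l
    c$frame_class <- f$value
    c$frame_pairs <- as.character(jsonlite::toJSON(f$pairs))
    ann_rows[[length(ann_rows) + 1L]] <- c
  }
  bindr <- function(rows, template_extra) {
    if (length(rows)) {
      out <- do.call(rbind, rows)
      rownames(out) <- NULL
      out
    } else {
      out <- candidates[0, , drop = FALSE]
      for (nm in template_extra) out[[nm]] <- character(0L)
      out
    }
  }
  list(
    annotated = bindr(ann_rows, c("gene_id5", "gene_id3", "junction_side5",
                                  "junction_side3", "junction_class",
                                  "locus_class", "frame_class", "frame_pairs")),
    rejects = bindr(rej_rows, "reason")
  )
}

#' @importFrom stats na.omit
NULL
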