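#' Gene-model index built from a GTF annotation
#'
#' `load_annotation()` reads a GTF (Ensembl/GENCODE attribute dialect) into a
#' `GeneModelSet`: an indexed set of gene, transcript, exon and CDS structures
#' supporting exon-boundary lookup, CDS-phase arithmetic and gene-adjacency
#' queries.  This index is the reference against which fusion junctions are
#' classified as falling on a known exon/intron boundary (an "E" side) or in
#' the middle of an exon (an "M" side).
#'
#' Coordinates are kept in the 1-based closed convention of GTF and
#' [GenomicRanges::GRanges], so annotation coordinates are stored verbatim.
#' Genes lacking an explicit `gene` feature line are inferred as the union of
#' their transcripts; a gene's biotype is `"coding"` exactly when at least one
#' of its transcripts carries CDS features.  The CDS phase (GTF frame column)
#' is recomputed from the CDS intervals in transcription order and
#' cross-checked against the file, with a warning on disagreement.
#'
#' @param gtf_path Path to a GTF file with `exon` features carrying `gene_id`
#'   and `transcript_id` attributes; `CDS`, `transcript` and `gene` features
#'   are used when present.
#' @return An object of class `GeneModelSet`: a list with elements
#'   `genes` (data.frame: gene_id, gene_name, chrom, strand, start, end,
#'   biotype), `transcripts` (transcript_id, gene_id, coding), `exons` and
#'   `cds` (per-interval data.frames), and `boundaries`, the exon-edge index
#'   (chrom, strand, coord, side) pooled over all transcripts.
#' @examples
#' gtf <- system.file("extdata", "toy_models.gtf", package = "chimerascape")
#' models <- load_annotation(gtf)
#' models$genes
#' @export
load_annotation <- function(gtf_path) {
  if (!file.exists(gtf_path)) {
    chs_stop("annotation file not found: ", gtf_path)
  }
  prescan_gtf(gtf_path)
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  if (length(gr) == 0L) {
    chs_stop("validation error: GTF contains no features: ", gtf_path)
  }

  feat <- as.character(gr$type)
  ex <- gr[feat == "exon"]
  if (length(ex) == 0L) {
    chs_stop("validation error: GTF contains no exon features: ", gtf_path)
  }
  if (anyNA(ex$gene_id) || anyNA(ex$transcript_id)) {
    chs_stop("validation error: exon feature lacking gene_id or transcript_id")
  }

  exons <- data.frame(
    transcript_id = as.character(ex$transcript_id),
    gene_id = as.character(ex$gene_id),
    chrom = as.character(GenomicRanges::seqnames(ex)),
    strand = as.character(GenomicRanges::strand(ex)),
    start = GenomicRanges::start(ex),
    end = GenomicRanges::end(ex),
    stringsAsFactors = FALSE
  )
  exons <- exons[order(exons$transcript_id, exons$start), , drop = FALSE]

  # exons of one transcript must not overlap
  by_tx <- split(exons, exons$transcript_id)
  for (tx in by_tx) {
    if (nrow(tx) > 1L && any(tx$start[-1L] <= tx$end[-nrow(tx)])) {
      chs_stop("validation error: overlapping exons in transcript ",
               tx$transcript_id[1L])
    }
    if (length(unique(tx$strand)) != 1L || length(unique(tx$chrom)) != 1L) {
      chs_stop("validation error: transcript ", tx$transcript_id[1L],
               " spans multiple strands or chromosomes")
    }
  }

  # exon outside its transcript's declared bounds
  txf <- gr[feat == "transcript"]
  if (length(txf) > 0L) {
    tx_lo <- setNames(GenomicRanges::start(txf), as.character(txf$transcript_id))
    tx_hi <- setNames(GenomicRanges::end(txf), as.character(txf$transcript_id))
    known <- exons$transcript_id %in% names(tx_lo)
    bad <- known & (exons$start < tx_lo[exons$transcript_id] |
                    exons$end > tx_hi[exons$transcript_id])
    if (any(bad)) {
      chs_stop("validation error: exon outside declared transcript bounds: ",
               exons$transcript_id[which(bad)[1L]])
    }
  }

  cf <- gr[feat == "CDS"]
  cds <- if (length(cf) > 0L) {
    data.frame(
      transcript_id = as.character(cf$transcript_id),
      gene_id = as.character(cf$gene_id),
      chrom = as.character(GenomicRanges::seqnames(cf)),
      strand = as.character(GenomicRanges::strand(cf)),
      start = GenomicRanges::start(cf),
      end = GenomicRanges::end(cf),
      phase_declared = if (!is.null(cf$phase)) as.integer(as.character(cf$phase)) else NA_integer_,
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(transcript_id = character(), gene_id = character(),
               chrom = character(), strand = character(),
               start = integer(), end = integer(),
               phase_declared = integer(), stringsAsFactors = FALSE)
  }
  cds <- cds[order(cds$transcript_id, cds$start), , drop = FALSE]

  # every CDS interval must be contained in an exon of the same transcript
  if (nrow(cds) > 0L) {
    for (i in seq_len(nrow(cds))) {
      e <- exons[exons$transcript_id == cds$transcript_id[i], , drop = FALSE]
      if (!any(e$start <= cds$start[i] & e$end >= cds$end[i])) {
        chs_stop("validation error: CDS interval not contained in an exon of ",
                 cds$transcript_id[i])
      }
    }
    check_declared_phase(cds)
  }

  transcripts <- unique(exons[, c("transcript_id", "gene_id")])
  transcripts$coding <- transcripts$transcript_id %in% cds$transcript_id
  rownames(transcripts) <- NULL

  # gene table: declared gene features where present, else union of transcripts
  gene_ids <- unique(exons$gene_id)
  gname <- setNames(gene_ids, gene_ids)
  if (!is.null(ex$gene_name)) {
    nm <- vapply(gene_ids, function(g) {
      v <- as.character(ex$gene_name[as.character(ex$gene_id) == g])
      v <- v[!is.na(v)]
      if (length(v)) v[1L] else g
    }, character(1L))
    gname[gene_ids] <- nm
  }
  genes <- do.call(rbind, lapply(gene_ids, function(g) {
    e <- exons[exons$gene_id == g, , drop = FALSE]
    data.frame(gene_id = g, gene_name = unname(gname[g]),
               chrom = e$chrom[1L], strand = e$strand[1L],
               start = min(e$start), end = max(e$end),
               stringsAsFactors = FALSE)
  }))
  gf <- gr[feat == "gene"]
  if (length(gf) > 0L) {
    m <- match(genes$gene_id, as.character(gf$gene_id))
    hit <- !is.na(m)
    genes$start[hit] <- pmin(genes$start[hit], GenomicRanges::start(gf)[m[hit]])
    genes$end[hit] <- pmax(genes$end[hit], GenomicRanges::end(gf)[m[hit]])
  }
  coding_genes <- unique(transcripts$gene_id[transcripts$coding])
  genes$biotype <- ifelse(genes$gene_id %in% coding_genes, "coding", "noncoding")
  genes <- genes[order(genes$chrom, genes$start, genes$gene_id), , drop = FALSE]
  rownames(genes) <- NULL

  boundaries <- exon_edge_table(exons)

  structure(
    list(genes = genes, transcripts = transcripts, exons = exons,
         cds = cds[, setdiff(names(cds), "phase_declared"), drop = FALSE],
         boundaries = boundaries),
    class = "GeneModelSet"
  )
}

# Reject structurally malformed GTF lines up front, naming the line number:
# rtracklayer's errors do not carry one.
prescan_gtf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- which(!grepl("^#", lines) & nzchar(lines))
  if (length(body) == 0L) {
    chs_stop("validation error: empty GTF file: ", path)
  }
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 9L) {
      chs_stop("malformed GTF line ", i, ": expected 9 tab-separated fields, got ",
               length(f))
    }
    if (is.na(suppressWarnings(as.integer(f[4L]))) ||
        is.na(suppressWarnings(as.integer(f[5L])))) {
      chs_stop("malformed GTF line ", i, ": non-numeric coordinates")
    }
    if (!f[7L] %in% c("+", "-", ".")) {
      chs_stop("malformed GTF line ", i, ": bad strand '", f[7L], "'")
    }
  }
  invisible(TRUE)
}

# donor = exon 3' edge, acceptor = exon 5' edge, in transcription orientation
exon_edge_table <- function(exons) {
  plus <- exons$strand == "+"
  donor <- ifelse(plus, exons$end, exons$start)
  acceptor <- ifelse(plus, exons$start, exons$end)
  b <- rbind(
    data.frame(chrom = exons$chrom, strand = exons$strand,
               coord = donor, side = "donor", stringsAsFactors = FALSE),
    data.frame(chrom = exons$chrom, strand = exons$strand,
               coord = acceptor, side = "acceptor", stringsAsFactors = FALSE)
  )
  b <- unique(b)
  b <- b[order(b$chrom, b$strand, b$side, b$coord), , drop = FALSE]
  rownames(b) <- NULL
  b
}

# phase expected by GTF: bases to skip before the first complete codon
cds_phases <- function(lengths) {
  cum <- c(0L, cumsum(lengths))[seq_along(lengths)]
  (3L - (cum %% 3L)) %% 3L
}

check_declared_phase <- function(cds) {
  for (tid in unique(cds$transcript_id)) {
    cc <- cds[cds$transcript_id == tid, , drop = FALSE]
    cc <- cc[order(if (cc$strand[1L] == "+") cc$start else -cc$start), , drop = FALSE]
    expected <- cds_phases(cc$end - cc$start + 1L)
    declared <- cc$phase_declared
    if (!anyNA(declared) && any(declared != expected)) {
      chs_warn("declared CDS frame disagrees with recomputed phase for ",
               tid, "; using recomputed values")
    }
  }
  invisible(TRUE)
}

#' Test whether a position is a known exon boundary
#'
#' An "E" side of a fusion junction coincides (within `tol`) with an annotated
#' splice-site edge.  Edges are taken in transcription orientation: the donor
#' is an exon's 3' edge and the acceptor its 5' edge, so on the minus strand
#' the donor is the lower genomic coordinate of the exon.
#'
#' @param models A `GeneModelSet` from [load_annotation()].
#' @param chrom,strand,pos Genomic location to test (1-based).
#' @param side `"donor"` or `"acceptor"`.
#' @param tol Non-negative integer tolerance in bases; default 0 (exact).
#' @return `TRUE` or `FALSE`.  An unknown chromosome yields `FALSE` with a
#'   warning, since caller output routinely names extra contigs.
#' @export
is_exon_boundary <- function(models, chrom, strand, pos,
                             side = c("donor", "acceptor"), tol = 0L) {
  side <- match.arg(side)
  stopifnot(inherits(models, "GeneModelSet"), tol >= 0L)
  if (!chrom %in% models$genes$chrom) {
    chs_warn("chromosome not in annotation: ", chrom)
    return(FALSE)
  }
  b <- models$boundaries
  hit <- b$chrom == chrom & b$strand == strand & b$side == side &
    abs(b$coord - pos) <= tol
  any(hit)
}

#' Genes whose span contains a position
#'
#' @inheritParams is_exon_boundary
#' @return A data.frame of matching gene records (both strands), ordered by
#'   `gene_id`; zero rows when the position is intergenic.
#' @export
genes_at <- function(models, chrom, pos) {
  stopifnot(inherits(models, "GeneModelSet"))
  g <- models$genes
  g <- g[g$chrom == chrom & g$start <= pos & g$end >= pos, , drop = FALSE]
  g <- g[order(g$gene_id), , drop = FALSE]
  rownames(g) <- NULL
  g
}

#' Count same-strand genes lying wholly between two genes
#'
#' Adjacency test behind read-through (cis-SAGe) classification: two genes are
#' neighbours when no other gene on the same strand lies wholly inside the gap
#' between their spans.
#'
#' @param models A `GeneModelSet`.
#' @param g5,g3 Gene identifiers (gene_id) of the two partners; must lie on
#'   the same chromosome and strand.
#' @return Integer count of intervening same-strand genes (0 when the spans
#'   touch or overlap).
#' @export
intervening_genes <- function(models, g5, g3) {
  stopifnot(inherits(models, "GeneModelSet"))
  a <- models$genes[models$genes$gene_id == g5, , drop = FALSE]
  b <- models$genes[models$genes$gene_id == g3, , drop = FALSE]
  if (nrow(a) != 1L || nrow(b) != 1L) {
    chs_stop("unknown gene id in intervening_genes()")
  }
  if (a$chrom != b$chrom || a$strand != b$strand) {
    chs_stop("intervening_genes() requires genes on the same chromosome and strand")
  }
  gap_lo <- min(a$end, b$end)
  gap_hi <- max(a$start, b$start)
  if (gap_lo >= gap_hi) return(0L)
  g <- models$genes
  sum(g$chrom == a$chrom & g$strand == a$strand &
      !(g$gene_id %in% c(g5, g3)) &
      g$start > gap_lo & g$end < gap_hi)
}

#' Write a GeneModelSet back to GTF
#'
#' Emits gene, transcript, exon and CDS lines with the frame column recomputed
#' from CDS interval order.  Output is deterministic, which makes it suitable
#' both for round-trip testing and for the synthetic-data generator.
#'
#' @param models A `GeneModelSet`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_gtf <- function(models, path) {
  stopifnot(inherits(models, "GeneModelSet"))
  lines <- character(0L)
  attr_gene <- function(g) {
    sprintf('gene_id "%s"; gene_name "%s";', g$gene_id, g$gene_name)
  }
  for (i in seq_len(nrow(models$genes))) {
    g <- models$genes[i, , drop = FALSE]
    lines <- c(lines, paste(g$chrom, "chimerascape", "gene", g$start, g$end,
                            ".", g$strand, ".", attr_gene(g), sep = "\t"))
    txs <- models$transcripts[models$transcripts$gene_id == g$gene_id, , drop = FALSE]
    txs <- txs[order(txs$transcript_id), , drop = FALSE]
    for (tid in txs$transcript_id) {
      e <- models$exons[models$exons$transcript_id == tid, , drop = FALSE]
      e <- e[order(e$start), , drop = FALSE]
      at <- sprintf('gene_id "%s"; transcript_id "%s"; gene_name "%s";',
                    g$gene_id, tid, g$gene_name)
      lines <- c(lines, paste(g$chrom, "chimerascape", "transcript",
                              min(e$start), max(e$end), ".", g$strand, ".", at,
                              sep = "\t"))
      lines <- c(lines, paste(e$chrom, "chimerascape", "exon", e$start, e$end,
                              ".", e$strand, ".", at, sep = "\t"))
      cc <- models$cds[models$cds$transcript_id == tid, , drop = FALSE]
      if (nrow(cc) > 0L) {
        tx_order <- order(if (g$strand == "+") cc$start else -cc$start)
        cc <- cc[tx_order, , drop = FALSE]
        ph <- cds_phases(cc$end - cc$start + 1L)
        genomic <- order(cc$start)
        lines <- c(lines, paste(cc$chrom[genomic], "chimerascape", "CDS",
                                cc$start[genomic], cc$end[genomic], ".",
                                cc$strand[genomic], ph[genomic], at, sep = "\t"))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

# exons of one transcript in transcription order (5' -> 3')
tx_exons <- function(models, transcript_id) {
  e <- models$exons[models$exons$transcript_id == transcript_id, , drop = FALSE]
  if (nrow(e) == 0L) chs_stop("unknown transcript: ", transcript_id)
  e[order(if (e$strand[1L] == "+") e$start else -e$start), , drop = FALSE]
}

tx_cds <- function(models, transcript_id) {
  cc <- models$cds[models$cds$transcript_id == transcript_id, , drop = FALSE]
  if (nrow(cc) == 0L) return(cc)
  cc[order(if (cc$strand[1L] == "+") cc$start else -cc$start), , drop = FALSE]
}

# pooled exon-edge set of one gene, across all its isoforms
gene_edges <- function(models, gene_id) {
  e <- models$exons[models$exons$gene_id == gene_id, , drop = FALSE]
  exon_edge_table(e)
}

#' @export
print.GeneModelSet <- function(x, ...) {
  cat("GeneModelSet:", nrow(x$genes), "genes,",
      nrow(x$transcripts), "transcripts,",
      nrow(x$exons), "exons,",
      nrow(x$boundaries), "indexed exon edges\n")
  invisible(x)
}
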