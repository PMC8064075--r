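#' Configuration for the synthetic fusion study generator
#'
#' Defines the toy study the generator emulates: a small multi-chromosome
#' genome and annotation, plus per-sample fusion call sets with controlled
#' proportions of junction types (E/E, E/M, M/E, M/M), locus classes
#' (Read-Through, INTRA-Others, INTERCHR) and frame outcomes (in-frame,
#' frame-shift, NA, both).  Gene placement is structured so that every
#' requested class cell is constructible: genes are laid out sequentially per
#' chromosome with a plus-strand block followed by a minus-strand block
#' (guaranteeing same-strand neighbours on both strands), and a fixed spacing
#' of non-coding genes realizes `fraction_noncoding` (non-coding 3' partners
#' drive the NA frame class).
#'
#' @param seed Integer seed; every placement and sequence draw flows from it.
#' @param n_chromosomes,genes_per_chromosome Genome scale (defaults 3 x 20).
#' @param exons_per_transcript,exon_bp,intron_bp,intergenic_bp Integer ranges
#'   (length-2 vectors) for gene structure, in bases.
#' @param utr5_bp,utr3_bp Untranslated-region length ranges of coding genes.
#' @param fraction_noncoding Fraction of genes without CDS.
#' @param class_counts data.frame with columns `locus`, `junction`, `count`;
#'   default 5 fusions in each of the 12 locus x junction cells.
#' @param frame_mix Named counts over IN_FRAME / FRAME_SHIFT / NA / BOTH,
#'   summing to the fusion total; default spreads all four classes through
#'   every cell.
#' @param n_samples,shared_fraction Number of call sets and the fraction of
#'   fusions injected into every sample (the rest are sample-specific).
#' @return list of class `sim_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_chromosomes = 3L,
                              genes_per_chromosome = 20L,
                              exons_per_transcript = c(3L, 6L),
                              exon_bp = c(100L, 300L),
                              intron_bp = c(50L, 500L),
                              intergenic_bp = c(200L, 800L),
                              utr5_bp = c(12L, 45L),
                              utr3_bp = c(12L, 60L),
                              fraction_noncoding = 0.2,
                              class_counts = NULL,
                              frame_mix = NULL,
                              n_samples = 3L,
                              shared_fraction = 0.2) {
  if (is.null(class_counts)) {
    class_counts <- expand.grid(locus = LOCUS_LEVELS, junction = JUNCTION_LEVELS,
                                stringsAsFactors = FALSE)
    class_counts$count <- 5L
  }
  total <- sum(class_counts$count)
  if (is.null(frame_mix)) {
    # spread all four frame classes across cells via per-cell rotation
    frame_mix <- NULL  # computed per cell in assign_frame_targets()
  }
  cfg <- list(seed = as.integer(seed), n_chromosomes = n_chromosomes,
              genes_per_chromosome = genes_per_chromosome,
              exons_per_transcript = exons_per_transcript,
              exon_bp = exon_bp, intron_bp = intron_bp,
              intergenic_bp = intergenic_bp,
              utr5_bp = utr5_bp, utr3_bp = utr3_bp,
              fraction_noncoding = fraction_noncoding,
              class_counts = class_counts, frame_mix = frame_mix,
              n_samples = n_samples, shared_fraction = shared_fraction)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg, total)
  cfg
}

validate_sim_config <- function(cfg, total) {
  stopifnot(cfg$n_chromosomes >= 1L, cfg$genes_per_chromosome >= 1L)
  if (any(cfg$class_counts$count < 0L)) chs_stop("class counts must be >= 0")
  if (cfg$shared_fraction < 0 || cfg$shared_fraction > 1) {
    chs_stop("shared_fraction must be in [0, 1]")
  }
  if (cfg$fraction_noncoding < 0 || cfg$fraction_noncoding > 1) {
    chs_stop("fraction_noncoding must be in [0, 1]")
  }
  rt <- sum(cfg$class_counts$count[cfg$class_counts$locus == "READ_THROUGH"])
  if (rt > 0L && cfg$genes_per_chromosome < 2L) {
    chs_stop("infeasible config: READ_THROUGH fusions need >= 2 genes per chromosome")
  }
  if (!is.null(cfg$frame_mix)) {
    if (!all(names(cfg$frame_mix) %in% FRAME_LEVELS)) {
      chs_stop("frame_mix names must be among ", paste(FRAME_LEVELS, collapse = ", "))
    }
    if (sum(cfg$frame_mix) != total) {
      chs_stop("frame_mix must sum to the total fusion count (", total, ")")
    }
    na_ct <- if ("NA" %in% names(cfg$frame_mix)) cfg$frame_mix[["NA"]] else 0L
    if (na_ct > 0L && cfg$fraction_noncoding == 0) {
      chs_stop("infeasible config: NA frame class needs non-coding genes")
    }
  }
  invisible(cfg)
}

rint <- function(range, n = 1L) {
  if (range[1L] == range[2L]) rep(range[1L], n) else
    sample(seq(range[1L], range[2L]), n, replace = TRUE)
}

# map a spliced-coordinate interval [lo, hi] (1-based along the mature
# transcript) to genomic intervals, given exons (genomic ascending) and strand
spliced_to_genomic <- function(exons, strand, lo, hi) {
  ord <- if (strand == "+") seq_len(nrow(exons)) else rev(seq_len(nrow(exons)))
  out <- NULL
  off <- 0L
  for (i in ord) {
    w <- exons$end[i] - exons$start[i] + 1L
    a <- max(lo, off + 1L); b <- min(hi, off + w)
    if (a <= b) {
      if (strand == "+") {
        gs <- exons$start[i] + (a - off - 1L); ge <- exons$start[i] + (b - off - 1L)
      } else {
        ge <- exons$end[i] - (a - off - 1L); gs <- exons$end[i] - (b - off - 1L)
      }
      out <- rbind(out, data.frame(start = gs, end = ge))
    }
    off <- off + w
  }
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# generator-side coding arithmetic on a raw gene record
g_retained5 <- function(g, pos) {
  if (is.null(g$cds)) return(NA_integer_)
  cc <- g$cds
  if (!any(cc$start <= pos & cc$end >= pos)) return(NA_integer_)
  if (g$strand == "+") sum(pmax(0L, pmin(cc$end, pos) - cc$start + 1L))
  else sum(pmax(0L, cc$end - pmax(cc$start, pos) + 1L))
}

g_discarded3 <- function(g, pos) {
  if (is.null(g$cds)) return(NA_integer_)
  cc <- g$cds
  if (!any(cc$start <= pos & cc$end >= pos)) return(NA_integer_)
  if (g$strand == "+") sum(pmax(0L, pmin(cc$end, pos - 1L) - cc$start + 1L))
  else sum(pmax(0L, cc$end - pmax(cc$start, pos + 1L) + 1L))
}

g_donor_edges <- function(g) if (g$strand == "+") g$exons$end else g$exons$start
g_acceptor_edges <- function(g) if (g$strand == "+") g$exons$start else g$exons$end

# a mid-exon position (never an exon edge); when residue is given, a CDS base
# whose retained (role "5") or discarded (role "3") count is = residue mod 3
g_interior_pos <- function(g, role, residue = NULL) {
  if (is.null(residue)) {
    w <- g$exons$end - g$exons$start + 1L
    i <- which(w >= 5L)[1L]
    if (is.na(i)) return(NA_integer_)
    return((g$exons$start[i] + g$exons$end[i]) %/% 2L)
  }
  if (is.null(g$cds)) return(NA_integer_)
  cc <- g$cds[order(-(g$cds$end - g$cds$start)), , drop = FALSE]
  dir <- if (g$strand == "+") 1L else -1L
  for (j in seq_len(nrow(cc))) {
    if (cc$end[j] - cc$start[j] + 1L < 9L) next
    pos0 <- (cc$start[j] + cc$end[j]) %/% 2L
    val0 <- if (role == "5") g_retained5(g, pos0) else g_discarded3(g, pos0)
    shift <- (residue - val0) %% 3L
    pos <- pos0 + dir * shift
    ex <- g$exons[g$exons$start <= pos & g$exons$end >= pos, , drop = FALSE]
    if (nrow(ex) == 1L && pos > ex$start && pos < ex$end) return(pos)
  }
  NA_integer_
}

# choose junction coordinates on a gene pair satisfying a junction class and
# frame target; returns list(pos5, pos3) or NULL when this pair cannot host it
place_junction <- function(g5, g3, jclass, ftarget, used_keys) {
  j5 <- substr(jclass, 1L, 1L); j3 <- substr(jclass, 2L, 2L)
  key <- function(p5, p3) paste(g5$gene_name, g3$gene_name, p5, p3, sep = "|")

  if (ftarget == "NA") {
    p5s <- if (j5 == "E") g_donor_edges(g5) else g_interior_pos(g5, "5")
    p3s <- if (j3 == "E") g_acceptor_edges(g3) else g_interior_pos(g3, "3")
    for (p5 in p5s) for (p3 in p3s) {
      if (!is.na(p5) && !is.na(p3) && !key(p5, p3) %in% used_keys) {
        return(list(pos5 = p5, pos3 = p3))
      }
    }
    return(NULL)
  }

  # coding targets: enumerate (pos5, r) and (pos3, d) options in CDS
  opts5 <- if (j5 == "E") {
    ps <- g_donor_edges(g5)
    rs <- vapply(ps, function(p) g_retained5(g5, p), integer(1L))
    data.frame(pos = ps[!is.na(rs)], val = rs[!is.na(rs)])
  } else {
    ps <- vapply(0:2, function(rho) g_interior_pos(g5, "5", rho), integer(1L))
    data.frame(pos = ps[!is.na(ps)],
               val = vapply(ps[!is.na(ps)], function(p) g_retained5(g5, p), integer(1L)))
  }
  opts3 <- if (j3 == "E") {
    ps <- g_acceptor_edges(g3)
    ds <- vapply(ps, function(p) g_discarded3(g3, p), integer(1L))
    data.frame(pos = ps[!is.na(ds)], val = ds[!is.na(ds)])
  } else {
    ps <- vapply(0:2, function(rho) g_interior_pos(g3, "3", rho), integer(1L))
    data.frame(pos = ps[!is.na(ps)],
               val = vapply(ps[!is.na(ps)], function(p) g_discarded3(g3, p), integer(1L)))
  }
  if (nrow(opts5) == 0L || nrow(opts3) == 0L) return(NULL)

  for (i in seq_len(nrow(opts5))) for (j in seq_len(nrow(opts3))) {
    r <- opts5$val[i]; d <- opts3$val[j]
    ok <- switch(ftarget,
      IN_FRAME = r %% 3L == d %% 3L,
      FRAME_SHIFT = r %% 3L != d %% 3L,
      # BOTH: the second 3' isoform (CDS start shifted one base downstream)
      # discards d-1 coding bases, so matching the primary isoform in frame
      # guarantees one in-frame and one shifted pair
      BOTH = (r %% 3L == d %% 3L) && d >= 1L)
    if (ok && !key(opts5$pos[i], opts3$pos[j]) %in% used_keys) {
      return(list(pos5 = opts5$pos[i], pos3 = opts3$pos[j]))
    }
  }
  NULL
}

# per-cell rotation through the four frame classes so every locus x junction
# cell sees every frame class when its count allows
assign_frame_targets <- function(class_counts, frame_mix = NULL) {
  if (is.null(frame_mix)) {
    unlist(lapply(class_counts$count, function(n) {
      rep(FRAME_LEVELS, length.out = n)
    }), use.names = FALSE)
  } else {
    remaining <- setNames(rep(0L, length(FRAME_LEVELS)), FRAME_LEVELS)
    remaining[names(frame_mix)] <- as.integer(frame_mix)
    out <- character(0L)
    for (n in class_counts$count) {
      ptr <- 1L
      for (s in seq_len(n)) {
        for (step in seq_len(4L)) {
          cand <- FRAME_LEVELS[(ptr + step - 2L) %% 4L + 1L]
          if (remaining[cand] > 0L) {
            out <- c(out, cand)
            remaining[cand] <- remaining[cand] - 1L
            ptr <- (ptr + step - 1L) %% 4L + 1L
            break
          }
        }
      }
    }
    out
  }
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a synthetic fusion study with complete ground truth
#'
#' Builds a deterministic toy genome (random sequence), a GTF-style gene
#' annotation, per-sample fusion call tables, and a truth table giving the
#' junction, locus and frame label of every emitted fusion — so the whole
#' classification pipeline is testable without any external data.  E/E
#' junction coordinates land exactly on generated exon edges and M sides land
#' strictly inside exon bodies; in-frame and frame-shift cases are built by
#' choosing coding-sequence positions with the required mod-3 relation; BOTH
#' cases add a second 3'-partner isoform whose CDS start is shifted by one
#' base; NA cases use non-coding 3' partners.  For every E/E fusion the truth
#' also records the spliced chimeric transcript sequence around the junction.
#'
#' @param config A `sim_config` from [simulation_config()].
#' @param outdir Optional directory; when given, `genome.fa`,
#'   `annotation.gtf`, `calls_<sample>.tsv` and `truth.tsv` are written there
#'   (byte-identical across runs with the same config).
#' @return list with `genome` ([Biostrings::DNAStringSet]), `models`
#'   (`GeneModelSet`), `calls` (named list of per-sample data.frames), `truth`
#'   (data.frame keyed like the call tables), `config`, and `paths` (NULL or
#'   the written file paths).
#' @export
simulate_fusion_study <- function(config = simulation_config(), outdir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)

  ## ---- gene and genome structure -----------------------------------------
  genes <- list()
  gi <- 0L
  chrom_len <- integer(config$n_chromosomes)
  nc_every <- if (config$fraction_noncoding > 0) {
    max(2L, round(1 / config$fraction_noncoding))
  } else Inf
  for (ci in seq_len(config$n_chromosomes)) {
    chrom <- paste0("chrS", ci)
    cursor <- 1L
    n_plus <- ceiling(config$genes_per_chromosome * 0.6)
    for (k in seq_len(config$genes_per_chromosome)) {
      gi <- gi + 1L
      strand <- if (k <= n_plus) "+" else "-"
      coding <- !(k %% nc_every == 0L)
      n_ex <- rint(config$exons_per_transcript)
      ex_len <- rint(config$exon_bp, n_ex)
      introns <- if (n_ex > 1L) rint(config$intron_bp, n_ex - 1L) else integer(0L)
      gstart <- cursor + rint(config$intergenic_bp)
      starts <- gstart + c(0L, cumsum(ex_len[-n_ex] + introns))
      exons <- data.frame(start = starts, end = starts + ex_len - 1L)
      cds <- NULL
      if (coding) {
        total <- sum(ex_len)
        u5 <- rint(config$utr5_bp); u3 <- rint(config$utr3_bp)
        cds_len <- total - u5 - u3
        u3 <- u3 + cds_len %% 3L
        cds <- spliced_to_genomic(exons, strand, u5 + 1L, total - u3)
      }
      genes[[gi]] <- list(
        gene_id = sprintf("G%03d", gi),
        gene_name = sprintf("SYNG%03d", gi),
        chrom = chrom, strand = strand, coding = coding,
        exons = exons, cds = cds, chrom_index = ci, local_index = k,
        iso_b = FALSE, skip_iso = FALSE
      )
      cursor <- max(exons$end)
    }
    chrom_len[ci] <- cursor + 500L
  }
  names(chrom_len) <- paste0("chrS", seq_len(config$n_chromosomes))

  ## ---- candidate gene-pair pools per locus class -------------------------
  gdf <- data.frame(
    idx = seq_along(genes),
    chrom = vapply(genes, `[[`, "", "chrom"),
    strand = vapply(genes, `[[`, "", "strand"),
    start = vapply(genes, function(g) min(g$exons$start), integer(1L)),
    end = vapply(genes, function(g) max(g$exons$end), integer(1L)),
    coding = vapply(genes, `[[`, TRUE, "coding"),
    stringsAsFactors = FALSE
  )
  locus_of_pair <- function(a, b) {
    if (gdf$chrom[a] != gdf$chrom[b]) return("INTERCHR")
    if (gdf$strand[a] != gdf$strand[b]) return("INTRA_OTHERS")
    upstream <- if (gdf$strand[a] == "+") gdf$start[a] < gdf$start[b]
                else gdf$end[a] > gdf$end[b]
    if (!upstream) return("INTRA_OTHERS")
    gap_lo <- min(gdf$end[a], gdf$end[b]); gap_hi <- max(gdf$start[a], gdf$start[b])
    between <- gdf$chrom == gdf$chrom[a] & gdf$strand == gdf$strand[a] &
      !(gdf$idx %in% c(a, b)) & gdf$start > gap_lo & gdf$end < gap_hi
    if (any(between)) "INTRA_OTHERS" else "READ_THROUGH"
  }
  pools <- list(READ_THROUGH = NULL, INTRA_OTHERS = NULL, INTERCHR = NULL)
  for (ch in unique(gdf$chrom)) {
    idx <- gdf$idx[gdf$chrom == ch]
    for (a in idx) for (b in idx) {
      if (a == b) next
      loc <- locus_of_pair(a, b)
      pools[[loc]] <- rbind(pools[[loc]], c(a, b))
    }
  }
  chroms <- unique(gdf$chrom)
  if (length(chroms) > 1L) {
    for (ci in seq_along(chroms)) {
      a_idx <- gdf$idx[gdf$chrom == chroms[ci]]
      b_idx <- gdf$idx[gdf$chrom == chroms[ci %% length(chroms) + 1L]]
      pools$INTERCHR <- rbind(pools$INTERCHR,
                              cbind(rep(a_idx, each = length(b_idx)), b_idx))
    }
  }
  pools <- lapply(pools, function(m) {
    if (is.null(m)) matrix(integer(0L), ncol = 2L) else m[sample(nrow(m)), , drop = FALSE]
  })

  ## ---- assemble fusions --------------------------------------------------
  cc <- config$class_counts
  rows <- cc[rep(seq_len(nrow(cc)), cc$count), c("locus", "junction"), drop = FALSE]
  rows$frame <- assign_frame_targets(cc, config$frame_mix)
  if (any(rows$frame == "NA") && !any(!gdf$coding)) {
    chs_stop("infeasible config: NA frame class needs non-coding genes")
  }
  used_keys <- character(0L)
  iso_locked <- integer(0L)    # genes given a BOTH isoform: frame-evaluable use barred
  frame_locked <- integer(0L)  # genes in frame-evaluable use: must stay isoform-stable
  cursors <- setNames(rep(1L, 3L), LOCUS_LEVELS)
  fusions <- vector("list", nrow(rows))
  evaluable <- c("IN_FRAME", "FRAME_SHIFT", "BOTH")
  # BOTH fusions are placed first: each needs a 3' gene untouched by any
  # other frame-evaluable fusion (its extra isoform would rewrite that
  # fusion's truth), and such genes run out if BOTH is placed last
  placement_order <- order(match(rows$frame,
                                 c("BOTH", "IN_FRAME", "FRAME_SHIFT", "NA")))
  for (fi in placement_order) {
    loc <- rows$locus[fi]; jc <- rows$junction[fi]; ft <- rows$frame[fi]
    pool <- pools[[loc]]
    if (nrow(pool) == 0L) chs_stop("infeasible config: no gene pair for ", loc)
    placed <- NULL
    for (try in seq_len(nrow(pool))) {
      at <- (cursors[loc] + try - 2L) %% nrow(pool) + 1L
      a <- pool[at, 1L]; b <- pool[at, 2L]
      if (ft == "NA") {
        if (gdf$coding[b]) next
      } else {
        if (!gdf$coding[a] || !gdf$coding[b]) next
        if (a %in% iso_locked || b %in% iso_locked) next
        # adding an isoform to a gene already used in a frame call would
        # retroactively change that call's truth
        if (ft == "BOTH" && b %in% frame_locked) next
      }
      placed <- place_junction(genes[[a]], genes[[b]], jc, ft, used_keys)
      if (!is.null(placed)) {
        cursors[loc] <- at %% nrow(pool) + 1L
        break
      }
    }
    if (is.null(placed)) {
      chs_stop("infeasible config: could not place a ", loc, "/", jc, "/", ft,
               " fusion with the generated gene structures")
    }
    if (ft == "BOTH") {
      genes[[b]]$iso_b <- TRUE
      iso_locked <- c(iso_locked, b)
    }
    if (ft %in% evaluable) frame_locked <- unique(c(frame_locked, a, b))
    fusions[[fi]] <- list(i5 = a, i3 = b, pos5 = placed$pos5, pos3 = placed$pos3,
                          junction = jc, locus = loc, frame = ft)
    used_keys <- c(used_keys,
                   paste(genes[[a]]$gene_name, genes[[b]]$gene_name,
                         placed$pos5, placed$pos3, sep = "|"))
  }

  ## ---- finalize models ---------------------------------------------------
  used_anywhere <- unique(unlist(lapply(fusions, function(f) c(f$i5, f$i3))))
  exon_rows <- list(); cds_rows <- list(); tx_rows <- list(); gene_rows <- list()
  for (g_idx in seq_along(genes)) {
    g <- genes[[g_idx]]
    t1 <- paste0(g$gene_id, ".t1")
    gene_rows[[g$gene_id]] <- data.frame(
      gene_id = g$gene_id, gene_name = g$gene_name, chrom = g$chrom,
      strand = g$strand, start = min(g$exons$start), end = max(g$exons$end),
      biotype = if (g$coding) "coding" else "noncoding", stringsAsFactors = FALSE)
    add_tx <- function(tid, exons, cds) {
      tx_rows[[tid]] <<- data.frame(transcript_id = tid, gene_id = g$gene_id,
                                    coding = !is.null(cds), stringsAsFactors = FALSE)
      exon_rows[[tid]] <<- data.frame(transcript_id = tid, gene_id = g$gene_id,
                                      chrom = g$chrom, strand = g$strand,
                                      start = exons$start, end = exons$end,
                                      stringsAsFactors = FALSE)
      if (!is.null(cds)) {
        cds_rows[[tid]] <<- data.frame(transcript_id = tid, gene_id = g$gene_id,
                                       chrom = g$chrom, strand = g$strand,
                                       start = cds$start, end = cds$end,
                                       stringsAsFactors = FALSE)
      }
    }
    add_tx(t1, g$exons, g$cds)
    if (g$iso_b) {
      # CDS start one base downstream in transcription orientation; same exons
      cds2 <- g$cds
      if (g$strand == "+") {
        first <- which.min(cds2$start)
        cds2$start[first] <- cds2$start[first] + 1L
      } else {
        first <- which.max(cds2$end)
        cds2$end[first] <- cds2$end[first] - 1L
      }
      add_tx(paste0(g$gene_id, ".t2"), g$exons, cds2)
    } else if (!g$coding && !(g_idx %in% used_anywhere) &&
               nrow(g$exons) >= 3L && g$local_index %% 2L == 0L) {
      # exercise multi-isoform parsing on untouched non-coding genes:
      # an exon-skipping isoform adds no new edge coordinates
      add_tx(paste0(g$gene_id, ".t2"),
             g$exons[-2L, , drop = FALSE], NULL)
    }
  }
  exons_df <- do.call(rbind, unname(exon_rows))
  cds_df <- if (length(cds_rows)) do.call(rbind, unname(cds_rows)) else
    data.frame(transcript_id = character(), gene_id = character(),
               chrom = character(), strand = character(),
               start = integer(), end = integer(), stringsAsFactors = FALSE)
  genes_df <- do.call(rbind, unname(gene_rows))
  genes_df <- genes_df[order(genes_df$chrom, genes_df$start, genes_df$gene_id), ]
  rownames(genes_df) <- NULL
  tx_df <- do.call(rbind, unname(tx_rows))
  rownames(tx_df) <- NULL
  models <- structure(list(genes = genes_df, transcripts = tx_df,
                           exons = exons_df[order(exons_df$transcript_id, exons_df$start), ],
                           cds = cds_df[order(cds_df$transcript_id, cds_df$start), ],
                           boundaries = exon_edge_table(exons_df)),
                      class = "GeneModelSet")

  genome <- Biostrings::DNAStringSet(vapply(chrom_len, random_dna, character(1L)))
  names(genome) <- names(chrom_len)

  ## ---- truth table and chimeric sequences --------------------------------
  truth <- do.call(rbind, lapply(fusions, function(f) {
    g5 <- genes[[f$i5]]; g3 <- genes[[f$i3]]
    data.frame(gene5 = g5$gene_name, gene3 = g3$gene_name,
               chrom5 = g5$chrom, strand5 = g5$strand, pos5 = f$pos5,
               chrom3 = g3$chrom, strand3 = g3$strand, pos3 = f$pos3,
               junction = f$junction, locus = f$locus, frame = f$frame,
               gene_id5 = g5$gene_id, gene_id3 = g3$gene_id,
               stringsAsFactors = FALSE)
  }))
  truth$chimeric_seq <- NA_character_
  for (i in seq_len(nrow(truth))) {
    if (truth$junction[i] != "EE") next
    t5 <- paste0(truth$gene_id5[i], ".t1"); t3 <- paste0(truth$gene_id3[i], ".t1")
    o5 <- tx_offset(models, t5, truth$pos5[i])
    o3 <- tx_offset(models, t3, truth$pos3[i])
    s5 <- spliced_transcript_seq(models, genome, t5)
    s3 <- spliced_transcript_seq(models, genome, t3)
    truth$chimeric_seq[i] <- paste0(
      as.character(Biostrings::subseq(s5, 1L, o5)),
      as.character(Biostrings::subseq(s3, o3, length(s3))))
  }

  ## ---- per-sample call tables --------------------------------------------
  samples <- sprintf("sample%d", seq_len(config$n_samples))
  n <- nrow(truth)
  ord <- sample(n)
  n_shared <- round(config$shared_fraction * n)
  assign_to <- vector("list", n)
  for (j in seq_len(n)) {
    f <- ord[j]
    assign_to[[f]] <- if (j <= n_shared) samples
                      else samples[(j - n_shared - 1L) %% length(samples) + 1L]
  }
  calls <- setNames(lapply(samples, function(s) {
    idx <- which(vapply(assign_to, function(a) s %in% a, logical(1L)))
    if (length(idx) == 0L) {
      return(truth[0, c("gene5", "chrom5", "strand5", "pos5",
                        "gene3", "chrom3", "strand3", "pos3"), drop = FALSE])
    }
    df <- truth[idx, c("gene5", "chrom5", "strand5", "pos5",
                       "gene3", "chrom3", "strand3", "pos3"), drop = FALSE]
    df <- cbind(sample = s, df)
    df$span_reads <- sample(5:60, nrow(df), replace = TRUE)
    df$junc_reads <- sample(2:20, nrow(df), replace = TRUE)
    rownames(df) <- NULL
    df
  }), samples)

  paths <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      genome = file.path(outdir, "genome.fa"),
      gtf = file.path(outdir, "annotation.gtf"),
      calls = setNames(file.path(outdir, sprintf("calls_%s.tsv", samples)), samples),
      truth = file.path(outdir, "truth.tsv")
    )
    Biostrings::writeXStringSet(genome, paths$genome)
    write_gtf(models, paths$gtf)
    for (s in samples) {
      write.table(calls[[s]][, setdiff(names(calls[[s]]), "sample")],
                  paths$calls[[s]], sep = "\t", quote = FALSE, row.names = FALSE)
    }
    write.table(truth, paths$truth, sep = "\t", quote = FALSE, row.names = FALSE)
  }

  list(genome = genome, models = models, calls = calls, truth = truth,
       config = config, paths = paths)
}

#' Simulate a qPCR Ct table from known fold changes
#'
#' Emits cycle-threshold values consistent with stated true fold changes
#' (relative to a calibrator sample, normalized to a reference target) plus
#' Gaussian replicate noise, so the 2^-ddCt arithmetic can be validated
#' against known truth.
#'
#' @param fold_changes data.frame with columns `target`, `sample`, `fc`
#'   (true fold change vs. the calibrator).  The calibrator itself need not
#'   appear; it is added with fold change 1.
#' @param reference Reference target name (default `"GAPDH"`).
#' @param calibrator Calibrator sample name (default `"calibrator"`).
#' @param n_replicates Technical replicates per (sample, target).
#' @param noise_sd Gaussian noise on each Ct, in cycles (default 0.1; 0 gives
#'   exact recovery).
#' @param base_ct Baseline reference Ct.
#' @return data.frame (`sample`, `target`, `replicate`, `ct`) with the truth
#'   attached as attribute `truth`.
#' @export
simulate_ct_table <- function(fold_changes, reference = "GAPDH",
                              calibrator = "calibrator", n_replicates = 3L,
                              noise_sd = 0.1, base_ct = 20) {
  stopifnot(all(c("target", "sample", "fc") %in% names(fold_changes)),
            all(fold_changes$fc > 0), noise_sd >= 0)
  targets <- unique(fold_changes$target)
  samples <- unique(c(calibrator, fold_changes$sample))
  target_offset <- setNames(3 + 2 * (seq_along(targets) - 1L), targets)
  fc_of <- function(t, s) {
    if (s == calibrator) return(1)
    v <- fold_changes$fc[fold_changes$target == t & fold_changes$sample == s]
    if (length(v) == 0L) 1 else v[1L]
  }
  rows <- list()
  for (s in samples) {
    for (t in c(reference, targets)) {
      true_dct <- if (t == reference) 0 else target_offset[[t]] - log2(fc_of(t, s))
      ct <- base_ct + true_dct + rnorm(n_replicates, 0, noise_sd)
      rows[[paste(s, t)]] <- data.frame(sample = s, target = t,
                                        replicate = seq_len(n_replicates),
                                        ct = ct, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, unname(rows))
  rownames(out) <- NULL
  attr(out, "truth") <- fold_changes
  attr(out, "reference") <- reference
  attr(out, "calibrator") <- calibrator
  out
}

#' Simulate a fractionation Ct table from known nuclear/cytoplasmic ratios
#'
#' @param ratios Named numeric vector of true nuclear/cytoplasmic expression
#'   ratios per target (e.g. a MALAT1-like nucleus-retained control has a
#'   ratio far above 1, a GAPDH-like mRNA far below 1).
#' @param n_replicates Replicates per (fraction, target).
#' @param noise_sd Gaussian Ct noise in cycles.
#' @param base_ct Baseline cytoplasmic Ct.
#' @return data.frame (`fraction`, `target`, `replicate`, `ct`) with attribute
#'   `truth`.
#' @export
simulate_nc_table <- function(ratios, n_replicates = 3L, noise_sd = 0.1,
                              base_ct = 22) {
  stopifnot(!is.null(names(ratios)), all(ratios > 0), noise_sd >= 0)
  rows <- list()
  for (t in names(ratios)) {
    ct_cyt <- base_ct + rnorm(n_replicates, 0, noise_sd)
    ct_nuc <- base_ct - log2(ratios[[t]]) + rnorm(n_replicates, 0, noise_sd)
    rows[[t]] <- rbind(
      data.frame(fraction = "cytoplasmic", target = t,
                 replicate = seq_len(n_replicates), ct = ct_cyt,
                 stringsAsFactors = FALSE),
      data.frame(fraction = "nuclear", target = t,
                 replicate = seq_len(n_replicates), ct = ct_nuc,
                 stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, unname(rows))
  rownames(out) <- NULL
  attr(out, "truth") <- ratios
  out
}
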