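#' Summarize the chimeric-RNA landscape of one sample
#'
#' Counts and proportions per category for each of the three classification
#' schemes (junction type, locus type, frame type), at a named filtering stage
#' — `"all"` (every candidate) or `"non_mm"` (after [filter_mm()]).  Passing
#' `stage = "non_mm"` with M/M rows still present is an error: the filter must
#' be applied first.  Proportions are exact fractions; rounding happens only
#' at presentation.
#'
#' @param annotated Annotated fusion data.frame from [annotate_all()].
#' @param sample Sample label stored on the summary (default: taken from the
#'   data, or `NA`).
#' @param stage `"all"` or `"non_mm"`.
#' @return Object of class `landscape_summary`: list with `sample`, `stage`,
#'   `n`, `counts` (named vectors per scheme) and `proportions` (absent
#'   entries when `n` is 0).
#' @export
summarize_landscape <- function(annotated, sample = NULL, stage = c("all", "non_mm")) {
  stage <- match.arg(stage)
  if (stage == "non_mm" && nrow(annotated) > 0L &&
      any(annotated$junction_class == "MM")) {
    chs_stop("stage 'non_mm' requires filter_mm() to have been applied")
  }
  if (is.null(sample)) {
    sample <- if (nrow(annotated) > 0L && "sample" %in% names(annotated)) {
      paste(unique(annotated$sample), collapse = "+")
    } else NA_character_
  }
  n <- nrow(annotated)
  counts <- list(
    junction = count_levels(annotated$junction_class, JUNCTION_LEVELS),
    locus = count_levels(annotated$locus_class, LOCUS_LEVELS),
    frame = count_levels(annotated$frame_class, FRAME_LEVELS)
  )
  proportions <- if (n > 0L) lapply(counts, function(x) x / n) else NULL
  structure(list(sample = sample, stage = stage, n = n,
                 counts = counts, proportions = proportions),
            class = "landscape_summary")
}

#' @export
print.landscape_summary <- function(x, ...) {
  cat("Landscape summary for", x$sample, "at stage", x$stage,
      "-", x$n, "fusions\n")
  for (scheme in names(x$counts)) {
    cnt <- x$counts[[scheme]]
    if (is.null(x$proportions)) {
      cat(" ", scheme, ": ", paste(names(cnt), cnt, sep = "=", collapse = " "), "\n")
    } else {
      pct <- sprintf("%d (%.0f%%)", cnt, 100 * x$proportions[[scheme]])
      cat(" ", scheme, ": ", paste(names(cnt), pct, sep = "=", collapse = "  "), "\n")
    }
  }
  invisible(x)
}

#' Flatten a landscape summary to a long data.frame
#'
#' @param x A `landscape_summary`.
#' @param ... Unused.
#' @return data.frame with columns sample, stage, scheme, category, count,
#'   proportion.
#' @export
as.data.frame.landscape_summary <- function(x, ...) {
  do.call(rbind, lapply(names(x$counts), function(scheme) {
    cnt <- x$counts[[scheme]]
    data.frame(sample = x$sample, stage = x$stage, scheme = scheme,
               category = names(cnt), count = as.integer(cnt),
               proportion = if (x$n > 0L) as.numeric(cnt) / x$n else NA_real_,
               stringsAsFactors = FALSE)
  }))
}

#' Cross-sample overlap decomposition of fusion sets
#'
#' Decomposes 2–5 per-sample fusion sets into their disjoint Venn regions.
#' Identity defaults to junction level (partner symbols plus both junction
#' coordinates); `mode = "gene_pair"` collapses junction forms of the same
#' partner pair, which merges entries such as two junction variants of one
#' read-through pair.
#'
#' @param per_sample_sets Named list of fusion data.frames, one per sample.
#' @param mode `"junction"` or `"gene_pair"`.
#' @return Object of class `overlap_report`: list with `mode`, `samples`,
#'   `regions` (named counts for every nonempty sample subset, disjoint),
#'   `members` (keys per region) and `union_size`.
#' @export
compute_overlap <- function(per_sample_sets, mode = c("junction", "gene_pair")) {
  mode <- match.arg(mode)
  k <- length(per_sample_sets)
  if (k < 2L || k > 5L) chs_stop("compute_overlap() supports 2-5 samples, got ", k)
  samples <- names(per_sample_sets)
  if (is.null(samples) || any(!nzchar(samples))) {
    chs_stop("per_sample_sets must be a named list")
  }
  keyfun <- if (mode == "junction") fusion_key else gene_pair_key
  keysets <- lapply(per_sample_sets, function(df) unique(keyfun(df)))
  universe <- sort(unique(unlist(keysets)))
  member <- vapply(keysets, function(ks) universe %in% ks, logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L,
                                               dimnames = list(NULL, samples))
  # every nonempty subset of samples, smallest first, named "A&B"
  subsets <- unlist(lapply(seq_len(k), function(m) {
    asplit(utils::combn(samples, m), 2L)
  }), recursive = FALSE)
  regions <- integer(0L)
  members <- list()
  for (ss in subsets) {
    sel <- if (length(universe)) {
      rowSums(member[, ss, drop = FALSE]) == length(ss) &
        rowSums(member[, setdiff(samples, ss), drop = FALSE]) == 0L
    } else logical(0L)
    nm <- paste(ss, collapse = "&")
    regions[nm] <- sum(sel)
    members[[nm]] <- universe[sel]
  }
  structure(list(mode = mode, samples = samples, regions = regions,
                 members = members, union_size = length(universe)),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat("Overlap of", length(x$samples), "samples (", x$mode, "identity ),",
      x$union_size, "distinct fusions\n")
  for (nm in names(x$regions)) cat(sprintf("  %-24s %d\n", nm, x$regions[[nm]]))
  invisible(x)
}

#' Export fusions as Circos-style link records
#'
#' One link per fusion: `chrom5 start5 end5 chrom3 start3 end3 class`, with
#' 1-based single-base intervals at each junction coordinate and the locus
#' class as the tag, ready for standard Circos tooling.  Fusions on
#' chromosomes absent from the length table are skipped with a warning.
#'
#' @param annotated Annotated fusion data.frame.
#' @param out_path Output TSV path.
#' @param chrom_lengths Named vector of chromosome lengths (e.g. from
#'   [chromosome_lengths()]).
#' @return `out_path` invisibly, with attribute `n_skipped`.
#' @export
export_circos_links <- function(annotated, out_path, chrom_lengths) {
  known <- annotated$chrom5 %in% names(chrom_lengths) &
    annotated$chrom3 %in% names(chrom_lengths)
  n_skip <- sum(!known)
  if (n_skip > 0L) {
    chs_warn("skipped ", n_skip, " link(s) on chromosomes absent from the length table")
  }
  a <- annotated[known, , drop = FALSE]
  links <- data.frame(
    chrom5 = a$chrom5, start5 = a$pos5, end5 = a$pos5,
    chrom3 = a$chrom3, start3 = a$pos3, end3 = a$pos3,
    class = if ("locus_class" %in% names(a)) a$locus_class else ".",
    stringsAsFactors = FALSE
  )
  write.table(links, out_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  out <- invisible(out_path)
  attr(out, "n_skipped") <- n_skip
  out
}

#' Chromosome lengths from a gene-model set or genome
#'
#' @param x A `GeneModelSet` (lengths are the furthest annotated gene end plus
#'   a margin) or a [Biostrings::DNAStringSet] genome (exact widths).
#' @param margin Extra bases beyond the last gene when derived from models.
#' @return Named numeric vector of lengths.
#' @export
chromosome_lengths <- function(x, margin = 1000L) {
  if (inherits(x, "DNAStringSet")) {
    return(setNames(Biostrings::width(x), names(x)))
  }
  if (inherits(x, "GeneModelSet")) {
    ends <- tapply(x$genes$end, x$genes$chrom, max)
    return(setNames(as.numeric(ends) + margin, names(ends)))
  }
  chs_stop("cannot derive chromosome lengths from class ", class(x)[1L])
}

#' Render landscape pie charts
#'
#' One pie per classification scheme, faithful to the summary's counts; purely
#' presentational (percentages rounded to whole numbers in labels).
#'
#' @param summary A `landscape_summary`.
#' @param file Output image path (extension selects the device, e.g. png).
#' @return `file`, invisibly.
#' @export
plot_landscape <- function(summary, file) {
  df <- as.data.frame(summary)
  df <- df[df$count > 0L, , drop = FALSE]
  if (nrow(df) == 0L) {
    df <- data.frame(sample = summary$sample, stage = summary$stage,
                     scheme = "junction", category = "none", count = 1L,
                     proportion = 1, stringsAsFactors = FALSE)
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = "", y = .data$count, fill = .data$category)) +
    ggplot2::geom_col(width = 1, colour = "white") +
    ggplot2::coord_polar(theta = "y") +
    ggplot2::facet_wrap(~scheme) +
    ggplot2::theme_void() +
    ggplot2::labs(title = sprintf("%s (%s stage, n = %d)",
                                  summary$sample, summary$stage, summary$n))
  ggplot2::ggsave(file, p, width = 9, height = 3.4, dpi = 120)
  invisible(file)
}

#' Render a Venn-style overlap diagram
#'
#' Draws 2- or 3-sample overlap reports as labelled circles; region counts are
#' taken verbatim from [compute_overlap()].
#'
#' @param report An `overlap_report` with 2 or 3 samples.
#' @param file Output image path.
#' @return `file`, invisibly.
#' @export
plot_overlap <- function(report, file) {
  k <- length(report$samples)
  if (!k %in% c(2L, 3L)) chs_stop("plot_overlap() draws 2- or 3-sample reports")
  centers <- if (k == 2L) {
    data.frame(x = c(-0.5, 0.5), y = c(0, 0))
  } else {
    data.frame(x = c(-0.55, 0.55, 0), y = c(0.35, 0.35, -0.6))
  }
  centers$sample <- report$samples
  theta <- seq(0, 2 * pi, length.out = 120)
  circles <- do.call(rbind, lapply(seq_len(k), function(i) {
    data.frame(x = centers$x[i] + cos(theta), y = centers$y[i] + sin(theta),
               sample = centers$sample[i])
  }))
  # region labels at subset centroids; singleton labels pushed outward
  lab2 <- do.call(rbind, lapply(names(report$regions), function(nm) {
    ss <- strsplit(nm, "&", fixed = TRUE)[[1L]]
    idx <- match(ss, centers$sample)
    f <- if (length(ss) == 1L) 1.35 else if (length(ss) == k) 1 else 1
    data.frame(x = mean(centers$x[idx]) * f, y = mean(centers$y[idx]) * f,
               n = report$regions[[nm]], stringsAsFactors = FALSE)
  }))
  p <- ggplot2::ggplot() +
    ggplot2::geom_path(data = circles,
                       ggplot2::aes(x = .data$x, y = .data$y, colour = .data$sample)) +
    ggplot2::geom_text(data = lab2,
                       ggplot2::aes(x = .data$x, y = .data$y, label = .data$n)) +
    ggplot2::geom_text(data = centers,
                       ggplot2::aes(x = .data$x * 1.9, y = .data$y * 1.9,
                                    label = .data$sample)) +
    ggplot2::coord_fixed() + ggplot2::theme_void() +
    ggplot2::labs(title = sprintf("Shared and unique fusions (%s identity)",
                                  report$mode))
  ggplot2::ggsave(file, p, width = 5, height = 5, dpi = 120)
  invisible(file)
}

#' @importFrom ggplot2 .data
NULL
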