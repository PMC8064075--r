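#' Default column mapping for fusion call tables
#'
#' SOAPfuse-like callers emit a tab-separated table with one row per candidate
#' chimeric junction; header names vary across caller versions, so the mapping
#' from the canonical field names used by this package to the file's column
#' names is configuration, not code.  Canonical fields: `gene5`, `gene3`
#' (partner symbols, 5' listed first), `chrom5`, `strand5`, `pos5` (last base
#' of the upstream segment), `chrom3`, `strand3`, `pos3` (first base of the
#' downstream segment), `span_reads`, `junc_reads`.
#'
#' @param ... Named overrides, e.g. `gene5 = "up_gene"`.
#' @return Named character vector mapping canonical names to file columns.
#' @export
fusion_columns <- function(...) {
  map <- c(gene5 = "gene5", chrom5 = "chrom5", strand5 = "strand5", pos5 = "pos5",
           gene3 = "gene3", chrom3 = "chrom3", strand3 = "strand3", pos3 = "pos3",
           span_reads = "span_reads", junc_reads = "junc_reads")
  ov <- c(...)
  if (length(ov)) map[names(ov)] <- ov
  map
}

#' Read a fusion-candidate call table
#'
#' Reads one caller output table into a data.frame of fusion candidates.  Rows
#' violating basic invariants (negative read counts, empty partner symbols,
#' non-positive coordinates) are skipped with a warning; the number skipped is
#' attached as attribute `skipped_rows`.  Duplicate rows are kept verbatim —
#' deduplication is [unique_fusions()]'s job.
#'
#' @param path Tab-separated file with a header row.
#' @param sample Sample name recorded on every returned row.
#' @param col_map Column mapping from [fusion_columns()].
#' @return data.frame with columns sample, gene5, chrom5, strand5, pos5,
#'   gene3, chrom3, strand3, pos3, span_reads, junc_reads.
#' @export
load_fusion_calls <- function(path, sample, col_map = fusion_columns()) {
  if (!file.exists(path)) chs_stop("call table not found: ", path)
  raw <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
  missing <- setdiff(unname(col_map), names(raw))
  if (length(missing)) {
    chs_stop("call table ", path, " lacks mandatory column(s): ",
             paste(missing, collapse = ", "))
  }
  df <- data.frame(sample = rep(sample, nrow(raw)), stringsAsFactors = FALSE)
  for (canon in names(col_map)) df[[canon]] <- raw[[col_map[[canon]]]]
  for (num in c("pos5", "pos3", "span_reads", "junc_reads")) {
    df[[num]] <- suppressWarnings(as.numeric(df[[num]]))
  }
  ok <- !is.na(df$pos5) & !is.na(df$pos3) & df$pos5 >= 1 & df$pos3 >= 1 &
    !is.na(df$span_reads) & df$span_reads >= 0 &
    !is.na(df$junc_reads) & df$junc_reads >= 0 &
    nzchar(df$gene5) & nzchar(df$gene3) &
    df$strand5 %in% c("+", "-") & df$strand3 %in% c("+", "-")
  n_skip <- sum(!ok)
  if (n_skip > 0L) {
    chs_warn("skipped ", n_skip, " malformed row(s) in ", path)
  }
  out <- df[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped_rows") <- n_skip
  attr(out, "col_map") <- col_map
  out
}

#' Write a fusion table (calls or annotated calls) as TSV
#'
#' A JSON sidecar (`<path>.json`) records the row count, the column mapping
#' in force and any skipped-row count carried by the input.
#'
#' @param calls data.frame of candidates or annotated candidates.
#' @param path Output TSV path.
#' @param sidecar Write the JSON sidecar (default TRUE).
#' @return `path`, invisibly.
#' @export
write_fusion_calls <- function(calls, path, sidecar = TRUE) {
  write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (sidecar) {
    meta <- list(
      rows = nrow(calls),
      skipped_rows = attr(calls, "skipped_rows") %||% 0L,
      col_map = as.list(attr(calls, "col_map") %||% fusion_columns())
    )
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

fusion_key <- function(calls) {
  paste(calls$gene5, calls$gene3, calls$pos5, calls$pos3, sep = "|")
}

gene_pair_key <- function(calls) {
  paste(calls$gene5, calls$gene3, sep = "|")
}

#' Collapse a call set to unique fusion junctions
#'
#' Identity is junction-resolved: two candidates are the same fusion only when
#' partner symbols and both junction coordinates agree.  Two junction forms of
#' the same gene pair (different coordinates) therefore stay distinct, which
#' is how per-sample "unique chimeric fusion transcript" counts are defined.
#' For each key the row with the highest junction-spanning read support is
#' kept (ties: first in input order); output is sorted by (chrom5, pos5).
#'
#' @param calls data.frame from [load_fusion_calls()].
#' @return Deduplicated data.frame.
#' @export
unique_fusions <- function(calls) {
  if (nrow(calls) == 0L) return(calls)
  key <- fusion_key(calls)
  keep <- unlist(lapply(split(seq_len(nrow(calls)), key), function(idx) {
    idx[which.max(calls$junc_reads[idx])]
  }), use.names = FALSE)
  out <- calls[keep, , drop = FALSE]
  out <- out[order(out$chrom5, out$pos5, out$gene5, out$gene3, out$pos3), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a candidate-validation summary table
#'
#' Parses the wet-lab validation bookkeeping dialect: one row per candidate
#' chimeric RNA with its name, a Sanger-sequencing confirmation flag, and
#' yes/no flags for neighbouring parental genes and interchromosomal partners.
#' A trailing asterisk on the name (the printed-table convention for a
#' confirmed candidate) also sets `sanger_confirmed`.  Flags are parsed
#' case-insensitively as Y/N; anything else is a parse error naming the row.
#' Rows are preserved verbatim otherwise — reconciling inconsistent flags or
#' variant gene-symbol spellings is left to the caller.
#'
#' @param path TSV with columns (in order): fusion name, Sanger flag,
#'   neighbouring flag, interchromosomal flag.  A header row is expected.
#' @return data.frame with columns fusion_name (asterisk stripped),
#'   sanger_confirmed, neighboring, interchromosomal.
#' @export
load_validation_table <- function(path) {
  if (!file.exists(path)) chs_stop("validation table not found: ", path)
  raw <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(raw) < 4L) chs_stop("validation table needs 4 columns, got ", ncol(raw))
  parse_yn <- function(x, row) {
    u <- toupper(trimws(x))
    if (!u %in% c("Y", "N")) {
      chs_stop("validation table row ", row, ": expected Y/N, got '", x, "'")
    }
    u == "Y"
  }
  name_raw <- trimws(raw[[1L]])
  starred <- grepl("\\*\\s*$", name_raw)
  name <- trimws(sub("\\*\\s*$", "", name_raw))
  if (any(!nzchar(name))) {
    chs_stop("validation table row ", which(!nzchar(name))[1L], ": empty fusion name")
  }
  n <- nrow(raw)
  data.frame(
    fusion_name = name,
    sanger_confirmed = vapply(seq_len(n), function(i) parse_yn(raw[[2L]][i], i), logical(1L)) | starred,
    neighboring = vapply(seq_len(n), function(i) parse_yn(raw[[3L]][i], i), logical(1L)),
    interchromosomal = vapply(seq_len(n), function(i) parse_yn(raw[[4L]][i], i), logical(1L)),
    stringsAsFactors = FALSE
  )
}

#' Bookkeeping summary of a validation table
#'
#' Counts candidates, Sanger-confirmed candidates, and gene pairs present in
#' two junction forms (names like `PAIR-1` / `PAIR-2` sharing a base name).
#'
#' @param records data.frame from [load_validation_table()].
#' @return list with `n_candidates`, `n_sanger_confirmed`, `n_dual_form_pairs`.
#' @export
validation_summary <- function(records) {
  base <- sub("-[0-9]+$", "", records$fusion_name)
  dual <- sum(table(base) >= 2L)
  list(
    n_candidates = nrow(records),
    n_sanger_confirmed = sum(records$sanger_confirmed),
    n_dual_form_pairs = as.integer(dual)
  )
}
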