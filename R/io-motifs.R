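#' Read motif-scan hits (FIMO-style TSV)
#'
#' Accepts the classic FIMO output layout (with or without the
#' `motif_alt_id` column): `motif_id`, sequence name, `start`, `stop`,
#' `strand`, `score`, `p-value` and optional trailing columns. FIMO reports
#' 1-based inclusive coordinates; they are converted to 0-based half-open on
#' read. Strand is retained but ignored when scores are attached to bins.
#'
#' @param path Path to the TSV (may be gzip-compressed; `#` comment lines
#'   are skipped).
#' @return Tibble with `motif_id`, `chrom`, `start`, `end` (0-based
#'   half-open), `strand`, `score`, `pvalue`.
#' @export
read_motif_hits <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                       comment = "#", progress = FALSE)
  empty <- tibble(motif_id = character(), chrom = character(),
                  start = double(), end = double(), strand = character(),
                  score = double(), pvalue = double())
  if (nrow(x) == 0) return(empty)
  nm <- tolower(names(x))
  names(x) <- nm
  chrom_col <- intersect(c("sequence_name", "sequence name", "chrom", "seqnames"), nm)[1]
  pcol <- intersect(c("p-value", "p_value", "pvalue"), nm)[1]
  needed <- c("motif_id", chrom_col, "start", "stop", "strand", "score", pcol)
  if (anyNA(needed) || !all(needed %in% nm)) {
    abort("motif hit file lacks the FIMO columns (motif_id, sequence_name, start, stop, strand, score, p-value)")
  }
  out <- tibble(
    motif_id = x$motif_id,
    chrom = x[[chrom_col]],
    start = suppressWarnings(as.double(x$start)) - 1,
    end = suppressWarnings(as.double(x$stop)),
    strand = x$strand,
    score = suppressWarnings(as.double(x$score)),
    pvalue = suppressWarnings(as.double(x[[pcol]]))
  )
  bad <- which(!is.finite(out$start) | !is.finite(out$end) | !is.finite(out$score))
  if (length(bad) > 0) abort(paste0("malformed motif hit at data row ", bad[1]))
  if (any(out$start >= out$end)) abort("motif hit with start >= stop")
  out
}

#' Write motif hits in FIMO-style TSV
#'
#' Inverse of [read_motif_hits()]: 0-based half-open coordinates are written
#' back as 1-based inclusive `start`/`stop`.
#'
#' @param hits Tibble as returned by [read_motif_hits()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_motif_hits <- function(hits, path) {
  df <- data.frame(
    motif_id = hits$motif_id,
    sequence_name = hits$chrom,
    start = format(hits$start + 1, scientific = FALSE, trim = TRUE),
    stop = format(hits$end, scientific = FALSE, trim = TRUE),
    strand = hits$strand,
    score = fmt_num(hits$score),
    `p-value` = fmt_num(hits$pvalue),
    check.names = FALSE
  )
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}
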