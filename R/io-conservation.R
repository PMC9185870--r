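#' Read a per-base conservation track
#'
#' Reads bedGraph or fixed-step wiggle text (optionally gzip-compressed) into
#' an interval table of per-base scores. Scores are expected in \[0, 1\]
#' (PhastCons-style posterior conservation probabilities); bases not covered
#' by any interval are treated as missing by downstream consumers.
#'
#' @param path Path to the track. Format is auto-detected: files containing a
#'   `fixedStep` declaration are parsed as wiggle, anything else as bedGraph.
#' @return Tibble with `chrom`, `start`, `end` (0-based half-open), `score`.
#' @export
read_conservation <- function(path) {
  fmt <- detect_track_format(path)
  gr <- rtracklayer::import(path, format = fmt)
  track <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = as.double(GenomicRanges::end(gr)),
    score = as.double(gr$score)
  )
  track <- arrange(track, .data$chrom, .data$start)
  if (any(track$score < 0 | track$score > 1)) {
    abort("conservation scores must lie in [0, 1]")
  }
  overlapping <- track |>
    group_by(.data$chrom) |>
    summarise(bad = any(.data$start[-1] < .data$end[-length(.data$end)]),
              .groups = "drop")
  if (any(overlapping$bad, na.rm = TRUE)) {
    abort("conservation track has overlapping intervals")
  }
  track
}

detect_track_format <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  head_lines <- readLines(con, n = 50)
  if (any(grepl("^(fixedStep|variableStep)", head_lines))) "wig" else "bedGraph"
}

#' Look up per-base conservation scores
#'
#' @param track Conservation tibble from [read_conservation()].
#' @param chrom Chromosome name (scalar).
#' @param pos 0-based base positions.
#' @return Numeric vector of scores; `NA` where a base is not covered.
#' @export
conservation_at <- function(track, chrom, pos) {
  tr <- track[track$chrom == chrom, , drop = FALSE]
  if (nrow(tr) == 0) return(rep(NA_real_, length(pos)))
  idx <- findInterval(pos, tr$start)
  score <- rep(NA_real_, length(pos))
  inside <- idx >= 1 & pos < tr$end[pmax(idx, 1)]
  score[inside] <- tr$score[idx[inside]]
  score
}
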