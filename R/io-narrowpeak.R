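np_cols <- c("chrom", "start", "end", "name", "score", "strand",
             "signalValue", "pValue", "qValue", "peak")

#' Read an ENCODE narrowPeak file
#'
#' narrowPeak is BED6+4: chrom, start, end, name, score, strand, signalValue,
#' -log10 p-value, -log10 q-value and the summit offset from `start`
#' (`peak`; -1 when no summit was called). Gzip input is handled by suffix.
#'
#' @param path Path to a narrowPeak file.
#' @return A tibble with the ten narrowPeak columns plus `summit`, the
#'   absolute 0-based summit position (`start + peak`, `NA` when `peak < 0`).
#' @export
read_narrowpeak <- function(path) {
  if (length(readr::read_lines(path, n_max = 1, progress = FALSE)) == 0) {
    empty <- as_tibble(setNames(rep(list(double()), 11), c(np_cols, "summit")))
    empty$chrom <- character(); empty$name <- character()
    empty$strand <- character()
    return(empty)
  }
  fields <- readr::count_fields(path, readr::tokenizer_tsv())
  bad <- which(fields != 10)
  if (length(bad) > 0) {
    abort(paste0("malformed narrowPeak line ", bad[1], " in ", path, ": ",
                 fields[bad[1]], " columns instead of 10"))
  }
  x <- readr::read_tsv(path, col_names = np_cols,
                       col_types = "cddcicdddd", progress = FALSE)
  prob <- readr::problems(x)
  if (nrow(prob) > 0) {
    abort(paste0("malformed narrowPeak line ", prob$row[1], " in ", path))
  }
  if (nrow(x) == 0) return(mutate(x, summit = double()))
  if (any(x$start >= x$end)) {
    abort(paste0("narrowPeak line ", which(x$start >= x$end)[1],
                 ": start must be < end"))
  }
  bad <- which(x$peak >= x$end - x$start)
  if (length(bad) > 0) {
    abort(paste0("narrowPeak line ", bad[1],
                 ": summit offset is outside the peak interval"))
  }
  mutate(x, summit = ifelse(.data$peak >= 0, .data$start + .data$peak, NA_real_))
}

#' Write records in narrowPeak format
#'
#' @param peaks Tibble with the ten narrowPeak columns (a `summit` column, if
#'   present, is dropped: it is derivable from `start + peak`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(peaks, path) {
  df <- as.data.frame(peaks[, np_cols])
  df$signalValue <- fmt_num(df$signalValue)
  df$pValue <- fmt_num(df$pValue)
  df$qValue <- fmt_num(df$qValue)
  readr::write_tsv(df, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

fmt_num <- function(x) formatC(x, format = "fg", digits = 6)

#' Read a BED3/BED5 file
#'
#' @param path Path to a BED file (3 or more columns; extra columns beyond
#'   the fifth are ignored).
#' @return A tibble with `chrom`, `start`, `end` and, when present, `name`
#'   and `score`.
#' @export
read_bed <- function(path) {
  x <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(),
                       progress = FALSE)
  if (nrow(x) == 0) return(tibble(chrom = character(), start = double(), end = double()))
  if (ncol(x) < 3) abort("BED file must have at least 3 columns")
  out <- tibble(chrom = as.character(x[[1]]), start = as.double(x[[2]]),
                end = as.double(x[[3]]))
  if (ncol(x) >= 4) out$name <- as.character(x[[4]])
  if (ncol(x) >= 5) out$score <- as.double(x[[5]])
  out
}

#' Write per-bin posterior predictions as BED5
#'
#' Serialises one line per bin with score `round(1000 * posterior)`, so a
#' round-trip through [read_predictions()] reproduces posteriors to three
#' decimals.
#'
#' @param predictions Tibble with `chrom`, `start`, `end` and `posterior`
#'   (each in \[0, 1\]).
#' @param path Output path.
#' @param cutoff Optional posterior cutoff; when given, only bins with
#'   `posterior >= cutoff` are written.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path, cutoff = NULL) {
  p <- predictions$posterior
  if (any(!is.finite(p) | p < 0 | p > 1)) {
    abort("`posterior` values must lie in [0, 1]")
  }
  if (!is.null(cutoff)) predictions <- predictions[p >= cutoff, , drop = FALSE]
  df <- data.frame(
    chrom = predictions$chrom,
    start = format(predictions$start, scientific = FALSE, trim = TRUE),
    end = format(predictions$end, scientific = FALSE, trim = TRUE),
    name = sprintf("bin_%d", seq_len(nrow(predictions))),
    score = round(1000 * predictions$posterior)
  )
  readr::write_tsv(df, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a BED5 posterior track written by [write_predictions()]
#'
#' @param path Path to the BED5 file.
#' @return Tibble with `chrom`, `start`, `end`, `posterior` (= score / 1000).
#' @export
read_predictions <- function(path) {
  x <- read_bed(path)
  x$posterior <- x$score / 1000
  x$score <- NULL
  x
}
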