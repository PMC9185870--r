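#' Sliding genomic bins
#'
#' Tiles each chromosome with fixed-width bins advancing by `stride`
#' (defaults: 200 bp bins every 50 bp, the resolution used for training and
#' prediction). Coordinates are 0-based half-open throughout; only bins fully
#' inside the chromosome are emitted, so a chromosome of length L contributes
#' `floor((L - width) / stride) + 1` bins (none if L < width).
#'
#' @param sizes Chromosome-size tibble (`chrom`, `length`).
#' @param width Bin width in bp (> 0).
#' @param stride Distance between consecutive bin starts in bp (> 0).
#' @return A bin tibble with columns `chrom`, `start`, `end` and attributes
#'   `bin_width`, `bin_stride`.
#' @examples
#' make_sliding_bins(tibble::tibble(chrom = "chrA", length = 300))
#' @export
make_sliding_bins <- function(sizes, width = 200, stride = 50) {
  if (length(width) != 1 || !is.finite(width) || width <= 0) {
    abort("`width` must be a single positive number")
  }
  if (length(stride) != 1 || !is.finite(stride) || stride <= 0) {
    abort("`stride` must be a single positive number")
  }
  if (nrow(sizes) == 0) {
    return(new_bins(tibble(chrom = character(), start = double(), end = double()),
                    width, stride))
  }
  validate_chrom_sizes(sizes)
  n_per_chrom <- pmax(0, floor((sizes$length - width) / stride) + 1)
  keep <- n_per_chrom > 0
  starts <- sequence(n_per_chrom[keep], from = 0, by = stride)
  bins <- tibble(
    chrom = rep(sizes$chrom[keep], n_per_chrom[keep]),
    start = as.double(starts),
    end = as.double(starts) + width
  )
  new_bins(bins, width, stride)
}

#' Fixed (non-overlapping) genomic bins
#'
#' Non-overlapping tiling from position 0; a trailing partial window is
#' dropped. The 100 bp default is the bin system used for the
#' binding-expression association matrix.
#'
#' @inheritParams make_sliding_bins
#' @return A bin tibble (see [make_sliding_bins()]); `bin_stride == bin_width`.
#' @export
make_fixed_bins <- function(sizes, width = 100) {
  make_sliding_bins(sizes, width = width, stride = width)
}

new_bins <- function(bins, width, stride) {
  attr(bins, "bin_width") <- width
  attr(bins, "bin_stride") <- stride
  bins
}

bin_width <- function(bins) {
  attr(bins, "bin_width") %||% (if (nrow(bins)) bins$end[1] - bins$start[1] else NA_real_)
}

bin_stride <- function(bins) {
  w <- attr(bins, "bin_stride")
  if (!is.null(w)) return(w)
  per_chrom <- split(bins$start, bins$chrom)
  strides <- unlist(lapply(per_chrom, function(s) unique(diff(s))))
  if (length(strides)) min(strides) else NA_real_
}

validate_bins <- function(bins) {
  if (!all(c("chrom", "start", "end") %in% names(bins))) {
    abort("bins must have columns `chrom`, `start`, `end`")
  }
  invisible(bins)
}

# 0-based half-open tibble -> GRanges (1-based closed)
bins_gr <- function(bins) {
  GenomicRanges::GRanges(
    seqnames = bins$chrom,
    ranges = IRanges::IRanges(start = bins$start + 1, end = bins$end)
  )
}

points_gr <- function(chrom, pos) {
  GenomicRanges::GRanges(seqnames = chrom,
                         ranges = IRanges::IRanges(start = pos + 1, width = 1))
}

#' Drop bins overlapping blacklist regions
#'
#' Removes every bin that overlaps any blacklist interval by at least 1 bp
#' (half-open intervals that merely touch do not overlap). Bin order is
#' preserved. Blacklist entries on chromosomes absent from `bins` are ignored
#' with a warning.
#'
#' @param bins Bin tibble.
#' @param blacklist Tibble of 0-based half-open intervals
#'   (`chrom`, `start`, `end`), e.g. from [read_bed()].
#' @return The filtered bin tibble.
#' @export
exclude_blacklist <- function(bins, blacklist) {
  validate_bins(bins)
  if (is.null(blacklist) || nrow(blacklist) == 0) return(bins)
  unknown <- setdiff(unique(blacklist$chrom), unique(bins$chrom))
  if (length(unknown) > 0) {
    warn(paste0("blacklist chromosome(s) not present in bins, ignored: ",
                paste(unknown, collapse = ", ")))
    blacklist <- blacklist[!blacklist$chrom %in% unknown, , drop = FALSE]
    if (nrow(blacklist) == 0) return(bins)
  }
  hits <- GenomicRanges::findOverlaps(bins_gr(bins), bins_gr(blacklist))
  drop <- unique(S4Vectors::queryHits(hits))
  if (length(drop) == 0) return(bins)
  out <- bins[-drop, , drop = FALSE]
  new_bins(out, attr(bins, "bin_width"), attr(bins, "bin_stride"))
}
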