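#' GRCh38 primary chromosome sizes
#'
#' Lengths of the 24 primary GRCh38/hg38 chromosomes (chr1-chr22, chrX, chrY),
#' bundled so that genome binning and genome-fraction arithmetic run without
#' any download.
#'
#' @return A tibble with columns `chrom` and `length` (bp), ordered
#'   chr1..chr22, chrX, chrY.
#' @examples
#' grch38_chrom_sizes()
#' @export
grch38_chrom_sizes <- function() {
  tibble(
    chrom = c(paste0("chr", 1:22), "chrX", "chrY"),
    length = c(
      248956422, 242193529, 198295559, 190214555, 181538259, 170805979,
      159345973, 145138636, 138394717, 133797422, 135086622, 133275309,
      114364328, 107043718, 101991189, 90338345, 83257441, 80373285,
      58617616, 64444167, 46709983, 50818468, 156040895, 57227415
    )
  )
}

#' Read a chrom.sizes table
#'
#' Two-column tab-separated file: chromosome name, length in bp.
#'
#' @param path Path to the file (may be gzip-compressed).
#' @param add_chr_prefix If `TRUE`, names lacking a `"chr"` prefix get one;
#'   if `FALSE`, a leading `"chr"` is stripped; if `NA` (default) names are
#'   kept as-is.
#' @return A tibble with columns `chrom`, `length`.
#' @export
read_chrom_sizes <- function(path, add_chr_prefix = NA) {
  x <- readr::read_tsv(path, col_names = c("chrom", "length"),
                       col_types = readr::cols(chrom = "c", length = "d"),
                       progress = FALSE)
  validate_chrom_sizes(x)
  if (isTRUE(add_chr_prefix)) {
    x$chrom <- ifelse(startsWith(x$chrom, "chr"), x$chrom, paste0("chr", x$chrom))
  } else if (isFALSE(add_chr_prefix)) {
    x$chrom <- sub("^chr", "", x$chrom)
  }
  x
}

validate_chrom_sizes <- function(sizes) {
  if (!all(c("chrom", "length") %in% names(sizes))) {
    abort("`sizes` must have columns `chrom` and `length`")
  }
  if (anyDuplicated(sizes$chrom)) abort("duplicate chromosome names in `sizes`")
  if (any(!is.finite(sizes$length) | sizes$length <= 0)) {
    abort("all chromosome lengths must be positive")
  }
  invisible(sizes)
}

#' Genomic share of a chromosome subset
#'
#' Total length of a set of chromosomes and the percentage of the whole
#' genome (all chromosomes in `sizes`) they represent.
#'
#' @param sizes Chromosome-size tibble (`chrom`, `length`).
#' @param selected Character vector of chromosome names; must all be present
#'   in `sizes`.
#' @return One-row tibble with `selected_bp` and `percent`.
#' @examples
#' genome_fraction(grch38_chrom_sizes(), c("chr5", "chr10", "chr15", "chr20"))
#' @export
genome_fraction <- function(sizes, selected) {
  validate_chrom_sizes(sizes)
  missing <- setdiff(selected, sizes$chrom)
  if (length(missing) > 0) {
    abort(paste0("unknown chromosome(s): ", paste(missing, collapse = ", ")))
  }
  sel_bp <- sum(sizes$length[sizes$chrom %in% selected])
  tibble(selected_bp = sel_bp, percent = 100 * sel_bp / sum(sizes$length))
}
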