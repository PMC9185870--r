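feature_base_cols <- c("expression_score", "binding_frequency",
                       "accessibility", "conservation")

#' Transfer 100 bp expression scores onto sliding bins
#'
#' The association matrix (and hence the expression score) lives on 100 bp
#' fixed bins while classification uses 200 bp sliding bins; each sliding bin
#' receives the mean of the non-NA scores of the fixed bins it overlaps
#' (`NA` when none).
#'
#' @param bins Sliding bin tibble.
#' @param scores Expression-score tibble from [expression_score()] (fixed
#'   bins plus `score`).
#' @return Numeric vector, one (possibly `NA`) score per sliding bin.
#' @export
map_expression_score <- function(bins, scores) {
  validate_bins(bins)
  out <- rep(NA_real_, nrow(bins))
  ok <- scores[!is.na(scores$score), , drop = FALSE]
  if (nrow(ok) == 0) return(out)
  hits <- GenomicRanges::findOverlaps(bins_gr(bins), bins_gr(ok))
  if (length(hits) == 0) return(out)
  means <- tapply(ok$score[S4Vectors::subjectHits(hits)],
                  S4Vectors::queryHits(hits), mean)
  out[as.integer(names(means))] <- means
  out
}

#' Bins with qualifying chromatin accessibility
#'
#' Flags bins overlapping (by >= 1 bp) an accessibility peak whose `qValue`
#' is at least `fdr_exponent`; used to pick training rows.
#'
#' @param bins Bin tibble.
#' @param acc_peaks Accessibility narrowPeak tibble.
#' @param fdr_exponent Minimum -log10 FDR (default 4).
#' @return Logical vector per bin.
#' @export
accessible_bins <- function(bins, acc_peaks, fdr_exponent = 4) {
  validate_bins(bins)
  out <- logical(nrow(bins))
  pk <- acc_peaks[acc_peaks$qValue >= fdr_exponent, , drop = FALSE]
  if (nrow(pk) == 0) return(out)
  hits <- GenomicRanges::findOverlaps(bins_gr(bins), bins_gr(pk))
  out[unique(S4Vectors::queryHits(hits))] <- TRUE
  out
}

#' Per-cell-type feature table
#'
#' Assembles the classifier's feature columns for one cell type in the fixed
#' documented order: expression score (NA scores imputed as 0),
#' binding frequency across training cell types, accessibility summit
#' signal, mean conservation, then up to 7 motif columns — p in \[4, 11\]
#' columns in total.
#'
#' @param bins Sliding bin tibble.
#' @param expression_score Per-bin score (e.g. [map_expression_score()]);
#'   `NA` treated as no information (0).
#' @param binding_frequency Per-bin count from [binding_frequency()].
#' @param accessibility Per-bin value from [map_accessibility()].
#' @param conservation Per-bin value from [mean_conservation()].
#' @param motif_cols Optional tibble of motif columns from
#'   [motif_features()].
#' @return Tibble: `bins` plus the feature columns.
#' @export
cell_feature_table <- function(bins, expression_score, binding_frequency,
                               accessibility, conservation,
                               motif_cols = NULL) {
  validate_bins(bins)
  out <- as_tibble(bins)
  out$expression_score <- ifelse(is.na(expression_score), 0, expression_score)
  out$binding_frequency <- as.double(binding_frequency)
  out$accessibility <- accessibility
  out$conservation <- conservation
  if (!is.null(motif_cols) && ncol(motif_cols) > 0) {
    clash <- intersect(names(motif_cols), names(out))
    if (length(clash) > 0) {
      abort(paste0("feature-name collision: ", paste(clash, collapse = ", ")))
    }
    out <- dplyr::bind_cols(out, motif_cols)
  }
  out
}

feature_names <- function(tbl) {
  setdiff(names(tbl), c("chrom", "start", "end", "cell_type", "bound"))
}

#' Concatenated training matrix over cell types
#'
#' For each training cell type, keeps the bins with qualifying chromatin
#' accessibility in that cell type or chromatin factor binding in any
#' training cell type, drops blacklisted bins, attaches the binary label,
#' and concatenates the per-cell-type tables with a `cell_type` tag.
#'
#' @param features Named list (by cell type) of feature tibbles from
#'   [cell_feature_table()], all on the same bin set.
#' @param labels Named list (by cell type) of label tibbles from
#'   [make_labels()] on the same bins.
#' @param accessible Named list (by cell type) of logical vectors from
#'   [accessible_bins()].
#' @param blacklist Optional blacklist interval tibble; matching bins are
#'   excluded from the training rows.
#' @return Tibble with `chrom`, `start`, `end`, `cell_type`, the feature
#'   columns (p in \[4, 11\]) and `bound`.
#' @export
assemble_training_matrix <- function(features, labels, accessible,
                                     blacklist = NULL) {
  cts <- names(features)
  if (is.null(cts) || !identical(sort(cts), sort(names(labels))) ||
      !identical(sort(cts), sort(names(accessible)))) {
    abort("`features`, `labels` and `accessible` must be named by the same cell types")
  }
  bins <- features[[1]][, c("chrom", "start", "end")]
  fnames <- feature_names(features[[1]])
  if (anyDuplicated(fnames)) abort("feature-name collision in feature table")
  if (length(fnames) < 4 || length(fnames) > 11) {
    abort("expected between 4 and 11 feature columns")
  }
  bound_any <- Reduce(`|`, lapply(cts, function(ct) labels[[ct]]$bound > 0))
  keep_black <- rep(TRUE, nrow(bins))
  if (!is.null(blacklist) && nrow(blacklist) > 0) {
    bl <- blacklist[blacklist$chrom %in% unique(bins$chrom), , drop = FALSE]
    if (nrow(bl) > 0) {
      hits <- GenomicRanges::findOverlaps(bins_gr(bins), bins_gr(bl))
      keep_black[unique(S4Vectors::queryHits(hits))] <- FALSE
    }
  }
  rows <- lapply(cts, function(ct) {
    f <- features[[ct]]
    if (!identical(feature_names(f), fnames)) {
      abort("feature columns differ between cell types")
    }
    keep <- (accessible[[ct]] | bound_any) & keep_black
    out <- f[keep, , drop = FALSE]
    out$cell_type <- ct
    out$bound <- labels[[ct]]$bound[keep]
    out
  })
  out <- dplyr::bind_rows(rows)
  out[, c("chrom", "start", "end", "cell_type", fnames, "bound")]
}
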