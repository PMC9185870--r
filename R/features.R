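#' Map chromatin-accessibility summit signal onto bins
#'
#' Within one experiment, every bin overlapping a peak summit receives that
#' summit's `signalValue`; when a bin overlaps several summits the one with
#' the smallest coordinate (closest to the p terminus) wins. Values are then
#' averaged across experiments, with experiments contributing 0 on bins where
#' they have no summit; bins without any summit score 0.
#'
#' @param bins Bin tibble (200 bp sliding by default).
#' @param peaks Accessibility narrowPeak tibble with an `experiment` column
#'   and a `summit` column (records without a summit are an error).
#' @return Numeric vector, one value per bin.
#' @export
map_accessibility <- function(bins, peaks) {
  validate_bins(bins)
  if (nrow(peaks) == 0) return(numeric(nrow(bins)))
  if (anyNA(peaks$summit)) abort("accessibility record without a summit")
  experiments <- unique(peaks$experiment)
  total <- numeric(nrow(bins))
  gr_bins <- bins_gr(bins)
  for (ex in experiments) {
    pk <- peaks[peaks$experiment == ex, , drop = FALSE]
    hits <- GenomicRanges::findOverlaps(gr_bins,
                                        points_gr(pk$chrom, pk$summit))
    if (length(hits) == 0) next
    df <- tibble(bin = S4Vectors::queryHits(hits),
                 pos = pk$summit[S4Vectors::subjectHits(hits)],
                 value = pk$signalValue[S4Vectors::subjectHits(hits)])
    df <- df |> group_by(.data$bin) |>
      summarise(value = .data$value[which.min(.data$pos)], .groups = "drop")
    total[df$bin] <- total[df$bin] + df$value
  }
  total / length(experiments)
}

#' Mean per-base conservation of each bin
#'
#' Arithmetic mean of the per-base conservation scores over the bin's bases;
#' uncovered (missing) bases contribute 0 to the sum but are counted in the
#' denominator, treating unalignable sequence as unconserved.
#'
#' @param bins Bin tibble.
#' @param track Conservation tibble from [read_conservation()].
#' @return Numeric vector, one mean score per bin.
#' @export
mean_conservation <- function(bins, track) {
  validate_bins(bins)
  out <- numeric(nrow(bins))
  if (nrow(track) == 0 || nrow(bins) == 0) return(out)
  hits <- GenomicRanges::findOverlaps(bins_gr(bins), bins_gr(track))
  if (length(hits) == 0) return(out)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  ov <- pmin(bins$end[q], track$end[s]) - pmax(bins$start[q], track$start[s])
  sums <- tapply(ov * track$score[s], q, sum)
  out[as.integer(names(sums))] <- sums
  out / (bins$end - bins$start)
}

#' Resolve a chromatin factor to its motif set
#'
#' Exact matches of the factor name in the motif catalog come first; when
#' the factor has no motif of its own, motifs of factors sharing the same
#' initial 3 letters (case-insensitive) are used instead. At most 7 motifs
#' are returned, in deterministic motif-id order; factors with no match at
#' all (e.g. EP300 in JASPAR) get an empty list and are modeled without
#' motif features.
#'
#' @param factor_name Chromatin factor name.
#' @param catalog Tibble with columns `motif_id`, `tf_name`.
#' @param max_motifs Cap on the number of motifs (default 7).
#' @return Character vector of motif ids (possibly empty).
#' @export
resolve_motifs <- function(factor_name, catalog, max_motifs = 7) {
  tf <- toupper(catalog$tf_name)
  ids <- sort(catalog$motif_id[tf == toupper(factor_name)])
  if (length(ids) == 0) {
    prefix <- toupper(substr(factor_name, 1, 3))
    ids <- sort(catalog$motif_id[substr(tf, 1, 3) == prefix])
  }
  head(ids, max_motifs)
}

#' Per-bin average motif scores
#'
#' One feature column per selected motif: the mean motif-scan score of that
#' motif's hits whose midpoint falls inside the bin (midpoint attachment
#' avoids counting one hit several times within a single window); bins with
#' no hit score 0.
#'
#' @param bins Bin tibble.
#' @param hits Motif-hit tibble from [read_motif_hits()].
#' @param motifs Ordered motif ids (length <= 7), e.g. from
#'   [resolve_motifs()].
#' @return Tibble with one numeric column `motif_<id>` per selected motif.
#' @export
motif_features <- function(bins, hits, motifs) {
  validate_bins(bins)
  if (length(motifs) > 7) abort("up to 7 motifs maximum")
  out <- lapply(motifs, function(m) {
    col <- numeric(nrow(bins))
    h <- hits[hits$motif_id == m, , drop = FALSE]
    if (nrow(h) > 0) {
      mid <- floor((h$start + h$end) / 2)
      ov <- GenomicRanges::findOverlaps(bins_gr(bins), points_gr(h$chrom, mid))
      if (length(ov) > 0) {
        means <- tapply(h$score[S4Vectors::subjectHits(ov)],
                        S4Vectors::queryHits(ov), mean)
        col[as.integer(names(means))] <- means
      }
    }
    col
  })
  names(out) <- paste0("motif_", motifs)
  as_tibble(out, .name_repair = "minimal")
}

#' Binary binding labels from replicated ChIP-seq peaks
#'
#' A peak qualifies in a replicate when its -log10 FDR (`qValue`) is at least
#' `fdr_exponent` (default 4, i.e. FDR < 1e-4). A qualifying peak is
#' reproducible when qualifying peaks overlapping it (by >= 1 bp) occur in at
#' least `min_replicates` replicates; with a single replicate the requirement
#' degrades to 1. A bin is labeled bound iff the summit of a reproducible
#' qualifying peak lies inside it.
#'
#' @param bins Bin tibble.
#' @param peaks narrowPeak tibble with `replicate`, `qValue` and `summit`
#'   columns.
#' @param fdr_exponent Minimum -log10 FDR for a peak to qualify (default 4).
#' @param min_replicates Replicates required for reproducibility (default 2).
#' @return Tibble: `bins` plus an integer `bound` column (0/1).
#' @export
make_labels <- function(bins, peaks, fdr_exponent = 4, min_replicates = 2) {
  validate_bins(bins)
  if (nrow(peaks) == 0) abort("no peak replicates supplied")
  reps <- unique(peaks$replicate)
  need <- if (length(reps) == 1) 1 else min_replicates
  qual <- peaks[peaks$qValue >= fdr_exponent, , drop = FALSE]
  bound <- integer(nrow(bins))
  if (nrow(qual) > 0) {
    if (anyNA(qual$summit)) abort("qualifying peak without a summit")
    gr_qual <- bins_gr(qual)
    per_rep <- lapply(reps, function(r) {
      GenomicRanges::countOverlaps(
        gr_qual, bins_gr(qual[qual$replicate == r, , drop = FALSE])) > 0
    })
    n_reps_with_overlap <- rowSums(matrix(unlist(per_rep), nrow = nrow(qual)))
    repro <- qual[n_reps_with_overlap >= need, , drop = FALSE]
    if (nrow(repro) > 0) {
      hits <- GenomicRanges::findOverlaps(
        bins_gr(bins), points_gr(repro$chrom, repro$summit))
      bound[unique(S4Vectors::queryHits(hits))] <- 1L
    }
  }
  out <- as_tibble(bins)
  out$bound <- bound
  out
}

#' Number of training cell types bound at each bin
#'
#' @param bins Bin tibble shared by all label vectors.
#' @param labels List of label tibbles from [make_labels()], one per training
#'   cell type, all on `bins`.
#' @return Integer vector of per-bin counts in \[0, length(labels)\].
#' @export
binding_frequency <- function(bins, labels) {
  validate_bins(bins)
  mats <- vapply(labels, function(l) {
    if (nrow(l) != nrow(bins) ||
        !identical(l$start, bins$start) || !identical(l$chrom, bins$chrom)) {
      abort("label vectors must share the same bin set")
    }
    l$bound
  }, integer(nrow(bins)))
  as.integer(rowSums(mats))
}

#' Fraction of bound bins
#'
#' The prevalence bound / (bound + unbound); this is also the expected auPR
#' of a no-skill classifier and hence the precision-recall baseline.
#'
#' @param labels Label tibble with a `bound` column (or a 0/1 vector).
#' @return Proportion in \[0, 1\].
#' @export
prevalence <- function(labels) {
  b <- if (is.data.frame(labels)) labels$bound else labels
  if (length(b) == 0) abort("empty label vector")
  mean(b > 0)
}
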