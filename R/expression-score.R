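#' Per-bin ChIP signal matrix across cell types
#'
#' Builds the M x N matrix of mean replicate peak signal per fixed-width bin
#' and cell type: within each replicate, a peak contributes its
#' `signalValue` to every bin its interval overlaps (mean if several peaks
#' hit one bin); the cell-type entry is the mean over replicates, with
#' replicates lacking any peak on a bin contributing 0.
#'
#' @param peaks Tibble of narrowPeak records (see [read_narrowpeak()]) with
#'   additional `cell_type` and `replicate` columns.
#' @param bins Fixed (non-overlapping) bin tibble from [make_fixed_bins()].
#' @param cell_types Optional cell-type order; defaults to order of first
#'   appearance in `peaks`.
#' @return An object of class `virchip_chip_matrix`: list with `bins`,
#'   `cell_types` and `values` (M x N, non-negative).
#' @export
build_chip_matrix <- function(peaks, bins, cell_types = NULL) {
  validate_bins(bins)
  if (!isTRUE(all.equal(bin_width(bins), bin_stride(bins))) &&
      !is.na(bin_stride(bins))) {
    abort("`bins` must be a fixed (non-overlapping) bin system")
  }
  cell_types <- cell_types %||% unique(peaks$cell_type)
  M <- nrow(bins)
  values <- matrix(0, nrow = M, ncol = length(cell_types),
                   dimnames = list(NULL, cell_types))
  if (nrow(peaks) > 0) {
    gr_bins <- bins_gr(bins)
    for (ct in cell_types) {
      pk_ct <- peaks[peaks$cell_type == ct, , drop = FALSE]
      reps <- unique(pk_ct$replicate)
      if (length(reps) == 0) next
      acc <- numeric(M)
      for (r in reps) {
        pk <- pk_ct[pk_ct$replicate == r, , drop = FALSE]
        hits <- GenomicRanges::findOverlaps(gr_bins, bins_gr(pk))
        if (length(hits) == 0) next
        per_bin <- tapply(pk$signalValue[S4Vectors::subjectHits(hits)],
                          S4Vectors::queryHits(hits), mean)
        acc[as.integer(names(per_bin))] <- acc[as.integer(names(per_bin))] + per_bin
      }
      values[, ct] <- acc / length(reps)
    }
  }
  structure(list(bins = bins, cell_types = cell_types, values = values),
            class = "virchip_chip_matrix")
}

#' @export
print.virchip_chip_matrix <- function(x, ...) {
  cat("<virchip_chip_matrix> ", nrow(x$values), " bins x ",
      ncol(x$values), " cell types\n", sep = "")
  invisible(x)
}

#' Quantile normalization across cell types
#'
#' Forces every column (cell type) of the signal matrix onto a common
#' reference distribution: the across-column mean of order statistics. Tied
#' values within a column all receive the mean of the reference values their
#' rank span covers.
#'
#' @param x A `virchip_chip_matrix` or a plain numeric matrix.
#' @return Same type as the input, quantile-normalized.
#' @export
quantile_normalize <- function(x) {
  if (inherits(x, "virchip_chip_matrix")) {
    x$values <- quantile_normalize(x$values)
    return(x)
  }
  if (ncol(x) < 2) abort("quantile normalization needs >= 2 columns")
  ref <- rowMeans(apply(x, 2, sort))
  csum <- c(0, cumsum(ref))
  apply(x, 2, function(col) {
    rmin <- rank(col, ties.method = "min")
    rmax <- rank(col, ties.method = "max")
    (csum[rmax + 1] - csum[rmin]) / (rmax - rmin + 1)
  })
}

#' Row normalization to \[0, 1\]
#'
#' Affinely rescales each row (bin) to min 0 and max 1. Constant rows
#' (including all-zero "never bound" bins) map to all zeros.
#'
#' @inheritParams quantile_normalize
#' @return Same type as the input with rows rescaled.
#' @export
row_normalize <- function(x) {
  if (inherits(x, "virchip_chip_matrix")) {
    x$values <- row_normalize(x$values)
    return(x)
  }
  lo <- apply(x, 1, min)
  hi <- apply(x, 1, max)
  span <- hi - lo
  out <- (x - lo) / ifelse(span == 0, 1, span)
  out[span == 0, ] <- 0
  out
}

#' Select genes with the highest expression variance
#'
#' Ranks genes by descending variance across the (training) cell types and
#' returns the top `n_genes`; variance ties break lexicographically by gene
#' id for determinism.
#'
#' @param expr Expression tibble (`gene_id` + cell-type columns).
#' @param n_genes Number of genes to keep (default 5000).
#' @param cell_types Optional subset/order of cell-type columns to use.
#' @return Character vector of gene ids (length `min(n_genes, #genes)`).
#' @export
select_high_variance_genes <- function(expr, n_genes = 5000, cell_types = NULL) {
  m <- expression_values(expr, cell_types)
  v <- apply(m, 1, var)
  ord <- order(-v, rownames(m))
  rownames(m)[ord][seq_len(min(n_genes, nrow(m)))]
}

#' Rank-normalized expression matrix
#'
#' Within each cell type, expression values of the selected genes are ranked
#' (average ranks for ties) and mapped to \[0, 1\] as `(rank - 1) / (G - 1)`
#' (0.5 when G = 1), making downstream correlations invariant to monotone
#' differences between expression pipelines.
#'
#' @param expr Expression tibble.
#' @param genes Gene ids to use (must all be present in `expr`).
#' @param cell_types Optional subset/order of cell types.
#' @return N x G numeric matrix (cell types x genes) of values in \[0, 1\].
#' @export
rank_normalize_expression <- function(expr, genes, cell_types = NULL) {
  m <- expression_values(expr, cell_types)
  missing <- setdiff(genes, rownames(m))
  if (length(missing) > 0) {
    abort(paste0("gene(s) absent from expression table: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  m <- m[genes, , drop = FALSE]
  G <- length(genes)
  out <- apply(m, 2, function(col) {
    if (G == 1) return(0.5)
    (rank(col, ties.method = "average") - 1) / (G - 1)
  })
  out <- matrix(out, nrow = G, dimnames = list(genes, colnames(m)))
  t(out)
}

#' Bins-by-genes association matrix
#'
#' For every (bin, gene) pair, the Pearson correlation across the N training
#' cell types between the bin's normalized ChIP signal and the gene's
#' rank-normalized expression. Correlations whose two-sided test p-value
#' (t statistic with N - 2 df) exceeds `alpha` are masked to `NA`, as are
#' entire rows with constant (e.g. all-zero) signal.
#'
#' @param chip A row-normalized `virchip_chip_matrix` (values in \[0, 1\]).
#' @param expr_ranks N x G matrix from [rank_normalize_expression()]; cell
#'   types must match the ChIP matrix in the same order.
#' @param alpha Significance threshold for masking (default 0.1).
#' @return An object of class `virchip_association`: list with `bins`,
#'   `genes`, `values` (M x G with `NA` masking), `n_cell_types`, `alpha`.
#' @export
build_association_matrix <- function(chip, expr_ranks, alpha = 0.1) {
  n <- length(chip$cell_types)
  if (n < 3) abort("need >= 3 cell types for a correlation test")
  if (nrow(expr_ranks) != n) {
    abort("`expr_ranks` must have one row per ChIP cell type")
  }
  if (!is.null(rownames(expr_ranks)) &&
      !identical(rownames(expr_ranks), chip$cell_types)) {
    abort("cell-type order differs between ChIP matrix and expression ranks")
  }
  X <- t(chip$values)                         # N x M
  sx <- apply(X, 2, sd)
  sy <- apply(expr_ranks, 2, sd)
  const_bin <- sx == 0
  const_gene <- sy == 0
  Xc <- scale(X[, !const_bin, drop = FALSE])
  Yc <- scale(expr_ranks[, !const_gene, drop = FALSE])
  r_ok <- crossprod(Xc, Yc) / (n - 1)
  r_ok[r_ok > 1] <- 1; r_ok[r_ok < -1] <- -1
  r <- matrix(NA_real_, nrow = ncol(X), ncol = ncol(expr_ranks),
              dimnames = list(NULL, colnames(expr_ranks)))
  r[!const_bin, !const_gene] <- r_ok
  r[abs(r) < critical_r(n, alpha)] <- NA
  structure(list(bins = chip$bins, genes = colnames(expr_ranks), values = r,
                 n_cell_types = n, alpha = alpha),
            class = "virchip_association")
}

# |r| below which the two-sided Pearson test has p > alpha at sample size n
critical_r <- function(n, alpha) {
  tc <- qt(1 - alpha / 2, df = n - 2)
  sqrt(tc^2 / (tc^2 + n - 2))
}

#' @export
print.virchip_association <- function(x, ...) {
  cat("<virchip_association> ", nrow(x$values), " bins x ",
      length(x$genes), " genes (N = ", x$n_cell_types,
      ", alpha = ", x$alpha, "); ",
      round(100 * mean(is.na(x$values)), 1), "% NA\n", sep = "")
  invisible(x)
}

#' @describeIn build_association_matrix Tidy the association matrix into a
#'   long tibble of non-NA entries (`bin`, `gene_id`, `r`).
#' @param x A `virchip_association`.
#' @param ... Unused.
#' @method tidy virchip_association
#' @export
tidy.virchip_association <- function(x, ...) {
  idx <- which(!is.na(x$values), arr.ind = TRUE)
  tibble(bin = idx[, 1], chrom = x$bins$chrom[idx[, 1]],
         start = x$bins$start[idx[, 1]],
         gene_id = x$genes[idx[, 2]], r = x$values[idx])
}

#' Per-bin expression score for a new cell type
#'
#' The expression score of a bin is the Spearman rank correlation between the
#' bin's non-NA association values and the new cell type's expression of
#' those genes. Bins with fewer than `min_genes` informative genes (or with
#' tie-degenerate ranks) score `NA`.
#'
#' @param assoc A `virchip_association`.
#' @param new_expr Expression tibble for the new cell type, or a named
#'   numeric vector of expression keyed by gene id.
#' @param cell_type Column of `new_expr` to use; defaults to its single
#'   cell-type column.
#' @param min_genes Minimum number of informative genes for a non-NA score
#'   (default 5).
#' @return Tibble: the association bins plus `score` and `n_genes_used`.
#' @export
expression_score <- function(assoc, new_expr, cell_type = NULL, min_genes = 5) {
  if (is.data.frame(new_expr)) {
    m <- expression_values(new_expr, cell_type)
    if (is.null(cell_type)) {
      if (ncol(m) != 1) abort("specify `cell_type`: table has several columns")
    }
    e_all <- m[, 1]
  } else {
    e_all <- new_expr
  }
  e <- e_all[match(assoc$genes, names(e_all))]
  if (all(is.na(e))) {
    warn("no overlap between association genes and the new expression data")
    return(mutate(as_tibble(assoc$bins), score = NA_real_, n_genes_used = 0L))
  }
  A <- assoc$values
  usable <- !is.na(A) & rep(!is.na(e), each = nrow(A))
  n_used <- as.integer(rowSums(usable))
  scores <- rep(NA_real_, nrow(A))
  todo <- which(n_used >= min_genes)
  if (length(todo) > 0) {
    # many bins share an identical association row (e.g. all never-bound
    # bins); compute each distinct row once
    sub <- A[todo, , drop = FALSE]
    # identical rows (common for never-bound bins) are computed once; rows
    # are grouped by two fixed projections of the NA-imputed values
    B <- sub
    B[is.na(B)] <- -2
    G <- ncol(B)
    proj <- B %*% cbind(sin(seq_len(G)), cos(sqrt(seq_len(G))))
    key <- paste(proj[, 1], proj[, 2])
    dup_of <- match(key, key)
    firsts <- which(dup_of == seq_along(dup_of))
    vals <- vapply(firsts, function(i) {
      keep <- usable[todo[i], ]
      spearman_rho(sub[i, keep], e[keep])
    }, numeric(1))
    scores[todo] <- vals[match(dup_of, firsts)]
  }
  out <- as_tibble(assoc$bins)
  out$score <- scores
  out$n_genes_used <- n_used
  out
}

# Spearman rho as Pearson correlation of average-tie ranks
spearman_rho <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (sd(rx) == 0 || sd(ry) == 0) return(NA_real_)
  cor(rx, ry)
}
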