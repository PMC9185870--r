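#' Confusion counts from predictions and labels
#'
#' @param predicted Logical (or 0/1) predicted-positive vector.
#' @param actual Logical (or 0/1) true-label vector.
#' @return One-row tibble with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(predicted, actual) {
  predicted <- as.logical(predicted); actual <- as.logical(actual)
  tibble(tp = sum(predicted & actual), fp = sum(predicted & !actual),
         tn = sum(!predicted & !actual), fn = sum(!predicted & actual))
}

#' Matthews correlation coefficient
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, in \[-1, 1\];
#' defined as 0 whenever a denominator factor is zero (e.g. an all-negative
#' prediction). Robust to class imbalance, which is why it drives model
#' selection.
#'
#' @param tp,fp,tn,fn Confusion counts (non-negative).
#' @return MCC in \[-1, 1\].
#' @export
mcc <- function(tp, fp, tn, fn) {
  tp <- as.double(tp); fp <- as.double(fp)
  tn <- as.double(tn); fn <- as.double(fn)
  if (tp + fp + tn + fn <= 0) abort("empty confusion matrix")
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom == 0) return(0)
  (tp * tn - fp * fn) / sqrt(denom)
}

#' F1 score and accuracy
#'
#' @inheritParams mcc
#' @return One-row tibble with `f1` (0 when no positives are predicted or
#'   present) and `accuracy`.
#' @export
f1_accuracy <- function(tp, fp, tn, fn) {
  tp <- as.double(tp); fp <- as.double(fp)
  tn <- as.double(tn); fn <- as.double(fn)
  total <- tp + fp + tn + fn
  if (total <= 0) abort("empty confusion matrix")
  f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  tibble(f1 = f1, accuracy = (tp + tn) / total)
}

#' ROC and precision-recall curves with areas
#'
#' Threshold-free evaluation of a scoring classifier. auROC is the trapezoid
#' area over all score thresholds (equal to the normalized Mann-Whitney U
#' statistic, midranks for ties). auPR uses the nonlinear precision-recall
#' interpolation of Davis & Goadrich, under which a constant-score
#' classifier scores exactly the prevalence (the auPR baseline); the plain
#' trapezoid value is reported alongside for transparency.
#'
#' @param posteriors Numeric classifier scores.
#' @param labels Binary labels (both classes must be present).
#' @return Object of class `virchip_curves`: list with `auroc`, `aupr`,
#'   `aupr_trapezoid`, `prevalence` and the `roc` / `pr` curve tibbles.
#' @export
roc_pr_curves <- function(posteriors, labels) {
  y <- as.logical(labels)
  if (all(y) || !any(y)) abort("labels contain a single class")
  P <- sum(y); N <- sum(!y)
  ord <- order(posteriors, decreasing = TRUE)
  s <- posteriors[ord]; yy <- y[ord]
  last <- c(s[-1] != s[-length(s)], TRUE)  # last index of each tied block
  tp <- cumsum(yy)[last]; fp <- cumsum(!yy)[last]
  tp <- c(0, tp); fp <- c(0, fp)
  tpr <- tp / P; fpr <- fp / N
  auroc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  prec <- ifelse(tp + fp == 0, 1, tp / (tp + fp))
  rec <- tpr
  aupr_trap <- sum(diff(rec) * (prec[-1] + prec[-length(prec)]) / 2)
  aupr <- 0
  for (i in seq_len(length(tp) - 1)) {
    dtp <- tp[i + 1] - tp[i]
    if (dtp == 0) next
    dfp <- fp[i + 1] - fp[i]
    x <- seq_len(dtp)
    aupr <- aupr + sum((tp[i] + x) / (tp[i] + x + fp[i] + dfp * x / dtp)) / P
  }
  structure(list(auroc = auroc, aupr = aupr, aupr_trapezoid = aupr_trap,
                 prevalence = P / (P + N),
                 roc = tibble(fpr = fpr, tpr = tpr),
                 pr = tibble(recall = rec, precision = prec)),
            class = "virchip_curves")
}

#' @export
print.virchip_curves <- function(x, ...) {
  cat("<virchip_curves> auROC = ", round(x$auroc, 4), ", auPR = ",
      round(x$aupr, 4), " (baseline ", round(x$prevalence, 4), ")\n", sep = "")
  invisible(x)
}

#' @method glance virchip_curves
#' @export
glance.virchip_curves <- function(x, ...) {
  tibble(auroc = x$auroc, aupr = x$aupr,
         aupr_trapezoid = x$aupr_trapezoid, prevalence = x$prevalence)
}

#' Posterior cutoff maximizing MCC
#'
#' Scans the cutoff grid 0, 0.01, ..., 1 (predictions are
#' `posterior >= cutoff`) and returns the cutoff with the highest MCC on the
#' tuning data, ties resolved toward the smallest cutoff. When no tuning
#' data is available the preset cutoff 0.4 (the mode of tuned cutoffs) is
#' returned.
#'
#' @param posteriors,labels Tuning data; both `NULL` to request the preset.
#' @param grid_step Cutoff grid resolution (default 0.01).
#' @param preset Fallback cutoff (default 0.4).
#' @return The chosen cutoff.
#' @export
choose_cutoff <- function(posteriors = NULL, labels = NULL, grid_step = 0.01,
                          preset = 0.4) {
  if (is.null(posteriors) || is.null(labels)) return(preset)
  y <- as.logical(labels)
  if (all(y) || !any(y)) abort("labels contain a single class")
  cutoffs <- seq(0, 1, by = grid_step)
  mccs <- vapply(cutoffs, function(ct) {
    cc <- confusion_counts(posteriors >= ct, y)
    mcc(cc$tp, cc$fp, cc$tn, cc$fn)
  }, numeric(1))
  cutoffs[which.max(mccs)]
}

#' Per-chromosome (or pooled) evaluation report
#'
#' Thresholded metrics (MCC, F1, accuracy at `cutoff`) and threshold-free
#' areas (auROC, auPR) with the prevalence baseline, per chromosome or
#' pooled across chromosomes.
#'
#' @param predictions Tibble with `chrom`, `posterior` and a binary `bound`
#'   column.
#' @param cutoff Posterior cutoff for the thresholded metrics.
#' @param mode `"per-chrom"` or `"pooled"`.
#' @return Tibble with one row per chromosome (or one `"pooled"` row):
#'   `chrom`, `mcc`, `f1`, `accuracy`, `auroc`, `aupr`, `prevalence`,
#'   `cutoff`.
#' @export
evaluate_predictions <- function(predictions, cutoff = 0.4,
                                 mode = c("per-chrom", "pooled")) {
  mode <- match.arg(mode)
  groups <- if (mode == "pooled") list(pooled = predictions)
            else split(predictions, predictions$chrom)
  purrr::imap(groups, function(df, chrom) {
    cc <- confusion_counts(df$posterior >= cutoff, df$bound > 0)
    fa <- f1_accuracy(cc$tp, cc$fp, cc$tn, cc$fn)
    curves <- if (any(df$bound > 0) && !all(df$bound > 0)) {
      roc_pr_curves(df$posterior, df$bound > 0)
    } else NULL
    tibble(chrom = chrom, mcc = mcc(cc$tp, cc$fp, cc$tn, cc$fn),
           f1 = fa$f1, accuracy = fa$accuracy,
           auroc = if (is.null(curves)) NA_real_ else curves$auroc,
           aupr = if (is.null(curves)) NA_real_ else curves$aupr,
           prevalence = mean(df$bound > 0), cutoff = cutoff)
  }) |> dplyr::bind_rows()
}

#' Jaccard similarity of co-clustered pairs
#'
#' Represents each clustering as its set of unordered same-cluster item
#' pairs and returns |intersection| / |union|; 1 when both clusterings have
#' no pairs at all (all singletons).
#'
#' @param a,b Cluster labelings: named vectors over the same item set.
#' @return Jaccard index in \[0, 1\].
#' @export
jaccard_coclusters <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) abort("need at least 2 items")
  if (!setequal(names(a), names(b))) abort("clusterings cover different items")
  b <- b[names(a)]
  pair_set <- function(cl) {
    unlist(lapply(split(names(cl), cl), function(items) {
      if (length(items) < 2) return(character(0))
      items <- sort(items)
      pairs <- utils::combn(items, 2)
      paste(pairs[1, ], pairs[2, ], sep = "\r")
    }), use.names = FALSE)
  }
  pa <- pair_set(a); pb <- pair_set(b)
  u <- union(pa, pb)
  if (length(u) == 0) return(1)
  length(intersect(pa, pb)) / length(u)
}

#' Cluster count selection by subsampling stability
#'
#' For each candidate number of clusters k, repeatedly (default 50 times)
#' draws two 75% row subsamples of the correlation matrix without
#' replacement, hierarchically clusters each (average linkage on
#' 1 - correlation), and records the Jaccard co-cluster similarity over the
#' shared items. The same procedure runs on the correlation matrix of a
#' seeded Gaussian random matrix of matching shape as a null control. The
#' selected k is the smallest k whose mean Jaccard increases over k - 1 in
#' the data matrix; when no k shows an increase the smallest candidate is
#' returned with `increase_found = FALSE`.
#'
#' @param corr Symmetric correlation matrix with row/column names (>= 4
#'   items).
#' @param k_range Candidate cluster counts (default 2:10).
#' @param subsample Row fraction per subsample (default 0.75).
#' @param repeats Subsampling repeats per k (default 50).
#' @param seed RNG seed.
#' @param control_features Number of columns of the Gaussian control matrix
#'   (default: number of items).
#' @return Object of class `virchip_stability`: list with `k` (selected),
#'   `increase_found`, and `stability` (tibble of per-k mean Jaccard for
#'   data and control).
#' @export
cluster_stability_select <- function(corr, k_range = 2:10, subsample = 0.75,
                                     repeats = 50, seed = 1,
                                     control_features = NULL) {
  n <- nrow(corr)
  if (n < 4) abort("need at least 4 items to assess cluster stability")
  if (is.null(rownames(corr))) {
    rownames(corr) <- colnames(corr) <- paste0("item", seq_len(n))
  }
  k_range <- k_range[k_range < n]
  set.seed(seed)
  control <- cor(matrix(rnorm(n * (control_features %||% n)), nrow = n))
  rownames(control) <- colnames(control) <- rownames(corr)
  stability_of <- function(mat) {
    vapply(k_range, function(k) {
      js <- vapply(seq_len(repeats), function(rep_i) {
        m <- max(2, floor(subsample * n))
        i1 <- sort(sample.int(n, m)); i2 <- sort(sample.int(n, m))
        cl1 <- cutree(hclust(as.dist(1 - mat[i1, i1]), method = "average"), k)
        cl2 <- cutree(hclust(as.dist(1 - mat[i2, i2]), method = "average"), k)
        shared <- intersect(rownames(mat)[i1], rownames(mat)[i2])
        if (length(shared) < 2) return(NA_real_)
        jaccard_coclusters(cl1[shared], cl2[shared])
      }, numeric(1))
      mean(js, na.rm = TRUE)
    }, numeric(1))
  }
  set.seed(seed + 1)
  j_data <- stability_of(corr)
  set.seed(seed + 1)
  j_control <- stability_of(control)
  increase <- which(diff(j_data) > 0)
  found <- length(increase) > 0
  k <- if (found) k_range[increase[1] + 1] else k_range[1]
  structure(list(k = k, increase_found = found,
                 stability = tibble(k = k_range, jaccard_data = j_data,
                                    jaccard_control = j_control)),
            class = "virchip_stability")
}

#' @export
print.virchip_stability <- function(x, ...) {
  cat("<virchip_stability> selected k = ", x$k,
      if (!x$increase_found) " (no stability increase found)" else "",
      "\n", sep = "")
  invisible(x)
}

#' @method tidy virchip_stability
#' @export
tidy.virchip_stability <- function(x, ...) x$stability
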