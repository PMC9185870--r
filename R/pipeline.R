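#' Run the full prediction pipeline on a cohort
#'
#' Executes every stage end to end on an in-memory cohort: the 100 bp
#' ChIP-expression association matrix and per-cell-type expression scores,
#' 200 bp feature assembly (binding frequency, accessibility, conservation,
#' motif scores), hyperparameter selection by leave-one-chromosome-out
#' cross-validation on MCC, final training, posterior prediction for every
#' bin of the held-out cell type, cutoff transfer from a tuning cell type,
#' and per-chromosome plus pooled evaluation.
#'
#' @param cohort A `virchip_cohort` from [generate_cohort()] (or any list
#'   with the same elements built from files).
#' @param grid Hyperparameter grid; default is a small two-point grid
#'   (relu/tanh, two hidden layers) appropriate for desk-scale cohorts —
#'   pass [default_hyperparameter_grid()] output for the full search.
#' @param n_genes High-variance genes for the association matrix
#'   (default 5000, capped at the cohort's gene count).
#' @param alpha Association-matrix significance threshold (default 0.1).
#' @param tune_cell_type Cell type used to tune the posterior cutoff; by
#'   default the last training cell type. `NULL` uses the preset cutoff 0.4.
#' @param max_epochs Training epoch cap for all fits (default 60).
#' @param seed Seed for model fitting.
#' @return A list of class `virchip_pipeline` with the association matrix,
#'   cross-validation result, trained model, chosen cutoff, per-bin
#'   held-out predictions, the per-chromosome evaluation report and pooled
#'   curves.
#' @export
run_cohort_pipeline <- function(cohort, grid = NULL, n_genes = 5000,
                                alpha = 0.1, tune_cell_type = NA,
                                max_epochs = 60, seed = 1) {
  sizes <- cohort$chrom_sizes
  train_cts <- cohort$train_cell_types
  heldout <- cohort$heldout_cell_types[1]
  bins100 <- make_fixed_bins(sizes)
  bins200 <- make_sliding_bins(sizes)

  chip_train <- cohort$chip_peaks[cohort$chip_peaks$cell_type %in% train_cts, ]
  C <- build_chip_matrix(chip_train, bins100, cell_types = train_cts)
  Cn <- row_normalize(quantile_normalize(C))
  genes <- select_high_variance_genes(cohort$expression,
                                      n_genes = min(n_genes, nrow(cohort$expression)),
                                      cell_types = train_cts)
  E <- rank_normalize_expression(cohort$expression, genes, train_cts)
  assoc <- build_association_matrix(Cn, E, alpha = alpha)

  motifs <- resolve_motifs(cohort$spec$factor_name, cohort$motif_catalog)
  motif_cols <- motif_features(bins200, cohort$motif_hits, motifs)
  cons <- mean_conservation(bins200, cohort$conservation)

  labels <- lapply(setNames(train_cts, train_cts), function(ct) {
    make_labels(bins200,
                cohort$chip_peaks[cohort$chip_peaks$cell_type == ct, ])
  })
  bind_freq <- binding_frequency(bins200, labels)

  feature_for <- function(ct) {
    score100 <- expression_score(assoc, cohort$expression, cell_type = ct)
    acc_ct <- cohort$acc_peaks[cohort$acc_peaks$cell_type == ct, ]
    cell_feature_table(
      bins200,
      expression_score = map_expression_score(bins200, score100),
      binding_frequency = bind_freq,
      accessibility = map_accessibility(bins200, acc_ct),
      conservation = cons,
      motif_cols = motif_cols
    )
  }
  features <- lapply(setNames(train_cts, train_cts), feature_for)
  accessible <- lapply(setNames(train_cts, train_cts), function(ct) {
    accessible_bins(bins200, cohort$acc_peaks[cohort$acc_peaks$cell_type == ct, ])
  })
  train_mat <- assemble_training_matrix(features, labels, accessible)

  p <- length(feature_names(features[[1]]))
  grid <- grid %||% tibble(activation = c("relu", "tanh"),
                           hidden_units = 2 * (p + 1),
                           hidden_layers = 2, l2 = 1e-4)
  cv <- mlp_grid_search(train_mat, grid = grid, seed = seed,
                        max_epochs = max_epochs)
  model <- mlp_train(train_mat, cv$best_config)

  cutoff <- if (is.null(tune_cell_type)) {
    choose_cutoff()
  } else {
    if (is.na(tune_cell_type)) tune_cell_type <- train_cts[length(train_cts)]
    tune_feat <- features[[tune_cell_type]]
    tune_lab <- labels[[tune_cell_type]]
    choose_cutoff(predict(model, tune_feat), tune_lab$bound)
  }

  ho_feat <- feature_for(heldout)
  ho_labels <- make_labels(
    bins200, cohort$chip_peaks[cohort$chip_peaks$cell_type == heldout, ])
  predictions <- ho_feat[, c("chrom", "start", "end")]
  predictions$posterior <- predict(model, ho_feat)
  predictions$bound <- ho_labels$bound
  report <- evaluate_predictions(predictions, cutoff = cutoff)
  pooled <- roc_pr_curves(predictions$posterior, predictions$bound > 0)

  structure(list(association = assoc, cv = cv, model = model,
                 cutoff = cutoff, heldout_cell_type = heldout,
                 predictions = predictions, report = report,
                 pooled = pooled, prevalence = prevalence(predictions)),
            class = "virchip_pipeline")
}

#' @export
print.virchip_pipeline <- function(x, ...) {
  cat("<virchip_pipeline> held-out cell type ", x$heldout_cell_type,
      ": pooled auPR = ", round(x$pooled$aupr, 3),
      " (prevalence ", round(x$pooled$prevalence, 4), "), cutoff = ",
      x$cutoff, "\n", sep = "")
  invisible(x)
}

#' @method glance virchip_pipeline
#' @export
glance.virchip_pipeline <- function(x, ...) {
  tibble(heldout_cell_type = x$heldout_cell_type, cutoff = x$cutoff,
         aupr = x$pooled$aupr, auroc = x$pooled$auroc,
         prevalence = x$pooled$prevalence,
         mcc_at_cutoff = with(
           confusion_counts(x$predictions$posterior >= x$cutoff,
                            x$predictions$bound > 0),
           mcc(tp, fp, tn, fn)))
}

#' End-to-end smoke run on a synthetic cohort
#'
#' Generates a cohort from `spec` and runs [run_cohort_pipeline()], holding
#' out one synthetic cell type. Warns when the held-out area under the
#' precision-recall curve does not beat the prevalence baseline or the MCC
#' at the transferred cutoff is not positive.
#'
#' @param spec A [cohort_spec()] (default: the standard desk-scale cohort).
#' @param ... Passed on to [run_cohort_pipeline()].
#' @return The `virchip_pipeline` result.
#' @export
end_to_end_smoke <- function(spec = cohort_spec(), ...) {
  cohort <- generate_cohort(spec)
  res <- run_cohort_pipeline(cohort, seed = spec$seed, ...)
  if (!(res$pooled$aupr > res$pooled$prevalence)) {
    warn("held-out auPR does not exceed the prevalence baseline")
  }
  g <- glance(res)
  if (!(g$mcc_at_cutoff > 0)) {
    warn("held-out MCC at the transferred cutoff is not positive")
  }
  res
}
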