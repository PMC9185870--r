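mlp_activations <- c("logistic", "tanh", "relu")

#' Multi-layer perceptron configuration
#'
#' @param activation Hidden-layer activation: `"logistic"`, `"tanh"` or
#'   `"relu"` (rectifier).
#' @param hidden_units Hidden units per layer.
#' @param hidden_layers Number of hidden layers.
#' @param l2 L2 regularization penalty.
#' @param minibatch Minibatch size for stochastic gradient descent
#'   (default 200).
#' @param max_epochs Maximum training epochs (default 200).
#' @param learning_rate Adam step size (default 1e-3).
#' @param tol Minimum loss improvement considered progress (default 1e-4).
#' @param patience Epochs without progress before early stopping
#'   (default 10).
#' @param seed RNG seed controlling initialization and minibatch shuffling.
#' @return A list of class `virchip_mlp_config`.
#' @export
mlp_config <- function(activation = "relu", hidden_units = 50,
                       hidden_layers = 2, l2 = 1e-4, minibatch = 200,
                       max_epochs = 200, learning_rate = 1e-3, tol = 1e-4,
                       patience = 10, seed = 1) {
  activation <- match.arg(activation, mlp_activations)
  stopifnot(hidden_units >= 1, hidden_layers >= 1, l2 >= 0, minibatch >= 1)
  structure(list(activation = activation, hidden_units = hidden_units,
                 hidden_layers = hidden_layers, l2 = l2,
                 minibatch = minibatch, max_epochs = max_epochs,
                 learning_rate = learning_rate, tol = tol,
                 patience = patience, seed = seed),
            class = "virchip_mlp_config")
}

#' Default hyperparameter grid
#'
#' The full search grid: 3 activation functions x 3 hidden-unit settings
#' (2(p + 1), 50, 100, with p the number of features of the factor's model)
#' x 4 depths (2, 5, 10, 50) x 3 L2 penalties (1e-4, 1e-3, 1e-2) = 108
#' configurations.
#'
#' @param p Number of feature columns (sets the `2(p + 1)` unit option).
#' @return Tibble with columns `activation`, `hidden_units`,
#'   `hidden_layers`, `l2` (108 rows).
#' @export
default_hyperparameter_grid <- function(p) {
  tidyr::expand_grid(
    activation = mlp_activations,
    hidden_units = unique(c(2 * (p + 1), 50, 100)),
    hidden_layers = c(2, 5, 10, 50),
    l2 = c(1e-4, 1e-3, 1e-2)
  )
}

#' Uniform initialization bound for one layer
#'
#' Weights and biases of a layer are drawn uniformly from (-b, b) with
#' `b = sqrt(l / (u_in + u_out))`, where the activation factor l is 2 for
#' the logistic activation and 6 otherwise.
#'
#' @param units_in,units_out Fan-in and fan-out of the layer.
#' @param activation Activation function of the layer.
#' @return The bound b.
#' @export
init_bound <- function(units_in, units_out, activation = "relu") {
  l <- if (activation == "logistic") 2 else 6
  sqrt(l / (units_in + units_out))
}

act_fun <- function(name) {
  switch(name,
         logistic = function(z) 1 / (1 + exp(-z)),
         tanh = tanh,
         relu = function(z) pmax(z, 0))
}

act_grad <- function(name) {
  switch(name,
         logistic = function(a) a * (1 - a),
         tanh = function(a) 1 - a^2,
         relu = function(a) (a > 0) * 1)
}

#' Train the multi-layer perceptron
#'
#' Binary cross-entropy loss with L2 penalty, minimised by adaptive-momentum
#' stochastic gradient descent (Adam) on minibatches of
#' `config$minibatch` rows. Training is deterministic given `config$seed`,
#' which fixes both initialization and the per-epoch row shuffle. Training
#' stops early once the epoch loss has not improved by `config$tol` for
#' `config$patience` consecutive epochs; a fit whose loss never improves (or
#' becomes non-finite) is flagged as non-converged.
#'
#' @param data Tibble of training rows: feature columns plus a binary label
#'   column.
#' @param config A [mlp_config()].
#' @param feature_cols Feature column names; defaults to all columns except
#'   `chrom`, `start`, `end`, `cell_type` and the label.
#' @param label_col Name of the binary label column (default `"bound"`).
#' @return Object of class `virchip_mlp` holding weights, biases, the
#'   config, the feature-name order, the loss history and a `converged`
#'   flag.
#' @export
mlp_train <- function(data, config = mlp_config(), feature_cols = NULL,
                      label_col = "bound") {
  feature_cols <- feature_cols %||%
    setdiff(names(data), c("chrom", "start", "end", "cell_type", label_col))
  X <- as.matrix(data[, feature_cols, drop = FALSE])
  y <- data[[label_col]]
  if (length(unique(y)) < 2) {
    abort("training labels contain a single class")
  }
  p <- ncol(X); n <- nrow(X)
  sizes <- c(p, rep(config$hidden_units, config$hidden_layers), 1)
  L <- length(sizes) - 1
  set.seed(config$seed)
  W <- vector("list", L); b <- vector("list", L)
  for (i in seq_len(L)) {
    layer_act <- if (i == L) "logistic" else config$activation
    bd <- init_bound(sizes[i], sizes[i + 1], layer_act)
    W[[i]] <- matrix(runif(sizes[i] * sizes[i + 1], -bd, bd),
                     nrow = sizes[i])
    b[[i]] <- runif(sizes[i + 1], -bd, bd)
  }
  f <- act_fun(config$activation); g <- act_grad(config$activation)
  mW <- lapply(W, function(w) w * 0); vW <- mW
  mB <- lapply(b, function(x) x * 0); vB <- mB
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; t_step <- 0
  losses <- numeric(0); best <- Inf; stall <- 0; eps_p <- 1e-10
  for (epoch in seq_len(config$max_epochs)) {
    idx <- sample.int(n)
    batch_starts <- seq(1, n, by = config$minibatch)
    epoch_loss <- 0
    for (s in batch_starts) {
      rows <- idx[s:min(s + config$minibatch - 1, n)]
      nb <- length(rows)
      A <- vector("list", L + 1)
      A[[1]] <- X[rows, , drop = FALSE]
      for (i in seq_len(L)) {
        Z <- A[[i]] %*% W[[i]] + rep(b[[i]], each = nb)
        A[[i + 1]] <- if (i == L) 1 / (1 + exp(-Z)) else f(Z)
      }
      prob <- pmin(pmax(A[[L + 1]][, 1], eps_p), 1 - eps_p)
      yb <- y[rows]
      l2_term <- 0.5 * config$l2 *
        sum(vapply(W, function(w) sum(w^2), numeric(1))) / nb
      epoch_loss <- epoch_loss +
        nb * (-mean(yb * log(prob) + (1 - yb) * log(1 - prob)) + l2_term)
      delta <- matrix((prob - yb) / nb, ncol = 1)
      t_step <- t_step + 1
      lr_t <- config$learning_rate *
        sqrt(1 - beta2^t_step) / (1 - beta1^t_step)
      for (i in rev(seq_len(L))) {
        gW <- crossprod(A[[i]], delta) + config$l2 * W[[i]] / nb
        gB <- colSums(delta)
        if (i > 1) {
          delta <- (delta %*% t(W[[i]])) * g(A[[i]])
        }
        mW[[i]] <- beta1 * mW[[i]] + (1 - beta1) * gW
        vW[[i]] <- beta2 * vW[[i]] + (1 - beta2) * gW^2
        W[[i]] <- W[[i]] - lr_t * mW[[i]] / (sqrt(vW[[i]]) + eps)
        mB[[i]] <- beta1 * mB[[i]] + (1 - beta1) * gB
        vB[[i]] <- beta2 * vB[[i]] + (1 - beta2) * gB^2
        b[[i]] <- b[[i]] - lr_t * mB[[i]] / (sqrt(vB[[i]]) + eps)
      }
    }
    losses <- c(losses, epoch_loss / n)
    if (!is.finite(losses[epoch])) break
    if (losses[epoch] < best - config$tol) {
      best <- losses[epoch]; stall <- 0
    } else {
      stall <- stall + 1
      if (stall >= config$patience) break
    }
  }
  converged <- length(losses) > 0 && is.finite(losses[length(losses)]) &&
    losses[1] - best > config$tol
  structure(list(weights = W, biases = b, config = config,
                 feature_names = feature_cols, loss = losses,
                 converged = converged, n_epochs = length(losses)),
            class = "virchip_mlp")
}

#' @export
print.virchip_mlp <- function(x, ...) {
  cfg <- x$config
  cat("<virchip_mlp> ", cfg$activation, ", ", cfg$hidden_layers,
      " hidden layers x ", cfg$hidden_units, " units, l2 = ", cfg$l2,
      "; trained ", x$n_epochs, " epochs (",
      if (x$converged) "converged" else "did not converge", ")\n", sep = "")
  invisible(x)
}

#' Posterior binding probabilities
#'
#' One posterior per row, computed independently of every other row; columns
#' of `newdata` are aligned to the training feature order by name.
#'
#' @param object A trained `virchip_mlp`.
#' @param newdata Tibble containing the model's feature columns.
#' @param ... Unused.
#' @return Numeric vector of posteriors in \[0, 1\].
#' @export
predict.virchip_mlp <- function(object, newdata, ...) {
  missing <- setdiff(object$feature_names, names(newdata))
  if (length(missing) > 0) {
    abort(paste0("missing feature column(s): ", paste(missing, collapse = ", ")))
  }
  A <- as.matrix(newdata[, object$feature_names, drop = FALSE])
  f <- act_fun(object$config$activation)
  L <- length(object$weights)
  for (i in seq_len(L)) {
    Z <- A %*% object$weights[[i]] + rep(object$biases[[i]], each = nrow(A))
    A <- if (i == L) 1 / (1 + exp(-Z)) else f(Z)
  }
  as.numeric(A)
}

#' @method tidy virchip_mlp
#' @export
tidy.virchip_mlp <- function(x, ...) {
  tibble(
    layer = seq_along(x$weights),
    units_in = vapply(x$weights, nrow, integer(1)),
    units_out = vapply(x$weights, ncol, integer(1)),
    weight_norm = vapply(x$weights, function(w) sqrt(sum(w^2)), numeric(1))
  )
}

#' @method glance virchip_mlp
#' @export
glance.virchip_mlp <- function(x, ...) {
  tibble(activation = x$config$activation,
         hidden_units = x$config$hidden_units,
         hidden_layers = x$config$hidden_layers, l2 = x$config$l2,
         n_epochs = x$n_epochs, final_loss = x$loss[length(x$loss)],
         converged = x$converged)
}

#' Leave-one-chromosome-out hyperparameter search
#'
#' For every grid configuration, trains on the training rows of all but one
#' chromosome and scores the Matthews correlation coefficient on the
#' held-out chromosome's evaluation rows at posterior cutoff `cutoff`,
#' rotating through the chromosomes; configurations are ranked by mean MCC
#' over the folds. Fits that fail to converge (or error) contribute MCC 0.
#' Ties break toward simpler models: fewer layers, then fewer units, then
#' stronger L2.
#'
#' @param data Training matrix (e.g. [assemble_training_matrix()]): feature
#'   columns plus `chrom` and the label.
#' @param grid Hyperparameter tibble (default: the full 108-point grid for
#'   this feature count).
#' @param eval_data Rows used for held-out evaluation; defaults to `data`.
#'   Pass a full-bin feature matrix to evaluate on every bin of the held-out
#'   chromosome.
#' @param cutoff Posterior cutoff used for the cross-validation MCC
#'   (default 0.5).
#' @param label_col Label column name.
#' @param seed Seed passed to every fit.
#' @param ... Further arguments to [mlp_config()] (e.g. `max_epochs`).
#' @return Object of class `virchip_cv`: list with `best_config` (an
#'   [mlp_config()]), `folds` (per config x fold MCC tibble) and `summary`
#'   (per-config mean MCC).
#' @export
mlp_grid_search <- function(data, grid = NULL, eval_data = data, cutoff = 0.5,
                            label_col = "bound", seed = 1, ...) {
  chroms <- unique(data$chrom)
  if (length(chroms) < 2) abort("cross-validation needs >= 2 chromosomes")
  feature_cols <- setdiff(names(data),
                          c("chrom", "start", "end", "cell_type", label_col))
  grid <- grid %||% default_hyperparameter_grid(length(feature_cols))
  folds <- tidyr::expand_grid(config_id = seq_len(nrow(grid)),
                              heldout = chroms)
  folds$mcc <- purrr::map2_dbl(folds$config_id, folds$heldout, function(ci, ho) {
    cfg <- mlp_config(activation = grid$activation[ci],
                      hidden_units = grid$hidden_units[ci],
                      hidden_layers = grid$hidden_layers[ci],
                      l2 = grid$l2[ci], seed = seed, ...)
    fit <- tryCatch(
      mlp_train(data[data$chrom != ho, , drop = FALSE], cfg,
                feature_cols = feature_cols, label_col = label_col),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) return(0)
    ev <- eval_data[eval_data$chrom == ho, , drop = FALSE]
    post <- predict(fit, ev)
    cc <- confusion_counts(post >= cutoff, ev[[label_col]] > 0)
    mcc(cc$tp, cc$fp, cc$tn, cc$fn)
  })
  means <- folds |>
    group_by(.data$config_id) |>
    summarise(mean_mcc = mean(.data$mcc), .groups = "drop")
  summary <- grid[, c("activation", "hidden_units", "hidden_layers", "l2")] |>
    mutate(config_id = dplyr::row_number()) |>
    left_join(means, by = "config_id")
  ord <- order(-summary$mean_mcc, summary$hidden_layers,
               summary$hidden_units, -summary$l2)
  best <- summary[ord[1], ]
  best_config <- mlp_config(activation = best$activation,
                            hidden_units = best$hidden_units,
                            hidden_layers = best$hidden_layers,
                            l2 = best$l2, seed = seed, ...)
  structure(list(best_config = best_config, folds = folds, summary = summary),
            class = "virchip_cv")
}

#' @export
print.virchip_cv <- function(x, ...) {
  cfg <- x$best_config
  cat("<virchip_cv> ", nrow(x$summary), " configurations x ",
      length(unique(x$folds$heldout)), " folds; best mean MCC = ",
      round(max(x$summary$mean_mcc), 3), " (", cfg$activation, ", ",
      cfg$hidden_layers, " x ", cfg$hidden_units, " units, l2 = ",
      cfg$l2, ")\n", sep = "")
  invisible(x)
}

#' @method tidy virchip_cv
#' @export
tidy.virchip_cv <- function(x, ...) {
  left_join(x$folds,
            x$summary[, c("config_id", "activation", "hidden_units",
                          "hidden_layers", "l2")],
            by = "config_id")
}

#' @method glance virchip_cv
#' @export
glance.virchip_cv <- function(x, ...) {
  cfg <- x$best_config
  tibble(activation = cfg$activation, hidden_units = cfg$hidden_units,
         hidden_layers = cfg$hidden_layers, l2 = cfg$l2,
         best_mean_mcc = max(x$summary$mean_mcc),
         n_configs = nrow(x$summary))
}

#' 50 bp overlap-count prediction track
#'
#' Collapses thresholded 200 bp sliding-bin predictions to a 50 bp track:
#' each 50 bp window's value is the number of positive bins covering it.
#' Interior windows are covered by exactly 4 sliding bins, so values range
#' from 0 to 4 (less at chromosome edges).
#'
#' @param bins Sliding bin tibble (200 bp / 50 bp grid per chromosome).
#' @param posteriors Per-bin posterior vector aligned to `bins`.
#' @param cutoff Posterior cutoff defining a positive bin.
#' @return Tibble with `chrom`, `start`, `end`, `count`.
#' @export
overlap_count_track <- function(bins, posteriors, cutoff) {
  validate_bins(bins)
  stride <- bin_stride(bins); width <- bin_width(bins)
  per_bin <- width / stride
  out <- lapply(split(seq_len(nrow(bins)), bins$chrom), function(ix) {
    n_win <- max(bins$end[ix]) / stride
    starts <- bins$start[ix][posteriors[ix] >= cutoff]
    counts <- integer(n_win)
    if (length(starts) > 0) {
      covered <- rep(starts / stride, each = per_bin) +
        rep(seq_len(per_bin) - 1, times = length(starts))
      tab <- tabulate(covered + 1, nbins = n_win)
      counts <- tab
    }
    tibble(chrom = bins$chrom[ix[1]],
           start = (seq_len(n_win) - 1) * stride,
           end = seq_len(n_win) * stride,
           count = as.integer(counts))
  })
  dplyr::bind_rows(out)
}
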