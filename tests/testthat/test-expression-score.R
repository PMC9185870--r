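test_that("ChIP matrix attributes peak signal to overlapping fixed bins", {
  bins <- make_fixed_bins(toy_sizes(c(chr1 = 1000)))
  pk <- peak_row(start = 100, end = 300, signal = 7)
  C <- build_chip_matrix(pk, bins)
  expect_equal(C$values[, 1], c(0, 7, 7, rep(0, 7)))

  two_reps <- dplyr::bind_rows(
    peak_row(start = 100, end = 200, signal = 4, replicate = "rep1"),
    peak_row(start = 100, end = 200, signal = 8, replicate = "rep2"))
  C2 <- build_chip_matrix(two_reps, bins)
  expect_equal(unname(C2$values[2, 1]), 6)

  C0 <- build_chip_matrix(pk[0, ], bins, cell_types = "ct1")
  expect_true(all(C0$values == 0))

  sliding <- make_sliding_bins(toy_sizes(c(chr1 = 1000)))
  expect_error(build_chip_matrix(pk, sliding), "fixed")
})

test_that("quantile normalization equalizes column order statistics", {
  out <- quantile_normalize(matrix(c(1, 3, 4, 2), 2))
  expect_equal(out, matrix(c(1.5, 3.5, 3.5, 1.5), 2))

  # identical columns as multisets are a fixed point up to reordering
  m <- cbind(c(5, 1, 3), c(3, 5, 1))
  expect_equal(quantile_normalize(m), m)

  # a constant column maps to the mean of the reference vector
  m2 <- cbind(c(2, 2, 2), c(1, 5, 9))
  out2 <- quantile_normalize(m2)
  expect_equal(out2[, 1], rep(mean(rowMeans(apply(m2, 2, sort))), 3))

  # sorted columns all equal the reference after normalization
  set.seed(21)
  m3 <- matrix(rexp(60), 12, 5)
  out3 <- quantile_normalize(m3)
  sorted <- apply(out3, 2, sort)
  expect_equal(sorted, sorted[, c(1, 1, 1, 1, 1)], tolerance = 1e-12)
})

test_that("quantile normalization matches the limma oracle on tie-free data", {
  # (tie handling deliberately uses the spanned-order-statistic mean, which
  # differs from limma's rank interpolation; ties are covered above)
  skip_if_not_installed("limma")
  set.seed(31)
  for (i in 1:5) {
    m <- matrix(rnorm(48), 12, 4)
    expect_equal(quantile_normalize(m),
                 unname(limma::normalizeQuantiles(m, ties = TRUE)),
                 tolerance = 1e-12)
  }
})

test_that("row normalization rescales to [0, 1] with zeroed constant rows", {
  m <- rbind(c(2, 4, 6), c(5, 5, 5))
  out <- row_normalize(m)
  expect_equal(out[1, ], c(0, 0.5, 1))
  expect_equal(out[2, ], c(0, 0, 0))

  set.seed(5)
  r <- matrix(rnorm(30), 3)
  out <- row_normalize(r)
  expect_equal(apply(out, 1, min), rep(0, 3))
  expect_equal(apply(out, 1, max), rep(1, 3))
  expect_equal(t(apply(out, 1, order)), t(apply(r, 1, order)))
})

test_that("high-variance gene selection is deterministic under ties", {
  expr <- tibble::tibble(gene_id = c("A", "B", "C"),
                         ct1 = c(0, 0, 0), ct2 = c(2, 1, 1.5),
                         ct3 = c(4, 2, 3.5))
  v <- apply(as.matrix(expr[, -1]), 1, var)
  expect_equal(order(-v), c(1, 3, 2))
  expect_equal(select_high_variance_genes(expr, 2), c("A", "C"))

  const <- tibble::tibble(gene_id = c("Z", "A", "M"), ct1 = 1, ct2 = 1)
  expect_equal(select_high_variance_genes(const, 2), c("A", "M"))
  expect_equal(length(select_high_variance_genes(const, 10)), 3)
})

test_that("expression rank normalization maps to [0,1] with average ties", {
  expr <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                         ct1 = c(10, 20, 30), ct2 = c(10, 10, 30))
  E <- rank_normalize_expression(expr, c("g1", "g2", "g3"))
  expect_equal(E["ct1", ], c(g1 = 0, g2 = 0.5, g3 = 1))
  expect_equal(E["ct2", ], c(g1 = 0.25, g2 = 0.25, g3 = 1))

  # invariant under strictly increasing transforms
  expr2 <- dplyr::mutate(expr, ct1 = exp(ct1 / 10), ct2 = ct2^3)
  expect_equal(rank_normalize_expression(expr2, expr$gene_id), E)
})

test_that("association matrix keeps exactly the significant correlations", {
  sizes <- toy_sizes(c(chr1 = 1200))
  bins <- make_fixed_bins(sizes)
  n <- 12
  cts <- sprintf("ct%02d", 1:n)
  e <- seq(0, 1, length.out = n)
  chip <- structure(list(
    bins = bins, cell_types = cts,
    values = rbind(matrix(rep(e, each = 2), nrow = 2, byrow = FALSE),
                   rev(e), matrix(0, nrow = 9, ncol = n))
  ), class = "virchip_chip_matrix")
  E <- cbind(gene_up = e, gene_dn = e)
  rownames(E) <- cts
  a <- build_association_matrix(chip, E)
  expect_equal(unname(a$values[1, "gene_up"]), 1)
  expect_equal(unname(a$values[3, "gene_up"]), -1)
  expect_true(all(is.na(a$values[4:12, ])))  # constant rows fully masked
  expect_error(build_association_matrix(
    structure(list(bins = bins, cell_types = cts[1:2],
                   values = chip$values[, 1:2]),
              class = "virchip_chip_matrix"), E[1:2, ]), ">= 3")
})

test_that("NA masking agrees with the t-distribution p-value oracle", {
  set.seed(77)
  n <- 5
  n_pairs <- 1000
  X <- matrix(rnorm(n * n_pairs), nrow = n)
  Y <- matrix(rnorm(n * n_pairs), nrow = n)
  bins <- make_fixed_bins(toy_sizes(c(chr1 = 100 * n_pairs)))
  chip <- structure(list(bins = bins, cell_types = paste0("ct", 1:n),
                         values = t(X)), class = "virchip_chip_matrix")
  colnames(Y) <- paste0("g", seq_len(n_pairs))
  rownames(Y) <- paste0("ct", 1:n)
  a <- build_association_matrix(chip, Y, alpha = 0.1)
  kept <- !is.na(diag(a$values))
  oracle <- vapply(seq_len(n_pairs), function(i) {
    stats::cor.test(X[, i], Y[, i])$p.value <= 0.1
  }, logical(1))
  expect_equal(kept, oracle)
  # and every kept entry clears the alpha-implied critical |r|
  tcrit <- qt(0.95, n - 2)
  rcrit <- sqrt(tcrit^2 / (tcrit^2 + n - 2))
  expect_true(all(abs(a$values[!is.na(a$values)]) >= rcrit - 1e-12))
})

test_that("expression score is the Spearman correlation with new expression", {
  sizes <- toy_sizes(c(chr1 = 300))
  bins <- make_fixed_bins(sizes)
  genes <- paste0("g", 1:10)
  vals <- matrix(NA_real_, nrow = 3, ncol = 10, dimnames = list(NULL, genes))
  set.seed(13)
  vals[1, ] <- seq(-0.9, 0.9, length.out = 10)
  vals[2, ] <- -vals[1, ]
  vals[3, ] <- runif(10, -1, 1)
  assoc <- structure(list(bins = bins, genes = genes, values = vals,
                          n_cell_types = 12, alpha = 0.1),
                     class = "virchip_association")
  new_expr <- stats::setNames(rank(vals[1, ]) + 0, genes)
  es <- expression_score(assoc, new_expr)
  expect_equal(es$score[1], 1)
  expect_equal(es$score[2], -1)
  brute <- cor(rank(vals[3, ]), rank(new_expr))
  expect_equal(es$score[3], brute)
  expect_equal(es$n_genes_used, rep(10L, 3))
})

test_that("expression score is invariant to monotone expression transforms", {
  co <- generate_cohort(small_cohort_spec())
  bins <- make_fixed_bins(co$chrom_sizes)
  C <- build_chip_matrix(
    co$chip_peaks[co$chip_peaks$cell_type %in% co$train_cell_types, ],
    bins, cell_types = co$train_cell_types)
  Cn <- row_normalize(quantile_normalize(C))
  genes <- select_high_variance_genes(co$expression,
                                      cell_types = co$train_cell_types)
  E <- rank_normalize_expression(co$expression, genes, co$train_cell_types)
  assoc <- build_association_matrix(Cn, E)
  ho <- co$heldout_cell_types[1]
  s1 <- expression_score(assoc, co$expression, cell_type = ho)
  warped <- co$expression
  warped[[ho]] <- exp(warped[[ho]] / max(warped[[ho]]))  # strictly increasing
  s2 <- expression_score(assoc, warped, cell_type = ho)
  expect_equal(s1$score, s2$score)
  expect_true(all(abs(s1$score[!is.na(s1$score)]) <= 1))
})

test_that("bins with too few informative genes score NA", {
  bins <- make_fixed_bins(toy_sizes(c(chr1 = 200)))
  vals <- rbind(c(0.5, 0.6, NA, NA, NA, NA), rep(NA, 6))
  colnames(vals) <- paste0("g", 1:6)
  assoc <- structure(list(bins = bins, genes = colnames(vals), values = vals,
                          n_cell_types = 12, alpha = 0.1),
                     class = "virchip_association")
  es <- expression_score(assoc, stats::setNames(1:6, colnames(vals)))
  expect_true(all(is.na(es$score)))
  expect_equal(es$n_genes_used, c(2L, 0L))
  expect_warning(
    all_na <- expression_score(assoc, stats::setNames(1:2, c("x", "y"))),
    "no overlap")
  expect_true(all(is.na(all_na$score)))
})

test_that("power analysis shrinks with cohort size and rejects bad input", {
  vals <- vapply(5:100, detectable_correlation, numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_error(detectable_correlation(3), "n")
  expect_error(detectable_correlation(21, power = 1.2), "power")
  # closed-form check: power at the solution equals the target
  r <- detectable_correlation(21)
  expect_equal(correlation_power(r, 21), 0.8, tolerance = 1e-8)
})

test_that("concordance correlation follows Lin's population-moment formula", {
  x <- c(1, 2, 3, 4)
  expect_equal(concordance_correlation(x, x), 1)
  z <- c(-2, -1, 1, 2)
  expect_equal(concordance_correlation(z, -z), -1)
  y <- c(1, 2, 3, 6)
  mx <- mean(x); my <- mean(y)
  expected <- 2 * mean((x - mx) * (y - my)) /
    (mean((x - mx)^2) + mean((y - my)^2) + (mx - my)^2)
  expect_equal(concordance_correlation(x, y), expected)
  expect_error(concordance_correlation(c(1, 1), c(1, 1)), "degenerate")
})

test_that("weak associations at few cell types are mostly masked", {
  # at alpha = 0.1 the masking test keeps ~10% of null-like pairs by
  # construction, so the NA rate for |r| = 0.2 at N = 5 plateaus near 90%
  set.seed(55)
  n <- 5; n_pairs <- 800; r <- 0.2
  Z <- matrix(rnorm(n * n_pairs), nrow = n)
  X <- r * Z + sqrt(1 - r^2) * matrix(rnorm(n * n_pairs), nrow = n)
  bins <- make_fixed_bins(toy_sizes(c(chr1 = 100 * n_pairs)))
  chip <- structure(list(bins = bins, cell_types = paste0("ct", 1:n),
                         values = t(X)), class = "virchip_chip_matrix")
  colnames(Z) <- paste0("g", seq_len(n_pairs))
  rownames(Z) <- paste0("ct", 1:n)
  a <- build_association_matrix(chip, Z, alpha = 0.1)
  expect_gte(mean(is.na(diag(a$values))), 0.8)
})
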