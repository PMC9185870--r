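test_that("accessibility maps summit signal with p-terminus tie-break", {
  bins <- make_sliding_bins(toy_sizes(c(chr1 = 300)))  # [0,200) [50,250) [100,300)
  one <- peak_row(start = 100, end = 200, signal = 9, summit_offset = 50)
  expect_equal(map_accessibility(bins, one), c(9, 9, 9))

  two <- dplyr::bind_rows(
    peak_row(start = 100, end = 200, signal = 9, summit_offset = 50),   # summit 150
    peak_row(start = 200, end = 300, signal = 2, summit_offset = 50))   # summit 250
  # bin [100,300) overlaps both summits; 150 is closer to the p terminus
  expect_equal(map_accessibility(bins, two), c(9, 9, 9))

  two_exp <- dplyr::bind_rows(
    peak_row(start = 100, end = 200, signal = 9, summit_offset = 50,
             experiment = "exp1"),
    peak_row(start = 100, end = 200, signal = 3, summit_offset = 50,
             experiment = "exp2"))
  expect_equal(map_accessibility(bins, two_exp), c(6, 6, 6))

  no_summit <- peak_row(start = 100, end = 200, summit_offset = -1)
  expect_error(map_accessibility(bins, no_summit), "summit")
})

test_that("mean conservation counts missing bases as zero", {
  bins <- make_sliding_bins(toy_sizes(c(chr1 = 200)))
  flat <- tibble::tibble(chrom = "chr1", start = 0, end = 200, score = 0.5)
  expect_equal(mean_conservation(bins, flat), 0.5)

  half <- tibble::tibble(chrom = "chr1", start = c(0, 100), end = c(100, 200),
                         score = c(1, 0))
  expect_equal(mean_conservation(bins, half), 0.5)

  missing_half <- tibble::tibble(chrom = "chr1", start = 0, end = 100, score = 1)
  expect_equal(mean_conservation(bins, missing_half), 0.5)
})

test_that("motif features average scores by hit midpoint", {
  bins <- make_sliding_bins(toy_sizes(c(chr1 = 250)))  # [0,200) [50,250)
  hits <- tibble::tibble(motif_id = "M1", chrom = "chr1",
                         start = c(60, 100), end = c(80, 120),
                         strand = "+", score = c(10, 14), pvalue = 1e-4)
  out <- motif_features(bins, hits, "M1")
  expect_equal(out$motif_M1, c(12, 12))

  none <- motif_features(bins, hits[0, ], "M1")
  expect_equal(none$motif_M1, c(0, 0))

  # a hit spanning a bin boundary belongs to the bins containing its midpoint
  spanning <- tibble::tibble(motif_id = "M1", chrom = "chr1",
                             start = 190, end = 220, strand = "+",
                             score = 8, pvalue = 1e-4)  # midpoint 205
  out2 <- motif_features(bins, spanning, "M1")
  expect_equal(out2$motif_M1, c(0, 8))

  expect_error(motif_features(bins, hits, paste0("M", 1:8)), "7 motifs")
})

test_that("motif resolution prefers exact names then 3-letter prefixes", {
  catalog <- tibble::tibble(
    motif_id = c("MA0631.1", "MA0853.1", "MA0854.1", paste0("MA09", 10:19)),
    tf_name = c("SIX3", "ALX1", "ALX4", paste0("ZNF", 10:19)))
  expect_equal(resolve_motifs("SIX5", catalog), "MA0631.1")
  expect_equal(resolve_motifs("ALX4", catalog), "MA0854.1")
  expect_equal(resolve_motifs("EP300", catalog), character(0))
  expect_equal(resolve_motifs("ZNF143", catalog),
               sort(paste0("MA09", 10:19))[1:7])
})

test_that("labels require reproducible qualifying peaks and summit containment", {
  bins <- make_sliding_bins(toy_sizes(c(chr1 = 400)))
  two_reps <- dplyr::bind_rows(
    peak_row(start = 100, end = 200, qvalue = 5, summit_offset = 50,
             replicate = "rep1"),
    peak_row(start = 95, end = 205, qvalue = 5, summit_offset = 55,
             replicate = "rep2"))
  lab <- make_labels(bins, two_reps)
  # summit 150: bins [100,300) and [150,350) bound, [0,200) and [50,250) too;
  # [200,400) not (150 < 200)
  expect_equal(lab$bound[lab$start == 100], 1L)
  expect_equal(lab$bound[lab$start == 150], 1L)
  expect_equal(lab$bound[lab$start == 200], 0L)

  weak <- dplyr::mutate(two_reps, qValue = 3.9)
  expect_equal(sum(make_labels(bins, weak)$bound), 0)

  lone <- dplyr::bind_rows(
    peak_row(start = 100, end = 200, qvalue = 5, replicate = "rep1"),
    peak_row(start = 300, end = 390, qvalue = 3, replicate = "rep2",
             summit_offset = 45))
  expect_equal(sum(make_labels(bins, lone)$bound), 0)

  # a single-replicate experiment degrades the requirement to one replicate
  single <- peak_row(start = 100, end = 200, qvalue = 5, summit_offset = 50)
  expect_gt(sum(make_labels(bins, single)$bound), 0)
  expect_error(make_labels(bins, single[0, ]), "replicates")
})

test_that("labels are invariant to replicate order and duplication", {
  set.seed(15)
  bins <- make_sliding_bins(toy_sizes(c(chr1 = 5000)))
  starts <- sample(seq(0, 4700, by = 10), 12)
  pk <- dplyr::bind_rows(lapply(1:2, function(r) {
    peak_row(start = starts, end = starts + 200,
             qvalue = sample(c(3, 5), 12, replace = TRUE),
             summit_offset = 100, replicate = paste0("rep", r))
  }))
  l1 <- make_labels(bins, pk)
  l2 <- make_labels(bins, pk[rev(seq_len(nrow(pk))), ])
  dup <- dplyr::bind_rows(pk, dplyr::mutate(
    pk[pk$replicate == "rep1", ], replicate = "rep1"))
  l3 <- make_labels(bins, dup)
  expect_equal(l1$bound, l2$bound)
  expect_equal(l1$bound, l3$bound)

  # monotone in the FDR threshold: raising it never adds bound bins
  for (thr in c(3, 4, 5, 6)) {
    la <- make_labels(bins, pk, fdr_exponent = thr)
    lb <- make_labels(bins, pk, fdr_exponent = thr + 1)
    expect_true(all(lb$bound <= la$bound))
  }
})

test_that("binding frequency sums label columns", {
  bins <- make_sliding_bins(toy_sizes(c(chr1 = 1000)))
  set.seed(8)
  labs <- lapply(1:5, function(i) {
    l <- tibble::as_tibble(bins)
    l$bound <- sample(0:1, nrow(bins), replace = TRUE)
    l
  })
  bf <- binding_frequency(bins, labs)
  expect_equal(bf, as.integer(rowSums(sapply(labs, `[[`, "bound"))))
  expect_equal(binding_frequency(bins, labs[1]), labs[[1]]$bound)
  other <- make_sliding_bins(toy_sizes(c(chr1 = 900)))
  expect_error(binding_frequency(other, labs), "same bin set")
})

test_that("prevalence is the bound fraction", {
  expect_equal(prevalence(c(rep(1, 5), rep(0, 95))), 0.05)
  expect_equal(prevalence(rep(0, 10)), 0)
  expect_equal(prevalence(rep(1, 10)), 1)
  expect_error(prevalence(integer(0)), "empty")
})

test_that("training matrix keeps accessible-or-bound rows per cell type", {
  co <- generate_cohort(small_cohort_spec())
  bins <- make_sliding_bins(co$chrom_sizes)
  cts <- co$train_cell_types
  labels <- lapply(stats::setNames(cts, cts), function(ct)
    make_labels(bins, co$chip_peaks[co$chip_peaks$cell_type == ct, ]))
  accessible <- lapply(stats::setNames(cts, cts), function(ct)
    accessible_bins(bins, co$acc_peaks[co$acc_peaks$cell_type == ct, ]))
  bf <- binding_frequency(bins, labels)
  cons <- mean_conservation(bins, co$conservation)
  features <- lapply(stats::setNames(cts, cts), function(ct) {
    cell_feature_table(bins, expression_score = rep(0, nrow(bins)),
                       binding_frequency = bf,
                       accessibility = map_accessibility(
                         bins, co$acc_peaks[co$acc_peaks$cell_type == ct, ]),
                       conservation = cons)
  })
  tm <- assemble_training_matrix(features, labels, accessible)
  expect_equal(setdiff(names(tm), c("chrom", "start", "end", "cell_type", "bound")),
               c("expression_score", "binding_frequency", "accessibility",
                 "conservation"))  # p = 4 for a factor with no motif
  # every row satisfies the accessibility-or-binding predicate
  bound_any <- Reduce(`|`, lapply(labels, function(l) l$bound > 0))
  key <- paste(bins$chrom, bins$start)
  for (ct in cts) {
    rows <- tm[tm$cell_type == ct, ]
    idx <- match(paste(rows$chrom, rows$start), key)
    expect_true(all(accessible[[ct]][idx] | bound_any[idx]))
  }
  # per-cell-type row counts add up on concatenation
  expect_equal(nrow(tm),
               sum(vapply(cts, function(ct)
                 sum((accessible[[ct]] | bound_any)), numeric(1))))

  # blacklisting removes its bins from the training rows
  bl <- tibble::tibble(chrom = bins$chrom[1], start = bins$start[1],
                       end = bins$end[1])
  tm_bl <- assemble_training_matrix(features, labels, accessible,
                                    blacklist = bl)
  expect_false(any(tm_bl$chrom == bl$chrom & tm_bl$start < bl$end &
                     tm_bl$end > bl$start))
})

test_that("expression scores transfer from fixed to sliding bins", {
  bins200 <- make_sliding_bins(toy_sizes(c(chr1 = 300)))
  scores <- tibble::as_tibble(make_fixed_bins(toy_sizes(c(chr1 = 300))))
  scores$score <- c(0.2, 0.6, NA)
  out <- map_expression_score(bins200, scores)
  expect_equal(out, c(0.4, 0.4, 0.6))  # NA fixed bins drop out of the mean
})
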