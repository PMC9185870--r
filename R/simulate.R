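#' Specification of a synthetic cohort
#'
#' Defines the study conditions emulated by the synthetic generator: a small
#' multi-chromosome genome carrying regularly spaced candidate binding
#' sites, a cohort of cell types with matched ChIP-seq (replicated),
#' chromatin accessibility, conservation, motif and expression data, and a
#' planted linear-Gaussian link between the expression of designated signal
#' genes and the across-cell-type binding strength of their sites.
#'
#' @param n_cell_types Total cell types (default 13: 12 training plus one
#'   held-out, mirroring a 12-cell-type training cohort).
#' @param n_train Number of training cell types (default 12).
#' @param chrom_lengths Named vector of chromosome lengths in bp
#'   (default: four 400 kb chromosomes).
#' @param n_genes Number of genes (default 1000).
#' @param n_signal_genes Genes with a planted binding association
#'   (default 300).
#' @param planted_r Target |Pearson r| between a signal gene's expression
#'   and its site's binding strength (default 0.95).
#' @param bound_fraction Target prevalence of bound 200 bp bins per cell
#'   type (default 0.02; must be < 0.5).
#' @param replicates ChIP-seq replicates per cell type (default 2).
#' @param signal_site_boost Mean binding-strength offset of signal sites,
#'   controlling how often they exceed the binding threshold (default 0.8).
#' @param acc_enrichment Probability that a bound site carries an
#'   accessibility peak (default 0.85).
#' @param acc_background Accessibility probability at unbound sites
#'   (default 0.1).
#' @param n_acc_experiments Accessibility experiments per cell type
#'   (default 1).
#' @param motif_enrichment Probability that a site bound in any cell type
#'   carries a motif hit (default 0.5).
#' @param factor_name Name of the simulated chromatin factor (default
#'   `"TF1"`).
#' @param seed RNG seed; the cohort is fully reproducible from it.
#' @return A list of class `virchip_cohort_spec`.
#' @export
cohort_spec <- function(n_cell_types = 13, n_train = 12,
                        chrom_lengths = c(chr1 = 4e5, chr2 = 4e5,
                                          chr3 = 4e5, chr4 = 4e5),
                        n_genes = 1000, n_signal_genes = 300,
                        planted_r = 0.95, bound_fraction = 0.02,
                        replicates = 2, signal_site_boost = 0.8,
                        acc_enrichment = 0.85, acc_background = 0.1,
                        n_acc_experiments = 1, motif_enrichment = 0.5,
                        factor_name = "TF1", seed = 1) {
  if (bound_fraction <= 0 || bound_fraction >= 0.5) {
    abort("`bound_fraction` must be in (0, 0.5)")
  }
  if (planted_r <= 0 || planted_r >= 1) abort("`planted_r` must be in (0, 1)")
  if (n_signal_genes > n_genes) abort("`n_signal_genes` must be <= `n_genes`")
  if (n_train >= n_cell_types) abort("need at least one held-out cell type")
  if (is.null(names(chrom_lengths))) abort("`chrom_lengths` must be named")
  structure(as.list(environment()), class = "virchip_cohort_spec")
}

#' Generate a synthetic cohort
#'
#' Draws the full multi-assay cohort described by a [cohort_spec()]:
#' per-cell-type replicated ChIP-seq narrowPeak sets (replicates are
#' interval-jittered copies sharing summits), accessibility peaks enriched
#' at bound sites, a 100 bp-step conservation track elevated at sites,
#' motif hits enriched at bound sites, a genes x cell-types expression
#' table, and truth tables recording the planted (site, gene) pairs, the
#' latent binding-strength matrix and the bound-site indicator per cell
#' type. A cell type binds the sites whose strength exceeds its
#' `bound_fraction`-derived quantile.
#'
#' @param spec A [cohort_spec()].
#' @param dir Optional directory; when given the cohort is also written to
#'   disk via [write_cohort()].
#' @return A list of class `virchip_cohort` with elements `spec`,
#'   `chrom_sizes`, `cell_types`, `train_cell_types`, `heldout_cell_types`,
#'   `expression`, `chip_peaks`, `acc_peaks`, `conservation`, `motif_hits`,
#'   `motif_catalog` and `truth`.
#' @export
generate_cohort <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "virchip_cohort_spec"))
  set.seed(spec$seed)
  sizes <- tibble(chrom = names(spec$chrom_lengths),
                  length = as.double(spec$chrom_lengths))
  n_bins <- sum(pmax(0, floor((sizes$length - 200) / 50) + 1))
  n_bound <- round(spec$bound_fraction * n_bins / 4)
  if (n_bound < 2) abort("infeasible spec: fewer than 2 bound sites")
  n_sites <- 3 * n_bound
  margin <- 300
  capacity <- sum(pmax(0, floor((sizes$length - 2 * margin) / 500) + 1))
  if (n_sites > capacity) {
    abort("infeasible spec: more bound bins requested than the genome can hold")
  }
  # spread sites across chromosomes proportionally to length, >= 400 bp apart
  n_per_chrom <- round(n_sites * sizes$length / sum(sizes$length))
  n_per_chrom[1] <- n_per_chrom[1] + (n_sites - sum(n_per_chrom))
  sites <- purrr::map2(sizes$chrom, seq_len(nrow(sizes)), function(chrom, i) {
    k <- n_per_chrom[i]
    centers <- round(seq(margin, sizes$length[i] - margin, length.out = k)) +
      sample(-40:40, k, replace = TRUE)
    tibble(chrom = chrom, center = centers)
  }) |> dplyr::bind_rows()
  sites$site_id <- seq_len(nrow(sites))

  cts <- sprintf("ct%02d", seq_len(spec$n_cell_types))
  genes <- sprintf("gene%04d", seq_len(spec$n_genes))
  Z <- matrix(rnorm(spec$n_genes * spec$n_cell_types), nrow = spec$n_genes,
              dimnames = list(genes, cts))
  expression <- as_tibble(round(pmax(50 + 10 * Z, 0), 4))
  expression <- dplyr::bind_cols(tibble(gene_id = genes), expression)

  n_signal <- min(spec$n_signal_genes, n_sites)
  signal_sites <- sort(sample.int(n_sites, n_signal))
  sites$gene_id <- NA_character_
  sites$gene_id[signal_sites] <- genes[seq_len(n_signal)]

  r <- spec$planted_r
  strength <- matrix(rnorm(n_sites * spec$n_cell_types), nrow = n_sites,
                     dimnames = list(NULL, cts))
  strength[signal_sites, ] <- spec$signal_site_boost +
    r * Z[sites$gene_id[signal_sites], , drop = FALSE] +
    sqrt(1 - r^2) * strength[signal_sites, , drop = FALSE]

  bound <- apply(strength, 2, function(s) {
    rank(-s, ties.method = "first") <= n_bound
  })

  chip <- purrr::map(cts, function(ct) {
    b <- which(bound[, ct])
    purrr::map(seq_len(spec$replicates), function(rep_i) {
      jit1 <- sample(-10:10, length(b), replace = TRUE)
      jit2 <- sample(-10:10, length(b), replace = TRUE)
      start <- sites$center[b] - 100 + jit1
      end <- sites$center[b] + 100 + jit2
      tibble(cell_type = ct, replicate = paste0("rep", rep_i),
             chrom = sites$chrom[b], start = start, end = end,
             name = sprintf("%s_rep%d_site%d", ct, rep_i, b),
             score = as.integer(pmin(1000, round(
               100 * (5 + 2 * strength[b, ct])))),
             strand = ".",
             signalValue = round(pmax(0.1, 5 + 2 * strength[b, ct]), 3),
             pValue = round(6 + abs(rnorm(length(b))), 3),
             qValue = round(5 + abs(rnorm(length(b))), 3),
             peak = sites$center[b] - start,
             summit = as.double(sites$center[b]))
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()

  acc <- purrr::map(cts, function(ct) {
    purrr::map(seq_len(spec$n_acc_experiments), function(ex) {
      p_open <- ifelse(bound[, ct], spec$acc_enrichment, spec$acc_background)
      open <- which(runif(n_sites) < p_open)
      tibble(cell_type = ct, experiment = paste0("exp", ex),
             chrom = sites$chrom[open],
             start = sites$center[open] - 150,
             end = sites$center[open] + 150,
             name = sprintf("%s_acc%d_site%d", ct, ex, open),
             score = 0L, strand = ".",
             signalValue = round(pmax(0.1, 3 + rnorm(length(open))), 3),
             pValue = round(6 + abs(rnorm(length(open))), 3),
             qValue = round(5 + abs(rnorm(length(open))), 3),
             peak = 150,
             summit = as.double(sites$center[open]))
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()

  conservation <- purrr::map(seq_len(nrow(sizes)), function(i) {
    starts <- seq(0, sizes$length[i] - 100, by = 100)
    score <- runif(length(starts), 0.05, 0.30)
    on_chrom <- sites[sites$chrom == sizes$chrom[i], , drop = FALSE]
    for (ctr in on_chrom$center) {
      idx <- (floor((ctr - 100) / 100):floor((ctr + 99) / 100)) + 1
      idx <- idx[idx >= 1 & idx <= length(starts)]
      score[idx] <- 0.6 + runif(length(idx), 0, 0.3)
    }
    tibble(chrom = sizes$chrom[i], start = as.double(starts),
           end = as.double(starts + 100), score = round(score, 4))
  }) |> dplyr::bind_rows()

  catalog <- tibble(motif_id = "MA0001.1", tf_name = spec$factor_name)
  bound_any <- rowSums(bound) > 0
  with_motif <- which(bound_any & runif(n_sites) < spec$motif_enrichment)
  bg <- sites[sample.int(n_sites, round(0.2 * n_sites)), , drop = FALSE]
  motif_hits <- dplyr::bind_rows(
    tibble(motif_id = "MA0001.1", chrom = sites$chrom[with_motif],
           start = sites$center[with_motif] - 10,
           end = sites$center[with_motif] + 11,
           strand = "+", score = round(8 + 2 * rnorm(length(with_motif)), 3),
           pvalue = 1e-4),
    tibble(motif_id = "MA0001.1", chrom = bg$chrom,
           start = bg$center + 120, end = bg$center + 141,
           strand = "-", score = round(6 + rnorm(nrow(bg)), 3), pvalue = 9e-4)
  ) |> arrange(.data$chrom, .data$start)

  cohort <- structure(list(
    spec = spec, chrom_sizes = sizes, cell_types = cts,
    train_cell_types = cts[seq_len(spec$n_train)],
    heldout_cell_types = cts[-seq_len(spec$n_train)],
    expression = expression, chip_peaks = chip, acc_peaks = acc,
    conservation = conservation, motif_hits = motif_hits,
    motif_catalog = catalog,
    truth = list(sites = sites, strength = strength, bound = bound,
                 n_bound_sites = n_bound)
  ), class = "virchip_cohort")
  if (!is.null(dir)) write_cohort(cohort, dir)
  cohort
}

#' @export
print.virchip_cohort <- function(x, ...) {
  cat("<virchip_cohort> ", length(x$cell_types), " cell types (",
      length(x$train_cell_types), " training), ",
      nrow(x$truth$sites), " sites on ", nrow(x$chrom_sizes),
      " chromosomes, ", nrow(x$expression), " genes\n", sep = "")
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Serialises every assay in its native text format: chrom.sizes TSV,
#' expression TSV, per-cell-type-and-replicate ChIP narrowPeak files,
#' per-cell-type accessibility narrowPeak files, a bedGraph conservation
#' track, FIMO-style motif hits, the motif catalog and the truth tables.
#'
#' @param cohort A `virchip_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "chip"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "accessibility"), showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  readr::write_tsv(cohort$chrom_sizes, file.path(dir, "chrom.sizes"),
                   col_names = FALSE, progress = FALSE)
  jsonlite::write_json(
    list(spec = list(factor_name = cohort$spec$factor_name,
                     seed = cohort$spec$seed),
         cell_types = cohort$cell_types,
         train_cell_types = cohort$train_cell_types,
         heldout_cell_types = cohort$heldout_cell_types),
    file.path(dir, "cohort.json"), auto_unbox = TRUE)
  readr::write_tsv(cohort$expression, file.path(dir, "expression.tsv"),
                   progress = FALSE)
  for (ct in cohort$cell_types) {
    for (r in unique(cohort$chip_peaks$replicate)) {
      pk <- cohort$chip_peaks[cohort$chip_peaks$cell_type == ct &
                                cohort$chip_peaks$replicate == r, ]
      write_narrowpeak(pk, file.path(dir, "chip",
                                     sprintf("%s_%s.narrowPeak", ct, r)))
    }
    for (ex in unique(cohort$acc_peaks$experiment)) {
      pk <- cohort$acc_peaks[cohort$acc_peaks$cell_type == ct &
                               cohort$acc_peaks$experiment == ex, ]
      write_narrowpeak(pk, file.path(dir, "accessibility",
                                     sprintf("%s_%s.narrowPeak", ct, ex)))
    }
  }
  cons <- cohort$conservation
  cons$start <- format(cons$start, scientific = FALSE, trim = TRUE)
  cons$end <- format(cons$end, scientific = FALSE, trim = TRUE)
  readr::write_tsv(cons, file.path(dir, "conservation.bedGraph"),
                   col_names = FALSE, progress = FALSE)
  write_motif_hits(cohort$motif_hits, file.path(dir, "motifs.tsv"))
  readr::write_tsv(cohort$motif_catalog, file.path(dir, "motif_catalog.tsv"),
                   progress = FALSE)
  readr::write_tsv(cohort$truth$sites, file.path(dir, "truth", "sites.tsv"),
                   progress = FALSE)
  readr::write_tsv(as_tibble(as.data.frame(cohort$truth$strength)),
                   file.path(dir, "truth", "strength.tsv"), progress = FALSE)
  readr::write_tsv(as_tibble(as.data.frame(cohort$truth$bound)),
                   file.path(dir, "truth", "bound.tsv"), progress = FALSE)
  invisible(dir)
}
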