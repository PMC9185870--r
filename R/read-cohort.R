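#' Read a cohort directory from disk
#'
#' Reconstructs an in-memory cohort from the layout written by
#' [write_cohort()]: chrom.sizes, expression TSV, `chip/<ct>_<rep>.narrowPeak`,
#' `accessibility/<ct>_<exp>.narrowPeak`, a bedGraph conservation track,
#' FIMO-style motif hits and the motif catalog, plus the `cohort.json`
#' metadata (factor name, cell-type split). Truth tables, when present, are
#' reloaded as well. The result can be passed straight to
#' [run_cohort_pipeline()].
#'
#' @param dir Cohort directory.
#' @return A list of class `virchip_cohort`.
#' @export
read_cohort <- function(dir) {
  meta_path <- file.path(dir, "cohort.json")
  if (!file.exists(meta_path)) abort(paste0("no cohort.json in ", dir))
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  read_peak_dir <- function(sub, group_col) {
    files <- sort(list.files(file.path(dir, sub), pattern = "\\.narrowPeak$",
                             full.names = TRUE))
    purrr::map(files, function(f) {
      parts <- strsplit(sub("\\.narrowPeak$", "", basename(f)), "_")[[1]]
      pk <- read_narrowpeak(f)
      pk[[group_col]] <- paste(parts[-1], collapse = "_")
      pk$cell_type <- parts[1]
      pk
    }) |> dplyr::bind_rows()
  }
  truth <- NULL
  if (file.exists(file.path(dir, "truth", "sites.tsv"))) {
    truth <- list(
      sites = readr::read_tsv(file.path(dir, "truth", "sites.tsv"),
                              col_types = "cdic", progress = FALSE),
      strength = as.matrix(readr::read_tsv(file.path(dir, "truth", "strength.tsv"),
                                           col_types = readr::cols(),
                                           progress = FALSE)),
      bound = as.matrix(readr::read_tsv(file.path(dir, "truth", "bound.tsv"),
                                        col_types = readr::cols(),
                                        progress = FALSE))
    )
  }
  structure(list(
    spec = meta$spec,
    chrom_sizes = read_chrom_sizes(file.path(dir, "chrom.sizes")),
    cell_types = meta$cell_types,
    train_cell_types = meta$train_cell_types,
    heldout_cell_types = meta$heldout_cell_types,
    expression = read_expression(file.path(dir, "expression.tsv")),
    chip_peaks = read_peak_dir("chip", "replicate"),
    acc_peaks = read_peak_dir("accessibility", "experiment"),
    conservation = read_conservation(file.path(dir, "conservation.bedGraph")),
    motif_hits = read_motif_hits(file.path(dir, "motifs.tsv")),
    motif_catalog = readr::read_tsv(file.path(dir, "motif_catalog.tsv"),
                                    col_types = "cc", progress = FALSE),
    truth = truth
  ), class = "virchip_cohort")
}
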