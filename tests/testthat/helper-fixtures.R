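# Small fixtures shared across test files; everything is generated in code.

toy_sizes <- function(lengths = c(chrA = 1000)) {
  tibble::tibble(chrom = names(lengths), length = as.double(lengths))
}

# a compact cohort spec for module-level tests (the default spec is used for
# the end-to-end checks)
small_cohort_spec <- function(seed = 7, ...) {
  cohort_spec(
    n_cell_types = 8, n_train = 7,
    chrom_lengths = c(chr1 = 1e5, chr2 = 1e5),
    n_genes = 300, n_signal_genes = 80,
    bound_fraction = 0.03, seed = seed, ...
  )
}

# narrowPeak-style tibble builder
peak_row <- function(chrom = "chr1", start, end, signal = 1, qvalue = 5,
                     summit_offset = (end - start) %/% 2, cell_type = "ct1",
                     replicate = "rep1", experiment = "exp1") {
  tibble::tibble(
    cell_type = cell_type, replicate = replicate, experiment = experiment,
    chrom = chrom, start = start, end = end, name = "p", score = 0L,
    strand = ".", signalValue = signal, pValue = qvalue + 1, qValue = qvalue,
    peak = summit_offset,
    summit = ifelse(summit_offset >= 0, start + summit_offset, NA_real_)
  )
}
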