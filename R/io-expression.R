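#' Read a gene-expression table
#'
#' Tab-separated, first column gene identifiers, remaining columns one per
#' cell type, values non-negative expression (RPKM or TPM).
#'
#' @param path Path to the TSV (may be gzip-compressed).
#' @return A tibble whose first column is `gene_id` followed by one numeric
#'   column per cell type.
#' @export
read_expression <- function(path) {
  hdr <- names(readr::read_tsv(path, n_max = 0,
                               col_types = readr::cols(.default = "c"),
                               progress = FALSE))
  spec <- readr::cols(.default = "d")
  spec$cols[[hdr[1]]] <- readr::col_character()
  x <- suppressWarnings(readr::read_tsv(path, col_types = spec, progress = FALSE))
  prob <- readr::problems(x)
  if (nrow(prob) > 0) {
    abort(paste0("non-numeric expression value at line ", prob$row[1],
                 " of ", path))
  }
  names(x)[1] <- "gene_id"
  validate_expression(x)
  x
}

validate_expression <- function(expr) {
  if (names(expr)[1] != "gene_id") abort("first column must be `gene_id`")
  if (anyDuplicated(expr$gene_id)) {
    abort(paste0("duplicate gene id(s): ",
                 paste(unique(expr$gene_id[duplicated(expr$gene_id)]), collapse = ", ")))
  }
  vals <- as.matrix(expr[, -1, drop = FALSE])
  if (any(vals < 0, na.rm = TRUE)) abort("expression values must be >= 0")
  invisible(expr)
}

#' Restrict two expression tables to their shared genes
#'
#' @param a,b Expression tibbles (`gene_id` + cell-type columns).
#' @return A list with elements `a` and `b`, both restricted to the common
#'   gene ids, in the gene order of `a`.
#' @export
intersect_expression <- function(a, b) {
  validate_expression(a); validate_expression(b)
  shared <- intersect(a$gene_id, b$gene_id)
  list(
    a = a[match(shared, a$gene_id), , drop = FALSE],
    b = b[match(shared, b$gene_id), , drop = FALSE]
  )
}

expression_values <- function(expr, cell_types = NULL) {
  m <- as.matrix(expr[, -1, drop = FALSE])
  rownames(m) <- expr$gene_id
  if (!is.null(cell_types)) {
    missing <- setdiff(cell_types, colnames(m))
    if (length(missing) > 0) {
      abort(paste0("cell type(s) not in expression table: ",
                   paste(missing, collapse = ", ")))
    }
    m <- m[, cell_types, drop = FALSE]
  }
  m
}
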