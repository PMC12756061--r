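#' Construct a genes-by-cells expression matrix
#'
#' The central input container: a dense numeric matrix with genes as rows and
#' cells as columns, carrying unique gene and cell identifiers as dimnames.
#' Values may be raw counts or normalized expression; they must be finite and
#' non-negative.
#'
#' @param values Numeric matrix (genes x cells), or something coercible.
#' @param gene_ids Character vector of unique gene identifiers (defaults to
#'   `rownames(values)`).
#' @param cell_ids Character vector of unique cell identifiers (defaults to
#'   `colnames(values)`).
#' @return A matrix of class `"ExpressionMatrix"` with dimnames set.
#' @examples
#' m <- matrix(rpois(12, 5), nrow = 3,
#'             dimnames = list(paste0("G", 1:3), paste0("C", 1:4)))
#' expression_matrix(m)
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              cell_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids) || is.null(cell_ids)) {
    abort("gene_ids and cell_ids are required (set dimnames or pass them explicitly).")
  }
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (length(gene_ids) != nrow(values)) {
    abort(sprintf("gene_ids has length %d but the matrix has %d rows.",
                  length(gene_ids), nrow(values)))
  }
  if (length(cell_ids) != ncol(values)) {
    abort(sprintf("cell_ids has length %d but the matrix has %d columns.",
                  length(cell_ids), ncol(values)))
  }
  dup_g <- gene_ids[duplicated(gene_ids)]
  if (length(dup_g)) {
    abort(sprintf("Duplicate gene identifier(s): %s",
                  paste(unique(dup_g), collapse = ", ")))
  }
  dup_c <- cell_ids[duplicated(cell_ids)]
  if (length(dup_c)) {
    abort(sprintf("Duplicate cell identifier(s): %s",
                  paste(unique(dup_c), collapse = ", ")))
  }
  bad <- which(!is.finite(values) | values < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    abort(sprintf(
      "Expression values must be finite and >= 0; first offender at gene '%s', cell '%s' (value %s).",
      gene_ids[bad[1, 1]], cell_ids[bad[1, 2]],
      format(values[bad[1, 1], bad[1, 2]])))
  }
  if (nrow(values) < 2) abort("At least 2 genes are required.")
  if (ncol(values) < 2) abort("At least 2 cells are required.")
  dimnames(values) <- list(gene_ids, cell_ids)
  class(values) <- c("ExpressionMatrix", "matrix", "array")
  values
}

#' @method print ExpressionMatrix
#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("<ExpressionMatrix> %d genes x %d cells\n", nrow(x), ncol(x)))
  cat(sprintf("  genes: %s%s\n", paste(utils::head(rownames(x), 4), collapse = ", "),
              if (nrow(x) > 4) ", ..." else ""))
  cat(sprintf("  cells: %s%s\n", paste(utils::head(colnames(x), 4), collapse = ", "),
              if (ncol(x) > 4) ", ..." else ""))
  invisible(x)
}

# Parse a delimited table of expression values with identifier header row and
# identifier first column, reporting the location of non-numeric entries.
read_delim_matrix <- function(path, sep) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) abort(sprintf("'%s' has fewer than 2 data rows.", path))
  cells <- strsplit(lines, sep, fixed = TRUE)
  header <- cells[[1]]
  # header may or may not carry a leading (possibly empty) corner label
  body <- cells[-1]
  ncol_body <- length(body[[1]])
  col_ids <- if (length(header) == ncol_body) header[-1] else header
  row_ids <- vapply(body, `[[`, character(1), 1)
  vals <- matrix(NA_real_, nrow = length(body), ncol = ncol_body - 1)
  for (i in seq_along(body)) {
    row <- body[[i]]
    if (length(row) != ncol_body) {
      abort(sprintf("Ragged row %d in '%s' (%d fields, expected %d).",
                    i + 1L, path, length(row), ncol_body))
    }
    v <- suppressWarnings(as.numeric(row[-1]))
    if (anyNA(v)) {
      j <- which(is.na(v))[1]
      abort(sprintf("Non-numeric value '%s' at row '%s', column '%s' in '%s'.",
                    row[-1][j], row_ids[i], col_ids[j], path))
    }
    vals[i, ] <- v
  }
  list(values = vals, row_ids = row_ids, col_ids = col_ids)
}

#' Read an expression matrix from CSV, TSV or MatrixMarket files
#'
#' Dense CSV/TSV files carry cell (or gene) identifiers in the header row and
#' gene (or cell) identifiers in the first column. Sparse MatrixMarket files
#' (1-based triplets) need sidecar text files listing the row and column names,
#' one per line. Whatever the on-disk layout, the returned matrix is always
#' genes x cells.
#'
#' @param path File to read.
#' @param layout `"genes_by_cells"` (rows are genes, the default) or
#'   `"cells_by_genes"` (rows are cells; the matrix is transposed after
#'   reading).
#' @param format `"csv"`, `"tsv"` or `"mtx"`; `"auto"` (default) picks by file
#'   extension.
#' @param genes_file,cells_file Sidecar name files for `format = "mtx"`
#'   (defaults: `<path minus .mtx>_genes.txt` / `_cells.txt`; for
#'   `cells_by_genes` these name the columns / rows respectively as implied by
#'   the layout).
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path,
                            layout = c("genes_by_cells", "cells_by_genes"),
                            format = c("auto", "csv", "tsv", "mtx"),
                            genes_file = NULL, cells_file = NULL) {
  layout <- match.arg(layout)
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("File not found: '%s'", path))
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", tsv = "tsv", txt = "tsv", mtx = "mtx",
                     abort(sprintf("Cannot infer format from extension '.%s'; pass format=.", ext)))
  }
  if (format == "mtx") {
    stem <- sub("\\.mtx$", "", path)
    rows_file <- genes_file %||% paste0(stem, "_genes.txt")
    cols_file <- cells_file %||% paste0(stem, "_cells.txt")
    if (layout == "cells_by_genes") { tmp <- rows_file; rows_file <- cols_file; cols_file <- tmp }
    for (f in c(rows_file, cols_file)) {
      if (!file.exists(f)) abort(sprintf("MTX sidecar file not found: '%s'", f))
    }
    mm <- as.matrix(Matrix::readMM(path))
    row_ids <- readLines(rows_file)
    col_ids <- readLines(cols_file)
    row_ids <- row_ids[nzchar(row_ids)]
    col_ids <- col_ids[nzchar(col_ids)]
    if (length(row_ids) != nrow(mm) || length(col_ids) != ncol(mm)) {
      abort(sprintf("Sidecar name counts (%d, %d) do not match MTX dimensions (%d, %d).",
                    length(row_ids), length(col_ids), nrow(mm), ncol(mm)))
    }
    parsed <- list(values = mm, row_ids = row_ids, col_ids = col_ids)
  } else {
    parsed <- read_delim_matrix(path, if (format == "csv") "," else "\t")
  }
  vals <- parsed$values
  dimnames(vals) <- list(parsed$row_ids, parsed$col_ids)
  if (layout == "cells_by_genes") vals <- t(vals)
  expression_matrix(vals)
}

#' Library-size normalize and log-transform an expression matrix
#'
#' Scales each cell's column so its total matches the median column total
#' across cells, then applies `log(1 + x)`. This is the default preprocessing
#' before PCA or diffusion-map pseudotime, where raw count magnitudes distort
#' Euclidean geometry.
#'
#' @param expr An [expression_matrix()].
#' @param normalize If `FALSE`, the input is returned unchanged.
#' @return An [expression_matrix()] of the same shape.
#' @export
preprocess_expression <- function(expr, normalize = TRUE) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (!isTRUE(normalize)) return(expr)
  totals <- colSums(expr)
  zero <- which(totals == 0)
  if (length(zero)) {
    abort(sprintf("Cell(s) with all-zero expression cannot be normalized: %s",
                  paste(colnames(expr)[zero], collapse = ", ")))
  }
  scaled <- sweep(unclass(expr), 2, stats::median(totals) / totals, `*`)
  expression_matrix(log1p(scaled), rownames(expr), colnames(expr))
}
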