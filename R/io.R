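#' Read a directed edge list
#'
#' Reads a TSV whose first two columns are regulator and target gene symbols
#' (extra columns are ignored). A leading header line whose first two fields
#' are `regulator` and `target` is skipped. Self-loops are dropped with a
#' warning and duplicate pairs are collapsed.
#'
#' @param path File to read.
#' @return A tibble with columns `regulator`, `target`.
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: '%s'", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) abort(sprintf("Edge list '%s' is empty.", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 2)
  if (length(short)) {
    abort(sprintf("Line %d of '%s' has fewer than 2 tab-separated columns.",
                  short[1], path))
  }
  first2 <- tolower(c(fields[[1]][1], fields[[1]][2]))
  if (identical(first2, c("regulator", "target"))) fields <- fields[-1]
  if (!length(fields)) abort(sprintf("Edge list '%s' has a header but no edges.", path))
  edges <- tibble::tibble(
    regulator = vapply(fields, `[[`, character(1), 1),
    target    = vapply(fields, `[[`, character(1), 2)
  )
  loops <- edges$regulator == edges$target
  if (any(loops)) {
    warn(sprintf("Dropped %d self-loop(s) from '%s' (e.g. %s).",
                 sum(loops), path, edges$regulator[which(loops)[1]]))
    edges <- edges[!loops, , drop = FALSE]
  }
  dplyr::distinct(edges)
}

#' Write a signed network to TSV
#'
#' Emits a four-column TSV (`regulator`, `target`, `score`, `sign`) with
#' scores printed to 8 significant digits. Rows are ordered by target, then by
#' selection rank when present (falling back to descending score, then
#' regulator), so repeated runs produce byte-identical files.
#'
#' @param net A signed-network tibble as returned by [sign_network()] (an
#'   empty network yields a header-only file).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  stopifnot(is.data.frame(net))
  needed <- c("regulator", "target", "score", "sign")
  missing <- setdiff(needed, names(net))
  if (length(missing)) {
    abort(sprintf("Network is missing column(s): %s", paste(missing, collapse = ", ")))
  }
  if (nrow(net)) {
    ord <- if ("rank" %in% names(net)) {
      order(net$target, net$rank, method = "radix")
    } else {
      order(net$target, -net$score, net$regulator, method = "radix")
    }
    net <- net[ord, , drop = FALSE]
  }
  con <- tryCatch(file(path, open = "wb"), error = function(e) {
    abort(sprintf("Cannot open '%s' for writing: %s", path, conditionMessage(e)))
  })
  on.exit(close(con))
  writeLines("regulator\ttarget\tscore\tsign", con)
  if (nrow(net)) {
    writeLines(sprintf("%s\t%s\t%s\t%s", net$regulator, net$target,
                       sprintf("%.8g", net$score), as.character(net$sign)), con)
  }
  invisible(path)
}

#' Read a long-format edge score table
#'
#' Reads a headered TSV with columns `regulator`, `target`, `score` (extra
#' columns are ignored), as written by [write_edge_scores()] or by
#' `pseudogrn scores`.
#'
#' @param path File to read.
#' @return A tibble with columns `regulator`, `target`, `score`.
#' @export
read_edge_scores <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: '%s'", path))
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  needed <- c("regulator", "target", "score")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    abort(sprintf("'%s' is missing column(s): %s", path, paste(missing, collapse = ", ")))
  }
  df$score <- as.numeric(df$score)
  if (anyNA(df$score)) abort(sprintf("Non-numeric score value in '%s'.", path))
  tibble::as_tibble(df[needed])
}

#' Write a long-format edge score table
#'
#' @param scores A tibble with columns `regulator`, `target`, `score`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_edge_scores <- function(scores, path) {
  stopifnot(all(c("regulator", "target", "score") %in% names(scores)))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("regulator\ttarget\tscore", con)
  if (nrow(scores)) {
    writeLines(sprintf("%s\t%s\t%s", scores$regulator, scores$target,
                       sprintf("%.8g", scores$score)), con)
  }
  invisible(path)
}

#' Write an expression matrix to CSV or TSV
#'
#' Genes-by-cells layout with cell ids in the header row and gene ids in the
#' first column (corner label `gene`), the inverse of [read_expression()].
#'
#' @param expr An [expression_matrix()].
#' @param path Output file; extension `.csv` writes comma-separated, anything
#'   else tab-separated.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(c("gene", colnames(expr)), collapse = sep), con)
  body <- apply(unclass(expr), 1, function(r)
    paste(sprintf("%.10g", r), collapse = sep))
  writeLines(paste(rownames(expr), body, sep = sep), con)
  invisible(path)
}
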