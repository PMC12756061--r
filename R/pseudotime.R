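#' PCA pseudotime
#'
#' Orders cells by their coordinate on the first principal component of the
#' gene-centered expression matrix. The axis is oriented so the root cell sits
#' at the low end, then shifted so the minimum is 0; when no root is given, the
#' cell with the smallest first-component coordinate (under a fixed sign
#' convention) becomes the root. Orientation matters downstream because the
#' time lag is directional.
#'
#' @param expr An [expression_matrix()], typically preprocessed with
#'   [preprocess_expression()].
#' @param root_cell Optional cell id anchoring the origin of the trajectory.
#' @return A tibble with columns `cell`, `pseudotime` (root at 0), in the
#'   input cell order.
#' @export
pca_pseudotime <- function(expr, root_cell = NULL) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  X <- unclass(expr)
  Xc <- X - rowMeans(X)
  if (max(abs(Xc)) < 1e-12) {
    abort("Expression matrix has zero variance; PCA pseudotime is undefined.")
  }
  sv <- svd(Xc, nu = 0, nv = 1)
  coord <- sv$d[1] * sv$v[, 1]
  # deterministic sign: the largest-magnitude coordinate is positive
  j <- which.max(abs(coord))
  if (coord[j] < 0) coord <- -coord
  cells <- colnames(expr)
  if (is.null(root_cell)) {
    root <- which.min(coord)
  } else {
    root <- match(root_cell, cells)
    if (is.na(root)) abort(sprintf("Root cell '%s' not found.", root_cell))
    # flip so the root lies on the low end of the axis
    if (coord[root] - min(coord) > max(coord) - coord[root]) coord <- -coord
    if (which.min(coord) != root) {
      warn(sprintf("Root cell '%s' is not at the trajectory extreme; pseudotime 0 is the extreme cell.",
                   root_cell))
    }
  }
  tibble::tibble(cell = cells, pseudotime = coord - min(coord))
}

#' Diffusion-map pseudotime
#'
#' Embeds cells with a diffusion map built from a Gaussian kernel on the
#' k-nearest-neighbor graph (per-cell adaptive bandwidth equal to the distance
#' to the k-th neighbor), then returns each cell's Euclidean distance from the
#' root cell in the eigenvalue-scaled embedding. Distance from the root is the
#' pseudotime, so the root is always at 0.
#'
#' @inheritParams pca_pseudotime
#' @param n_neighbors Neighborhood size for the kNN graph (must be < number of
#'   cells).
#' @param n_comps Number of non-trivial diffusion components kept.
#' @return A tibble with columns `cell`, `pseudotime`, in the input cell order.
#' @export
diffusion_pseudotime <- function(expr, root_cell = NULL, n_neighbors = 15,
                                 n_comps = 10) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  n <- ncol(expr)
  if (n_neighbors >= n) {
    abort(sprintf("n_neighbors (%d) must be smaller than the number of cells (%d).",
                  n_neighbors, n))
  }
  n_comps <- min(n_comps, n - 1L)
  Dm <- as.matrix(dist(t(unclass(expr))))
  # adaptive bandwidth: distance to the k-th nearest neighbor (excluding self)
  sigma <- apply(Dm, 1, function(d) sort(d)[n_neighbors + 1L])
  if (all(sigma == 0)) abort("All cells are identical; diffusion map is undefined.")
  pos <- Dm[Dm > 0]
  if (any(sigma == 0)) sigma[sigma == 0] <- min(pos)
  # mutual/union kNN mask keeps the kernel sparse in spirit
  nn_mask <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    nn <- order(Dm[i, ], method = "radix")[seq_len(n_neighbors + 1L)]
    nn_mask[i, nn] <- TRUE
  }
  nn_mask <- nn_mask | t(nn_mask)
  A <- exp(-Dm^2 / outer(sigma, sigma))
  A[!nn_mask] <- 0
  diag(A) <- 1
  comp <- graph_components(A > 0)
  if (max(comp) > 1L) {
    abort(sprintf("kNN graph is disconnected (%d components); increase n_neighbors.",
                  max(comp)))
  }
  d <- rowSums(A)
  M <- A / sqrt(outer(d, d))
  eig <- eigen(M, symmetric = TRUE)
  keep <- seq(2L, n_comps + 1L)
  psi <- eig$vectors[, keep, drop = FALSE] / sqrt(d)
  # eigenvalue scaling lambda/(1 - lambda): the accumulated weight of the
  # component over all diffusion scales, which keeps the leading (slowest)
  # component dominant so distances from the root follow the trajectory
  lam_ev <- pmin(eig$values[keep], 1 - 1e-12)
  emb <- sweep(psi, 2, lam_ev / (1 - lam_ev), `*`)
  cells <- colnames(expr)
  if (is.null(root_cell)) {
    c1 <- emb[, 1]
    if (c1[which.max(abs(c1))] < 0) c1 <- -c1
    root <- which.min(c1)
  } else {
    root <- match(root_cell, cells)
    if (is.na(root)) abort(sprintf("Root cell '%s' not found.", root_cell))
  }
  pt <- sqrt(colSums((t(emb) - emb[root, ])^2))
  tibble::tibble(cell = cells, pseudotime = pt)
}

# connected components of an undirected adjacency (logical matrix), by BFS
graph_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Load a precomputed pseudotime table
#'
#' Imports per-cell pseudotime computed elsewhere (e.g. a Slingshot, PHATE or
#' PAGA run reduced to a single lineage). The file is a headered two-column
#' TSV (`cell`, `pseudotime`); rows may be in any order but must cover every
#' cell of the expression matrix exactly once.
#'
#' @param path File to read.
#' @param expr The [expression_matrix()] the pseudotime belongs to.
#' @return A tibble with columns `cell`, `pseudotime` aligned to `expr`'s cell
#'   order.
#' @export
read_pseudotime <- function(path, expr) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (!file.exists(path)) abort(sprintf("File not found: '%s'", path))
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2) abort(sprintf("'%s' must have two columns (cell, pseudotime).", path))
  cell <- as.character(df[[1]])
  val <- suppressWarnings(as.numeric(df[[2]]))
  if (anyNA(val)) {
    abort(sprintf("Non-numeric pseudotime for cell '%s' in '%s'.",
                  cell[which(is.na(val))[1]], path))
  }
  dup <- cell[duplicated(cell)]
  if (length(dup)) {
    abort(sprintf("Duplicate cell id(s) in '%s': %s", path,
                  paste(unique(dup), collapse = ", ")))
  }
  idx <- match(colnames(expr), cell)
  if (anyNA(idx)) {
    abort(sprintf("Pseudotime missing for cell(s): %s",
                  paste(colnames(expr)[is.na(idx)], collapse = ", ")))
  }
  tibble::tibble(cell = colnames(expr), pseudotime = val[idx])
}

#' Sort cells by pseudotime and smooth with a sliding window
#'
#' Cells are ordered by ascending pseudotime (ties broken lexicographically by
#' cell id for determinism) and expression is averaged over windows of `width`
#' consecutive cells advanced by `step`. The windows are the method's "time
#' points": with n cells, `floor((n - width)/step) + 1` full windows are kept
#' and any partial window at the end is dropped so every profile value averages
#' the same number of cells.
#'
#' @param expr An [expression_matrix()].
#' @param pseudotime A tibble with columns `cell`, `pseudotime` covering every
#'   cell of `expr` (as returned by the pseudotime backends).
#' @param width Window width in cells (default 5).
#' @param step Window step in cells (default 1).
#' @return A `"smoothed_trajectory"`: list with `values` (genes x windows
#'   matrix), `window_centers` (mean pseudotime per window, non-decreasing),
#'   `width`, `step`.
#' @export
order_and_smooth <- function(expr, pseudotime, width = 5L, step = 1L) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  n <- ncol(expr)
  width <- as.integer(width); step <- as.integer(step)
  if (width < 1L || step < 1L) abort("width and step must be positive integers.")
  if (width > n) abort(sprintf("Window width (%d) exceeds the number of cells (%d).", width, n))
  if (is.data.frame(pseudotime)) {
    idx <- match(colnames(expr), pseudotime[[1]])
    if (anyNA(idx)) {
      abort(sprintf("Pseudotime missing for cell(s): %s",
                    paste(colnames(expr)[is.na(idx)], collapse = ", ")))
    }
    pt <- as.numeric(pseudotime[[2]])[idx]
  } else {
    if (length(pseudotime) != n) abort("Pseudotime length must equal the number of cells.")
    pt <- as.numeric(pseudotime)
  }
  if (any(!is.finite(pt))) abort("Pseudotime values must all be finite.")
  ord <- order(pt, colnames(expr), method = "radix")
  sorted <- unclass(expr)[, ord, drop = FALSE]
  pt_sorted <- pt[ord]
  n_windows <- (n - width) %/% step + 1L
  starts <- (seq_len(n_windows) - 1L) * step + 1L
  vals <- matrix(0, nrow = nrow(expr), ncol = n_windows,
                 dimnames = list(rownames(expr), NULL))
  centers <- numeric(n_windows)
  for (j in seq_len(n_windows)) {
    cols <- starts[j]:(starts[j] + width - 1L)
    vals[, j] <- rowMeans(sorted[, cols, drop = FALSE])
    centers[j] <- mean(pt_sorted[cols])
  }
  structure(list(values = vals, window_centers = centers,
                 width = width, step = step),
            class = "smoothed_trajectory")
}

#' @method print smoothed_trajectory
#' @export
print.smoothed_trajectory <- function(x, ...) {
  cat(sprintf("<smoothed_trajectory> %d genes x %d windows (width %d, step %d)\n",
              nrow(x$values), ncol(x$values), x$width, x$step))
  invisible(x)
}

#' Tidy a smoothed trajectory into long format
#'
#' @param x A `"smoothed_trajectory"`.
#' @param ... Unused.
#' @return A tibble with columns `gene`, `window`, `window_center`, `value`.
#' @export
tidy.smoothed_trajectory <- function(x, ...) {
  tibble::tibble(
    gene = rep(rownames(x$values), times = ncol(x$values)),
    window = rep(seq_len(ncol(x$values)), each = nrow(x$values)),
    window_center = rep(x$window_centers, each = nrow(x$values)),
    value = as.vector(x$values)
  )
}
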