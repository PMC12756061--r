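test_that("preprocessing scales cells to the median total then log-transforms", {
  # hand-computed 2x2 case: column totals 100 and 200, median 150
  expr <- expression_matrix(matrix(c(40, 60, 80, 120), 2, 2,
                                   dimnames = list(c("GA", "GB"), c("C1", "C2"))))
  out <- preprocess_expression(expr)
  expect_equal(unclass(out),
               matrix(log1p(c(40 * 1.5, 60 * 1.5, 80 * 0.75, 120 * 0.75)), 2, 2,
                      dimnames = dimnames(expr)),
               tolerance = 1e-12)

  # equal totals: scaling is the identity, only log1p applies
  eq <- expression_matrix(matrix(c(1, 3, 2, 2), 2, 2,
                                 dimnames = list(c("GA", "GB"), c("C1", "C2"))))
  expect_equal(unclass(preprocess_expression(eq)), log1p(unclass(eq)))

  # disabled: identity
  expect_identical(preprocess_expression(expr, normalize = FALSE), expr)

  zero <- expression_matrix(matrix(c(1, 1, 0, 0), 2, 2,
                                   dimnames = list(c("GA", "GB"), c("C1", "Cz"))))
  expect_error(preprocess_expression(zero), "Cz")
})

test_that("PCA pseudotime recovers exact 1-D structure and honors the root", {
  lin <- linear_trajectory_expr(20)
  pt <- pca_pseudotime(lin$expr)
  # equally spaced cells on a line stay equally spaced in pseudotime
  spacing <- diff(sort(pt$pseudotime))
  expect_equal(spacing, rep(spacing[1], length(spacing)), tolerance = 1e-8)
  expect_equal(abs(cor(pt$pseudotime, lin$truth, method = "spearman")), 1)

  # root at one extreme: it gets 0 and the opposite extreme gets the max
  root <- pt$cell[which.max(pt$pseudotime)]
  flipped <- pca_pseudotime(lin$expr, root_cell = root)
  expect_equal(flipped$pseudotime[flipped$cell == root], 0)
  expect_equal(which.max(flipped$pseudotime), which.min(pt$pseudotime))

  const <- expression_matrix(matrix(1, 3, 6,
                                    dimnames = list(paste0("G", 1:3),
                                                    paste0("C", 1:6))))
  expect_error(pca_pseudotime(const), "zero variance")
})

test_that("PCA pseudotime matches the closed-form 2x2 eigenprojection", {
  vals <- matrix(c(1, 5, 2, 4, 4, 2, 6, 1, 3, 3, 5, 2), nrow = 2,
                 dimnames = list(c("GA", "GB"), sprintf("C%d", 1:6)))
  expr <- expression_matrix(vals)
  pt <- pca_pseudotime(expr)
  # independent route: leading eigenvector of the 2x2 gene covariance
  xc <- vals - rowMeans(vals)
  ev <- eigen(tcrossprod(xc))$vectors[, 1]
  proj <- as.vector(ev %*% xc)
  expect_equal(cor(pt$pseudotime, proj * sign(cor(proj, pt$pseudotime))), 1,
               tolerance = 1e-12)
})

test_that("diffusion pseudotime is 0 at the root and orders a 1-D chain", {
  set.seed(5)
  n <- 30
  t_true <- seq_len(n)
  vals <- rbind(0.5 * t_true, 10 - 0.3 * t_true, sin(t_true / 7) + 2)
  dimnames(vals) <- list(paste0("G", 1:3), sprintf("C%02d", seq_len(n)))
  expr <- expression_matrix(vals)
  pt <- diffusion_pseudotime(expr, root_cell = "C01", n_neighbors = 5)
  expect_equal(pt$pseudotime[pt$cell == "C01"], 0)
  expect_gte(abs(cor(pt$pseudotime, t_true, method = "spearman")), 0.95)

  # an exact duplicate of the root also lands at pseudotime 0
  dup <- expression_matrix(cbind(vals, dup = vals[, 1]),
                           cell_ids = c(colnames(vals), "Cdup"))
  pt2 <- diffusion_pseudotime(dup, root_cell = "C01", n_neighbors = 5)
  expect_equal(pt2$pseudotime[pt2$cell == "Cdup"], 0, tolerance = 1e-8)

  expect_error(diffusion_pseudotime(expr, n_neighbors = 30), "smaller")
})

test_that("precomputed pseudotime aligns to the matrix and validates input", {
  expr <- random_expr(3, 5, seed = 2)
  f <- withr::local_tempfile(fileext = ".tsv")
  shuffled <- rev(colnames(expr))
  writeLines(c("cell\tpseudotime",
               sprintf("%s\t%g", shuffled, seq_along(shuffled))), f)
  pt <- read_pseudotime(f, expr)
  expect_equal(pt$cell, colnames(expr))
  expect_equal(pt$pseudotime, rev(seq_len(5)))

  writeLines(c("cell\tpseudotime",
               sprintf("%s\t%g", colnames(expr)[-3], 1:4)), f)
  expect_error(read_pseudotime(f, expr), colnames(expr)[3])

  writeLines(c("cell\tpseudotime", "C001\t1", "C001\t2"), f)
  expect_error(read_pseudotime(f, expr), "Duplicate")

  writeLines(c("cell\tpseudotime",
               sprintf("%s\t%s", colnames(expr), c("1", "x", "3", "4", "5"))), f)
  expect_error(read_pseudotime(f, expr), "Non-numeric")

  # ties are accepted; downstream ordering breaks them
  writeLines(c("cell\tpseudotime",
               sprintf("%s\t%g", colnames(expr), c(1, 1, 1, 2, 2))), f)
  expect_equal(nrow(read_pseudotime(f, expr)), 5L)
})

test_that("sliding windows obey the count formula and average member cells", {
  set.seed(9)
  for (case in list(c(120, 5, 1), c(30, 7, 3), c(10, 10, 1), c(25, 4, 5))) {
    n <- case[1]; w <- case[2]; s <- case[3]
    expr <- random_expr(3, n, seed = n)
    pt <- tibble::tibble(cell = colnames(expr), pseudotime = runif(n))
    traj <- order_and_smooth(expr, pt, width = w, step = s)
    expect_equal(ncol(traj$values), (n - w) %/% s + 1L)
    expect_true(all(diff(traj$window_centers) >= -1e-12))
    # spot-check one window against a direct mean
    ord <- order(pt$pseudotime, pt$cell, method = "radix")
    expect_equal(traj$values[, 1], rowMeans(unclass(expr)[, ord[seq_len(w)]]))
  }
  # n = 120, width 5, step 1 gives 116 windows
  expr <- random_expr(2, 120, seed = 1)
  pt <- tibble::tibble(cell = colnames(expr), pseudotime = seq_len(120))
  expect_equal(ncol(order_and_smooth(expr, pt, 5, 1)$values), 116L)
  expect_error(order_and_smooth(expr, pt, width = 121), "exceeds")
})

test_that("degenerate windows behave: constant genes, width 1, tie-breaking", {
  expr <- expression_matrix(rbind(GA = rep(2.5, 8), GB = 1:8),
                            cell_ids = sprintf("C%d", 1:8))
  pt <- tibble::tibble(cell = colnames(expr), pseudotime = 8:1)
  traj <- order_and_smooth(expr, pt, width = 3)
  expect_equal(unname(traj$values["GA", ]), rep(2.5, 6))

  # width 1, step 1: smoothing is the identity on the sorted matrix
  traj1 <- order_and_smooth(expr, pt, width = 1)
  expect_equal(unname(traj1$values["GB", ]), 8:1)

  # all-tied pseudotime: cells fall back to lexicographic id order
  tie <- tibble::tibble(cell = colnames(expr), pseudotime = rep(0, 8))
  trajt <- order_and_smooth(expr, tie, width = 1)
  expect_equal(unname(trajt$values["GB", ]), 1:8)
})

test_that("smoothing is invariant to monotone relabeling of pseudotime", {
  expr <- random_expr(4, 25, seed = 3)
  set.seed(31)
  pt <- tibble::tibble(cell = colnames(expr), pseudotime = rnorm(25))
  base <- order_and_smooth(expr, pt, 5, 2)
  for (f in list(function(x) exp(x), function(x) rank(x),
                 function(x) 100 + 3 * x)) {
    tr <- order_and_smooth(expr,
                           dplyr::mutate(pt, pseudotime = f(.data$pseudotime)),
                           5, 2)
    expect_equal(tr$values, base$values, tolerance = 1e-12)
  }
})

test_that("planted linear order is recovered by both native backends", {
  lin <- linear_trajectory_expr(100)
  rho_pca <- cor(pca_pseudotime(lin$expr)$pseudotime, lin$truth,
                 method = "spearman")
  expect_gte(abs(rho_pca), 0.99)
  rho_dm <- cor(diffusion_pseudotime(lin$expr)$pseudotime, lin$truth,
                method = "spearman")
  expect_gte(abs(rho_dm), 0.9)
})
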