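# Independent oracles and small fixture builders shared across tests.
# The oracles deliberately re-derive results from first principles (direct
# summation, explicit loops) rather than calling package internals.

# f-divergence by direct summation of q * f(p/q) with the textbook f(u).
oracle_f_core <- function(p, q, fam) {
  f <- switch(fam,
    f_kl    = function(u) u * log(u),
    pearson = function(u) (u - 1)^2,
    neyman  = function(u) (1 - u)^2 / u)
  sum(q * f(p / q))
}

oracle_divergence <- function(p, q, family) {
  switch(family,
    f_kl      = oracle_f_core(p, q, "f_kl"),
    pearson   = oracle_f_core(p, q, "pearson"),
    neyman    = oracle_f_core(p, q, "neyman"),
    s_kl      = (oracle_f_core(p, q, "f_kl") + oracle_f_core(q, p, "f_kl")) / 2,
    s_pearson = (oracle_f_core(p, q, "pearson") + oracle_f_core(q, p, "pearson")) / 2,
    js        = {
      m <- (p + q) / 2
      (oracle_f_core(p, m, "f_kl") + oracle_f_core(q, m, "f_kl")) / 2
    })
}

random_discrete_pair <- function(n_bins) {
  p <- rgamma(n_bins, shape = 1) + 0.05
  q <- rgamma(n_bins, shape = 1) + 0.05
  structure(list(edges = seq(0, 1, length.out = n_bins + 1L),
                 p = p / sum(p), q = q / sum(q)),
            class = "discrete_pair")
}

# Step-by-step reimplementation of the penalized greedy selection, explicit
# loops, first-hit-in-sorted-order tie breaking.
oracle_greedy <- function(D, target, candidates, lam) {
  cands <- sort(setdiff(candidates, target))
  sel <- character(0)
  dst <- numeric(0)
  while (length(sel) < length(cands)) {
    rem <- setdiff(cands, sel)
    best <- NA_character_
    best_v <- -Inf
    for (x in rem) {
      v <- D[x, target]
      if (length(sel)) {
        pen <- 0
        for (y in sel) pen <- pen + D[x, y]
        v <- v - lam * pen / length(sel)
      }
      if (v > best_v) {
        best <- x
        best_v <- v
      }
    }
    sel <- c(sel, best)
    dst <- c(dst, best_v)
  }
  list(regulator = sel, adjusted_score = dst)
}

# Wrap a plain genes x windows matrix as a smoothed trajectory.
make_traj <- function(values, width = 5L, step = 1L) {
  structure(list(values = values,
                 window_centers = seq_len(ncol(values)),
                 width = width, step = step),
            class = "smoothed_trajectory")
}

random_traj <- function(n_genes, n_windows, seed = 1L) {
  set.seed(seed)
  vals <- matrix(abs(rnorm(n_genes * n_windows)), n_genes, n_windows,
                 dimnames = list(sprintf("G%02d", seq_len(n_genes)), NULL))
  make_traj(vals)
}

random_expr <- function(m = 5L, n = 20L, seed = 1L) {
  set.seed(seed)
  expression_matrix(matrix(abs(rnorm(m * n)), m, n,
                           dimnames = list(sprintf("G%02d", seq_len(m)),
                                           sprintf("C%03d", seq_len(n)))))
}

# Cells spaced along a noiseless line in gene space: expression of gene g for
# cell i is a_g + b_g * t_i, so the data are exactly one-dimensional.
linear_trajectory_expr <- function(n_cells = 100L, seed = 42L) {
  set.seed(seed)
  t_true <- seq(0, 1, length.out = n_cells)
  perm <- sample.int(n_cells)         # hide the ordering in the cell labels
  vals <- rbind(1 + 2 * t_true[perm], 3 - 1 * t_true[perm])
  dimnames(vals) <- list(c("GA", "GB"), sprintf("C%03d", seq_len(n_cells)))
  list(expr = expression_matrix(vals), truth = t_true[perm])
}

expect_tibble_cols <- function(x, cols) {
  expect_s3_class(x, "tbl_df")
  expect_true(all(cols %in% names(x)))
}

cli_path <- function() system.file("exec", "pseudogrn", package = "pseudogrn")

run_cli <- function(...) {
  args <- c(...)
  out <- suppressWarnings(system2("Rscript", c(cli_path(), args),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status") %||% 0L
  list(status = status, output = out)
}
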