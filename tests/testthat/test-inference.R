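test_that("greedy selection reproduces the hand-traced penalized recurrence", {
  genes <- c("A", "B", "C", "Z")
  D <- matrix(0, 3, 4, dimnames = list(c("A", "B", "C"), genes))
  D["A", "Z"] <- 0.9; D["B", "Z"] <- 0.8; D["C", "Z"] <- 0.5
  D["B", "A"] <- 0.6; D["C", "A"] <- 0.1; D["C", "B"] <- 0.1
  D["B", "C"] <- 0.1   # redundancy between B and C is symmetric here
  sel <- greedy_select(D, "Z", c("A", "B", "C"), lam = 1)
  expect_equal(sel$regulator, c("A", "C", "B"))
  expect_equal(sel$adjusted_score, c(0.9, 0.4, 0.45), tolerance = 1e-12)
  expect_equal(sel$rank, 1:3)
})

test_that("lambda = 0 reduces to a plain descending sort with raw scores", {
  set.seed(77)
  genes <- sprintf("G%02d", 1:7)
  D <- matrix(runif(49), 7, 7, dimnames = list(genes, genes))
  sel <- greedy_select(D, "G07", genes, lam = 0)
  ord <- order(-D[setdiff(genes, "G07"), "G07"],
               setdiff(genes, "G07"), method = "radix")
  expect_equal(sel$regulator, setdiff(genes, "G07")[ord])
  expect_equal(sel$adjusted_score,
               unname(D[sel$regulator, "G07"]), tolerance = 1e-15)
})

test_that("greedy selection matches a brute-force reimplementation exactly", {
  set.seed(314)
  for (i in seq_len(100)) {
    genes <- c(sprintf("R%02d", 1:6), "TGT")
    D <- matrix(runif(49), 7, 7, dimnames = list(genes, genes))
    if (i %% 3 == 0) D <- round(D, 1)      # force plenty of exact ties
    lam <- sample(c(0, 0.5, 1.5, 5), 1)
    got <- greedy_select(D, "TGT", genes, lam = lam)
    want <- oracle_greedy(D, "TGT", genes, lam)
    expect_identical(got$regulator, want$regulator)
    expect_equal(got$adjusted_score, want$adjusted_score, tolerance = 1e-12)
  }
})

test_that("edge cases: target removed from candidates, empty candidate set", {
  genes <- c("A", "B")
  D <- matrix(c(0, 0.2, 0.3, 0), 2, 2, dimnames = list(genes, genes))
  sel <- greedy_select(D, "A", c("A", "B"), lam = 1)
  expect_equal(sel$regulator, "B")
  expect_warning(empty <- greedy_select(D, "A", "A", lam = 1), "candidate")
  expect_equal(nrow(empty), 0L)
})

test_that("recorded scores shrink monotonically in lambda at fixed order", {
  set.seed(99)
  genes <- sprintf("G%02d", 1:8)
  D <- matrix(runif(64, 0.01, 1), 8, 8, dimnames = list(genes, genes))
  target <- "G08"
  lams <- c(0, 0.5, 1.5, 5, 20)
  base <- greedy_select(D, target, genes, lam = 1.5)
  fixed_order <- base$regulator
  dstar_at <- function(lam) {
    vapply(seq_along(fixed_order), function(i) {
      x <- fixed_order[i]
      if (i == 1) return(unname(D[x, target]))
      sel <- fixed_order[seq_len(i - 1)]
      unname(D[x, target] - lam * sum(D[x, sel]) / length(sel))
    }, numeric(1))
  }
  prev <- dstar_at(lams[1])
  for (lam in lams[-1]) {
    cur <- dstar_at(lam)
    expect_true(all(cur <= prev + 1e-12))
    prev <- cur
  }
  # edge count under the fixed order is therefore non-increasing
  counts <- vapply(lams, function(l) sum(dstar_at(l) > 0), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("the top-ranked regulator survives every lambda when its score > 0", {
  set.seed(4)
  genes <- sprintf("G%02d", 1:6)
  D <- matrix(runif(36, 0.01, 1), 6, 6, dimnames = list(genes, genes))
  for (lam in c(0, 1.5, 10, 1e6)) {
    sel <- select_regulators(D, lam = lam)
    edges <- threshold_edges(sel)
    rank1 <- dplyr::filter(sel, .data$rank == 1, .data$adjusted_score > 0)
    expect_true(all(paste(rank1$regulator, rank1$target) %in%
                      paste(edges$regulator, edges$target)))
  }
})

test_that("thresholding keeps strictly positive recorded scores only", {
  sel <- tibble::tibble(target = "Z", regulator = c("A", "B", "C", "D"),
                        rank = 1:4, adjusted_score = c(3, 0.1, -0.2, 0),
                        lam = 1.5)
  edges <- threshold_edges(sel)
  expect_equal(nrow(edges), 2L)
  expect_setequal(edges$regulator, c("A", "B"))
})

test_that("partial correlation handles perfect dependence and conditioning", {
  vals <- matrix(0, 3, 21, dimnames = list(c("X", "Z", "C"), NULL))
  x <- sin(seq_len(20))
  vals["X", 1:20] <- x
  vals["Z", 2:21] <- 2 * x
  traj <- make_traj(vals)
  expect_equal(partial_correlation(traj, "X", "Z"), 1, tolerance = 1e-12)
  vals["Z", 2:21] <- -x + 0.5
  expect_equal(partial_correlation(make_traj(vals), "X", "Z"), -1,
               tolerance = 1e-12)
})

test_that("partial correlation matches the first-order closed form", {
  # build samples with exact correlations r_xz = 0.6, r_xc = r_zc = 0.5
  set.seed(11)
  n <- 60
  basis <- qr.Q(qr(cbind(1, matrix(rnorm(n * 3), n, 3))))[, 2:4] * sqrt(n - 1)
  u1 <- basis[, 1]; u2 <- basis[, 2]; u3 <- basis[, 3]
  cvec <- u1
  xvec <- 0.5 * u1 + sqrt(0.75) * u2
  r <- (0.6 - 0.25) / sqrt(0.75)
  zvec <- 0.5 * u1 + r * u2 + sqrt(1 - 0.25 - r^2) * u3
  expect_equal(cor(xvec, zvec), 0.6, tolerance = 1e-10)
  expect_equal(cor(xvec, cvec), 0.5, tolerance = 1e-10)

  vals <- matrix(0, 3, n + 1, dimnames = list(c("X", "Z", "C"), NULL))
  vals["X", 1:n] <- xvec
  vals["C", 1:n] <- cvec
  vals["Z", 2:(n + 1)] <- zvec
  got <- partial_correlation(make_traj(vals), "X", "Z", conditioning = "C")
  expect_equal(got, (0.6 - 0.25) / 0.75, tolerance = 1e-10)
})

test_that("short samples fall back to the unconditional correlation", {
  vals <- matrix(abs(rnorm(4 * 5)), 4, 5,
                 dimnames = list(c("X", "Z", "C1", "C2"), NULL))
  traj <- make_traj(vals)
  expect_warning(got <- partial_correlation(traj, "X", "Z",
                                            conditioning = c("C1", "C2")),
                 "too short")
  expect_equal(got, partial_correlation(traj, "X", "Z"), tolerance = 1e-12)
})

test_that("edges are signed by the lag-aligned regulation direction", {
  # single activating edge, noise-free: activation
  net_a <- plant_network(4, 1, 0, seed = 1)
  net_a$edges <- tibble::tibble(regulator = "G1", target = "G3", weight = 1.2)
  sim_a <- simulate_expression(net_a, n_cells = 150, n_steps = 60,
                               noise_sd = 0, obs_noise_sd = 0, seed = 5)
  traj_a <- order_and_smooth(sim_a$expr, sim_a$pseudotime, 5, 1)
  edges_a <- tibble::tibble(regulator = "G1", target = "G3",
                            score = 1, rank = 1L)
  net <- sign_network(edges_a, traj_a)
  expect_equal(net$sign, "activation")
  expect_gt(net$partial_corr, 0)

  # planted strong repressor: inhibition
  net_i <- net_a
  net_i$edges$weight <- -1.4
  sim_i <- simulate_expression(net_i, n_cells = 150, n_steps = 60,
                               noise_sd = 0, obs_noise_sd = 0, seed = 5)
  traj_i <- order_and_smooth(sim_i$expr, sim_i$pseudotime, 5, 1)
  net2 <- sign_network(edges_a, traj_i)
  expect_equal(net2$sign, "inhibition")
  expect_lt(net2$partial_corr, 0)
})

test_that("signed networks carry finite correlations inside [-1, 1]", {
  traj <- random_traj(6, 50, seed = 8)
  D <- divergence_scores(traj, measure = "cramer")
  net <- sign_network(threshold_edges(select_regulators(D, lam = 1.5)), traj)
  expect_true(all(is.finite(net$partial_corr)))
  expect_true(all(abs(net$partial_corr) <= 1))
  expect_true(all(net$sign %in% c("activation", "inhibition")))
  expect_true(all(net$score > 0))
  expect_false(any(net$regulator == net$target))
  expect_false(any(duplicated(paste(net$regulator, net$target))))
})
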