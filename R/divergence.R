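#' Extract lag-aligned samples for a regulator-target pair
#'
#' Under the first-order Markov premise, a regulator X acting on a target Z is
#' scored by comparing X's profile at window t with Z's profile at window
#' t + lag. This returns the two aligned slices of the smoothed trajectory:
#' X's windows `1..T-lag` and Z's windows `1+lag..T`.
#'
#' @param traj A `"smoothed_trajectory"` from [order_and_smooth()].
#' @param regulator,target Gene ids present in the trajectory.
#' @param lag Non-negative integer time lag in windows (default 1).
#' @return A list with numeric vectors `x` (lagged regulator sample) and `z`
#'   (led target sample), each of length `T - lag`.
#' @export
lagged_samples <- function(traj, regulator, target, lag = 1L) {
  stopifnot(inherits(traj, "smoothed_trajectory"))
  lag <- as.integer(lag)
  if (lag < 0L) abort("lag must be >= 0.")
  n_windows <- ncol(traj$values)
  if (n_windows <= lag) {
    abort(sprintf("Need more windows (%d) than the lag (%d).", n_windows, lag))
  }
  for (g in c(regulator, target)) {
    if (!g %in% rownames(traj$values)) abort(sprintf("Gene '%s' not in trajectory.", g))
  }
  list(
    x = traj$values[regulator, seq_len(n_windows - lag)],
    z = traj$values[target, seq(1L + lag, n_windows)]
  )
}

#' Discretize two samples on a shared histogram
#'
#' Builds B equal-width bins spanning the pooled range of both samples
#' (left-closed bins, right-closed last bin), adds a pseudocount to every bin
#' of each sample's counts, and normalizes. The pseudocount keeps every bin
#' strictly positive, which the ratio-based f-divergences (KL, Pearson,
#' Neyman) require. A pooled range of zero width (both samples constant and
#' equal) degenerates to a pair of uniform distributions.
#'
#' @param x,z Non-empty numeric samples.
#' @param n_bins Number of bins B (>= 2, default 10).
#' @param pseudocount Additive smoothing per bin (> 0, default 0.5).
#' @return A `"discrete_pair"`: list with `edges` (B+1 bin boundaries), `p`
#'   (distribution of `x`), `q` (distribution of `z`).
#' @export
shared_histogram <- function(x, z, n_bins = 10L, pseudocount = 0.5) {
  if (!length(x) || !length(z)) abort("Both samples must be non-empty.")
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) abort("n_bins must be >= 2.")
  if (pseudocount <= 0) abort("pseudocount must be > 0.")
  pooled <- range(c(x, z))
  if (diff(pooled) == 0) {
    # degenerate rule: no scale to bin on, fall back to uniform distributions
    inform("Pooled sample range has zero width; using uniform distributions.")
    u <- rep(1 / n_bins, n_bins)
    return(structure(list(edges = seq(pooled[1] - 0.5, pooled[1] + 0.5,
                                      length.out = n_bins + 1L),
                          p = u, q = u),
                     class = "discrete_pair"))
  }
  edges <- seq(pooled[1], pooled[2], length.out = n_bins + 1L)
  bin_of <- function(v) findInterval(v, edges, rightmost.closed = TRUE)
  cx <- tabulate(bin_of(x), nbins = n_bins) + pseudocount
  cz <- tabulate(bin_of(z), nbins = n_bins) + pseudocount
  structure(list(edges = edges, p = cx / sum(cx), q = cz / sum(cz)),
            class = "discrete_pair")
}

kl_div <- function(p, q) sum(p * log(p / q))
pearson_div <- function(p, q) sum((p - q)^2 / q)

#' f-divergences between two discretized distributions
#'
#' Computes the discrete form `sum_i q_i f(p_i / q_i)` for a convex f with
#' f(1) = 0, in nats:
#' \describe{
#'   \item{`f_kl`}{forward Kullback-Leibler, `sum p log(p/q)`}
#'   \item{`s_kl`}{symmetrized KL, `(KL(p||q) + KL(q||p)) / 2`}
#'   \item{`js`}{Jensen-Shannon, `KL(p||m)/2 + KL(q||m)/2` with `m = (p+q)/2`;
#'     bounded by `log(2)`}
#'   \item{`pearson`}{Pearson chi-squared, `sum (p-q)^2 / q`}
#'   \item{`s_pearson`}{symmetrized Pearson, mean of both directions}
#'   \item{`neyman`}{Neyman chi-squared, `sum (q-p)^2 / p`}
#' }
#' Symmetric variants average the two directions so they stay on the scale of
#' a single direction.
#'
#' @param pair A `"discrete_pair"` from [shared_histogram()].
#' @param family One of `"f_kl"`, `"s_kl"`, `"js"`, `"pearson"`,
#'   `"s_pearson"`, `"neyman"`.
#' @return A non-negative scalar; 0 when `p == q`.
#' @export
f_divergence <- function(pair,
                         family = c("f_kl", "s_kl", "js", "pearson",
                                    "s_pearson", "neyman")) {
  stopifnot(inherits(pair, "discrete_pair"))
  family <- match.arg(family)
  p <- pair$p; q <- pair$q
  val <- switch(family,
    f_kl = kl_div(p, q),
    s_kl = (kl_div(p, q) + kl_div(q, p)) / 2,
    js = { m <- (p + q) / 2; (kl_div(p, m) + kl_div(q, m)) / 2 },
    pearson = pearson_div(p, q),
    s_pearson = (pearson_div(p, q) + pearson_div(q, p)) / 2,
    neyman = pearson_div(q, p)
  )
  # guard against -1e-17 style rounding when p ~ q
  if (val < 0 && val > -1e-12) val <- 0
  val
}

# empirical CDF of sample `s` evaluated at sorted points `v`
ecdf_at <- function(s, v) findInterval(v, sort(s)) / length(s)

# sum of |a_i - a_j| over ALL ordered pairs (i, j), including self-pairs
sum_abs_pairs_within <- function(a) {
  a <- sort(a)
  n <- length(a)
  2 * sum((seq_len(n)) * a - cumsum(a))
}

# sum of |x_i - z_j| over all ordered cross pairs
sum_abs_pairs_cross <- function(x, z) {
  z <- sort(z)
  cz <- cumsum(z)
  tot <- cz[length(z)]
  k <- findInterval(x, z)
  below <- ifelse(k > 0, cz[pmax(k, 1L)], 0)
  sum(x * k - below + (tot - below) - x * (length(z) - k))
}

#' Integral probability metrics between two one-dimensional samples
#'
#' Nonparametric two-sample distances computed directly on the raw samples
#' (no binning):
#' \describe{
#'   \item{`wasserstein`}{Wasserstein-1, the integral of `|F - G|` between the
#'     empirical CDFs over the pooled support; for equal sample sizes this
#'     equals the mean absolute difference of the sorted samples}
#'   \item{`energy`}{energy distance as the pairwise-distance V-statistic
#'     `2 mean|x - z| - mean|x - x'| - mean|z - z'|` over all ordered pairs
#'     including self-pairs}
#'   \item{`cramer`}{Cramér distance as the unweighted sum of squared CDF
#'     differences `sum_j (F(v_j) - G(v_j))^2` over the distinct pooled sample
#'     values; `weighted = TRUE` switches to the spacing-weighted integral
#'     (classical Cramér-von Mises-style form)}
#' }
#' On a unit-spaced pooled support the energy distance equals exactly twice
#' the (unweighted) Cramér distance, which ties the two estimators together.
#'
#' @param x,z Non-empty numeric samples.
#' @param kind One of `"wasserstein"`, `"energy"`, `"cramer"`.
#' @param weighted For `kind = "cramer"`: weight each squared CDF difference
#'   by the spacing to the next pooled value (default `FALSE`).
#' @return A non-negative scalar; 0 when the samples are identical.
#' @export
ipm_distance <- function(x, z, kind = c("wasserstein", "energy", "cramer"),
                         weighted = FALSE) {
  kind <- match.arg(kind)
  if (!length(x) || !length(z)) abort("Both samples must be non-empty.")
  if (kind == "energy") {
    nx <- length(x); nz <- length(z)
    val <- 2 * sum_abs_pairs_cross(x, z) / (nx * nz) -
      sum_abs_pairs_within(x) / nx^2 -
      sum_abs_pairs_within(z) / nz^2
    return(max(val, 0))
  }
  v <- sort(unique(c(x, z)))
  dF <- ecdf_at(x, v) - ecdf_at(z, v)
  if (kind == "wasserstein") {
    if (length(v) == 1L) return(0)
    return(sum(abs(dF[-length(v)]) * diff(v)))
  }
  # cramer
  if (weighted) {
    if (length(v) == 1L) return(0)
    return(sum(dF[-length(v)]^2 * diff(v)))
  }
  sum(dF^2)
}

#' Score all regulator-target pairs with a time-lagged divergence
#'
#' Computes the directed dependency score `D(X || Z)` between every candidate
#' regulator X and every gene Z (including regulator-regulator pairs, which
#' the redundancy penalty in [greedy_select()] needs): X's windowed profile at
#' lag `lag` behind Z's is compared with the chosen measure. Histogram-based
#' f-divergences share `n_bins` and `pseudocount`; the IPMs work on the raw
#' window samples.
#'
#' @param traj A `"smoothed_trajectory"` from [order_and_smooth()].
#' @param regulators Candidate regulator ids (default: all genes).
#' @param measure One of `"cramer"`, `"wasserstein"`, `"energy"`, `"f_kl"`,
#'   `"s_kl"`, `"js"`, `"pearson"`, `"s_pearson"`, `"neyman"`.
#' @param lag Time lag in windows (default 1).
#' @param n_bins,pseudocount Histogram settings for the f-divergence families.
#' @param cramer_weighted Use the spacing-weighted Cramér form (default
#'   `FALSE`).
#' @return A `"divergence_matrix"`: numeric matrix (regulators x genes) with
#'   attributes `measure` and `lag`.
#' @export
divergence_scores <- function(traj, regulators = NULL,
                              measure = c("cramer", "wasserstein", "energy",
                                          "f_kl", "s_kl", "js", "pearson",
                                          "s_pearson", "neyman"),
                              lag = 1L, n_bins = 10L, pseudocount = 0.5,
                              cramer_weighted = FALSE) {
  stopifnot(inherits(traj, "smoothed_trajectory"))
  measure <- match.arg(measure)
  genes <- rownames(traj$values)
  regulators <- regulators %||% genes
  missing <- setdiff(regulators, genes)
  if (length(missing)) {
    abort(sprintf("Regulator(s) not in trajectory: %s", paste(missing, collapse = ", ")))
  }
  lag <- as.integer(lag)
  n_windows <- ncol(traj$values)
  if (n_windows <= lag) {
    abort(sprintf("Need more windows (%d) than the lag (%d).", n_windows, lag))
  }
  lagged <- traj$values[, seq_len(n_windows - lag), drop = FALSE]
  led <- traj$values[, seq(1L + lag, n_windows), drop = FALSE]
  is_ipm <- measure %in% c("wasserstein", "energy", "cramer")
  scores <- matrix(0, nrow = length(regulators), ncol = length(genes),
                   dimnames = list(regulators, genes))
  for (X in regulators) {
    xs <- lagged[X, ]
    for (Z in genes) {
      zs <- led[Z, ]
      scores[X, Z] <- if (is_ipm) {
        ipm_distance(xs, zs, kind = measure, weighted = cramer_weighted)
      } else {
        f_divergence(
          suppressMessages(shared_histogram(xs, zs, n_bins, pseudocount)),
          family = measure)
      }
    }
  }
  structure(scores, measure = measure, lag = lag,
            class = c("divergence_matrix", "matrix", "array"))
}

#' @method print divergence_matrix
#' @export
print.divergence_matrix <- function(x, ...) {
  cat(sprintf("<divergence_matrix> %d regulators x %d genes (measure %s, lag %d)\n",
              nrow(x), ncol(x), attr(x, "measure"), attr(x, "lag")))
  invisible(x)
}

#' Tidy a divergence matrix into a long edge-score table
#'
#' Self-pairs are dropped: the diagonal is defined but never eligible as an
#' edge.
#'
#' @param x A `"divergence_matrix"`.
#' @param ... Unused.
#' @return A tibble with columns `regulator`, `target`, `score`.
#' @export
tidy.divergence_matrix <- function(x, ...) {
  out <- tibble::tibble(
    regulator = rep(rownames(x), times = ncol(x)),
    target = rep(colnames(x), each = nrow(x)),
    score = as.vector(unclass(x))
  )
  dplyr::filter(out, .data$regulator != .data$target)
}
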