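#' Penalized greedy regulator selection for one target
#'
#' Implements the lambda-penalized max-relevance/min-redundancy rule. For a
#' target Z and candidate set U, the first pick is the candidate with the
#' largest raw divergence `D(X || Z)` (recorded as its adjusted score).
#' Thereafter, each remaining candidate's adjusted score is
#' `D*(X || Z) = D(X || Z) - lambda / |S| * sum_{Y in S} D(X || Y)`
#' where S is the set already selected; the argmax is picked, its adjusted
#' score recorded at the moment of selection, and the loop continues until
#' every candidate is ranked. Ties break lexicographically on regulator id.
#'
#' @param D A `"divergence_matrix"` from [divergence_scores()] whose rows
#'   cover the candidates and whose columns cover the target and candidates.
#' @param target Target gene id (removed from `candidates` if present).
#' @param candidates Candidate regulator ids (default: all rows of `D` minus
#'   the target).
#' @param lam Redundancy penalty lambda >= 0 (default 1.5).
#' @return A tibble with columns `target`, `regulator`, `rank`,
#'   `adjusted_score`, `lam`; one row per candidate, ranks consecutive from 1.
#' @export
greedy_select <- function(D, target, candidates = NULL, lam = 1.5) {
  stopifnot(is.matrix(D))
  if (lam < 0) abort("lam must be >= 0.")
  if (!target %in% colnames(D)) abort(sprintf("Target '%s' not in divergence matrix.", target))
  candidates <- candidates %||% rownames(D)
  candidates <- setdiff(candidates, target)
  missing <- setdiff(candidates, rownames(D))
  if (length(missing)) {
    abort(sprintf("Candidate(s) not in divergence matrix: %s",
                  paste(missing, collapse = ", ")))
  }
  if (!length(candidates)) {
    warn(sprintf("No candidate regulators for target '%s'; empty selection.", target))
    return(tibble::tibble(target = character(), regulator = character(),
                          rank = integer(), adjusted_score = numeric(),
                          lam = numeric()))
  }
  # lexicographic ordering makes which.max's first-hit rule break ties by id
  candidates <- sort(candidates, method = "radix")
  relevance <- setNames(as.numeric(D[candidates, target]), candidates)
  selected <- character(0)
  recorded <- numeric(0)
  remaining <- candidates
  while (length(remaining)) {
    if (!length(selected)) {
      dstar <- relevance[remaining]
    } else {
      penalty <- if (length(selected) == 1L) {
        D[remaining, selected]
      } else {
        rowSums(D[remaining, selected, drop = FALSE])
      }
      dstar <- relevance[remaining] - (lam / length(selected)) * penalty
    }
    pick <- which.max(dstar)
    selected <- c(selected, remaining[pick])
    recorded <- c(recorded, dstar[[pick]])
    remaining <- remaining[-pick]
  }
  tibble::tibble(target = target, regulator = selected,
                 rank = seq_along(selected), adjusted_score = recorded,
                 lam = lam)
}

#' Run greedy selection for every target gene
#'
#' @param D A `"divergence_matrix"`.
#' @param lam Redundancy penalty lambda (default 1.5).
#' @param targets Target gene ids (default: all columns of `D`).
#' @param candidates Candidate regulator ids (default: all rows of `D`); each
#'   target is removed from its own candidate set.
#' @return Row-bound [greedy_select()] tibbles, targets in sorted order.
#' @export
select_regulators <- function(D, lam = 1.5, targets = NULL, candidates = NULL) {
  targets <- sort(targets %||% colnames(D), method = "radix")
  purrr::map_dfr(targets, function(Z) greedy_select(D, Z, candidates, lam))
}

#' Keep edges whose recorded adjusted score is positive
#'
#' An edge X -> Z enters the network iff the adjusted score recorded when X
#' was selected for Z is strictly greater than 0.
#'
#' @param selections A selection table from [select_regulators()] or
#'   [greedy_select()].
#' @return A tibble with columns `regulator`, `target`, `score` (the recorded
#'   adjusted score), `rank`.
#' @export
threshold_edges <- function(selections) {
  stopifnot(all(c("target", "regulator", "rank", "adjusted_score") %in% names(selections)))
  selections |>
    dplyr::filter(.data$adjusted_score > 0) |>
    dplyr::transmute(regulator = .data$regulator, target = .data$target,
                     score = .data$adjusted_score, rank = .data$rank)
}

#' Lag-aligned (partial) correlation between a regulator and a target
#'
#' Pearson correlation between the regulator's lagged window sample and the
#' target's led window sample after both are linearly adjusted for the lagged
#' samples of the conditioning genes. An empty conditioning set gives the
#' plain lagged Pearson correlation. If the sample is shorter than
#' `|conditioning| + 3` the conditioning set is dropped with a warning; a
#' near-singular regression is stabilized with a small ridge term (1e-6) on
#' the normal equations.
#'
#' @param traj A `"smoothed_trajectory"`.
#' @param regulator,target Gene ids.
#' @param conditioning Character vector of conditioning gene ids (must not
#'   contain `regulator` or `target`).
#' @param lag Time lag in windows (default 1).
#' @return A correlation in `[-1, 1]` (0 with a warning if a residual is
#'   constant).
#' @export
partial_correlation <- function(traj, regulator, target,
                                conditioning = character(), lag = 1L) {
  stopifnot(inherits(traj, "smoothed_trajectory"))
  conditioning <- setdiff(unique(conditioning), c(regulator, target))
  s <- lagged_samples(traj, regulator, target, lag)
  nobs <- length(s$x)
  if (length(conditioning) && nobs < length(conditioning) + 3L) {
    warn(sprintf("Sample length %d too short to condition on %d gene(s); using unconditional correlation.",
                 nobs, length(conditioning)))
    conditioning <- character(0)
  }
  if (!length(conditioning)) {
    rx <- s$x; rz <- s$z
  } else {
    n_windows <- ncol(traj$values)
    C <- t(traj$values[conditioning, seq_len(n_windows - lag), drop = FALSE])
    M <- cbind(1, C)
    G <- crossprod(M)
    if (rcond(G) < 1e-10) {
      inform("Near-singular conditioning design; adding ridge 1e-6 to the normal equations.")
      G <- G + 1e-6 * diag(ncol(M))
    }
    rx <- s$x - M %*% solve(G, crossprod(M, s$x))
    rz <- s$z - M %*% solve(G, crossprod(M, s$z))
  }
  if (stats::sd(rx) == 0 || stats::sd(rz) == 0) {
    warn(sprintf("Constant residual for pair %s -> %s; correlation set to 0.",
                 regulator, target))
    return(0)
  }
  max(-1, min(1, cor(as.vector(rx), as.vector(rz))))
}

#' Sign retained edges by partial correlation
#'
#' For each edge X -> Z, computes the partial correlation between X's lagged
#' and Z's led window samples conditioning on Z's other retained regulators,
#' and labels the edge `activation` when the correlation is positive and
#' `inhibition` when negative. An exactly-zero correlation is labeled
#' `activation` with a warning (deterministic tie rule).
#'
#' @param edges An unsigned edge tibble from [threshold_edges()].
#' @param traj The `"smoothed_trajectory"` the scores came from.
#' @param lag Time lag in windows (default 1).
#' @return A signed-network tibble: columns `regulator`, `target`, `score`,
#'   `rank`, `sign`, `partial_corr`.
#' @export
sign_network <- function(edges, traj, lag = 1L) {
  stopifnot(is.data.frame(edges))
  if (!nrow(edges)) {
    return(tibble::tibble(regulator = character(), target = character(),
                          score = numeric(), rank = integer(),
                          sign = character(), partial_corr = numeric()))
  }
  pcors <- purrr::map_dbl(seq_len(nrow(edges)), function(i) {
    others <- edges$regulator[edges$target == edges$target[i]]
    partial_correlation(traj, edges$regulator[i], edges$target[i],
                        conditioning = setdiff(others, edges$regulator[i]),
                        lag = lag)
  })
  zero <- which(pcors == 0)
  if (length(zero)) {
    warn(sprintf("%d edge(s) have exactly zero partial correlation; labeled activation.",
                 length(zero)))
  }
  edges |>
    dplyr::mutate(sign = ifelse(pcors < 0, "inhibition", "activation"),
                  partial_corr = pcors)
}
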