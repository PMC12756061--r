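#' Plant a random signed regulatory network
#'
#' Draws a ground-truth directed network: the first `n_tfs` genes are eligible
#' regulators, `n_edges` regulator -> target pairs are sampled uniformly
#' without replacement from all non-self pairs, and each edge gets a weight
#' with magnitude uniform on `[w_min, w_max]` and a negative (inhibitory) sign
#' with probability `frac_inhibitory`.
#'
#' @param n_genes,n_tfs,n_edges Network size (edges must fit in
#'   `n_tfs * (n_genes - 1)` candidate pairs).
#' @param frac_inhibitory Probability an edge is inhibitory (default 0.3).
#' @param w_min,w_max Weight magnitude range (defaults 0.5, 1.5).
#' @param seed Integer seed; the same seed reproduces the same network.
#' @return A `"planted_network"`: list with `genes`, `tfs`, `edges` (tibble
#'   `regulator`, `target`, `weight`), `seed`.
#' @export
plant_network <- function(n_genes = 20L, n_tfs = 5L, n_edges = 15L,
                          frac_inhibitory = 0.3, w_min = 0.5, w_max = 1.5,
                          seed = 1L) {
  n_genes <- as.integer(n_genes); n_tfs <- as.integer(n_tfs)
  n_edges <- as.integer(n_edges)
  if (n_tfs < 1L || n_tfs > n_genes) abort("n_tfs must be in [1, n_genes].")
  n_pairs <- n_tfs * (n_genes - 1L)
  if (n_edges > n_pairs) {
    abort(sprintf("Requested %d edges but only %d regulator-target pairs exist.",
                  n_edges, n_pairs))
  }
  genes <- sprintf("G%0*d", nchar(n_genes), seq_len(n_genes))
  tfs <- genes[seq_len(n_tfs)]
  pairs <- tidyr::expand_grid(regulator = tfs, target = genes) |>
    dplyr::filter(.data$regulator != .data$target)
  edges <- with_seed(seed, {
    picked <- pairs[sample.int(nrow(pairs), n_edges), ]
    magnitude <- runif(n_edges, w_min, w_max)
    negative <- rbinom(n_edges, 1L, frac_inhibitory) == 1L
    dplyr::mutate(picked, weight = ifelse(negative, -magnitude, magnitude))
  })
  structure(list(genes = genes, tfs = tfs,
                 edges = dplyr::arrange(edges, .data$target, .data$regulator),
                 seed = as.integer(seed)),
            class = "planted_network")
}

#' @method print planted_network
#' @export
print.planted_network <- function(x, ...) {
  cat(sprintf("<planted_network> %d genes, %d TFs, %d edges (%d inhibitory), seed %d\n",
              length(x$genes), length(x$tfs), nrow(x$edges),
              sum(x$edges$weight < 0), x$seed))
  invisible(x)
}

#' Simulate expression snapshots from a planted lag-1 network
#'
#' Integrates additive-sigmoidal dynamics with first-order (Markov) regulation:
#' `g[t+1] = max(0, g[t] + eta * (W sigma(g[t]) + basal - decay * g[t]) + noise)`
#' where `sigma` is a steep logistic centered at the unregulated steady state
#' `basal / decay` — switch-like, cooperative regulation in the spirit of a
#' Hill function, so a repressed target transiently rises on basal drive
#' before its repressor switches on and pushes it down (repression leaves a
#' visible signature). All genes start off (`g[0] = 0`), as at the onset of a
#' differentiation time course. Cells are then drawn at uniformly random
#' trajectory times with replacement — so the cell ordering is unknown and
#' pseudotime estimation has real work to do — and observed with additive
#' Gaussian noise, clipped at 0.
#'
#' @param net A `"planted_network"` from [plant_network()].
#' @param n_cells Number of cells to sample (default 600).
#' @param n_steps Trajectory length in integration steps (default 200, about
#'   six relaxation times, covering the transient and the regulated steady
#'   state; must be >= 20 so the transient is represented).
#' @param noise_sd Process noise SD per step (default 0.05).
#' @param obs_noise_sd Observation noise SD (default 0.1).
#' @param seed Integer seed.
#' @param step_size,decay,basal Dynamics constants eta, gamma, b (defaults
#'   0.1, 0.3, 0.2).
#' @param sigmoid_mid,sigmoid_slope Logistic midpoint and slope (defaults
#'   `basal / decay` and 4).
#' @return A `"simulated_dataset"`: list with `expr` (an
#'   [expression_matrix()]), `pseudotime` (tibble `cell`, `pseudotime` of true
#'   sampling times), `network` (the planted network).
#' @export
simulate_expression <- function(net, n_cells = 600L, n_steps = 200L,
                                noise_sd = 0.05, obs_noise_sd = 0.1,
                                seed = 1L, step_size = 0.1, decay = 0.3,
                                basal = 0.2, sigmoid_mid = basal / decay,
                                sigmoid_slope = 4) {
  stopifnot(inherits(net, "planted_network"))
  n_steps <- as.integer(n_steps); n_cells <- as.integer(n_cells)
  if (n_steps < 20L) abort("n_steps must be >= 20.")
  genes <- net$genes
  m <- length(genes)
  W <- matrix(0, m, m, dimnames = list(genes, genes))  # target x regulator
  if (nrow(net$edges)) {
    W[cbind(match(net$edges$target, genes), match(net$edges$regulator, genes))] <-
      net$edges$weight
  }
  sigmoid <- function(g) 1 / (1 + exp(-sigmoid_slope * (g - sigmoid_mid)))
  with_seed(seed, {
    latent <- matrix(0, m, n_steps + 1L)
    g <- numeric(m)
    for (t in seq_len(n_steps)) {
      drive <- as.vector(W %*% sigmoid(g)) + basal - decay * g
      g <- pmax(0, g + step_size * drive + rnorm(m, 0, noise_sd))
      latent[, t + 1L] <- g
    }
    times <- sample.int(n_steps + 1L, n_cells, replace = TRUE) - 1L
    obs <- latent[, times + 1L, drop = FALSE] +
      matrix(rnorm(m * n_cells, 0, obs_noise_sd), m, n_cells)
    obs <- pmax(obs, 0)
    cells <- sprintf("C%0*d", nchar(n_cells), seq_len(n_cells))
    structure(list(
      expr = expression_matrix(obs, genes, cells),
      pseudotime = tibble::tibble(cell = cells, pseudotime = as.numeric(times)),
      network = net
    ), class = "simulated_dataset")
  })
}

#' @method print simulated_dataset
#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf("<simulated_dataset> %d genes x %d cells from a %d-edge planted network\n",
              nrow(x$expr), ncol(x$expr), nrow(x$network$edges)))
  invisible(x)
}

#' End-to-end recovery experiment on planted networks
#'
#' For each replicate: plant a network, simulate expression, run the full
#' inference pipeline, and score the complete candidate ranking (recorded
#' adjusted scores of every TF -> gene pair) against the planted edges with
#' AUROC/AUPRC. Sign accuracy is the fraction of true-positive edges (inferred
#' and planted) whose activation/inhibition label matches the planted weight
#' sign. A shuffled-label null redraws the reference edge set at random (same
#' size, same candidate pairs) and rescoring gives the chance-level AUROC.
#'
#' @param n_replicates Number of independent replicates (default 5).
#' @param config A [pgrn_config()] controlling the pipeline. The default
#'   disables library-size normalization: the simulator measures latent
#'   concentrations directly and has no library-size artifact to correct, and
#'   rescaling cell totals would erase the very trajectory signal pseudotime
#'   needs.
#' @param n_genes,n_tfs,n_edges,frac_inhibitory Passed to [plant_network()].
#' @param n_cells,n_steps,noise_sd,obs_noise_sd Passed to
#'   [simulate_expression()].
#' @param shuffled_null Also compute the shuffled-reference null AUROC
#'   (default `TRUE`).
#' @param seed Base seed; replicate r uses `seed + r - 1` offsets.
#' @return A `"recovery_report"`: list with `replicates` (one tibble row per
#'   replicate: `auroc`, `auprc`, `null_auroc`, `sign_accuracy`, edge counts)
#'   and `summary` (means and SDs).
#' @export
recovery_experiment <- function(n_replicates = 5L,
                                config = pgrn_config(normalize = FALSE),
                                n_genes = 20L, n_tfs = 5L, n_edges = 15L,
                                frac_inhibitory = 0.3, n_cells = 600L,
                                n_steps = 200L, noise_sd = 0.05,
                                obs_noise_sd = 0.1, shuffled_null = TRUE,
                                seed = 1L) {
  reps <- purrr::map_dfr(seq_len(n_replicates), function(r) {
    seed_r <- as.integer(seed) + r - 1L
    net <- plant_network(n_genes, n_tfs, n_edges, frac_inhibitory, seed = seed_r)
    sim <- simulate_expression(net, n_cells = n_cells, n_steps = n_steps,
                               noise_sd = noise_sd, obs_noise_sd = obs_noise_sd,
                               seed = seed_r + 1000L)
    fit <- run_pipeline(sim$expr, tfs = net$tfs, config = config)
    sc <- edge_scores(fit)
    ev <- evaluate_network(sc, net$edges, regulators = net$tfs, genes = net$genes)
    truth_key <- paste(net$edges$regulator, net$edges$target)
    hit <- paste(fit$network$regulator, fit$network$target) %in% truth_key
    sign_acc <- if (any(hit)) {
      tp <- fit$network[hit, ]
      w <- net$edges$weight[match(paste(tp$regulator, tp$target), truth_key)]
      mean((tp$sign == "activation") == (w > 0))
    } else NA_real_
    null_auroc <- NA_real_
    if (isTRUE(shuffled_null)) {
      null_net <- plant_network(n_genes, n_tfs, n_edges, frac_inhibitory,
                                seed = seed_r + 5000L)
      null_auroc <- auroc(sc, null_net$edges, regulators = net$tfs,
                          genes = net$genes)
    }
    tibble::tibble(replicate = r, auroc = ev$auroc, auprc = ev$auprc,
                   null_auroc = null_auroc, sign_accuracy = sign_acc,
                   n_true_edges = nrow(net$edges),
                   n_inferred = nrow(fit$network),
                   n_true_positive = sum(hit))
  })
  summary <- tibble::tibble(
    mean_auroc = mean(reps$auroc),
    sd_auroc = stats::sd(reps$auroc),
    mean_auprc = mean(reps$auprc),
    sd_auprc = stats::sd(reps$auprc),
    mean_null_auroc = mean(reps$null_auroc),
    mean_sign_accuracy = mean(reps$sign_accuracy, na.rm = TRUE),
    n_replicates = n_replicates
  )
  structure(list(replicates = reps, summary = summary, config = config),
            class = "recovery_report")
}

#' @method print recovery_report
#' @export
print.recovery_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<recovery_report> %d replicates (measure %s, lambda %.3g)\n",
              s$n_replicates, x$config$measure, x$config$lam))
  cat(sprintf("  mean AUROC %.4f (sd %.4f), mean AUPRC %.4f (sd %.4f)\n",
              s$mean_auroc, s$sd_auroc, s$mean_auprc, s$sd_auprc))
  cat(sprintf("  null AUROC %.4f, sign accuracy %.4f\n",
              s$mean_null_auroc, s$mean_sign_accuracy))
  invisible(x)
}

#' @rdname recovery_experiment
#' @param x A `"recovery_report"`.
#' @param ... Unused.
#' @export
glance.recovery_report <- function(x, ...) x$summary

#' @rdname recovery_experiment
#' @export
tidy.recovery_report <- function(x, ...) x$replicates
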