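#' Pipeline run configuration
#'
#' Bundles and validates every tunable of the inference pipeline.
#'
#' @param pseudotime_method `"pca"`, `"diffmap"`, or `"precomputed"` (a
#'   per-cell pseudotime table is then supplied to [run_pipeline()]).
#' @param measure Divergence measure scoring directed dependencies; one of
#'   `"cramer"` (default, the best-performing measure), `"wasserstein"`,
#'   `"energy"`, `"f_kl"`, `"s_kl"`, `"js"`, `"pearson"`, `"s_pearson"`,
#'   `"neyman"`.
#' @param lag Time lag in smoothed windows (default 1, the first-order Markov
#'   assumption).
#' @param window_width,window_step Sliding-window smoothing geometry
#'   (defaults 5 and 1).
#' @param lam Redundancy penalty lambda >= 0 (default 1.5).
#' @param n_bins,pseudocount Histogram settings for f-divergence families
#'   (defaults 10 and 0.5).
#' @param root_cell Optional root cell id anchoring pseudotime orientation.
#' @param normalize Median-library-size scaling + log1p before pseudotime and
#'   smoothing; default `NULL` means on for `pca`/`diffmap`, off for
#'   `precomputed`.
#' @param cramer_weighted Use the spacing-weighted Cramér estimator (default
#'   `FALSE`).
#' @param n_neighbors,n_comps Diffusion-map settings (defaults 15 and 10).
#' @param seed Integer seed recorded with the run (the pipeline itself is
#'   deterministic; the seed also pins any downstream simulation).
#' @return A list of class `"pgrn_config"`.
#' @export
pgrn_config <- function(pseudotime_method = c("pca", "diffmap", "precomputed"),
                        measure = c("cramer", "wasserstein", "energy", "f_kl",
                                    "s_kl", "js", "pearson", "s_pearson",
                                    "neyman"),
                        lag = 1L, window_width = 5L, window_step = 1L,
                        lam = 1.5, n_bins = 10L, pseudocount = 0.5,
                        root_cell = NULL, normalize = NULL,
                        cramer_weighted = FALSE, n_neighbors = 15L,
                        n_comps = 10L, seed = 1L) {
  pseudotime_method <- match.arg(pseudotime_method)
  measure <- match.arg(measure)
  lag <- as.integer(lag)
  if (lag < 1L) abort("lag must be >= 1.")
  window_width <- as.integer(window_width)
  window_step <- as.integer(window_step)
  if (window_width < 1L || window_step < 1L) {
    abort("window_width and window_step must be positive.")
  }
  if (lam < 0) abort("lam must be >= 0.")
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) abort("n_bins must be >= 2.")
  if (pseudocount <= 0) abort("pseudocount must be > 0.")
  normalize <- normalize %||% (pseudotime_method != "precomputed")
  structure(list(pseudotime_method = pseudotime_method, measure = measure,
                 lag = lag, window_width = window_width,
                 window_step = window_step, lam = lam, n_bins = n_bins,
                 pseudocount = pseudocount, root_cell = root_cell,
                 normalize = isTRUE(normalize),
                 cramer_weighted = isTRUE(cramer_weighted),
                 n_neighbors = as.integer(n_neighbors),
                 n_comps = as.integer(n_comps), seed = as.integer(seed)),
            class = "pgrn_config")
}

#' @method print pgrn_config
#' @export
print.pgrn_config <- function(x, ...) {
  cat("<pgrn_config>\n")
  for (k in names(x)) {
    cat(sprintf("  %-18s %s\n", k,
                if (is.null(x[[k]])) "NULL" else format(x[[k]])))
  }
  invisible(x)
}

#' Run the full network-inference pipeline
#'
#' Executes the four steps end to end: (1) pseudotime estimation and
#' sliding-window smoothing, (2) time-lagged divergence scoring of every
#' candidate regulator against every gene, (3) lambda-penalized greedy
#' non-redundant regulator selection with the strict `D* > 0` edge test, and
#' (4) partial-correlation signing of retained edges. The pipeline is
#' deterministic: identical inputs and configuration give identical output.
#'
#' @param expr An [expression_matrix()].
#' @param tfs Candidate regulator ids (default `NULL`: every gene except the
#'   target is a candidate). All must be present in `expr`.
#' @param config A [pgrn_config()].
#' @param pseudotime For `pseudotime_method = "precomputed"`: a tibble
#'   (`cell`, `pseudotime`) or a path to a headered TSV.
#' @param verbose Log step dimensions, parameters and timings (default
#'   `getOption("pseudogrn.verbose", FALSE)`).
#' @return A `"pgrn_fit"`: list with `network` (signed edge tibble),
#'   `selections` (per-target ranking with recorded adjusted scores),
#'   `scores` (the divergence matrix), `trajectory`, `pseudotime`, `config`,
#'   `tfs`.
#' @export
run_pipeline <- function(expr, tfs = NULL, config = pgrn_config(),
                         pseudotime = NULL,
                         verbose = getOption("pseudogrn.verbose", FALSE)) {
  stopifnot(inherits(expr, "ExpressionMatrix"), inherits(config, "pgrn_config"))
  genes <- rownames(expr)
  if (!is.null(tfs)) {
    missing <- setdiff(tfs, genes)
    if (length(missing)) {
      abort(sprintf("TF(s) absent from the expression matrix: %s",
                    paste(missing, collapse = ", ")))
    }
  }
  candidates <- tfs %||% genes
  set.seed(config$seed)
  t0 <- proc.time()[3]
  pg_log(verbose, "input: %d genes x %d cells; measure=%s lambda=%.3g lag=%d window=%d/%d",
         nrow(expr), ncol(expr), config$measure, config$lam, config$lag,
         config$window_width, config$window_step)

  work <- preprocess_expression(expr, normalize = config$normalize)
  pt <- switch(config$pseudotime_method,
    pca = pca_pseudotime(work, root_cell = config$root_cell),
    diffmap = diffusion_pseudotime(work, root_cell = config$root_cell,
                                   n_neighbors = config$n_neighbors,
                                   n_comps = config$n_comps),
    precomputed = {
      if (is.null(pseudotime)) {
        abort("pseudotime_method = 'precomputed' needs a pseudotime table or file.")
      }
      if (is.character(pseudotime)) read_pseudotime(pseudotime, expr)
      else {
        # accept any (cell, value) table; validate coverage via order_and_smooth
        tibble::tibble(cell = as.character(pseudotime[[1]]),
                       pseudotime = as.numeric(pseudotime[[2]]))
      }
    })
  traj <- order_and_smooth(work, pt, width = config$window_width,
                           step = config$window_step)
  pg_log(verbose, "step 1 (pseudotime %s + smoothing): %d windows [%.2fs]",
         config$pseudotime_method, ncol(traj$values), proc.time()[3] - t0)

  t1 <- proc.time()[3]
  D <- divergence_scores(traj, regulators = candidates,
                         measure = config$measure, lag = config$lag,
                         n_bins = config$n_bins,
                         pseudocount = config$pseudocount,
                         cramer_weighted = config$cramer_weighted)
  pg_log(verbose, "step 2 (time-lagged %s divergence): %d x %d scores [%.2fs]",
         config$measure, nrow(D), ncol(D), proc.time()[3] - t1)

  t2 <- proc.time()[3]
  selections <- select_regulators(D, lam = config$lam, targets = genes,
                                  candidates = candidates)
  edges <- threshold_edges(selections)
  pg_log(verbose, "step 3 (greedy selection, lambda=%.3g): %d edges with D* > 0 [%.2fs]",
         config$lam, nrow(edges), proc.time()[3] - t2)

  t3 <- proc.time()[3]
  network <- sign_network(edges, traj, lag = config$lag)
  pg_log(verbose, "step 4 (partial-correlation signing): %d activation / %d inhibition [%.2fs]",
         sum(network$sign == "activation"), sum(network$sign == "inhibition"),
         proc.time()[3] - t3)

  structure(list(network = network, selections = selections, scores = D,
                 trajectory = traj, pseudotime = pt, config = config,
                 tfs = tfs, genes = genes),
            class = "pgrn_fit")
}

#' @method print pgrn_fit
#' @export
print.pgrn_fit <- function(x, ...) {
  cat(sprintf("<pgrn_fit> %d genes, %d candidate regulators -> %d signed edges\n",
              length(x$genes), length(x$tfs %||% x$genes), nrow(x$network)))
  cat(sprintf("  measure %s, lambda %.3g, lag %d, pseudotime %s\n",
              x$config$measure, x$config$lam, x$config$lag,
              x$config$pseudotime_method))
  invisible(x)
}

#' Tidy a fitted pipeline into its signed edge table
#'
#' @param x A `"pgrn_fit"` from [run_pipeline()].
#' @param ... Unused.
#' @return The signed-network tibble (`regulator`, `target`, `score`, `rank`,
#'   `sign`, `partial_corr`).
#' @export
tidy.pgrn_fit <- function(x, ...) x$network

#' One-row summary of a fitted pipeline
#'
#' @param x A `"pgrn_fit"`.
#' @param ... Unused.
#' @return A one-row tibble: problem size, configuration and edge counts.
#' @export
glance.pgrn_fit <- function(x, ...) {
  tibble::tibble(
    n_genes = length(x$genes),
    n_cells = length(x$pseudotime$cell),
    n_windows = ncol(x$trajectory$values),
    n_candidates = length(x$tfs %||% x$genes),
    n_edges = nrow(x$network),
    n_activation = sum(x$network$sign == "activation"),
    n_inhibition = sum(x$network$sign == "inhibition"),
    measure = x$config$measure,
    lam = x$config$lam,
    lag = x$config$lag,
    pseudotime_method = x$config$pseudotime_method
  )
}

#' Complete candidate ranking of a fitted pipeline
#'
#' Every candidate regulator of every target, scored by the adjusted score
#' recorded at its selection. This is the threshold-free ranking used for
#' AUROC/AUPRC evaluation, so the metrics do not depend on the `D* > 0`
#' retention cutoff.
#'
#' @param fit A `"pgrn_fit"`.
#' @return A tibble with columns `regulator`, `target`, `score`.
#' @export
edge_scores <- function(fit) {
  stopifnot(inherits(fit, "pgrn_fit"))
  fit$selections |>
    dplyr::transmute(regulator = .data$regulator, target = .data$target,
                     score = .data$adjusted_score)
}
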