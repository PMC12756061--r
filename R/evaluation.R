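# Build the evaluation universe (all ordered regulator -> gene pairs minus
# self-pairs) and attach scores; unscored pairs get 0.
build_eval_table <- function(scores, reference, regulators = NULL, genes = NULL) {
  stopifnot(is.data.frame(scores), is.data.frame(reference))
  if (!all(c("regulator", "target") %in% names(reference))) {
    reference <- setNames(reference[, 1:2], c("regulator", "target"))
  }
  genes <- genes %||% sort(unique(c(reference$regulator, reference$target)))
  regulators <- regulators %||% genes
  universe <- tidyr::expand_grid(regulator = sort(regulators),
                                 target = sort(genes)) |>
    dplyr::filter(.data$regulator != .data$target)
  ref_keys <- paste(reference$regulator, reference$target, sep = "\r")
  uni_keys <- paste(universe$regulator, universe$target, sep = "\r")
  if (!any(uni_keys %in% ref_keys)) abort("Reference contains no positive pairs inside the evaluation universe.")
  if (all(uni_keys %in% ref_keys)) abort("Reference covers every candidate pair; negatives are empty.")
  sc <- scores |> dplyr::distinct(.data$regulator, .data$target, .keep_all = TRUE)
  sc_keys <- paste(sc$regulator, sc$target, sep = "\r")
  if (any(!is.finite(sc$score))) abort("Edge scores must all be finite.")
  idx <- match(uni_keys, sc_keys)
  universe |>
    dplyr::mutate(score = ifelse(is.na(idx), 0, sc$score[idx]),
                  label = uni_keys %in% ref_keys)
}

#' Area under the ROC curve for a ranked edge table
#'
#' Ranks every ordered regulator -> gene pair of the evaluation universe by
#' its score (pairs absent from `scores` rank at 0) and computes AUROC with
#' the Mann-Whitney midrank formulation, so tied scores contribute 1/2.
#'
#' @param scores Edge score tibble (`regulator`, `target`, `score`), e.g. from
#'   [edge_scores()] or [tidy.divergence_matrix()].
#' @param reference Reference edge tibble (`regulator`, `target`), e.g. from
#'   [read_edge_list()]; these pairs are the positives.
#' @param regulators Regulator ids spanning the universe's edge sources
#'   (default: the reference gene set — every gene may regulate).
#' @param genes Gene ids spanning the universe's edge targets (default: all
#'   genes in the reference).
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, reference, regulators = NULL, genes = NULL) {
  tab <- build_eval_table(scores, reference, regulators, genes)
  r <- rank(tab$score)           # midranks
  n_pos <- sum(tab$label)
  n_neg <- sum(!tab$label)
  (sum(r[tab$label]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve (average precision)
#'
#' Sweeps the universe's pairs in descending score order and accumulates
#' `(recall_k - recall_{k-1}) * precision_k`, processing tied scores as a
#' single block (precision evaluated after the whole block enters). With all
#' scores tied this equals the positive prevalence; a perfect ranking gives 1.
#'
#' @inheritParams auroc
#' @return AUPRC in `(0, 1]`.
#' @export
auprc <- function(scores, reference, regulators = NULL, genes = NULL) {
  tab <- build_eval_table(scores, reference, regulators, genes)
  n_pos <- sum(tab$label)
  blocks <- tab |>
    dplyr::group_by(.data$score) |>
    dplyr::summarise(tp = sum(.data$label), n = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$score))
  cum_tp <- cumsum(blocks$tp)
  cum_n <- cumsum(blocks$n)
  sum((blocks$tp / n_pos) * (cum_tp / cum_n))
}

#' Evaluate a ranked edge table against a reference network
#'
#' @inheritParams auroc
#' @return A one-row tibble with `auroc`, `auprc`, `n_pos`, `n_neg`.
#' @export
evaluate_network <- function(scores, reference, regulators = NULL, genes = NULL) {
  tab <- build_eval_table(scores, reference, regulators, genes)
  tibble::tibble(
    auroc = auroc(scores, reference, regulators, genes),
    auprc = auprc(scores, reference, regulators, genes),
    n_pos = sum(tab$label),
    n_neg = sum(!tab$label)
  )
}
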