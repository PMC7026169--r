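#' Tidy the node table of a fitted tree
#'
#' @param x An `edura_tree`.
#' @param ... Unused.
#' @return Tibble with one row per node: sample count, class counts,
#'   impurity, split feature/threshold (NA for leaves), child impurity and
#'   child ids.
#' @export
tidy.edura_tree <- function(x, ...) {
  nodes <- x$nodes
  nodes$feature <- x$feature_names[nodes$feature]
  nodes
}

#' One-row summary of a fitted tree
#'
#' @param x An `edura_tree`.
#' @param ... Unused.
#' @return Tibble with node/leaf counts, maximum depth, and training
#'   accuracy under majority vote at the leaves.
#' @export
glance.edura_tree <- function(x, ...) {
  nodes <- x$nodes
  leaves <- nodes[nodes$leaf, , drop = FALSE]
  correct <- sum(pmax(leaves$n_pos, leaves$n - leaves$n_pos))
  tibble(n_nodes = nrow(nodes), n_leaves = nrow(leaves),
         max_depth = max(nodes$depth),
         training_accuracy = correct / x$n_samples,
         criterion = x$criterion)
}

#' Tidy an axis scan into long format
#'
#' @param x An `edura_scan`.
#' @param ... Unused.
#' @return Long tibble with `position`, `series`, `value` for the
#'   asymmetry curves (raw and, when present, baseline-subtracted).
#' @export
tidy.edura_scan <- function(x, ...) {
  keep <- intersect(c("position", "a_pm_r", "a_pm_l", "a_cross_along",
                      "b_pm_r", "b_pm_l", "b_cross_along"), names(x))
  tidyr::pivot_longer(as_tibble(x)[keep], -"position",
                      names_to = "series", values_to = "value")
}

#' One-row summary of an axis scan
#'
#' @param x An `edura_scan`.
#' @param ... Unused.
#' @return Tibble with the number of positions, genome length, edge count
#'   scanned, and whether a baseline has been subtracted.
#' @export
glance.edura_scan <- function(x, ...) {
  tibble(n_positions = nrow(x),
         genome_length = attr(x, "genome_length"),
         n_edges = sum(unlist(x[1, .count_cols])),
         n_self_loops = attr(x, "n_self_loops"),
         baseline_subtracted = "b_pm_r" %in% names(x))
}
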