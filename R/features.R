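.feature_names <- c("pos_oric", "crp_density", "hns_density", "fis_density",
                    "gpn_cont", "trn_cont", "hns_dig_cont", "fis_dig_cont",
                    "crp_dig_cont")

#' Binding-site density around chromosomal positions
#'
#' Number of sites whose circular distance to each center is at most
#' `half_window` (inclusive at the boundary).
#'
#' @param sites Numeric vector of site positions in `[0, g)` (or a data
#'   frame with a `position` column).
#' @param centers Numeric vector of gene centers.
#' @param g Genome length.
#' @param half_window Window half-width in bp (default 50000).
#' @return Integer vector of counts, one per center.
#' @export
binding_site_density <- function(sites, centers, g, half_window = 50000) {
  if (is.data.frame(sites)) sites <- sites$position
  if (length(sites) == 0) return(rep(0L, length(centers)))
  s <- sort(sites %% g)
  # count sites in the circular interval [c - w, c + w]
  lo <- (centers - half_window) %% g
  hi <- (centers + half_window) %% g
  cum <- function(x) findInterval(x, s)  # sites <= x
  n_all <- length(s)
  wrap <- lo > hi  # interval crosses the origin
  cnt <- integer(length(centers))
  if (2 * half_window >= g) return(rep(n_all, length(centers)))
  cnt[!wrap] <- cum(hi[!wrap]) - cum(lo[!wrap] - 1e-9)
  cnt[wrap] <- (n_all - cum(lo[wrap] - 1e-9)) + cum(hi[wrap])
  as.integer(cnt)
}

#' Unsigned chromosomal distance to Ori
#'
#' @param center Gene center coordinate(s).
#' @param ori_bp Ori position.
#' @param g Genome length.
#' @return Circular distance in `[0, g/2]`.
#' @export
pos_oric <- function(center, ori_bp, g) {
  circular_distance(center, ori_bp, g)
}

#' Per-gene feature table for decision-tree analysis
#'
#' Builds the nine features used to classify genes of one contrast into
#' differentially expressed or not: the distance to Ori, the
#' crp/hns/fis binding-site densities within +/-50 kbp, the number of
#' called GPN neighbors (`gpn_cont`), the number of called direct TRN
#' regulators (`trn_cont`; set `ancestors = TRUE` for the transitive
#' closure instead), and three binary flags for hns/fis/crp being among a
#' gene's direct TRN regulators.
#'
#' @param genome A [circular_genome()].
#' @param trn Directed `igraph` (regulator -> target).
#' @param gpn Undirected `igraph`.
#' @param sites Named list with elements `fis`, `hns`, `crp`: site position
#'   vectors or data frames with a `position` column.
#' @param called Character vector of called gene ids for the contrast.
#' @param ori_bp Ori position.
#' @param factor_genes Named character vector giving the gene ids encoding
#'   the three factors, default `c(fis = "fis", hns = "hns", crp = "crp")`.
#' @param half_window Site-density half-window in bp.
#' @param ancestors Use transitive TRN ancestors for `trn_cont`.
#' @return Tibble with `gene_id`, the nine feature columns, and the logical
#'   label `called`.
#' @export
compute_feature_table <- function(genome, trn, gpn, sites, called, ori_bp,
                                  factor_genes = c(fis = "fis", hns = "hns", crp = "crp"),
                                  half_window = 50000, ancestors = FALSE) {
  g <- genome_length(genome)
  ids <- genome$gene_id
  called <- intersect(called, ids)
  called_flag <- ids %in% called

  dens <- lapply(c(crp = "crp", hns = "hns", fis = "fis"), function(f) {
    binding_site_density(sites[[f]], genome$center, g, half_window)
  })

  count_called_neighbors <- function(graph, mode) {
    cnt <- rep(0L, length(ids))
    vn <- igraph::V(graph)$name
    present <- ids %in% vn
    if (!any(present) || length(called) == 0) return(cnt)
    el <- igraph::as_edgelist(graph)
    if (nrow(el) == 0) return(cnt)
    called_set <- called
    if (mode == "gpn") {
      # undirected: count called partners on either side
      a_called <- el[, 1] %in% called_set
      b_called <- el[, 2] %in% called_set
      tab <- c(el[b_called, 1], el[a_called, 2])
    } else {
      # directed: called regulators (predecessors) of the target
      tab <- el[el[, 1] %in% called_set, 2]
    }
    t2 <- table(tab)
    m <- match(names(t2), ids)
    cnt[m[!is.na(m)]] <- as.integer(t2[!is.na(m)])
    cnt
  }

  gpn_cont <- count_called_neighbors(gpn, "gpn")
  trn_cont <- if (ancestors) count_called_ancestors(trn, ids, called)
              else count_called_neighbors(trn, "trn")

  dig_flag <- function(fgene) {
    flags <- rep(0L, length(ids))
    if (!fgene %in% igraph::V(trn)$name) {
      warn(paste0("factor gene '", fgene, "' absent from the TRN; flag set to 0."))
      return(flags)
    }
    succ <- igraph::neighbors(trn, fgene, mode = "out")$name
    flags[ids %in% succ] <- 1L
    flags
  }

  out <- tibble(
    gene_id = ids,
    pos_oric = pos_oric(genome$center, ori_bp, g),
    crp_density = dens$crp,
    hns_density = dens$hns,
    fis_density = dens$fis,
    gpn_cont = gpn_cont,
    trn_cont = trn_cont,
    hns_dig_cont = dig_flag(unname(factor_genes["hns"])),
    fis_dig_cont = dig_flag(unname(factor_genes["fis"])),
    crp_dig_cont = dig_flag(unname(factor_genes["crp"])),
    called = called_flag
  )
  out
}

count_called_ancestors <- function(trn, ids, called) {
  cnt <- rep(0L, length(ids))
  vn <- igraph::V(trn)$name
  for (cg in intersect(called, vn)) {
    reach <- igraph::subcomponent(trn, cg, mode = "out")$name
    reach <- setdiff(reach, cg)
    m <- match(reach, ids)
    m <- m[!is.na(m)]
    cnt[m] <- cnt[m] + 1L
  }
  cnt
}

#' Aggregate a gene-level feature table to the operon level
#'
#' Numeric features are averaged over the member genes of each operon; the
#' label follows the any-member rule (an operon is called when any member
#' gene is called). Gene-level control analyses are the primary use of the
#' feature table; this aggregation extends the tree analysis to operons.
#'
#' @param feature_table Output of [compute_feature_table()].
#' @param operons Tibble mapping `gene_id` to `operon_id`; must cover all
#'   genes in the table.
#' @return Tibble with `operon_id`, the averaged feature columns, and the
#'   logical label `called`.
#' @export
operon_feature_table <- function(feature_table, operons) {
  unmapped <- setdiff(feature_table$gene_id, operons$gene_id)
  if (length(unmapped) > 0) {
    abort(paste0("genes missing from the operon map: ",
                 paste(head(unmapped, 5), collapse = ", ")),
          class = "edura_unmapped_gene")
  }
  joined <- dplyr::inner_join(feature_table, operons, by = "gene_id")
  dplyr::summarise(
    dplyr::group_by(joined, .data$operon_id),
    dplyr::across(dplyr::all_of(.feature_names), mean),
    called = any(.data$called),
    .groups = "drop")
}

#' Fit a binary classification tree
#'
#' Grows an axis-aligned binary tree on feature-threshold tests, choosing
#' at each node the split maximizing the entropy gain (or Gini impurity
#' gain) over all features and all midpoints of consecutive distinct
#' values, until nodes are pure or no impurity-reducing split exists
#' (identical feature vectors with different labels stop growth at an
#' impure leaf). Ties are broken deterministically: lowest feature index,
#' then lowest threshold. Samples with `x <= threshold` go left.
#'
#' @param x Data frame or numeric matrix of features.
#' @param y Binary labels (logical or 0/1), one per row of `x`.
#' @param criterion `"entropy"` (natural log, default) or `"gini"`.
#' @return An `edura_tree` object; see [tidy.edura_tree()] for the per-node
#'   table.
#' @export
fit_tree <- function(x, y, criterion = c("entropy", "gini")) {
  criterion <- match.arg(criterion)
  xm <- as.matrix(x)
  storage.mode(xm) <- "double"
  yv <- as.integer(as.logical(y))
  if (length(yv) != nrow(xm)) abort("`x` and `y` lengths differ.",
                                    class = "edura_parameter_error")
  if (anyNA(xm) || anyNA(yv)) abort("missing values are not supported.",
                                    class = "edura_parameter_error")
  res <- cpp_fit_tree(xm, yv, criterion == "gini")
  nodes <- as_tibble(res)
  nodes$leaf <- is.na(nodes$feature)
  structure(list(nodes = nodes, criterion = criterion,
                 n_features = ncol(xm),
                 feature_names = colnames(xm) %||% paste0("x", seq_len(ncol(xm))),
                 n_samples = nrow(xm)),
            class = "edura_tree")
}

#' @export
print.edura_tree <- function(x, ...) {
  cat("<edura_tree> ", x$criterion, " criterion, ", nrow(x$nodes), " nodes, ",
      sum(x$nodes$leaf), " leaves, ", x$n_samples, " samples\n", sep = "")
  invisible(x)
}

#' Mean-decrease-impurity feature importance
#'
#' For every internal node splitting on feature `i`, adds
#' `n_node * (impurity - weighted child impurity)` to feature `i`, then
#' normalizes the vector to sum to 1. A tree with no split yields all
#' zeros.
#'
#' @param tree An `edura_tree` from [fit_tree()].
#' @return Tibble with columns `feature` and `importance`.
#' @export
mdi_importance <- function(tree) {
  nodes <- tree$nodes[!tree$nodes$leaf, , drop = FALSE]
  imp <- numeric(tree$n_features)
  if (nrow(nodes) > 0) {
    contrib <- nodes$n * (nodes$impurity - nodes$child_impurity)
    for (i in seq_len(nrow(nodes))) {
      imp[nodes$feature[i]] <- imp[nodes$feature[i]] + contrib[i]
    }
    tot <- sum(imp)
    if (tot > 0) imp <- imp / tot
  }
  tibble(feature = tree$feature_names, importance = imp)
}

#' Shuffle-corrected feature importance
#'
#' Raw MDI importance of a tree fit on `(x, y)`, minus the mean importance
#' over `n_shuffles` refits with the labels permuted (class counts
#' preserved). Negative corrected values indicate a feature used less than
#' chance. A constant label vector yields all zeros with the `degenerate`
#' attribute set.
#'
#' @inheritParams fit_tree
#' @param n_shuffles Number of label permutations (default 100).
#' @param seed Optional integer seed.
#' @return An `edura_importance` tibble with columns `feature`, `raw`,
#'   `shuffled_mean`, `corrected`.
#' @export
corrected_importance <- function(x, y, criterion = c("entropy", "gini"),
                                 n_shuffles = 100, seed = NULL) {
  criterion <- match.arg(criterion)
  if (!is.null(seed)) set.seed(seed)
  y <- as.logical(y)
  nms <- colnames(as.data.frame(x)) %||% paste0("x", seq_len(ncol(x)))
  if (length(unique(y)) < 2) {
    out <- tibble(feature = nms, raw = 0, shuffled_mean = 0, corrected = 0)
    attr(out, "degenerate") <- TRUE
    class(out) <- c("edura_importance", class(tibble()))
    return(out)
  }
  xm <- as.matrix(x); storage.mode(xm) <- "double"
  raw <- mdi_importance(fit_tree(xm, y, criterion))$importance
  acc <- numeric(length(raw))
  for (s in seq_len(n_shuffles)) {
    ys <- sample(y)
    acc <- acc + mdi_importance(fit_tree(xm, ys, criterion))$importance
  }
  shuf <- acc / n_shuffles
  out <- tibble(feature = nms, raw = raw, shuffled_mean = shuf,
                corrected = raw - shuf)
  attr(out, "degenerate") <- FALSE
  attr(out, "n_shuffles") <- n_shuffles
  class(out) <- c("edura_importance", class(tibble()))
  out
}

.feature_classes <- c(pos_oric = "dual", crp_density = "analog",
                      hns_density = "analog", fis_density = "analog",
                      gpn_cont = "analog", trn_cont = "digital",
                      hns_dig_cont = "digital", fis_dig_cont = "digital",
                      crp_dig_cont = "digital")

#' Correlate feature importances with control strengths across contrasts
#'
#' Spearman rank correlation (average ranks on ties) of every corrected
#' importance column with the analog and digital CTC across contrasts. The
#' two CTC columns themselves are appended as additional rows, so their
#' mutual anti-correlation is visible in the same table.
#'
#' @param profiles Tibble of corrected importances, one row per contrast:
#'   a `contrast_id` column plus one column per feature.
#' @param ctc_table Tibble with `contrast_id`, `digital_ctc`, `analog_ctc`
#'   (e.g. a [control_scan()] result).
#' @return Tibble with `feature`, `feature_class` (analog / digital / dual
#'   / ctc), `spearman_analog`, `spearman_digital`; constant columns give 0
#'   and are flagged in `degenerate`.
#' @export
importance_ctc_correlation <- function(profiles, ctc_table) {
  merged <- dplyr::inner_join(profiles, ctc_table[, c("contrast_id", "digital_ctc", "analog_ctc")],
                              by = "contrast_id")
  if (nrow(merged) < 3) {
    abort("need at least 3 contrasts for rank correlations.",
          class = "edura_parameter_error")
  }
  feats <- setdiff(names(profiles), "contrast_id")
  cols <- c(feats, "digital_ctc", "analog_ctc")
  rows <- lapply(cols, function(f) {
    v <- merged[[f]]
    degen <- sd(v) == 0
    sp_a <- if (degen || sd(merged$analog_ctc) == 0) 0 else
      cor(v, merged$analog_ctc, method = "spearman")
    sp_d <- if (degen || sd(merged$digital_ctc) == 0) 0 else
      cor(v, merged$digital_ctc, method = "spearman")
    tibble(feature = f,
           feature_class = unname(.feature_classes[f]) %||% "ctc",
           spearman_analog = sp_a, spearman_digital = sp_d,
           degenerate = degen)
  })
  out <- dplyr::bind_rows(rows)
  out$feature_class[is.na(out$feature_class)] <- "ctc"
  out
}
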