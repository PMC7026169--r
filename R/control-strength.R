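#' Analysis configuration
#'
#' Bundles the tunable thresholds of the functional analysis. Defaults
#' follow the reference setting: logFC threshold `t_fc = 2.5`, proximity
#' threshold `t_gpn = 20000` bp, `n_null = 10000` null-model draws,
#' `n_steps = 5000` accepted swaps per randomization, `n_shuffles = 100`
#' label shuffles for importance correction.
#'
#' @param t_fc Positive logFC threshold.
#' @param t_gpn Positive GPN distance threshold (bp).
#' @param n_null Null-model draws for CTC.
#' @param n_random Randomized graphs per axis-scan baseline.
#' @param n_steps Accepted swaps per randomization.
#' @param n_shuffles Label shuffles for corrected importance.
#' @param seed Integer seed from which all substreams derive.
#' @return A list of class `edura_config`.
#' @export
analysis_config <- function(t_fc = 2.5, t_gpn = 20000, n_null = 10000,
                            n_random = 100, n_steps = 5000, n_shuffles = 100,
                            seed = 1L) {
  if (t_fc <= 0 || t_gpn <= 0) {
    abort("thresholds must be positive.", class = "edura_parameter_error")
  }
  structure(list(t_fc = t_fc, t_gpn = t_gpn, n_null = n_null,
                 n_random = n_random, n_steps = n_steps,
                 n_shuffles = n_shuffles, seed = as.integer(seed)),
            class = "edura_config")
}

#' Read a logFC contrast matrix
#'
#' TSV whose first column is `gene_id` and whose remaining columns are
#' contrasts; cells hold logFC values and may be empty (missing).
#'
#' @param path Path to the TSV file.
#' @return A tibble (genes x contrasts) with first column `gene_id`.
#' @export
read_contrasts <- function(path) {
  tab <- read_edura_tsv(path)
  names(tab)[1] <- "gene_id"
  tab$gene_id <- as.character(tab$gene_id)
  as_tibble(tab)
}

#' Differential-expression calls from a contrast matrix
#'
#' Three call modes on the per-gene logFC: `absdge` (`|logFC| > t_fc`),
#' `posdge` (`logFC > t_fc`), `negdge` (`logFC < -t_fc`). All inequalities
#' are strict; a gene at exactly the threshold is not called, and missing
#' values are never called.
#'
#' @param contrasts Contrast matrix tibble (first column `gene_id`).
#' @param t_fc Positive threshold.
#' @param mode One of `"absdge"`, `"posdge"`, `"negdge"`.
#' @return Long tibble with columns `contrast_id`, `gene_id`, `logfc` of
#'   called genes.
#' @export
differential_calls <- function(contrasts, t_fc = 2.5, mode = c("absdge", "posdge", "negdge")) {
  mode <- match.arg(mode)
  if (t_fc <= 0) abort("`t_fc` must be positive.", class = "edura_parameter_error")
  long <- tidyr::pivot_longer(contrasts, -"gene_id",
                              names_to = "contrast_id", values_to = "logfc")
  long <- dplyr::filter(long, !is.na(.data$logfc))
  called <- switch(mode,
    absdge = dplyr::filter(long, abs(.data$logfc) > t_fc),
    posdge = dplyr::filter(long, .data$logfc > t_fc),
    negdge = dplyr::filter(long, .data$logfc < -t_fc))
  dplyr::select(called, "contrast_id", "gene_id", "logfc")
}

#' Effective network of one contrast
#'
#' Induced subgraph of a base graph (TRN or GPN) on the called genes; genes
#' absent from the base graph are dropped.
#'
#' @param graph Base `igraph`.
#' @param genes Character vector of called gene ids.
#' @return The induced `igraph`.
#' @export
effective_subgraph <- function(graph, genes) {
  keep <- intersect(genes, igraph::V(graph)$name)
  igraph::induced_subgraph(graph, keep)
}

#' Extended effective TRN
#'
#' Induced subgraph on the called genes plus all their TRN neighbors in
#' either direction; the vertex attribute `called` distinguishes the two.
#'
#' @inheritParams effective_subgraph
#' @return An `igraph` with logical vertex attribute `called`.
#' @export
extended_subgraph <- function(graph, genes) {
  called <- intersect(genes, igraph::V(graph)$name)
  if (length(called) == 0) {
    sub <- igraph::induced_subgraph(graph, called)
    return(igraph::set_vertex_attr(sub, "called", value = logical(0)))
  }
  nbl <- igraph::adjacent_vertices(graph, called, mode = "all")
  nb <- unique(unlist(lapply(nbl, function(v) v$name)))
  nodes <- union(called, nb)
  sub <- igraph::induced_subgraph(graph, nodes)
  igraph::set_vertex_attr(sub, "called", value = igraph::V(sub)$name %in% called)
}

#' Control ratio of an effective network
#'
#' `n_connected` is the number of nodes with non-zero degree in the
#' subgraph, `n_isolated` the number with degree zero, and the ratio
#' `R = n_connected / max(n_isolated, 1)` (the denominator is clamped at 1
#' so that a fully connected effective network has a finite ratio).
#'
#' @param effnet An `igraph` (typically from [effective_subgraph()]).
#' @return One-row tibble with `n_connected`, `n_isolated`, `ratio`.
#' @export
control_ratio <- function(effnet) {
  n <- igraph::vcount(effnet)
  if (n == 0) return(tibble(n_connected = 0L, n_isolated = 0L, ratio = 0))
  deg <- igraph::degree(effnet, mode = "all")
  nc <- sum(deg > 0)
  ni <- n - nc
  tibble(n_connected = nc, n_isolated = ni, ratio = nc / max(ni, 1))
}

# Precompute the sparse symmetric adjacency of `graph` over `universe`.
# Self-loops give a diagonal 1 so loop-only nodes count as connected.
ctc_prepare <- function(graph, universe) {
  u <- as.character(universe)
  idx <- setNames(seq_along(u), u)
  el <- igraph::as_edgelist(graph)
  keep <- el[, 1] %in% u & el[, 2] %in% u
  el <- el[keep, , drop = FALSE]
  i <- unname(idx[el[, 1]]); j <- unname(idx[el[, 2]])
  A <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i),
                            x = 1, dims = c(length(u), length(u)))
  A@x[] <- 1  # collapse duplicates / reciprocal edges to 0/1
  list(A = A, universe = u, idx = idx)
}

# ratio statistic for one membership logical/index set, via the adjacency
ctc_ratio_obs <- function(prep, members, statistic) {
  k <- length(members)
  if (k == 0) return(0)
  m <- numeric(length(prep$universe)); m[members] <- 1
  conn <- sum(m * (as.numeric(prep$A %*% m) > 0))
  if (statistic == "connected") return(conn)
  conn / max(k - conn, 1)
}

# null distribution of the statistic for subsets of size k, chunked matmul
ctc_null_stats <- function(prep, k, n_null, statistic, chunk = 2500L) {
  U <- length(prep$universe)
  vals <- numeric(n_null)
  done <- 0L
  while (done < n_null) {
    b <- min(chunk, n_null - done)
    draws <- vapply(seq_len(b), function(i) sample.int(U, k), integer(k))
    draws <- matrix(draws, nrow = k)
    M <- matrix(0, nrow = U, ncol = b)
    M[cbind(as.vector(draws), rep(seq_len(b), each = k))] <- 1
    P <- as.matrix(prep$A %*% M)
    conn <- colSums((P > 0) * M)
    vals[done + seq_len(b)] <- if (statistic == "connected") conn
                               else conn / pmax(k - conn, 1)
    done <- done + b
  }
  vals
}

#' Control type confidence (CTC) of a called gene set
#'
#' z-score of the control ratio of the effective network against a null
#' model that places the same number of genes at random in the universe
#' (the base-graph node set for digital control, all genome genes for
#' analog control), with the null mean and SD estimated from `n_null`
#' draws.
#'
#' @param graph Base `igraph` (TRN for digital, GPN for analog control).
#' @param called Character vector of called gene ids.
#' @param universe Node universe for the null (default the graph's nodes).
#' @param n_null Number of null draws (default 10000).
#' @param statistic `"ratio"` (default) or `"connected"` (the raw count of
#'   non-isolated nodes).
#' @param seed Optional integer seed.
#' @return One-row tibble with `n_called`, `n_connected`, `n_isolated`,
#'   `ratio`, `null_mean`, `null_sd`, `z_score`, `n_null`, `degenerate`.
#' @export
ctc <- function(graph, called, universe = igraph::V(graph)$name,
                n_null = 10000, statistic = c("ratio", "connected"),
                seed = NULL) {
  statistic <- match.arg(statistic)
  if (!is.null(seed)) set.seed(seed)
  prep <- ctc_prepare(graph, universe)
  members <- unname(prep$idx[intersect(as.character(called), prep$universe)])
  k <- length(members)
  if (k == 0) {
    abort("no called genes intersect the universe.", class = "edura_empty_call")
  }
  cr <- control_ratio(effective_subgraph(graph, intersect(called, igraph::V(graph)$name)))
  r_obs <- ctc_ratio_obs(prep, members, statistic)
  nulls <- ctc_null_stats(prep, k, n_null, statistic)
  mu <- mean(nulls); sigma <- sd(nulls)
  degen <- !is.finite(sigma) || sigma == 0
  z <- if (degen) 0 else (r_obs - mu) / sigma
  tibble(n_called = k, n_connected = cr$n_connected, n_isolated = cr$n_isolated,
         ratio = r_obs, null_mean = mu, null_sd = sigma, z_score = z,
         n_null = as.integer(n_null), degenerate = degen)
}

#' Analog control strength against a uniform-position null
#'
#' Variant of the analog [ctc()] whose null draws place the same number of
#' genes at *uniform random positions* on the circle instead of resampling
#' the existing gene positions; use it to ask whether a signal depends on
#' the empirical gene-density profile. Proximity is the same inclusive
#' circular threshold as the GPN.
#'
#' @param genome A [circular_genome()].
#' @param called Character vector of called gene ids.
#' @param t_gpn Proximity threshold in bp (default 20000).
#' @param n_null Number of null draws.
#' @param seed Optional integer seed.
#' @return One-row tibble as in [ctc()].
#' @export
analog_ctc_uniform <- function(genome, called, t_gpn = 20000, n_null = 10000,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- genome_length(genome)
  cen <- genome$center[match(intersect(called, genome$gene_id), genome$gene_id)]
  k <- length(cen)
  if (k == 0) abort("no called genes found in the genome.", class = "edura_empty_call")
  conn_count <- function(pos) {
    if (length(pos) < 2) return(0L)
    s <- sort(pos)
    gap_next <- c(diff(s), s[1] + g - s[length(s)])
    near <- gap_next <= t_gpn
    sum(near | c(near[length(near)], near[-length(near)]))
  }
  ratio_of <- function(pos) {
    nc <- conn_count(pos)
    nc / max(length(pos) - nc, 1)
  }
  r_obs <- ratio_of(cen)
  nulls <- vapply(seq_len(n_null), function(i) ratio_of(runif(k, 0, g)),
                  numeric(1))
  mu <- mean(nulls); sigma <- sd(nulls)
  degen <- !is.finite(sigma) || sigma == 0
  nc <- conn_count(cen)
  tibble(n_called = k, n_connected = nc, n_isolated = k - nc,
         ratio = r_obs, null_mean = mu, null_sd = sigma,
         z_score = if (degen) 0 else (r_obs - mu) / sigma,
         n_null = as.integer(n_null), degenerate = degen)
}

#' Operon-level differential-expression calls
#'
#' An operon is called when any member gene is called. In `posdge`/`negdge`
#' mode an operon with members past both thresholds raises a conflict
#' warning and is assigned by the member with the largest `|logFC|`.
#'
#' @param contrasts Contrast matrix tibble (first column `gene_id`).
#' @param operons Tibble mapping `gene_id` to `operon_id`; must cover all
#'   called genes.
#' @param t_fc Positive threshold.
#' @param mode Call mode as in [differential_calls()].
#' @return Tibble with columns `contrast_id`, `operon_id`.
#' @export
operon_calls <- function(contrasts, operons, t_fc = 2.5,
                         mode = c("absdge", "posdge", "negdge")) {
  mode <- match.arg(mode)
  any_called <- differential_calls(contrasts, t_fc, "absdge")
  unmapped <- setdiff(unique(any_called$gene_id), operons$gene_id)
  if (length(unmapped) > 0) {
    abort(paste0("called genes missing from the operon map: ",
                 paste(head(unmapped, 5), collapse = ", ")),
          class = "edura_unmapped_gene")
  }
  joined <- dplyr::inner_join(any_called, operons, by = "gene_id")
  per_op <- dplyr::summarise(
    dplyr::group_by(joined, .data$contrast_id, .data$operon_id),
    up = any(.data$logfc > t_fc), down = any(.data$logfc < -t_fc),
    top_sign = sign(.data$logfc[which.max(abs(.data$logfc))]),
    .groups = "drop")
  if (mode == "absdge") {
    return(dplyr::select(per_op, "contrast_id", "operon_id"))
  }
  conflicts <- per_op$up & per_op$down
  if (any(conflicts)) {
    warn(paste0(sum(conflicts), " operon call(s) with both up- and ",
                "down-regulated members; assigned by largest |logFC|."))
  }
  keep <- if (mode == "posdge") {
    (per_op$up & !per_op$down) | (conflicts & per_op$top_sign > 0)
  } else {
    (per_op$down & !per_op$up) | (conflicts & per_op$top_sign < 0)
  }
  dplyr::select(per_op[keep, , drop = FALSE], "contrast_id", "operon_id")
}

#' Digital and analog control strengths across contrasts
#'
#' For every contrast, computes the digital CTC (effective TRN against the
#' TRN-node null) and the analog CTC (effective GPN against the all-genes
#' null), then the Spearman rank correlation of the two across contrasts.
#' Contrasts with no called genes are skipped with a message.
#'
#' @param contrasts Contrast matrix tibble (first column `gene_id`).
#' @param trn Directed `igraph` (TRN).
#' @param gpn Undirected `igraph` (GPN).
#' @param genome A [circular_genome()] giving the analog null universe.
#' @param config An [analysis_config()].
#' @param mode Call mode as in [differential_calls()].
#' @return An `edura_control_scan` tibble (one row per retained contrast)
#'   with columns `contrast_id`, `n_called`, `digital_ctc`, `analog_ctc`
#'   plus null details; attribute `spearman` holds the rank correlation.
#' @export
control_scan <- function(contrasts, trn, gpn, genome,
                         config = analysis_config(),
                         mode = c("absdge", "posdge", "negdge")) {
  mode <- match.arg(mode)
  calls <- differential_calls(contrasts, config$t_fc, mode)
  ids <- setdiff(names(contrasts), "gene_id")
  set.seed(config$seed)
  prep_trn <- ctc_prepare(trn, igraph::V(trn)$name)
  prep_gpn <- ctc_prepare(gpn, genome$gene_id)
  rows <- vector("list", length(ids))
  skipped <- character(0)
  for (ci in seq_along(ids)) {
    id <- ids[ci]
    genes <- calls$gene_id[calls$contrast_id == id]
    res <- one_contrast_ctc(genes, prep_trn, prep_gpn, config$n_null)
    if (is.null(res)) { skipped <- c(skipped, id); next }
    res$contrast_id <- id
    rows[[ci]] <- res
  }
  if (length(skipped) > 0) {
    inform(paste0("skipped ", length(skipped), " contrast(s) with no called genes."))
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) abort("all contrasts empty.", class = "edura_empty_call")
  out <- dplyr::relocate(out, "contrast_id")
  out$mode <- mode
  sp <- if (nrow(out) >= 2) {
    suppressWarnings(cor(out$digital_ctc, out$analog_ctc, method = "spearman"))
  } else NA_real_
  attr(out, "spearman") <- sp
  class(out) <- c("edura_control_scan", class(tibble()))
  out
}

one_contrast_ctc <- function(genes, prep_trn, prep_gpn, n_null) {
  md <- unname(prep_trn$idx[intersect(genes, prep_trn$universe)])
  ma <- unname(prep_gpn$idx[intersect(genes, prep_gpn$universe)])
  if (length(md) == 0 || length(ma) == 0) return(NULL)
  zd <- ctc_from_prep(prep_trn, md, n_null)
  za <- ctc_from_prep(prep_gpn, ma, n_null)
  tibble(n_called = length(unique(genes)),
         digital_ctc = zd$z, digital_ratio = zd$r,
         digital_null_mean = zd$mu, digital_null_sd = zd$sigma,
         analog_ctc = za$z, analog_ratio = za$r,
         analog_null_mean = za$mu, analog_null_sd = za$sigma)
}

ctc_from_prep <- function(prep, members, n_null) {
  r <- ctc_ratio_obs(prep, members, "ratio")
  nulls <- ctc_null_stats(prep, length(members), n_null, "ratio")
  mu <- mean(nulls); sigma <- sd(nulls)
  z <- if (!is.finite(sigma) || sigma == 0) 0 else (r - mu) / sigma
  list(r = r, mu = mu, sigma = sigma, z = z)
}

#' @export
glance.edura_control_scan <- function(x, ...) {
  tibble(n_contrasts = nrow(x),
         spearman = attr(x, "spearman"),
         mean_digital_ctc = mean(x$digital_ctc),
         mean_analog_ctc = mean(x$analog_ctc))
}
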