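#' Degree-preserving switch randomization
#'
#' Rewires a directed graph by repeated double-edge swaps
#' `(a->b, c->d) => (a->d, c->b)`, rejecting swaps that would create a
#' self-loop or a duplicate edge. `n_steps` counts *accepted* swaps, so the
#' amount of mixing does not depend on the rejection rate; a safety cap of
#' `100 * n_steps` attempts guards against livelock. Gene positions (vertex
#' attributes) and existing self-loops are untouched, and every node keeps
#' its in- and out-degree exactly.
#'
#' @param graph Directed `igraph`.
#' @param n_steps Number of accepted swaps (default 5000).
#' @param seed Optional integer seed.
#' @return A rewired `igraph` with the same vertices and vertex attributes.
#' @export
switch_randomize <- function(graph, n_steps = 5000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  el <- igraph::as_edgelist(graph, names = FALSE)
  loop <- el[, 1] == el[, 2]
  ml <- el[loop, , drop = FALSE]
  el <- el[!loop, , drop = FALSE]
  if (nrow(el) < 2) {
    warn("fewer than 2 non-loop edges; returning the graph unchanged.")
    return(graph)
  }
  res <- cpp_switch_randomize(el[, 1], el[, 2], igraph::vcount(graph),
                              as.integer(n_steps), 100 * as.double(n_steps))
  if (!res$converged) {
    abort(paste0("switch randomization did not reach ", n_steps,
                 " accepted swaps within ", format(100 * n_steps, scientific = FALSE),
                 " attempts."), class = "edura_randomization_error")
  }
  new_el <- rbind(cbind(res$src, res$dst), ml)
  out <- igraph::make_empty_graph(igraph::vcount(graph), directed = TRUE)
  out <- igraph::add_edges(out, t(new_el))
  for (a in igraph::vertex_attr_names(graph)) {
    out <- igraph::set_vertex_attr(out, a, value = igraph::vertex_attr(graph, a))
  }
  out
}

# sample k distinct unordered index pairs (i < j by position in `pool`)
sample_unordered_pairs <- function(pool, k) {
  m <- length(pool)
  cap <- m * (m - 1) / 2
  if (k > cap) abort("requested more pairs than available.", class = "edura_capacity_error")
  if (k == 0) return(matrix(integer(0), ncol = 2))
  picked <- matrix(integer(0), ncol = 2)
  while (nrow(picked) < k) {
    need <- k - nrow(picked)
    i <- sample.int(m, 2 * need + 10, replace = TRUE)
    j <- sample.int(m, 2 * need + 10, replace = TRUE)
    ok <- i != j
    pr <- cbind(pmin(i[ok], j[ok]), pmax(i[ok], j[ok]))
    picked <- unique(rbind(picked, pr))
  }
  picked <- picked[seq_len(k), , drop = FALSE]
  cbind(pool[picked[, 1]], pool[picked[, 2]])
}

# sample k distinct ordered pairs (src from `from`, dst from `to`)
sample_cross_pairs <- function(from, to, k) {
  cap <- length(from) * length(to)
  if (k > cap) abort("requested more pairs than available.", class = "edura_capacity_error")
  if (k == 0) return(matrix(integer(0), ncol = 2))
  picked <- matrix(integer(0), ncol = 2)
  while (nrow(picked) < k) {
    need <- k - nrow(picked)
    i <- sample(from, 2 * need + 10, replace = TRUE)
    j <- sample(to, 2 * need + 10, replace = TRUE)
    picked <- unique(rbind(picked, cbind(i, j)))
  }
  unname(picked[seq_len(k), , drop = FALSE])
}

#' Generate a systematic random network with a planted axis
#'
#' Creates `n_nodes` point genes (`N/2` per chromosomal arm of the axis at
#' `ori_bp`), then draws, per edge category, the requested number of
#' distinct ordered gene pairs uniformly among all pairs realizing that
#' category relative to the planted axis. Recounting categories at `ori_bp`
#' reproduces the request exactly.
#'
#' @param n_nodes Even number of genes.
#' @param counts Named vector or one-row data frame with `n_r_plus`,
#'   `n_r_minus`, `n_l_plus`, `n_l_minus`, `n_rl`, `n_lr`.
#' @param ori_bp Planted axis (Ori) position.
#' @param g Genome length.
#' @param seed Optional integer seed.
#' @return A list with elements `genome` (a [circular_genome()]) and `trn`
#'   (directed `igraph`).
#' @export
generate_systematic_network <- function(n_nodes, counts, ori_bp = 0, g = 1e6,
                                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_nodes %% 2 != 0 || n_nodes < 2) {
    abort("`n_nodes` must be an even integer >= 2.", class = "edura_parameter_error")
  }
  counts <- as.list(counts)
  if (!all(.count_cols %in% names(counts))) {
    abort(paste0("`counts` needs entries ", paste(.count_cols, collapse = ", ")),
          class = "edura_parameter_error")
  }
  half <- n_nodes / 2
  # admissible integer offsets from ori: right arm 0 < d < g/2, left g/2 < d < g
  right_max <- ceiling(g / 2) - 1
  left_span <- (g - 1) - floor(g / 2)
  if (half > right_max || half > left_span) {
    abort("genome too small for the requested number of genes.",
          class = "edura_parameter_error")
  }
  d_right <- sample.int(right_max, half)
  d_left <- floor(g / 2) + sample.int(left_span, half)
  centers <- (ori_bp + c(d_right, d_left)) %% g
  ids <- sprintf("g%04d", seq_len(n_nodes))
  genome <- circular_genome(
    tibble(gene_id = ids, start = floor(centers), end = floor(centers)), g = g)
  genome$center <- centers  # keep exact (possibly non-integer for real ori)

  dist_ori <- circular_distance(centers, ori_bp, g)
  right <- seq_len(half)
  left <- half + seq_len(half)
  # order each arm by distance to Ori so pair (closer, farther) is "+"
  r_by_d <- right[order(dist_ori[right])]
  l_by_d <- left[order(dist_ori[left])]

  cap_same <- half * (half - 1) / 2
  cap_cross <- half * half
  req <- vapply(.count_cols, function(k) as.numeric(counts[[k]]), numeric(1))
  caps <- c(cap_same, cap_same, cap_same, cap_same, cap_cross, cap_cross)
  over <- req > caps
  if (any(over)) {
    abort(paste0("unrealizable category count(s): ",
                 paste(.count_cols[over], collapse = ", ")),
          class = "edura_capacity_error")
  }

  plus_pairs <- function(arm_sorted, k) {
    pr <- sample_unordered_pairs(seq_along(arm_sorted), k)
    cbind(arm_sorted[pr[, 1]], arm_sorted[pr[, 2]])  # closer -> farther
  }
  minus_pairs <- function(arm_sorted, k) {
    pr <- sample_unordered_pairs(seq_along(arm_sorted), k)
    cbind(arm_sorted[pr[, 2]], arm_sorted[pr[, 1]])  # farther -> closer
  }
  el <- rbind(
    plus_pairs(r_by_d, req[1]),
    minus_pairs(r_by_d, req[2]),
    plus_pairs(l_by_d, req[3]),
    minus_pairs(l_by_d, req[4]),
    sample_cross_pairs(right, left, req[5]),
    sample_cross_pairs(left, right, req[6])
  )
  trn <- igraph::make_empty_graph(n_nodes, directed = TRUE)
  if (nrow(el) > 0) trn <- igraph::add_edges(trn, t(el))
  trn <- igraph::set_vertex_attr(trn, "name", value = ids)
  trn <- igraph::set_vertex_attr(trn, "center", value = centers)
  list(genome = genome, trn = trn)
}

#' Draw random node subsets for null models
#'
#' @param universe Vector of node ids (or anything sampleable).
#' @param k Subset size (`0 <= k <= length(universe)`).
#' @param n_draws Number of independent draws.
#' @param seed Optional integer seed.
#' @return A list of `n_draws` vectors, each a size-`k` sample without
#'   replacement.
#' @export
sample_node_subsets <- function(universe, k, n_draws, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (k > length(universe)) {
    abort("`k` cannot exceed the universe size.", class = "edura_parameter_error")
  }
  lapply(seq_len(n_draws), function(i) universe[sample.int(length(universe), k)])
}
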