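# Independent brute-force oracles, written scalar-style so they share no
# code path with the vectorised implementations they check.

# circular distance, scalar
oracle_cdist <- function(a, b, g) {
  d <- abs(a - b)
  if (d > g - d) g - d else d
}

# edge category of one edge, scalar if-chain
oracle_category <- function(sc, dc, ori, g) {
  arm <- function(cen) {
    d <- (cen - ori) %% g
    if (d <= g / 2) "right" else "left"
  }
  as_ <- arm(sc); at <- arm(dc)
  if (as_ == "right" && at == "left") return("rl")
  if (as_ == "left" && at == "right") return("lr")
  ds <- oracle_cdist(sc, ori, g); dt <- oracle_cdist(dc, ori, g)
  plus <- dt >= ds
  if (as_ == "right") { if (plus) "r+" else "r-" } else { if (plus) "l+" else "l-" }
}

# six category counts, brute force over edges
oracle_counts <- function(src, dst, ori, g) {
  cats <- vapply(seq_along(src),
                 function(i) oracle_category(src[i], dst[i], ori, g),
                 character(1))
  c(n_r_plus = sum(cats == "r+"), n_r_minus = sum(cats == "r-"),
    n_l_plus = sum(cats == "l+"), n_l_minus = sum(cats == "l-"),
    n_rl = sum(cats == "rl"), n_lr = sum(cats == "lr"))
}

# exhaustive best split: all features x all midpoints of consecutive
# distinct values; ties -> lowest feature index, then lowest threshold
oracle_best_split <- function(X, y, criterion = "entropy") {
  imp <- function(yv) {
    n <- length(yv); if (n == 0) return(0)
    p1 <- mean(yv); p0 <- 1 - p1
    if (criterion == "gini") return(p1 * (1 - p1) + p0 * (1 - p0))
    s <- 0
    if (p1 > 0) s <- s - p1 * log(p1)
    if (p0 > 0) s <- s - p0 * log(p0)
    s
  }
  n <- length(y)
  parent <- imp(y)
  best <- list(gain = 0, feature = NA, threshold = NA)
  for (f in seq_len(ncol(X))) {
    v <- sort(unique(X[, f]))
    if (length(v) < 2) next
    for (t in (v[-length(v)] + v[-1]) / 2) {
      l <- y[X[, f] <= t]; r <- y[X[, f] > t]
      gain <- parent - (length(l) * imp(l) + length(r) * imp(r)) / n
      if (gain > best$gain + 1e-12) best <- list(gain = gain, feature = f, threshold = t)
    }
  }
  best
}

# small embedded toy graph used across tests
toy_embedding <- function(n_genes = 12, n_edges = 20, g = 100000, seed = 1) {
  set.seed(seed)
  centers <- sort(sample(seq(0, g - 2, by = 2), n_genes))  # even, so
  # breakpoints (centers and antipodes) are integers on an even circle
  gen <- circular_genome(tibble::tibble(
    gene_id = sprintf("t%02d", seq_len(n_genes)),
    start = centers, end = centers), g = g)
  el <- unique(cbind(sample(n_genes, 3 * n_edges, replace = TRUE),
                     sample(n_genes, 3 * n_edges, replace = TRUE)))
  el <- el[el[, 1] != el[, 2], , drop = FALSE][seq_len(n_edges), , drop = FALSE]
  trn <- igraph::graph_from_data_frame(
    data.frame(from = gen$gene_id[el[, 1]], to = gen$gene_id[el[, 2]]),
    directed = TRUE,
    vertices = data.frame(name = gen$gene_id, center = gen$center))
  list(genome = gen, trn = trn)
}
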