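#' Assign a chromosomal arm relative to a candidate Ori-Ter axis
#'
#' The axis through `ori_bp` and its antipode splits the circle into two
#' arms. The "right" arm is the semicircle of increasing coordinates from
#' Ori (looking from Ori to Ter); centers exactly at Ori or Ter are assigned
#' to the right arm by convention.
#'
#' @param center Gene center coordinate(s) in `[0, g)`.
#' @param ori_bp Position of the Ori end of the axis.
#' @param g Genome length.
#' @return Character vector, `"right"` or `"left"`.
#' @export
assign_arm <- function(center, ori_bp, g) {
  d <- (center - ori_bp) %% g
  ifelse(d <= g / 2, "right", "left")
}

.category_levels <- c("r+", "r-", "l+", "l-", "rl", "lr")
.count_cols <- c("n_r_plus", "n_r_minus", "n_l_plus", "n_l_minus", "n_rl", "n_lr")

#' Categorize directed edges relative to an axis
#'
#' Each non-self-loop edge falls into one of six categories: on the right or
#' left arm pointing away from Ori (`r+`, `l+`) or towards Ori (`r-`, `l-`),
#' or across the arms (`rl` = right to left, `lr` = left to right). Same-arm
#' edges whose endpoints are equidistant from Ori count as `+`.
#'
#' @param src_center,dst_center Centers of edge source and target (vectors).
#' @param ori_bp Ori position of the candidate axis.
#' @param g Genome length.
#' @return Factor with levels `r+`, `r-`, `l+`, `l-`, `rl`, `lr`.
#' @export
categorize_edges <- function(src_center, dst_center, ori_bp, g) {
  ds <- (src_center - ori_bp) %% g
  dt <- (dst_center - ori_bp) %% g
  rs <- ds <= g / 2
  rt <- dt <= g / 2
  dist_s <- pmin(ds, g - ds)
  dist_t <- pmin(dt, g - dt)
  away <- dist_t >= dist_s
  out <- character(length(ds))
  out[rs & rt] <- ifelse(away[rs & rt], "r+", "r-")
  out[!rs & !rt] <- ifelse(away[!rs & !rt], "l+", "l-")
  out[rs & !rt] <- "rl"
  out[!rs & rt] <- "lr"
  factor(out, levels = .category_levels)
}

# Edge endpoints (centers) of a TRN embedded in a genome, self-loops split off.
edge_centers <- function(trn, genome) {
  el <- igraph::as_edgelist(trn)
  cen <- setNames(genome$center, genome$gene_id)
  missing <- setdiff(unique(c(el[, 1], el[, 2])), genome$gene_id)
  if (length(missing) > 0) {
    abort(paste0("graph genes missing from genome: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  loop <- el[, 1] == el[, 2]
  list(src = unname(cen[el[!loop, 1]]), dst = unname(cen[el[!loop, 2]]),
       n_self_loops = sum(loop))
}

#' Count the six edge categories for one axis position
#'
#' Self-loops carry no direction along an arm and are excluded from the six
#' categories; their number is reported separately.
#'
#' @param trn Directed `igraph` embedded in `genome`.
#' @param genome A [circular_genome()].
#' @param ori_bp Ori position of the candidate axis.
#' @return One-row tibble with `n_r_plus`, `n_r_minus`, `n_l_plus`,
#'   `n_l_minus`, `n_rl`, `n_lr`, and `n_self_loops`.
#' @export
count_categories <- function(trn, genome, ori_bp) {
  ec <- edge_centers(trn, genome)
  g <- genome_length(genome)
  cats <- categorize_edges(ec$src, ec$dst, ori_bp, g)
  tab <- table(cats)
  out <- as.list(as.integer(tab[.category_levels]))
  names(out) <- .count_cols
  out <- as_tibble(out)
  out$n_self_loops <- ec$n_self_loops
  out
}

#' Up/down asymmetry of one chromosomal arm
#'
#' For the right arm: `(n(r+) - n(r-)) / (n(r+) + n(r-) + n(rl))`; the left
#' arm uses `n(lr)` in the denominator. A zero denominator yields 0 with the
#' `undefined` attribute flagged.
#'
#' @param counts One-row tibble (or list) of category counts as produced by
#'   [count_categories()].
#' @param arm `"right"` or `"left"`.
#' @return Numeric value(s) in `[-1, 1]`; attribute `undefined` marks zero
#'   denominators.
#' @export
asymmetry_pm <- function(counts, arm = c("right", "left")) {
  arm <- match.arg(arm)
  if (arm == "right") {
    num <- counts$n_r_plus - counts$n_r_minus
    den <- counts$n_r_plus + counts$n_r_minus + counts$n_rl
  } else {
    num <- counts$n_l_plus - counts$n_l_minus
    den <- counts$n_l_plus + counts$n_l_minus + counts$n_lr
  }
  undef <- den == 0
  out <- ifelse(undef, 0, num / ifelse(undef, 1, den))
  attr(out, "undefined") <- undef
  out
}

#' Cross-versus-along asymmetry
#'
#' Number of edges across the arms minus the number along the arms,
#' normalized by the total: `(n(lr)+n(rl) - n(l+)-n(l-)-n(r+)-n(r-)) / sum`.
#'
#' @inheritParams asymmetry_pm
#' @return Numeric value(s) in `[-1, 1]`; attribute `undefined` marks zero
#'   denominators.
#' @export
asymmetry_cross_along <- function(counts) {
  cross <- counts$n_rl + counts$n_lr
  along <- counts$n_r_plus + counts$n_r_minus + counts$n_l_plus + counts$n_l_minus
  den <- cross + along
  undef <- den == 0
  out <- ifelse(undef, 0, (cross - along) / ifelse(undef, 1, den))
  attr(out, "undefined") <- undef
  out
}

# Vectorised category counting over many axis positions.
# Returns a matrix (length(positions) x 6) with columns .count_cols.
scan_counts <- function(src, dst, positions, g, chunk = 1024L) {
  np <- length(positions)
  out <- matrix(0L, nrow = np, ncol = 6L, dimnames = list(NULL, .count_cols))
  if (length(src) == 0 || np == 0) return(out)
  g2 <- g / 2
  for (lo in seq(1L, np, by = chunk)) {
    hi <- min(lo + chunk - 1L, np)
    pos <- positions[lo:hi]
    S <- outer(-pos, src, "+") %% g   # (src - pos) mod g, p x E
    T_ <- outer(-pos, dst, "+") %% g
    rs <- S <= g2
    rt <- T_ <= g2
    away <- pmin(T_, g - T_) >= pmin(S, g - S)
    rr <- rs & rt
    ll <- !rs & !rt
    out[lo:hi, 1] <- rowSums(rr & away)
    out[lo:hi, 2] <- rowSums(rr & !away)
    out[lo:hi, 3] <- rowSums(ll & away)
    out[lo:hi, 4] <- rowSums(ll & !away)
    out[lo:hi, 5] <- rowSums(rs & !rt)
    out[lo:hi, 6] <- rowSums(!rs & rt)
  }
  out
}

counts_to_asymmetries <- function(cm) {
  counts <- as_tibble(as.data.frame(cm))
  a_r <- asymmetry_pm(counts, "right")
  a_l <- asymmetry_pm(counts, "left")
  a_x <- asymmetry_cross_along(counts)
  tibble(a_pm_r = as.numeric(a_r), a_pm_l = as.numeric(a_l),
         a_cross_along = as.numeric(a_x),
         a_undefined = attr(a_r, "undefined") | attr(a_l, "undefined") |
           attr(a_x, "undefined"))
}

#' Default scan positions for an embedded graph
#'
#' Edge categorization is piecewise constant in the axis position between
#' "breakpoints" -- the gene centers and their antipodes. Scanning at the
#' midpoints of consecutive breakpoints therefore represents the whole curve
#' exactly.
#'
#' @param genome A [circular_genome()].
#' @return Sorted numeric vector of axis positions in `[0, g)`.
#' @export
scan_positions <- function(genome) {
  g <- genome_length(genome)
  br <- sort(unique(c(genome$center %% g, (genome$center + g / 2) %% g)))
  if (length(br) < 2) {
    abort("fewer than 2 distinct breakpoints; cannot scan.",
          class = "edura_parameter_error")
  }
  mids <- (br + c(br[-1], br[1] + g)) / 2
  sort(unique(mids %% g))
}

#' Scan all candidate axis positions (EDURA)
#'
#' Counts the six edge categories and the three asymmetries at every
#' candidate axis position. By default positions are breakpoint midpoints
#' (see [scan_positions()]); a uniform grid can be requested instead for
#' plotting.
#'
#' @param trn Directed `igraph` embedded in `genome`.
#' @param genome A [circular_genome()].
#' @param positions Optional numeric vector of axis positions; default
#'   breakpoint midpoints.
#' @param largest_cluster If `TRUE`, restrict the scan to the largest weakly
#'   connected component of `trn`.
#' @return An `edura_scan`: a tibble with one row per position holding the
#'   six counts and the raw asymmetries (`a_pm_r`, `a_pm_l`,
#'   `a_cross_along`), with attributes `genome_length` and `n_self_loops`.
#' @export
scan_axes <- function(trn, genome, positions = NULL, largest_cluster = FALSE) {
  if (largest_cluster) {
    comp <- igraph::components(trn, mode = "weak")
    trn <- igraph::induced_subgraph(trn, which(comp$membership == which.max(comp$csize)))
  }
  g <- genome_length(genome)
  if (is.null(positions)) positions <- scan_positions(genome)
  positions <- sort(unique(positions %% g))
  ec <- edge_centers(trn, genome)
  cm <- scan_counts(ec$src, ec$dst, positions, g)
  out <- dplyr::bind_cols(tibble(position = positions),
                          as_tibble(as.data.frame(cm)),
                          counts_to_asymmetries(cm))
  attr(out, "genome_length") <- g
  attr(out, "n_self_loops") <- ec$n_self_loops
  class(out) <- c("edura_scan", class(tibble()))
  out
}

#' Subtract the randomized-graph baseline from an axis scan
#'
#' The asymmetry curves of any embedded graph carry a geometry-driven
#' signal; the systematic part is isolated by subtracting the mean curves of
#' degree-preserving switch-randomized copies of the graph evaluated at the
#' same positions (gene positions stay fixed).
#'
#' @param scan An `edura_scan` from [scan_axes()].
#' @param trn,genome The graph and genome the scan was computed from.
#' @param n_random Number of randomized graphs (default 100).
#' @param n_steps Accepted swaps per randomization (default 5000).
#' @param seed Optional integer seed.
#' @return The scan with added columns `b_pm_r`, `b_pm_l`, `b_cross_along`
#'   (baseline-subtracted asymmetries).
#' @export
baseline_subtract <- function(scan, trn, genome, n_random = 100, n_steps = 5000,
                              seed = NULL) {
  stopifnot(n_random >= 1)
  if (!is.null(seed)) set.seed(seed)
  g <- attr(scan, "genome_length")
  positions <- scan$position
  acc <- matrix(0, nrow = length(positions), ncol = 3)
  for (r in seq_len(n_random)) {
    rg <- switch_randomize(trn, n_steps = n_steps)
    ec <- edge_centers(rg, genome)
    cm <- scan_counts(ec$src, ec$dst, positions, g)
    asy <- counts_to_asymmetries(cm)
    acc <- acc + as.matrix(asy[, c("a_pm_r", "a_pm_l", "a_cross_along")])
  }
  acc <- acc / n_random
  scan$b_pm_r <- scan$a_pm_r - acc[, 1]
  scan$b_pm_l <- scan$a_pm_l - acc[, 2]
  scan$b_cross_along <- scan$a_cross_along - acc[, 3]
  attr(scan, "n_random") <- n_random
  scan
}

#' Windowed Pearson correlation of two circular sequences
#'
#' Pearson correlation of `x` and `y` inside a centered window at each
#' position, treating the sequences as circular. Windows in which either
#' series is constant yield 0 and are flagged.
#'
#' @param x,y Equal-length numeric sequences (length >= `window`).
#' @param window Odd window width >= 3.
#' @return Numeric vector of correlations; attribute `degenerate` flags
#'   zero-variance windows.
#' @export
windowed_correlation <- function(x, y, window) {
  if (length(window) != 1L || window < 3 || window %% 2 == 0) {
    abort("`window` must be a single odd integer >= 3.",
          class = "edura_parameter_error")
  }
  n <- length(x)
  if (length(y) != n || n < window) {
    abort("`x` and `y` must have equal length >= `window`.",
          class = "edura_parameter_error")
  }
  h <- (window - 1) / 2
  out <- numeric(n)
  degen <- logical(n)
  for (i in seq_len(n)) {
    idx <- ((i - h):(i + h) - 1) %% n + 1
    xs <- x[idx]; ys <- y[idx]
    if (sd(xs) == 0 || sd(ys) == 0) {
      degen[i] <- TRUE
      out[i] <- 0
    } else {
      out[i] <- cor(xs, ys)
    }
  }
  attr(out, "degenerate") <- degen
  out
}

default_window <- function(n) {
  w <- max(11, ceiling(0.10 * n))
  if (w %% 2 == 0) w <- w + 1
  as.integer(min(w, if (n %% 2 == 0) n - 1 else n))
}

#' Detect the systematic axis from an axis scan
#'
#' Along most axis positions the arm asymmetries of the right and left arm
#' are strongly positively correlated because edge categories transform into
#' one another smoothly under rotation. A systematic arrangement of edges
#' reveals itself as a sharp drop of that correlation at the true axis; the
#' detected axis is the position minimizing the windowed correlation of the
#' two arm asymmetries (baseline-subtracted when available).
#'
#' Because the correlation curve is invariant under a half-turn of the
#' axis, the drop only fixes the axis *line*; with `orient = TRUE`
#' (default) the Ori end is taken to be the candidate around which the raw
#' arm asymmetries are more positive, i.e. the end from which same-arm
#' edges dominantly point away.
#'
#' @param scan An `edura_scan`, ideally after [baseline_subtract()].
#' @param window Odd window width; default the smallest odd integer >= 10%
#'   of the number of positions (minimum 11).
#' @param use_baseline Use baseline-subtracted asymmetries when present
#'   (default `TRUE`).
#' @param orient Disambiguate the two ends of the detected axis line by the
#'   sign of the local arm asymmetries (default `TRUE`).
#' @return One-row tibble with `ori_bp`, `ter_bp`, `correlation_min`, and
#'   `window`. The full correlation curve is attached as attribute
#'   `correlation_curve`.
#' @export
detect_axis <- function(scan, window = NULL, use_baseline = TRUE, orient = TRUE) {
  g <- attr(scan, "genome_length")
  has_base <- use_baseline && "b_pm_r" %in% names(scan)
  x <- if (has_base) scan$b_pm_r else scan$a_pm_r
  y <- if (has_base) scan$b_pm_l else scan$a_pm_l
  if (is.null(window)) window <- default_window(length(x))
  cc <- windowed_correlation(x, y, window)
  if (all(attr(cc, "degenerate"))) {
    abort("correlation curve undefined everywhere.", class = "edura_degenerate")
  }
  i <- which.min(cc)           # which.min returns the first (smallest position)
  if (orient) {
    n <- length(cc)
    h <- (window - 1) / 2
    anti <- (scan$position[i] + g / 2) %% g
    j <- which.min(abs(scan$position - anti))
    win_mean <- function(k) {
      idx <- ((k - h):(k + h) - 1) %% n + 1
      mean(scan$a_pm_r[idx] + scan$a_pm_l[idx])
    }
    if (win_mean(j) > win_mean(i)) i <- j
  }
  out <- tibble(ori_bp = scan$position[i],
                ter_bp = (scan$position[i] + g / 2) %% g,
                correlation_min = cc[i],
                window = as.integer(window))
  attr(out, "correlation_curve") <- as.numeric(cc)
  out
}
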