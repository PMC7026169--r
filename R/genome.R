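#' Circular (shortest-arc) distance between chromosomal coordinates
#'
#' Distance between two positions on a circular chromosome of length `g`,
#' taken along the shorter of the two arcs. The result is always in
#' `[0, g/2]`.
#'
#' @param a,b Coordinates in base pairs, in `[0, g)`. Vectorised and recycled.
#' @param g Genome length in base pairs (> 0).
#' @return Numeric vector of distances in base pairs.
#' @examples
#' circular_distance(0, 10, 100)   # 10
#' circular_distance(10, 90, 100)  # 20, the wrap-around arc
#' @export
circular_distance <- function(a, b, g) {
  if (length(g) != 1L || !is.finite(g) || g <= 0) {
    abort("`g` must be a single positive genome length.", class = "edura_invalid_genome")
  }
  d <- abs(a - b)
  pmin(d, g - d)
}

#' Chromosomal center of a gene
#'
#' The center is the average of the start and end positions. Genes that wrap
#' across the origin (`start > end`) use the midpoint of the arc running
#' forward from `start` through the origin to `end`, reduced mod `g`.
#'
#' @param start,end Gene boundaries in base pairs, in `[0, g)`. Vectorised.
#' @param g Genome length in base pairs.
#' @return Numeric vector of center coordinates in `[0, g)` (may be half-integer).
#' @export
gene_center <- function(start, end, g) {
  if (length(g) != 1L || !is.finite(g) || g <= 0) {
    abort("`g` must be a single positive genome length.", class = "edura_invalid_genome")
  }
  ifelse(start <= end,
         (start + end) / 2,
         (start + (end + g - start) / 2) %% g)
}

#' Construct a circular genome from a gene table
#'
#' @param genes Data frame with columns `gene_id`, `start`, `end`
#'   (0-based coordinates in `[0, g)`).
#' @param g Genome length in base pairs. The default is the length of the
#'   *E. coli* K-12 chromosome.
#' @return A `circular_genome`: a tibble with columns `gene_id`, `start`,
#'   `end`, `center` and a `genome_length` attribute.
#' @export
circular_genome <- function(genes, g = 4641652) {
  genes <- as_tibble(genes)
  need <- c("gene_id", "start", "end")
  missing_cols <- setdiff(need, names(genes))
  if (length(missing_cols) > 0) {
    abort(paste0("gene table lacks column(s): ", paste(missing_cols, collapse = ", ")),
          class = "edura_parse_error")
  }
  if (length(g) != 1L || !is.finite(g) || g <= 0) {
    abort("`g` must be a single positive genome length.", class = "edura_invalid_genome")
  }
  genes$gene_id <- as.character(genes$gene_id)
  for (cl in c("start", "end")) {
    v <- genes[[cl]]
    if (!is.numeric(v) || anyNA(v) || any(v != trunc(v))) {
      bad <- which(!is.finite(suppressWarnings(as.numeric(v))) | as.numeric(v) != trunc(as.numeric(v)))
      abort(paste0("non-integer `", cl, "` coordinate in row(s): ",
                   paste(head(bad, 5), collapse = ", ")),
            class = "edura_parse_error")
    }
  }
  dup <- unique(genes$gene_id[duplicated(genes$gene_id)])
  if (length(dup) > 0) {
    abort(paste0("duplicated gene_id(s): ", paste(head(dup, 5), collapse = ", ")),
          class = "edura_parse_error")
  }
  if (nrow(genes) > 0 && (any(genes$start < 0 | genes$start >= g) ||
                          any(genes$end < 0 | genes$end >= g))) {
    abort("gene coordinates must lie in [0, genome length).", class = "edura_parse_error")
  }
  out <- tibble(
    gene_id = genes$gene_id,
    start = as.numeric(genes$start),
    end = as.numeric(genes$end),
    center = gene_center(as.numeric(genes$start), as.numeric(genes$end), g)
  )
  attr(out, "genome_length") <- as.numeric(g)
  class(out) <- c("circular_genome", class(tibble()))
  out
}

#' Genome length of a circular genome
#' @param genome A `circular_genome`.
#' @return Genome length in base pairs.
#' @export
genome_length <- function(genome) {
  g <- attr(genome, "genome_length")
  if (is.null(g)) abort("not a circular_genome: missing genome_length attribute.")
  g
}

#' Read a gene annotation table
#'
#' Tab-separated file with header columns `gene_id`, `start`, `end`;
#' lines starting with `#` are ignored.
#'
#' @param path Path to the TSV file.
#' @inheritParams circular_genome
#' @return A [circular_genome()].
#' @export
read_genome <- function(path, g = 4641652) {
  tab <- read_edura_tsv(path)
  circular_genome(tab, g = g)
}

read_edura_tsv <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("input file not found: ", path), class = "edura_io_error")
  }
  readr::read_tsv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
}

#' Read a directed regulatory edge list and build the TRN
#'
#' Two-column TSV (`regulator`, `target`). Edges whose endpoints are not in
#' the genome are dropped with a warning; duplicate edges are collapsed.
#' Self-loops (autoregulation) are retained; analyses that exclude them say
#' so individually.
#'
#' @param path Path to the edge-list TSV.
#' @param genome A [circular_genome()] giving the admissible gene set.
#' @return A directed `igraph` whose vertices carry `name` and `center`.
#' @export
read_trn <- function(path, genome) {
  tab <- read_edura_tsv(path)
  if (ncol(tab) < 2) abort("edge list needs two columns (regulator, target).",
                           class = "edura_parse_error")
  build_trn(tibble(regulator = as.character(tab[[1]]), target = as.character(tab[[2]])),
            genome)
}

#' Build a TRN graph from an edge data frame
#'
#' @param edges Data frame with columns `regulator` and `target` (gene ids).
#' @param genome A [circular_genome()]; edges to genes absent from it are
#'   dropped with a warning. All genome genes become vertices.
#' @return A directed `igraph`; vertex attribute `center` holds chromosomal
#'   centers.
#' @export
build_trn <- function(edges, genome) {
  edges <- as_tibble(edges)
  known <- edges$regulator %in% genome$gene_id & edges$target %in% genome$gene_id
  n_drop <- sum(!known)
  if (n_drop > 0) {
    warn(paste0("dropped ", n_drop, " edge(s) with endpoints absent from the genome."))
  }
  edges <- edges[known, , drop = FALSE]
  edges <- dplyr::distinct(edges, .data$regulator, .data$target)
  gr <- igraph::graph_from_data_frame(
    edges, directed = TRUE,
    vertices = data.frame(name = genome$gene_id, center = genome$center)
  )
  gr
}

#' Build the gene proximity network (GPN)
#'
#' Undirected graph linking genes whose chromosomal centers are separated by
#' a circular distance less than or equal to `threshold_bp` (inclusive, so a
#' pair at exactly the threshold is linked). No self-edges.
#'
#' @param genome A [circular_genome()].
#' @param threshold_bp Distance threshold in base pairs (default 20 kbp).
#' @return An undirected `igraph` on all genome genes.
#' @export
build_gpn <- function(genome, threshold_bp = 20000) {
  if (length(threshold_bp) != 1L || !is.finite(threshold_bp) || threshold_bp < 0) {
    abort("`threshold_bp` must be a single non-negative number.",
          class = "edura_parameter_error")
  }
  g <- genome_length(genome)
  n <- nrow(genome)
  if (n == 0) {
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  ord <- order(genome$center)
  cen <- genome$center[ord]
  ids <- genome$gene_id[ord]
  # sweep: for each gene, walk forward (cyclically) while within threshold
  src <- integer(0); dst <- integer(0)
  if (n > 1) {
    from <- vector("list", n)
    for (i in seq_len(n)) {
      j <- i
      repeat {
        j2 <- if (j == n) 1L else j + 1L
        if (j2 == i) break
        d <- (cen[j2] - cen[i]) %% g
        d <- min(d, g - d)
        if (d > threshold_bp) break
        j <- j2
      }
      if (j >= i) ks <- setdiff(seq(i, j), i)
      else ks <- setdiff(c(seq(i, n), seq_len(j)), i)
      # keep each unordered pair once (i < k in sorted order handled below)
      from[[i]] <- ks
    }
    pairs <- do.call(rbind, lapply(seq_len(n), function(i) {
      ks <- from[[i]]
      if (length(ks) == 0) return(NULL)
      cbind(pmin(i, ks), pmax(i, ks))
    }))
    if (!is.null(pairs)) {
      pairs <- unique(pairs)
      # verify distance (the sweep can overshoot past the antipode on tiny circles)
      d <- circular_distance(cen[pairs[, 1]], cen[pairs[, 2]], g)
      pairs <- pairs[d <= threshold_bp, , drop = FALSE]
      src <- pairs[, 1]; dst <- pairs[, 2]
    }
  }
  gr <- igraph::graph_from_data_frame(
    data.frame(from = ids[src], to = ids[dst]),
    directed = FALSE,
    vertices = data.frame(name = genome$gene_id, center = genome$center)
  )
  gr
}

#' Read an operon map
#'
#' TSV with columns `gene_id`, `operon_id`; every gene maps to exactly one
#' operon.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `gene_id`, `operon_id`.
#' @export
read_operon_map <- function(path) {
  tab <- read_edura_tsv(path)
  if (!all(c("gene_id", "operon_id") %in% names(tab))) {
    abort("operon map needs columns gene_id, operon_id.", class = "edura_parse_error")
  }
  out <- tibble(gene_id = as.character(tab$gene_id),
                operon_id = as.character(tab$operon_id))
  dup <- unique(out$gene_id[duplicated(out$gene_id)])
  if (length(dup) > 0) {
    abort(paste0("gene(s) mapped to more than one operon: ",
                 paste(head(dup, 5), collapse = ", ")), class = "edura_parse_error")
  }
  out
}

#' Collapse a gene-level TRN to the operon level
#'
#' An operon-level edge O1 -> O2 exists when some gene in O1 regulates some
#' gene in O2 with O1 != O2; within-operon regulation is dropped, so the
#' operon graph has no self-loops.
#'
#' @param trn Directed gene-level `igraph`.
#' @param operons Data frame mapping `gene_id` to `operon_id` (all TRN genes
#'   must be covered).
#' @return A directed `igraph` on operons.
#' @export
collapse_to_operons <- function(trn, operons) {
  operons <- as_tibble(operons)
  genes <- igraph::V(trn)$name
  unmapped <- setdiff(genes, operons$gene_id)
  if (length(unmapped) > 0) {
    abort(paste0("genes missing from the operon map: ",
                 paste(head(unmapped, 5), collapse = ", "),
                 if (length(unmapped) > 5) " ..."),
          class = "edura_unmapped_gene")
  }
  map <- setNames(operons$operon_id, operons$gene_id)
  el <- igraph::as_edgelist(trn)
  ops <- sort(unique(map[genes]))
  if (nrow(el) == 0) {
    return(igraph::make_empty_graph(directed = TRUE) + igraph::vertices(ops))
  }
  oe <- tibble(from = unname(map[el[, 1]]), to = unname(map[el[, 2]]))
  oe <- dplyr::distinct(dplyr::filter(oe, .data$from != .data$to))
  igraph::graph_from_data_frame(oe, directed = TRUE, vertices = data.frame(name = ops))
}

#' Summary statistics of a graph
#'
#' Reports node/edge counts, degree extremes, the mean total degree (exactly
#' `2E/N`), the size of the largest (weakly) connected component, and the
#' degree assortativity on total degree, both for the full graph and for its
#' largest component.
#'
#' @param graph An `igraph`.
#' @return A one-row tibble.
#' @export
graph_summary <- function(graph) {
  n <- igraph::vcount(graph)
  e <- igraph::ecount(graph)
  if (n == 0) {
    return(tibble(n_nodes = 0L, n_edges = 0L, min_degree = NA_real_,
                  max_degree = NA_real_, mean_total_degree = NA_real_,
                  largest_component_nodes = 0L, largest_component_edges = 0L,
                  degree_assortativity = NA_real_,
                  degree_assortativity_largest_component = NA_real_))
  }
  deg <- igraph::degree(graph, mode = "all")
  comp <- igraph::components(graph, mode = "weak")
  big <- which.max(comp$csize)
  sub <- igraph::induced_subgraph(graph, which(comp$membership == big))
  assort <- function(gr) {
    if (igraph::ecount(gr) == 0) return(NA_real_)
    ug <- igraph::as_undirected(gr, mode = "each")
    suppressWarnings(igraph::assortativity_degree(ug))
  }
  tibble(
    n_nodes = n, n_edges = e,
    min_degree = min(deg), max_degree = max(deg),
    mean_total_degree = 2 * e / n,
    largest_component_nodes = igraph::vcount(sub),
    largest_component_edges = igraph::ecount(sub),
    degree_assortativity = assort(graph),
    degree_assortativity_largest_component = assort(sub)
  )
}

#' Write a graph summary as JSON
#' @param summary A one-row tibble from [graph_summary()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_graph_summary <- function(summary, path) {
  jsonlite::write_json(as.list(summary), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
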