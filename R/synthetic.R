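#' Generate a synthetic circular genome
#'
#' Point genes (start = end = center) at distinct integer positions, either
#' uniform on the circle or clustered (a mixture of wrapped normals) to
#' emulate nonuniform gene density.
#'
#' @param n_genes Number of genes (>= 1).
#' @param g Genome length (> `n_genes`).
#' @param density `"uniform"` or `"clustered"`.
#' @param n_clusters Number of density clusters (clustered mode).
#' @param cluster_sd SD of each wrapped-normal cluster in bp.
#' @param seed Optional integer seed.
#' @return A [circular_genome()].
#' @export
generate_genome <- function(n_genes, g = 1e6, density = c("uniform", "clustered"),
                            n_clusters = 4, cluster_sd = g / 40, seed = NULL) {
  density <- match.arg(density)
  if (!is.null(seed)) set.seed(seed)
  if (n_genes < 1) abort("`n_genes` must be >= 1.", class = "edura_parameter_error")
  if (n_genes > g) abort("`n_genes` cannot exceed `g`.", class = "edura_parameter_error")
  if (density == "uniform") {
    centers <- sample.int(g, n_genes) - 1
  } else {
    mu <- runif(n_clusters, 0, g)
    centers <- integer(0)
    while (length(centers) < n_genes) {
      need <- n_genes - length(centers)
      x <- floor((rnorm(2 * need + 10, mean = sample(mu, 2 * need + 10, replace = TRUE),
                        sd = cluster_sd)) %% g)
      centers <- unique(c(centers, x))
    }
    centers <- centers[seq_len(n_genes)]
  }
  ids <- sprintf("g%05d", seq_len(n_genes))
  circular_genome(tibble(gene_id = ids, start = centers, end = centers), g = g)
}

#' Generate a hub-dominated directed regulatory network
#'
#' `n_hubs` regulator genes receive a source-sampling weight of
#' `concentration` (others 1), so most edges emanate from a few hubs and
#' the resulting graph is disassortative, as empirical regulatory networks
#' are. Targets are uniform; no self-loops or duplicate edges; the exact
#' edge count is honored.
#'
#' @param genome A [circular_genome()] providing the gene set.
#' @param n_edges Number of distinct directed edges.
#' @param n_hubs Number of hub regulators (default 20).
#' @param concentration Source weight of a hub relative to a non-hub
#'   (default 200; `Inf` makes hubs the only sources).
#' @param seed Optional integer seed.
#' @return A directed `igraph` on all genome genes.
#' @export
generate_trn <- function(genome, n_edges, n_hubs = 20, concentration = 200,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(genome)
  if (n_edges > n * (n - 1)) {
    abort("more edges requested than distinct ordered pairs.",
          class = "edura_parameter_error")
  }
  hubs <- sample.int(n, min(n_hubs, n))
  w <- rep(1, n)
  if (is.infinite(concentration)) {
    w[] <- 0; w[hubs] <- 1
    if (n_edges > length(hubs) * (n - 1)) {
      abort("edge count infeasible with hub-only sources.",
            class = "edura_parameter_error")
    }
  } else {
    w[hubs] <- concentration
  }
  picked <- matrix(integer(0), ncol = 2)
  while (nrow(picked) < n_edges) {
    need <- n_edges - nrow(picked)
    src <- sample.int(n, 2 * need + 10, replace = TRUE, prob = w)
    dst <- sample.int(n, 2 * need + 10, replace = TRUE)
    ok <- src != dst
    picked <- unique(rbind(picked, cbind(src[ok], dst[ok])))
  }
  picked <- picked[seq_len(n_edges), , drop = FALSE]
  gr <- igraph::make_empty_graph(n, directed = TRUE)
  gr <- igraph::add_edges(gr, t(picked))
  gr <- igraph::set_vertex_attr(gr, "name", value = genome$gene_id)
  igraph::set_vertex_attr(gr, "center", value = genome$center)
}

#' Generate binding-site tables
#'
#' Either uniform positions on the circle, or sites jittered around the
#' chromosomal positions of a factor's TRN targets (`near_targets`), which
#' produces the clustered site landscapes typical of nucleoid-associated
#' proteins.
#'
#' @param genome A [circular_genome()].
#' @param n_sites Number of sites (>= 0).
#' @param placement `"uniform"` or `"near_targets"`.
#' @param trn Directed `igraph` (required for `near_targets`).
#' @param factor_gene Gene id of the factor (required for `near_targets`).
#' @param jitter_sd SD of the placement jitter in bp.
#' @param seed Optional integer seed.
#' @return Tibble with columns `site_id`, `position`.
#' @export
generate_binding_sites <- function(genome, n_sites,
                                   placement = c("uniform", "near_targets"),
                                   trn = NULL, factor_gene = NULL,
                                   jitter_sd = 5000, seed = NULL) {
  placement <- match.arg(placement)
  if (!is.null(seed)) set.seed(seed)
  g <- genome_length(genome)
  if (n_sites == 0) return(tibble(site_id = character(0), position = numeric(0)))
  if (placement == "uniform") {
    pos <- floor(runif(n_sites, 0, g))
  } else {
    if (is.null(trn) || is.null(factor_gene) ||
        !factor_gene %in% igraph::V(trn)$name) {
      abort("`near_targets` placement needs a TRN containing `factor_gene`.",
            class = "edura_parameter_error")
    }
    targets <- igraph::neighbors(trn, factor_gene, mode = "out")$name
    if (length(targets) == 0) {
      abort(paste0("factor gene '", factor_gene, "' has no TRN targets."),
            class = "edura_parameter_error")
    }
    tc <- genome$center[match(targets, genome$gene_id)]
    anchor <- sample(tc, n_sites, replace = TRUE)
    pos <- floor((anchor + rnorm(n_sites, 0, jitter_sd)) %% g)
  }
  tibble(site_id = sprintf("s%05d", seq_len(n_sites)), position = pos)
}

#' Specification of the synthetic contrast generator
#'
#' Describes how differentially expressed gene sets of one contrast arise
#' from a mixture of two mechanisms: "digital" seed events pick a regulator
#' and spread the call to its TRN successors, "analog" seed events pick a
#' focal chromosomal position and call genes in its circular neighborhood.
#'
#' @param lambda Mixing weight in `[0, 1]`; probability that a seed event
#'   is digital (1 = pure digital, 0 = pure analog).
#' @param n_seed_events Seed events per contrast.
#' @param p_d Probability a TRN successor of a digital seed is called.
#' @param w_a Analog half-window in bp (circular).
#' @param p_a Probability a gene within the analog window is called.
#' @param rho Background call probability per gene.
#' @param mu_fc,sigma_fc Mean and SD of `|logFC|` for called genes
#'   (resampled to stay strictly above `t_fc`).
#' @param sigma0 SD of the uncalled-gene noise (truncated to
#'   `|logFC| <= t_fc`).
#' @param t_fc The threshold that the generated logFC values respect.
#' @return A list of class `edura_contrast_spec`.
#' @export
contrast_spec <- function(lambda = 0.5, n_seed_events = 2, p_d = 0.7,
                          w_a = 10000, p_a = 0.3, rho = 0.001,
                          mu_fc = 4, sigma_fc = 0.5, sigma0 = 0.5,
                          t_fc = 2.5) {
  probs <- c(lambda, p_d, p_a, rho)
  if (any(probs < 0 | probs > 1)) {
    abort("lambda, p_d, p_a, rho must lie in [0, 1].", class = "edura_parameter_error")
  }
  if (mu_fc <= t_fc) {
    abort("`mu_fc` must exceed `t_fc` so called genes pass the threshold.",
          class = "edura_parameter_error")
  }
  structure(list(lambda = lambda, n_seed_events = n_seed_events, p_d = p_d,
                 w_a = w_a, p_a = p_a, rho = rho, mu_fc = mu_fc,
                 sigma_fc = sigma_fc, sigma0 = sigma0, t_fc = t_fc),
            class = "edura_contrast_spec")
}

#' Generate a synthetic logFC contrast matrix
#'
#' Draws `n_contrasts` contrasts under a [contrast_spec()]: each seed event
#' is digital with probability `lambda` (a random regulator is called
#' together with each TRN successor with probability `p_d`) and analog
#' otherwise (genes within `w_a` bp of a uniform focal position are called
#' with probability `p_a`); background calls occur with probability `rho`.
#' Called genes receive `logFC = sign * N(mu_fc, sigma_fc)` resampled to
#' exceed `t_fc` in magnitude; uncalled genes receive `N(0, sigma0)`
#' truncated to `|logFC| <= t_fc`, so threshold calls recover the ground
#' truth exactly.
#'
#' @param genome A [circular_genome()].
#' @param trn Directed `igraph`.
#' @param spec A [contrast_spec()].
#' @param n_contrasts Number of contrasts.
#' @param seed Optional integer seed.
#' @param contrast_prefix Prefix for contrast ids.
#' @return List with `contrasts` (wide tibble, `gene_id` + one column per
#'   contrast) and `truth` (long tibble `contrast_id`, `gene_id`,
#'   `mechanism` in digital/analog/background).
#' @export
generate_contrasts <- function(genome, trn, spec = contrast_spec(),
                               n_contrasts = 40, seed = NULL,
                               contrast_prefix = "c") {
  if (!is.null(seed)) set.seed(seed)
  g <- genome_length(genome)
  ids <- genome$gene_id
  n <- length(ids)
  regulators <- igraph::V(trn)$name[igraph::degree(trn, mode = "out") > 0]
  succ_of <- NULL  # lazily built adjacency list

  mat <- matrix(NA_real_, nrow = n, ncol = n_contrasts)
  truth <- vector("list", n_contrasts)
  cids <- sprintf("%s%03d", contrast_prefix, seq_len(n_contrasts))

  for (ci in seq_len(n_contrasts)) {
    mech <- rep(NA_character_, n)
    for (ev in seq_len(spec$n_seed_events)) {
      if (runif(1) < spec$lambda) {
        reg <- sample(regulators, 1)
        succ <- igraph::neighbors(trn, reg, mode = "out")$name
        hit <- succ[runif(length(succ)) < spec$p_d]
        sel <- match(c(reg, hit), ids)
        mech[sel] <- ifelse(is.na(mech[sel]), "digital", mech[sel])
      } else {
        focal <- runif(1, 0, g)
        inwin <- which(circular_distance(genome$center, focal, g) <= spec$w_a)
        hit <- inwin[runif(length(inwin)) < spec$p_a]
        mech[hit] <- ifelse(is.na(mech[hit]), "analog", mech[hit])
      }
    }
    bg <- which(runif(n) < spec$rho & is.na(mech))
    mech[bg] <- "background"
    called <- !is.na(mech)

    lfc <- numeric(n)
    nc <- sum(called)
    if (nc > 0) {
      mag <- rnorm(nc, spec$mu_fc, spec$sigma_fc)
      while (any(mag <= spec$t_fc)) {
        bad <- mag <= spec$t_fc
        mag[bad] <- rnorm(sum(bad), spec$mu_fc, spec$sigma_fc)
      }
      lfc[called] <- sample(c(-1, 1), nc, replace = TRUE) * mag
    }
    nu <- n - nc
    noise <- rnorm(nu, 0, spec$sigma0)
    while (any(abs(noise) > spec$t_fc)) {
      bad <- abs(noise) > spec$t_fc
      noise[bad] <- rnorm(sum(bad), 0, spec$sigma0)
    }
    lfc[!called] <- noise
    mat[, ci] <- lfc
    truth[[ci]] <- tibble(contrast_id = cids[ci], gene_id = ids[called],
                          mechanism = mech[called])
  }
  contrasts <- dplyr::bind_cols(tibble(gene_id = ids),
                                as_tibble(as.data.frame(mat, col.names = cids)))
  names(contrasts) <- c("gene_id", cids)
  list(contrasts = contrasts, truth = dplyr::bind_rows(truth))
}

#' Write a simulated dataset to a directory
#'
#' Writes `genes.tsv`, `edges.tsv`, `sites_fis.tsv`, `sites_hns.tsv`,
#' `sites_crp.tsv`, `contrasts.tsv` and `truth.json` in the package's input
#' formats.
#'
#' @param dir Output directory (created if needed).
#' @param genome,trn,sites,contrasts,truth Objects from the generators.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(dir, genome, trn, sites, contrasts, truth) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(tibble(gene_id = genome$gene_id, start = genome$start,
                          end = genome$end), file.path(dir, "genes.tsv"))
  el <- igraph::as_edgelist(trn)
  readr::write_tsv(tibble(regulator = el[, 1], target = el[, 2]),
                   file.path(dir, "edges.tsv"))
  for (f in names(sites)) {
    readr::write_tsv(sites[[f]], file.path(dir, paste0("sites_", f, ".tsv")))
  }
  readr::write_tsv(contrasts, file.path(dir, "contrasts.tsv"))
  jsonlite::write_json(truth, file.path(dir, "truth.json"), dataframe = "rows")
  invisible(dir)
}
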