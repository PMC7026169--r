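mk_contrasts <- function(...) {
  vals <- list(...)
  tibble::tibble(gene_id = names(vals[[1]]), !!!lapply(vals, unname))
}

test_that("differential calls use strict inequalities in all three modes", {
  cm <- tibble::tibble(gene_id = c("a", "b", "c", "d", "e"),
                       k1 = c(3, -3, 1, 2.5, NA))
  expect_setequal(differential_calls(cm, 2.5, "absdge")$gene_id, c("a", "b"))
  expect_setequal(differential_calls(cm, 2.5, "posdge")$gene_id, "a")
  expect_setequal(differential_calls(cm, 2.5, "negdge")$gene_id, "b")
  # exactly at the threshold and missing values are never called
  expect_false("d" %in% differential_calls(cm, 2.5, "absdge")$gene_id)
  expect_false("e" %in% differential_calls(cm, 2.5, "absdge")$gene_id)
  expect_error(differential_calls(cm, -1, "absdge"), class = "edura_parameter_error")
})

test_that("effective and extended subgraphs select the right nodes", {
  gen <- circular_genome(tibble::tibble(gene_id = c("h", "a", "b", "c"),
                                        start = c(0, 10, 20, 30),
                                        end = c(0, 10, 20, 30)), g = 100)
  star <- build_trn(tibble::tibble(regulator = c("h", "h", "h"),
                                   target = c("a", "b", "c")), gen)
  eff <- effective_subgraph(star, c("a", "b"))
  expect_equal(igraph::vcount(eff), 2)
  expect_equal(igraph::ecount(eff), 0)
  expect_equal(igraph::vcount(effective_subgraph(star, character(0))), 0)
  full <- effective_subgraph(star, gen$gene_id)
  expect_equal(igraph::ecount(full), 3)

  ext <- extended_subgraph(star, "a")
  expect_setequal(igraph::V(ext)$name, c("a", "h"))
  expect_equal(sum(igraph::V(ext)$called), 1)
  ext_hub <- extended_subgraph(star, "h")
  expect_setequal(igraph::V(ext_hub)$name, c("h", "a", "b", "c"))
})

test_that("control ratio counts connected and isolated nodes", {
  gr <- igraph::make_empty_graph(4, directed = FALSE)
  gr <- igraph::set_vertex_attr(gr, "name", value = letters[1:4])
  gr <- igraph::add_edges(gr, c(1, 2))
  cr <- control_ratio(gr)
  expect_equal(unlist(cr), c(n_connected = 2, n_isolated = 2, ratio = 1))

  none <- igraph::make_empty_graph(3, directed = FALSE)
  expect_equal(control_ratio(none)$ratio, 0)

  k5 <- igraph::make_full_graph(5)
  expect_equal(control_ratio(k5)$ratio, 5)  # clamped denominator

  expect_equal(control_ratio(igraph::make_empty_graph(0))$ratio, 0)
})

test_that("adding an edge between isolated called nodes never lowers R", {
  set.seed(2)
  for (i in 1:5) {
    gr <- igraph::sample_gnm(30, 25, directed = FALSE)
    gr <- igraph::set_vertex_attr(gr, "name", value = paste0("g", 1:30))
    called <- paste0("g", sample(30, 12))
    eff <- effective_subgraph(gr, called)
    iso <- igraph::V(eff)$name[igraph::degree(eff) == 0]
    if (length(iso) < 2) next
    r0 <- control_ratio(eff)$ratio
    gr2 <- igraph::add_edges(gr, match(iso[1:2], igraph::V(gr)$name))
    r1 <- control_ratio(effective_subgraph(gr2, called))$ratio
    expect_gte(r1, r0)
  }
})

test_that("CTC flags degenerate nulls and rewards planted cliques", {
  # complete graph: every null draw has the same ratio -> z = 0, flagged
  k8 <- igraph::make_full_graph(8)
  k8 <- igraph::set_vertex_attr(k8, "name", value = paste0("g", 1:8))
  res <- ctc(k8, paste0("g", 1:4), n_null = 200, seed = 1)
  expect_true(res$degenerate)
  expect_equal(res$z_score, 0)

  # a 10-clique planted in a sparse 500-node graph stands far out of the null
  set.seed(33)
  base <- igraph::sample_gnm(500, 250, directed = FALSE)
  base <- igraph::set_vertex_attr(base, "name", value = paste0("g", 1:500))
  clique_nodes <- paste0("g", 1:10)
  base <- igraph::add_edges(base, match(
    as.vector(t(combn(clique_nodes, 2))), igraph::V(base)$name))
  res <- ctc(base, clique_nodes, n_null = 2000, seed = 5)
  expect_gt(res$z_score, 3)

  expect_error(ctc(k8, "absent"), class = "edura_empty_call")
})

test_that("CTC is invariant under gene relabeling", {
  set.seed(8)
  gr <- igraph::sample_gnm(40, 60, directed = FALSE)
  gr <- igraph::set_vertex_attr(gr, "name", value = paste0("g", 1:40))
  called <- paste0("g", c(3, 7, 11, 19, 25, 30))
  r1 <- ctc(gr, called, n_null = 500, seed = 77)
  perm <- sample(40)
  gr2 <- igraph::set_vertex_attr(gr, "name", value = paste0("h", perm))
  called2 <- paste0("h", perm[c(3, 7, 11, 19, 25, 30)])
  r2 <- ctc(gr2, called2, n_null = 500, seed = 77)
  expect_equal(r1$ratio, r2$ratio)
  expect_equal(r1$n_connected, r2$n_connected)
})

test_that("operon calls follow the any-member rule and the conflict rule", {
  cm <- tibble::tibble(gene_id = c("a", "b", "c", "d"),
                       k1 = c(3, 1, -4, 1))
  ops <- tibble::tibble(gene_id = c("a", "b", "c", "d"),
                        operon_id = c("O1", "O1", "O2", "O3"))
  res <- operon_calls(cm, ops, 2.5, "absdge")
  expect_setequal(res$operon_id, c("O1", "O2"))

  # conflicting operon: a (+3) and c (-4) together; largest |logFC| wins
  ops2 <- tibble::tibble(gene_id = c("a", "b", "c", "d"),
                         operon_id = c("O1", "O1", "O1", "O3"))
  expect_warning(pos <- operon_calls(cm, ops2, 2.5, "posdge"), regexp = "both")
  expect_equal(nrow(pos), 0)  # the -4 member dominates, so not up-called
  expect_warning(neg <- operon_calls(cm, ops2, 2.5, "negdge"), regexp = "both")
  expect_equal(neg$operon_id, "O1")

  expect_error(operon_calls(cm, ops[1:2, ], 2.5, "absdge"),
               class = "edura_unmapped_gene")
})

test_that("control_scan gives identical CTC pairs to identical contrasts", {
  gen <- generate_genome(120, g = 1e5, seed = 3)
  trn <- generate_trn(gen, 300, n_hubs = 5, seed = 4)
  gpn <- build_gpn(gen, 4000)
  sim <- generate_contrasts(gen, trn, contrast_spec(lambda = 0.5, w_a = 4000),
                            n_contrasts = 2, seed = 5)
  cm <- sim$contrasts
  cm$dup1 <- cm[[2]]
  cm$dup2 <- cm[[2]]
  cfg <- analysis_config(n_null = 400, seed = 11)
  cs <- control_scan(cm[, c("gene_id", "dup1", "dup2")], trn, gpn, gen, cfg)
  expect_equal(cs$digital_ratio[1], cs$digital_ratio[2])
  expect_equal(cs$analog_ratio[1], cs$analog_ratio[2])
  # z-scores agree up to null-model Monte Carlo error
  expect_lt(abs(cs$digital_ctc[1] - cs$digital_ctc[2]), 0.5)
})

test_that("control_scan Spearman is -1 for two oppositely ordered contrasts", {
  skip_if_not_installed("withr")
  # construct two contrasts whose digital and analog CTCs order oppositely:
  # one clustered-on-the-chromosome call set, one TRN-hub-successor call set
  gen <- generate_genome(150, g = 1e5, seed = 6)
  trn <- generate_trn(gen, 350, n_hubs = 3, seed = 7)
  gpn <- build_gpn(gen, 4000)
  sim_d <- generate_contrasts(gen, trn, contrast_spec(lambda = 1, p_d = 0.9),
                              1, seed = 8, contrast_prefix = "dig")
  sim_a <- generate_contrasts(gen, trn,
                              contrast_spec(lambda = 0, w_a = 4000, p_a = 0.9),
                              1, seed = 9, contrast_prefix = "ana")
  cm <- dplyr::inner_join(sim_d$contrasts, sim_a$contrasts, by = "gene_id")
  cs <- control_scan(cm, trn, gpn, gen, analysis_config(n_null = 600, seed = 12))
  expect_equal(nrow(cs), 2)
  expect_equal(attr(cs, "spearman"), -1)
})

test_that("a contrast with no calls is skipped; all-empty input errors", {
  gen <- generate_genome(50, g = 1e5, seed = 13)
  trn <- generate_trn(gen, 100, n_hubs = 3, seed = 14)
  gpn <- build_gpn(gen, 5000)
  cm <- tibble::tibble(gene_id = gen$gene_id,
                       silent = rnorm(50, 0, 0.1))
  expect_error(control_scan(cm, trn, gpn, gen, analysis_config(n_null = 100)),
               class = "edura_empty_call")
})

test_that("the uniform-position analog null is calibrated and detects clusters", {
  gen <- generate_genome(300, g = 1e6, seed = 60)
  # clustered called set: 12 genes nearest to one focal point
  d <- circular_distance(gen$center, 123456, 1e6)
  clustered <- gen$gene_id[order(d)][1:12]
  res <- analog_ctc_uniform(gen, clustered, t_gpn = 20000, n_null = 2000,
                            seed = 61)
  expect_gt(res$z_score, 3)
  expect_equal(res$n_called, 12L)

  # uniform-position genomes: null-like called sets give small z
  set.seed(62)
  zs <- vapply(1:30, function(i) {
    analog_ctc_uniform(gen, sample(gen$gene_id, 12), t_gpn = 20000,
                       n_null = 500)$z_score
  }, numeric(1))
  expect_lt(abs(mean(zs)), 0.6)
  expect_error(analog_ctc_uniform(gen, "absent"), class = "edura_empty_call")
})
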