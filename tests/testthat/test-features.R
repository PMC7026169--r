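test_that("binding-site density uses an inclusive circular window", {
  g <- 4641652
  center <- 100000
  sites <- c(center + 10000, center + 49000, center + 51000)
  expect_equal(binding_site_density(sites, center, g), 2L)
  expect_equal(binding_site_density(center + 50000, center, g), 1L)  # boundary
  expect_equal(binding_site_density(numeric(0), center, g), 0L)
  # wrap across the origin
  expect_equal(binding_site_density(c(g - 1000, 2000), 500, g, 5000), 2L)
  # window covering the whole circle counts every site
  expect_equal(binding_site_density(c(1, 2, 3), 50, 100, 60), 3L)
})

test_that("pos_oric is the unsigned circular distance to Ori", {
  expect_equal(pos_oric(1234, 1234, 1e6), 0)
  expect_equal(pos_oric(0, 500000, 1e6), 5e5)
  expect_equal(pos_oric(75, 0, 100), 25)
})

test_that("feature table counts called neighbors, regulators and factor flags", {
  gen <- circular_genome(tibble::tibble(
    gene_id = c("fis", "x", "y", "z", "w"),
    start = c(0, 10000, 20000, 30000, 60000),
    end = c(0, 10000, 20000, 30000, 60000)), g = 100000)
  trn <- build_trn(tibble::tibble(regulator = c("fis", "fis", "x"),
                                  target = c("x", "y", "z")), gen)
  gpn <- build_gpn(gen, 15000)
  sites <- list(fis = c(5000, 95000), hns = numeric(0), crp = 25000)
  suppressWarnings(
    ft <- compute_feature_table(gen, trn, gpn, sites, called = c("x", "y"),
                                ori_bp = 0,
                                factor_genes = c(fis = "fis", hns = "hns", crp = "crp"))
  )
  expect_equal(names(ft), c("gene_id", "pos_oric", "crp_density", "hns_density",
                            "fis_density", "gpn_cont", "trn_cont",
                            "hns_dig_cont", "fis_dig_cont", "crp_dig_cont",
                            "called"))
  i <- function(id) which(ft$gene_id == id)
  # z's only GPN neighbor within 15 kbp is y (called); x is 20 kbp away
  expect_equal(ft$gpn_cont[i("z")], 1L)
  expect_equal(ft$gpn_cont[i("w")], 0L)
  # z is regulated by called x -> trn_cont 1; x regulated by uncalled fis -> 0
  expect_equal(ft$trn_cont[i("z")], 1L)
  expect_equal(ft$trn_cont[i("x")], 0L)
  # fis flag only for direct fis targets, regardless of fis being called
  expect_equal(ft$fis_dig_cont[i("x")], 1L)
  expect_equal(ft$fis_dig_cont[i("y")], 1L)
  expect_equal(ft$fis_dig_cont[i("z")], 0L)
  # hns absent from the TRN -> all-zero flag (warning)
  expect_true(all(ft$hns_dig_cont == 0))
  # isolated unregulated gene
  expect_equal(ft$gpn_cont[i("fis")] + ft$trn_cont[i("fis")], 1L)  # fis-x GPN edge
  expect_equal(ft$called, c(FALSE, TRUE, TRUE, FALSE, FALSE))
})

test_that("ancestor counting can use the transitive closure", {
  gen <- circular_genome(tibble::tibble(
    gene_id = c("a", "b", "c"), start = c(0, 10, 20), end = c(0, 10, 20)),
    g = 100)
  trn <- build_trn(tibble::tibble(regulator = c("a", "b"), target = c("b", "c")), gen)
  gpn <- build_gpn(gen, 5)
  sites <- list(fis = numeric(0), hns = numeric(0), crp = numeric(0))
  suppressWarnings({
    direct <- compute_feature_table(gen, trn, gpn, sites, called = "a", ori_bp = 0)
    trans <- compute_feature_table(gen, trn, gpn, sites, called = "a", ori_bp = 0,
                                   ancestors = TRUE)
  })
  # c is regulated directly by b (uncalled) but transitively by a (called)
  expect_equal(direct$trn_cont[3], 0L)
  expect_equal(trans$trn_cont[3], 1L)
})

test_that("tree impurities match closed forms and pure leaves stop growth", {
  # p1 = p0 = 0.5: entropy ln 2, Gini 0.5
  x <- data.frame(f = c(1, 1, 2, 2))
  y <- c(0, 1, 0, 1)
  tr <- fit_tree(x, y, "entropy")
  expect_equal(tr$nodes$impurity[1], log(2))
  expect_true(tr$nodes$leaf[1])  # no informative split exists
  trg <- fit_tree(x, y, "gini")
  expect_equal(trg$nodes$impurity[1], 0.5)

  pure <- fit_tree(data.frame(f = 1:4), c(1, 1, 1, 1))
  expect_equal(nrow(pure$nodes), 1)
  expect_equal(pure$nodes$impurity[1], 0)

  # perfectly separable 1-D data trains to zero error
  sep <- fit_tree(data.frame(f = 1:10), rep(c(0, 1), each = 5))
  expect_equal(glance(sep)$training_accuracy, 1)
  expect_error(fit_tree(data.frame(f = 1:3), c(0, 1)),
               class = "edura_parameter_error")
})

test_that("tree splits equal the exhaustive search on small datasets", {
  set.seed(55)
  for (rep in 1:12) {
    n <- sample(8:50, 1)
    p <- sample(2:5, 1)
    X <- matrix(sample(0:6, n * p, replace = TRUE) +
                  ifelse(runif(n * p) < 0.5, 0, 0.5), n, p)
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    crit <- sample(c("entropy", "gini"), 1)
    want <- oracle_best_split(X, y, crit)
    tr <- fit_tree(X, y, crit)
    root <- tr$nodes[1, ]
    if (is.na(want$feature)) {
      expect_true(root$leaf)
    } else {
      expect_equal(root$feature, want$feature)
      expect_equal(root$threshold, want$threshold)
    }
  }
})

test_that("tie-breaking picks the lowest feature index, then lowest threshold", {
  # two identical perfectly-splitting features -> feature 1 wins
  X <- cbind(a = c(0, 0, 1, 1), b = c(0, 0, 1, 1))
  tr <- fit_tree(X, c(0, 0, 1, 1))
  expect_equal(tr$nodes$feature[1], 1)
  # two thresholds with equal gain on one feature -> the lower one
  X2 <- cbind(a = c(0, 1, 2, 3))
  tr2 <- fit_tree(X2, c(0, 0, 1, 1))
  expect_equal(tr2$nodes$threshold[1], 1.5)
  X3 <- cbind(a = c(0, 1, 2))   # splitting the lone positive off: both sides tie
  tr3 <- fit_tree(X3, c(1, 0, 0))
  expect_equal(tr3$nodes$threshold[1], 0.5)
})

test_that("trees are deterministic across repeated fits", {
  set.seed(77)
  X <- matrix(rnorm(200), 40, 5)
  y <- rbinom(40, 1, 0.5)
  t1 <- fit_tree(X, y)
  t2 <- fit_tree(X, y)
  expect_identical(t1$nodes, t2$nodes)
})

test_that("MDI importances are non-negative and normalized", {
  X <- cbind(a = c(1, 2, 3, 4, 5, 6), b = c(1, 1, 0, 0, 1, 1))
  tr <- fit_tree(X, c(0, 0, 0, 1, 1, 1))
  imp <- mdi_importance(tr)
  expect_equal(imp$importance, c(1, 0))  # single split on a

  pure <- fit_tree(data.frame(a = 1:4), rep(1, 4))
  expect_equal(sum(mdi_importance(pure)$importance), 0)

  set.seed(91)
  for (i in 1:5) {
    X <- matrix(sample(0:4, 120, replace = TRUE), 30, 4)
    y <- rbinom(30, 1, 0.5)
    v <- mdi_importance(fit_tree(X, y))$importance
    expect_true(all(v >= 0))
    expect_true(abs(sum(v) - 1) < 1e-12 || sum(v) == 0)
  }
})

test_that("corrected importance centers label-independent features near zero", {
  # labels independent of every feature: the raw importance is itself a
  # draw from the shuffle null, so the correction centers it at zero
  set.seed(101)
  vals <- replicate(20, {
    X <- cbind(noise1 = rnorm(40), noise2 = rnorm(40))
    y <- sample(rep(c(0, 1), each = 20))
    ci <- corrected_importance(X, y, n_shuffles = 40)
    ci$corrected[ci$feature == "noise1"]
  })
  expect_lt(abs(mean(vals)), 0.05)

  # a perfectly predictive feature dominates the corrected ranking
  set.seed(102)
  X <- cbind(good = rep(c(0, 1), each = 25),
             n1 = rnorm(50), n2 = rnorm(50))
  y <- rep(c(0, 1), each = 25)
  ci <- corrected_importance(X, y, n_shuffles = 50, seed = 4)
  expect_equal(ci$feature[which.max(ci$corrected)], "good")

  # constant labels -> all zeros, flagged
  cz <- corrected_importance(X, rep(1, 50), n_shuffles = 10, seed = 1)
  expect_true(attr(cz, "degenerate"))
  expect_true(all(cz$corrected == 0))
})

test_that("Spearman with average ranks matches the hand-computed value", {
  x <- c(1, 2, 2, 4); y <- c(1, 2, 3, 4)
  expect_equal(round(cor(x, y, method = "spearman"), 4), 0.9487)
})

test_that("importance-CTC correlation recovers perfect and reversed rankings", {
  profiles <- tibble::tibble(contrast_id = paste0("c", 1:5),
                             f_up = c(1, 2, 3, 4, 5),
                             f_down = c(5, 4, 3, 2, 1),
                             f_flat = rep(1, 5))
  ctc_tab <- tibble::tibble(contrast_id = paste0("c", 1:5),
                            analog_ctc = c(1, 2, 3, 4, 5),
                            digital_ctc = c(5, 4, 3, 2, 1))
  res <- importance_ctc_correlation(profiles, ctc_tab)
  expect_equal(res$spearman_analog[res$feature == "f_up"], 1)
  expect_equal(res$spearman_analog[res$feature == "f_down"], -1)
  expect_equal(res$spearman_analog[res$feature == "f_flat"], 0)
  expect_true(res$degenerate[res$feature == "f_flat"])
  # the appended CTC columns expose their own anti-correlation
  expect_equal(res$spearman_digital[res$feature == "analog_ctc"], -1)
  expect_error(importance_ctc_correlation(profiles[1:2, ], ctc_tab),
               class = "edura_parameter_error")
})

test_that("operon aggregation averages features and applies the any-member rule", {
  ft <- tibble::tibble(
    gene_id = c("a", "b", "c"),
    pos_oric = c(10, 30, 100), crp_density = c(1, 3, 5),
    hns_density = c(0, 0, 2), fis_density = c(2, 4, 6),
    gpn_cont = c(1, 1, 0), trn_cont = c(0, 2, 0),
    hns_dig_cont = c(0, 1, 0), fis_dig_cont = c(1, 1, 0),
    crp_dig_cont = c(0, 0, 0), called = c(TRUE, FALSE, FALSE))
  ops <- tibble::tibble(gene_id = c("a", "b", "c"),
                        operon_id = c("O1", "O1", "O2"))
  agg <- operon_feature_table(ft, ops)
  o1 <- agg[agg$operon_id == "O1", ]
  expect_equal(o1$pos_oric, 20)
  expect_equal(o1$trn_cont, 1)
  expect_true(o1$called)
  expect_false(agg$called[agg$operon_id == "O2"])
  expect_error(operon_feature_table(ft, ops[1:2, ]), class = "edura_unmapped_gene")
})
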