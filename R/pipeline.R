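#' Run the full analysis pipeline on input tables
#'
#' Orchestrates the three analyses on files in the package's TSV formats:
#' the EDURA axis scan (with randomized baseline and axis detection), the
#' digital/analog control scan in all three call modes, and the per-contrast
#' shuffle-corrected decision-tree importances with their CTC correlations.
#' All outputs, a parameter/seed log, and an input checksum manifest are
#' written to `out_dir`.
#'
#' @param genes,edges,contrasts Paths to the annotation, edge-list and
#'   contrast TSVs.
#' @param sites Named list of site-table paths (`fis`, `hns`, `crp`);
#'   `NULL` skips the feature stage.
#' @param out_dir Output directory.
#' @param g Genome length in bp.
#' @param ori_bp Ori position used for the `pos_oric` feature.
#' @param config An [analysis_config()]; its seed drives every random
#'   substream.
#' @param factor_genes Named character vector of the fis/hns/crp gene ids.
#' @param operons Optional path to an operon map TSV; when given, the
#'   control scan is additionally run at the operon level.
#' @param window Correlation window for axis detection (default automatic).
#' @return Invisibly, a list with the in-memory results (`scan`, `axis`,
#'   `control` per mode, `importance`, `correlations`).
#' @export
run_all <- function(genes, edges, contrasts, sites = NULL, out_dir,
                    g = 4641652, ori_bp = 0, config = analysis_config(),
                    factor_genes = c(fis = "fis", hns = "hns", crp = "crp"),
                    operons = NULL, window = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  inputs <- c(genes = genes, edges = edges, contrasts = contrasts,
              unlist(sites), operons = operons)
  for (p in inputs) {
    if (!file.exists(p)) abort(paste0("input file not found: ", p),
                               class = "edura_io_error")
  }
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) cat(format(Sys.time(), "%H:%M:%S"), " ", ...,
                            "\n", sep = "", file = log_path, append = TRUE)
  cat("", file = log_path)
  logf("parameters: g=", g, " ori_bp=", ori_bp, " t_fc=", config$t_fc,
       " t_gpn=", config$t_gpn, " n_null=", config$n_null,
       " n_random=", config$n_random, " n_steps=", config$n_steps,
       " n_shuffles=", config$n_shuffles, " seed=", config$seed)
  manifest <- tibble(input = names(inputs), path = unname(inputs),
                     md5 = unname(tools::md5sum(unname(inputs))))
  readr::write_tsv(manifest, file.path(out_dir, "manifest.tsv"))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("stage '", name, "' failed: ", conditionMessage(e)),
            class = "edura_stage_error")
    })
  }

  genome <- stage("load", read_genome(genes, g = g))
  trn <- stage("load", read_trn(edges, genome))
  gpn <- stage("load", build_gpn(genome, config$t_gpn))
  cm <- stage("load", read_contrasts(contrasts))
  logf("loaded ", nrow(genome), " genes, ", igraph::ecount(trn), " TRN edges, ",
       igraph::ecount(gpn), " GPN edges, ", ncol(cm) - 1, " contrasts")

  res <- list()
  res$scan <- stage("edura-scan", {
    sc <- scan_axes(trn, genome)
    sc <- baseline_subtract(sc, trn, genome, n_random = config$n_random,
                            n_steps = config$n_steps, seed = config$seed)
    sc
  })
  res$axis <- stage("edura-scan", detect_axis(res$scan, window = window))
  scan_out <- res$scan
  scan_out$correlation <- attr(res$axis, "correlation_curve")
  readr::write_csv(as_tibble(scan_out), file.path(out_dir, "edura_scan.csv"))
  jsonlite::write_json(as.list(res$axis), file.path(out_dir, "edura_axis.json"),
                       auto_unbox = TRUE, digits = NA)
  logf("detected axis at ", res$axis$ori_bp, " (min correlation ",
       signif(res$axis$correlation_min, 4), ")")

  res$control <- list()
  for (mode in c("absdge", "posdge", "negdge")) {
    res$control[[mode]] <- stage(paste0("control-", mode), {
      cs <- control_scan(cm, trn, gpn, genome, config = config, mode = mode)
      readr::write_csv(as_tibble(cs),
                       file.path(out_dir, paste0("control_", mode, ".csv")))
      cs
    })
    logf("control scan [", mode, "]: ", nrow(res$control[[mode]]),
         " contrasts, Spearman(digital, analog) = ",
         signif(attr(res$control[[mode]], "spearman"), 4))
  }
  jsonlite::write_json(
    lapply(res$control, function(cs) as.list(glance(cs))),
    file.path(out_dir, "control_summary.json"), auto_unbox = TRUE, digits = NA)

  if (!is.null(operons)) {
    res$operon_control <- stage("control-operon", {
      omap <- read_operon_map(operons)
      otrn <- collapse_to_operons(trn, omap)
      ocalls <- operon_calls(cm, omap, t_fc = config$t_fc, mode = "absdge")
      run_operon_control(ocalls, otrn, config)
    })
    readr::write_csv(as_tibble(res$operon_control),
                     file.path(out_dir, "control_operon.csv"))
  }

  if (!is.null(sites)) {
    res$importance <- stage("features", {
      site_tabs <- lapply(sites, function(p) read_edura_tsv(p))
      run_feature_stage(genome, trn, gpn, site_tabs, cm, ori_bp, config,
                        factor_genes)
    })
    readr::write_csv(res$importance, file.path(out_dir, "importance.csv"))
    res$correlations <- stage("features", {
      importance_ctc_correlation(res$importance, res$control$absdge)
    })
    readr::write_csv(res$correlations,
                     file.path(out_dir, "importance_ctc_correlation.csv"))
  }
  logf("done")
  invisible(res)
}

run_operon_control <- function(ocalls, otrn, config) {
  ids <- unique(ocalls$contrast_id)
  prep <- ctc_prepare(otrn, igraph::V(otrn)$name)
  rows <- lapply(ids, function(id) {
    ops <- ocalls$operon_id[ocalls$contrast_id == id]
    m <- unname(prep$idx[intersect(ops, prep$universe)])
    if (length(m) == 0) return(NULL)
    z <- ctc_from_prep(prep, m, config$n_null)
    tibble(contrast_id = id, n_called = length(m), digital_ctc = z$z,
           digital_ratio = z$r, digital_null_mean = z$mu,
           digital_null_sd = z$sigma)
  })
  dplyr::bind_rows(rows)
}

run_feature_stage <- function(genome, trn, gpn, site_tabs, cm, ori_bp, config,
                              factor_genes) {
  calls <- differential_calls(cm, config$t_fc, "absdge")
  ids <- setdiff(names(cm), "gene_id")
  rows <- lapply(ids, function(id) {
    genes <- calls$gene_id[calls$contrast_id == id]
    if (length(genes) == 0) return(NULL)
    ft <- compute_feature_table(genome, trn, gpn, site_tabs, genes, ori_bp,
                                factor_genes = factor_genes)
    imp <- corrected_importance(ft[.feature_names], ft$called,
                                n_shuffles = config$n_shuffles)
    wide <- as.list(setNames(imp$corrected, imp$feature))
    dplyr::bind_cols(tibble(contrast_id = id), as_tibble(wide))
  })
  dplyr::bind_rows(rows)
}

#' Robustness sweep over the two analysis thresholds
#'
#' Re-runs the control scan over a grid of logFC thresholds and GPN
#' distance thresholds, rebuilding the proximity network for each, and
#' reports the digital-analog Spearman correlation per grid point.
#'
#' @param contrasts Contrast matrix tibble.
#' @param trn Directed `igraph`.
#' @param genome A [circular_genome()].
#' @param tfc_grid,tgpn_grid Non-empty numeric grids.
#' @param config An [analysis_config()] (its `t_fc`/`t_gpn` are overridden
#'   by the grid).
#' @param mode Call mode.
#' @return Tibble with `t_fc`, `t_gpn`, `n_contrasts`, `spearman`.
#' @export
parameter_sweep <- function(contrasts, trn, genome, tfc_grid, tgpn_grid,
                            config = analysis_config(),
                            mode = c("absdge", "posdge", "negdge")) {
  mode <- match.arg(mode)
  if (length(tfc_grid) == 0 || length(tgpn_grid) == 0) {
    abort("threshold grids must be non-empty.", class = "edura_parameter_error")
  }
  grid <- tidyr::expand_grid(t_fc = tfc_grid, t_gpn = tgpn_grid)
  rows <- purrr::pmap(grid, function(t_fc, t_gpn) {
    cfg <- config
    cfg$t_fc <- t_fc
    cfg$t_gpn <- t_gpn
    gpn <- build_gpn(genome, t_gpn)
    cs <- control_scan(contrasts, trn, gpn, genome, config = cfg, mode = mode)
    tibble(t_fc = t_fc, t_gpn = t_gpn, n_contrasts = nrow(cs),
           spearman = attr(cs, "spearman"))
  })
  dplyr::bind_rows(rows)
}
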