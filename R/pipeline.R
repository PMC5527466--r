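#' Validate a pipeline run configuration
#'
#' A run configuration is a plain list (typically read from YAML) with
#' components `seed`, `out_dir`, `simulation` (arguments for
#' [sim_config()]) and `thresholds` (`z_min`, `toxicity_z_cut`,
#' `fold_cut`, `k_required`, `kd_cut`, `alpha`). All thresholds are
#' checked up front so a bad configuration fails before any stage
#' runs.
#'
#' @param config list or path to a YAML file.
#' @return the validated config list with defaults filled in.
#' @export
read_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML path",
                             call. = FALSE)
  defaults <- list(seed = 1L, out_dir = NULL, simulation = list(),
                   thresholds = list())
  config <- modifyList(defaults, config)
  thr_defaults <- list(z_min = 3, toxicity_z_cut = -2, fold_cut = 2,
                       k_required = 2L, kd_cut = 0.4, alpha = 0.05)
  thr <- modifyList(thr_defaults, config$thresholds)
  if (!is.numeric(thr$z_min) || thr$z_min <= 0)
    stop("config error: z_min must be positive", call. = FALSE)
  if (thr$fold_cut <= 0)
    stop("config error: fold_cut must be positive", call. = FALSE)
  if (thr$k_required < 0)
    stop("config error: k_required must be >= 0", call. = FALSE)
  if (thr$kd_cut <= 0 || thr$kd_cut >= 1)
    stop("config error: kd_cut must be in (0, 1)", call. = FALSE)
  if (thr$alpha <= 0 || thr$alpha >= 1)
    stop("config error: alpha must be in (0, 1)", call. = FALSE)
  config$thresholds <- thr
  config
}

#' Run the full screen-analysis pipeline
#'
#' Executes the stages simulate, score, call_hits, viability,
#' deconvolution and enrichment in order on a simulated screen,
#' writes one CSV per stage plus a machine-readable JSON manifest
#' (stage order, row counts, parameters, seed) into `out_dir`, and
#' returns the result tables. A rerun with the same configuration
#' produces identical tables.
#'
#' @param config run configuration (list or YAML path), see
#'   [read_run_config()].
#' @param quiet suppress per-stage log lines.
#' @return invisibly, a list with the per-stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  config <- read_run_config(config)
  out_dir <- config$out_dir
  if (is.null(out_dir)) stop("config error: out_dir is required",
                             call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  thr <- config$thresholds
  manifest <- list(stages = list(), seed = config$seed,
                   thresholds = thr)
  log_stage <- function(stage, rows) {
    if (!quiet) message(sprintf("[%s] %d rows", stage, rows))
    manifest$stages[[length(manifest$stages) + 1L]] <<-
      list(stage = stage, rows = rows)
  }
  save_csv <- function(df, name) {
    write.csv(as.data.frame(df), file.path(out_dir, name),
              row.names = FALSE)
  }
  run <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "' failed: ",
           conditionMessage(e), call. = FALSE))
  }

  # -- simulate ------------------------------------------------------
  sim <- run("simulate", {
    cfg <- do.call(sim_config,
                   c(config$simulation, list(seed = config$seed)))
    simulate_screen(cfg)
  })
  save_csv(sim$truth, "truth.csv")
  write_layout(sim$layout, file.path(out_dir, "layout.csv"))
  write_measurements(sim$reporter, file.path(out_dir, "reporter.csv"))
  write_measurements(sim$viability, file.path(out_dir, "viability_raw.csv"))
  log_stage("simulate", nrow(sim$reporter))

  # -- score ---------------------------------------------------------
  scored <- run("score", {
    z <- robust_z(log2_normalize(sim$reporter, sim$layout,
                                 reference_role = "mock"))
    scores <- aggregate_gene_scores(z)
    list(z = z, scores = scores, summary = gene_summary(scores),
         anchors = control_anchors(z))
  })
  save_csv(scored$z, "scores.csv")
  save_csv(scored$summary, "gene_summary.csv")
  log_stage("score", nrow(scored$z))

  # -- call_hits -----------------------------------------------------
  hits <- run("call_hits",
              select_fixed_threshold(scored$scores, z_min = thr$z_min))
  save_csv(hits, "hits.csv")
  log_stage("call_hits", nrow(hits))

  # -- viability -----------------------------------------------------
  viab <- run("viability", {
    v <- score_viability(sim$viability, sim$layout)
    down <- hits[hits$selected & hits$direction == "enhancer", ]
    strat <- stratify_down_hits(down, v$gene,
                                toxicity_z_cut = thr$toxicity_z_cut)
    list(gene = v$gene, stratified = strat)
  })
  save_csv(viab$gene, "viability.csv")
  save_csv(viab$stratified, "down_hits_stratified.csv")
  log_stage("viability", nrow(viab$gene))

  # -- deconvolution -------------------------------------------------
  deconv <- run("deconvolution", {
    up <- hits$gene_id[hits$selected & hits$direction == "inhibitor"]
    if (length(up) == 0L)
      list(data = NULL,
           genes = data.frame(gene_id = character(0),
                              n_consistent = integer(0),
                              confirmed = logical(0)))
    else {
      d <- simulate_deconvolution(sim$truth, genes = up,
                                  seed = config$seed + 1L)
      c(d, confirm_deconvolution(d$data, fold_cut = thr$fold_cut,
                                 k_required = thr$k_required))
    }
  })
  if (!is.null(deconv$data)) save_csv(deconv$data, "deconvolution.csv")
  save_csv(deconv$genes, "deconvolution_confirmed.csv")
  log_stage("deconvolution", nrow(deconv$genes))

  # -- enrichment ----------------------------------------------------
  enrich <- run("enrichment", {
    sets <- simulate_genesets(sim$truth, seed = config$seed + 2L)
    subgroup_shift_scan(scored$summary, sets)
  })
  save_csv(enrich, "enrichment.csv")
  log_stage("enrichment", nrow(enrich))

  manifest$row_counts <- vapply(manifest$stages, `[[`, numeric(1), "rows")
  manifest$stage_order <- vapply(manifest$stages, `[[`, character(1),
                                 "stage")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(sim = sim, scored = scored, hits = hits,
                 viability = viab, deconvolution = deconv,
                 enrichment = enrich, manifest = manifest))
}
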