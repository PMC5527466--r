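#' Configuration for a synthetic siRNA screen
#'
#' Defines the generative model of the simulator. Raw signal of a well
#' is `2^(mu_plate + delta_reagent + edge(row, col) + eps)` with
#' `eps ~ N(0, sigma^2)` independently per well and replicate, i.e.
#' log-normal well noise around a per-plate baseline. Mock and
#' nontargeting wells have `delta = 0`; positive enhancer/inhibitor
#' control wells carry fixed log2 effects of -2 / +2 by default
#' (approximately fourfold down/up, the stated effect size of the
#' siTP53 and siSYVN1 controls); a fraction of library genes are true
#' reporter modulators. Viability measurements use the same model
#' with per-gene toxicity shifts.
#'
#' @param n_genes number of library genes (default 2000).
#' @param n_rows,n_cols plate geometry (default 16 x 24).
#' @param replicates independent replicate screens (default 3).
#' @param sigma well noise SD in log2 units (default 0.5).
#' @param plate_sd SD of per-plate log2 offsets (default 0.3).
#' @param edge_amp additive log2 bump on outer wells (default 0, off).
#' @param baseline_log2 log2 baseline signal (default 10, i.e. raw
#'   signals around 1024 arbitrary units).
#' @param delta_enhancer,delta_inhibitor log2 effects of the positive
#'   controls (defaults -2, +2).
#' @param hit_fraction fraction of library genes that are true
#'   reporter-up hits (default 0.01).
#' @param hit_effect,hit_effect_sd log2 effect of true up-hits
#'   (default +3, SD 0).
#' @param down_fraction,down_effect fraction and log2 effect of true
#'   reporter-down genes (defaults 0.005, -3).
#' @param down_toxic_prob probability that a reporter-down gene is in
#'   fact toxicity-confounded (default 0.5).
#' @param hit_toxic_prob probability that a true up-hit also reduces
#'   viability (default 0.6).
#' @param toxicity_mean,toxicity_sd log2 viability shift of toxic
#'   genes (defaults -1.5, 0.5).
#' @param n_mock,n_nontargeting,n_pos_enhancer,n_pos_inhibitor control
#'   wells per plate (defaults 8, 8, 4, 4).
#' @param seed integer seed driving every random draw.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000L, n_rows = 16L, n_cols = 24L,
                       replicates = 3L, sigma = 0.5, plate_sd = 0.3,
                       edge_amp = 0, baseline_log2 = 10,
                       delta_enhancer = -2, delta_inhibitor = 2,
                       hit_fraction = 0.01, hit_effect = 3,
                       hit_effect_sd = 0, down_fraction = 0.005,
                       down_effect = -3, down_toxic_prob = 0.5,
                       hit_toxic_prob = 0.6, toxicity_mean = -1.5,
                       toxicity_sd = 0.5, n_mock = 8L,
                       n_nontargeting = 8L, n_pos_enhancer = 4L,
                       n_pos_inhibitor = 4L, seed = 1L) {
  cfg <- as.list(environment())
  if (cfg$sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (cfg$hit_fraction < 0 || cfg$hit_fraction >= 1)
    stop("hit_fraction must be in [0, 1)", call. = FALSE)
  if (cfg$down_fraction < 0 || cfg$down_fraction >= 1)
    stop("down_fraction must be in [0, 1)", call. = FALSE)
  if (cfg$replicates < 1L) stop("need >= 1 replicate", call. = FALSE)
  n_ctrl <- cfg$n_mock + cfg$n_nontargeting + cfg$n_pos_enhancer +
    cfg$n_pos_inhibitor
  if (n_ctrl > 2L * cfg$n_rows)
    stop("plate geometry too small for the requested control wells ",
         "(controls occupy the first two columns)", call. = FALSE)
  if (cfg$n_cols < 3L)
    stop("plate needs at least 3 columns (2 control + library)",
         call. = FALSE)
  structure(cfg, class = "sim_config")
}

# Layout for one simulated plate: controls in columns 1-2, library
# wells in columns 3..n_cols.
sim_plate_layout <- function(cfg, plate_id, gene_ids) {
  ctrl_roles <- c(rep("mock", cfg$n_mock),
                  rep("nontargeting", cfg$n_nontargeting),
                  rep("pos_control_enhancer", cfg$n_pos_enhancer),
                  rep("pos_control_inhibitor", cfg$n_pos_inhibitor))
  ctrl_pos <- expand.grid(row = seq_len(cfg$n_rows), col = 1:2)
  n_ctrl <- length(ctrl_roles)
  ctrl <- data.frame(plate_id = plate_id,
                     row = ctrl_pos$row[seq_len(n_ctrl)],
                     col = ctrl_pos$col[seq_len(n_ctrl)],
                     role = ctrl_roles,
                     reagent_id = NA_character_,
                     gene_id = NA_character_,
                     stringsAsFactors = FALSE)
  ctrl$reagent_id[ctrl$role == "nontargeting"] <- "NTp2"
  ctrl$reagent_id[ctrl$role == "pos_control_enhancer"] <- "siTP53"
  ctrl$reagent_id[ctrl$role == "pos_control_inhibitor"] <- "siSYVN1"
  empty <- if (n_ctrl < nrow(ctrl_pos)) {
    data.frame(plate_id = plate_id,
               row = ctrl_pos$row[(n_ctrl + 1L):nrow(ctrl_pos)],
               col = ctrl_pos$col[(n_ctrl + 1L):nrow(ctrl_pos)],
               role = "empty", reagent_id = NA_character_,
               gene_id = NA_character_, stringsAsFactors = FALSE)
  } else NULL
  lib_pos <- expand.grid(row = seq_len(cfg$n_rows),
                         col = 3:cfg$n_cols)
  lib_pos <- lib_pos[seq_along(gene_ids), , drop = FALSE]
  lib <- data.frame(plate_id = plate_id, row = lib_pos$row,
                    col = lib_pos$col, role = "library",
                    reagent_id = paste0("pool_", gene_ids),
                    gene_id = gene_ids, stringsAsFactors = FALSE)
  rbind(ctrl, empty, lib)
}

#' Simulate a multi-plate replicate reporter screen with ground truth
#'
#' Generates plate layouts, raw reporter-luminescence measurements for
#' each replicate screen, matched viability-fluorescence measurements,
#' and a ground-truth table of the true log2 effect of every reagent.
#' Identical configurations (including seed) give identical outputs.
#'
#' @param cfg a [sim_config()].
#' @return list of class `sim_screen` with elements `layout`
#'   ([plate_layout()]), `reporter` and `viability`
#'   ([screen_measurements()]), `truth` (data.frame `reagent_id,
#'   gene_id, reporter_effect, toxicity_effect, is_true_hit,
#'   direction`), and `config`.
#' @export
simulate_screen <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    gene_ids <- sprintf("G%05d", seq_len(cfg$n_genes))
    lib_per_plate <- cfg$n_rows * (cfg$n_cols - 2L)
    n_plates <- ceiling(cfg$n_genes / lib_per_plate)
    plate_ids <- sprintf("P%03d", seq_len(n_plates))
    splits <- split(gene_ids,
                    ceiling(seq_along(gene_ids) / lib_per_plate))
    layout_df <- do.call(rbind, Map(function(pid, genes)
      sim_plate_layout(cfg, pid, genes), plate_ids, splits))
    layout <- plate_layout(layout_df, n_rows = cfg$n_rows,
                           n_cols = cfg$n_cols)

    # ground-truth effects
    n_hit <- round(cfg$hit_fraction * cfg$n_genes)
    n_down <- round(cfg$down_fraction * cfg$n_genes)
    picked <- sample(gene_ids, n_hit + n_down)
    up_genes <- picked[seq_len(n_hit)]
    down_genes <- setdiff(picked, up_genes)
    effect <- setNames(numeric(cfg$n_genes), gene_ids)
    effect[up_genes] <- cfg$hit_effect +
      rnorm(n_hit, sd = cfg$hit_effect_sd)
    effect[down_genes] <- cfg$down_effect
    toxicity <- setNames(numeric(cfg$n_genes), gene_ids)
    up_toxic <- up_genes[runif(n_hit) < cfg$hit_toxic_prob]
    down_toxic <- down_genes[runif(n_down) < cfg$down_toxic_prob]
    toxic <- c(up_toxic, down_toxic)
    toxicity[toxic] <- rnorm(length(toxic), mean = cfg$toxicity_mean,
                             sd = cfg$toxicity_sd)
    truth <- data.frame(reagent_id = paste0("pool_", gene_ids),
                        gene_id = gene_ids,
                        reporter_effect = unname(effect),
                        toxicity_effect = unname(toxicity),
                        is_true_hit = unname(effect != 0),
                        direction = unname(
                          ifelse(effect > 0, "inhibitor",
                                 ifelse(effect < 0, "enhancer", "none"))),
                        stringsAsFactors = FALSE)

    lay <- as.data.frame(layout)
    measured <- lay[lay$role != "empty", ]
    delta_reporter <- ifelse(
      measured$role == "library", effect[measured$gene_id],
      ifelse(measured$role == "pos_control_enhancer", cfg$delta_enhancer,
             ifelse(measured$role == "pos_control_inhibitor",
                    cfg$delta_inhibitor, 0)))
    delta_viability <- ifelse(measured$role == "library",
                              toxicity[measured$gene_id], 0)
    edge <- if (cfg$edge_amp != 0) {
      cfg$edge_amp * as.numeric(
        measured$row == 1L | measured$row == cfg$n_rows |
          measured$col == 1L | measured$col == cfg$n_cols)
    } else 0

    one_channel <- function(channel, delta, screen_id) {
      reps <- lapply(seq_len(cfg$replicates), function(r) {
        mu_plate <- setNames(
          cfg$baseline_log2 + rnorm(n_plates, sd = cfg$plate_sd),
          plate_ids)
        eps <- rnorm(nrow(measured), sd = cfg$sigma)
        data.frame(screen_id = screen_id,
                   replicate_id = sprintf("R%d", r),
                   plate_id = measured$plate_id,
                   row = measured$row, col = measured$col,
                   channel = channel,
                   value = 2^(mu_plate[measured$plate_id] + delta +
                                edge + eps),
                   stringsAsFactors = FALSE)
      })
      screen_measurements(do.call(rbind, reps), layout)
    }
    reporter <- one_channel("reporter_luminescence", delta_reporter,
                            "reporter")
    viability <- one_channel("viability_fluorescence", delta_viability,
                             "viability")
    structure(list(layout = layout, reporter = reporter,
                   viability = viability, truth = truth, config = cfg),
              class = "sim_screen")
  })
}

#' Simulate siRNA deconvolution follow-up data
#'
#' Each selected gene gets `n_sirna` individual duplexes whose effect
#' is the gene's pool effect times a per-siRNA attenuation drawn
#' uniformly from `atten_range`; with probability `dud_prob` a siRNA
#' is a "dud" with attenuation in `dud_range` (a weak or inactive
#' duplex), reproducing the 2-to-4-of-4 consistency patterns seen in
#' real deconvolution screens. Observed fold induction per experiment
#' is `2^(attenuation * effect + noise)`.
#'
#' @param truth ground-truth table from [simulate_screen()] (or any
#'   data.frame `gene_id, reporter_effect`).
#' @param genes genes to deconvolve (default: all true hits with
#'   positive effect).
#' @param n_sirna duplexes per gene (default 4).
#' @param experiments_range inclusive range of independent experiments
#'   per gene (default 2:4, drawn uniformly).
#' @param atten_range attenuation range of active duplexes (default
#'   c(0.6, 1)).
#' @param dud_prob probability a duplex is a dud (default 0.25).
#' @param dud_range attenuation range of duds (default c(0, 0.25)).
#' @param sigma log2 measurement noise (default 0.25).
#' @param seed integer seed.
#' @return list with `data` (data.frame `gene_id, sirna_id,
#'   experiment_id, fold`) and `sirna_truth` (per-duplex attenuation
#'   and effect).
#' @export
simulate_deconvolution <- function(truth, genes = NULL, n_sirna = 4L,
                                   experiments_range = 2:4,
                                   atten_range = c(0.6, 1),
                                   dud_prob = 0.25,
                                   dud_range = c(0, 0.25),
                                   sigma = 0.25, seed = 1L) {
  if (is.null(genes))
    genes <- truth$gene_id[truth$reporter_effect > 0]
  if (length(genes) == 0L) stop("no genes to deconvolve", call. = FALSE)
  effects <- truth$reporter_effect[match(genes, truth$gene_id)]
  if (anyNA(effects))
    stop("genes absent from truth table", call. = FALSE)
  with_seed(seed, {
    rows <- list()
    truth_rows <- list()
    for (i in seq_along(genes)) {
      n_exp <- sample(experiments_range, 1L)
      dud <- runif(n_sirna) < dud_prob
      atten <- ifelse(dud,
                      runif(n_sirna, dud_range[1], dud_range[2]),
                      runif(n_sirna, atten_range[1], atten_range[2]))
      for (s in seq_len(n_sirna)) {
        m <- atten[s] * effects[i] + rnorm(n_exp, sd = sigma)
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = genes[i], sirna_id = sprintf("si%d", s),
          experiment_id = sprintf("E%d", seq_len(n_exp)),
          fold = 2^m, stringsAsFactors = FALSE)
      }
      truth_rows[[i]] <- data.frame(
        gene_id = genes[i], sirna_id = sprintf("si%d", seq_len(n_sirna)),
        attenuation = atten, is_dud = dud,
        effect = atten * effects[i], stringsAsFactors = FALSE)
    }
    list(data = do.call(rbind, rows),
         sirna_truth = do.call(rbind, truth_rows))
  })
}

#' Simulate a gene-set table with one shifted subgroup
#'
#' Builds subgroups by sampling library genes; the first subgroup
#' preferentially samples true hits so a shift scan has a known
#' positive. Useful for exercising [subgroup_shift_scan()] end to end.
#'
#' @param truth ground-truth table from [simulate_screen()].
#' @param n_subgroups number of subgroups (default 6).
#' @param size genes per subgroup (default 25).
#' @param set_name gene-set name (default "simset").
#' @param seed integer seed.
#' @return data.frame `set_name, subgroup_name, gene_id`.
#' @export
simulate_genesets <- function(truth, n_subgroups = 6L, size = 25L,
                              set_name = "simset", seed = 1L) {
  with_seed(seed, {
    hits <- truth$gene_id[truth$reporter_effect > 0]
    nulls <- truth$gene_id[truth$reporter_effect == 0]
    n_hit_members <- min(length(hits), ceiling(size / 2))
    enriched <- c(sample(hits, n_hit_members),
                  sample(nulls, size - n_hit_members))
    rows <- data.frame(set_name = set_name, subgroup_name = "SG01",
                       gene_id = enriched, stringsAsFactors = FALSE)
    for (i in seq_len(n_subgroups - 1L)) {
      rows <- rbind(rows, data.frame(
        set_name = set_name,
        subgroup_name = sprintf("SG%02d", i + 1L),
        gene_id = sample(nulls, size), stringsAsFactors = FALSE))
    }
    rows
  })
}

#' Confusion-matrix recovery of simulated hits
#'
#' Compares a hit-call table against the simulator's ground truth for
#' one direction and reports precision, recall and the false-discovery
#' proportion. With no selected calls, recall is 0 and precision (and
#' FDP) are undefined and returned as `NA`.
#'
#' @param truth ground-truth table from [simulate_screen()].
#' @param calls hit table from [select_fixed_threshold()] or
#'   [select_control_anchored()].
#' @param direction truth/call direction to evaluate (default
#'   `"inhibitor"`).
#' @return list `precision, recall, fdp, tp, fp, fn, n_called`.
#' @export
evaluate_recovery <- function(truth, calls, direction = "inhibitor") {
  if (length(intersect(truth$gene_id, calls$gene_id)) == 0L)
    stop("truth and calls share no gene ids", call. = FALSE)
  true_pos <- truth$gene_id[truth$is_true_hit &
                              truth$direction == direction]
  called <- calls$gene_id[calls$selected & calls$direction == direction]
  tp <- length(intersect(called, true_pos))
  fp <- length(setdiff(called, true_pos))
  fn <- length(setdiff(true_pos, called))
  precision <- if (length(called) == 0L) NA_real_ else tp / (tp + fp)
  recall <- if (length(true_pos) == 0L) NA_real_ else tp / (tp + fn)
  list(precision = precision, recall = recall,
       fdp = if (is.na(precision)) NA_real_ else 1 - precision,
       tp = tp, fp = fp, fn = fn, n_called = length(called))
}
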