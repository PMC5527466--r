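#' Score a viability counterscreen
#'
#' Runs the standard scoring pipeline on viability fluorescence data:
#' log2 transform, per-plate normalization to nontargeting control
#' wells, robust Z-scoring against the library distribution, then
#' aggregation to per-gene replicate scores. A viability Z well below
#' zero indicates loss of cell viability upon silencing.
#'
#' @param measurements a [screen_measurements()] table with channel
#'   `viability_fluorescence`.
#' @param layout a [plate_layout()].
#' @param scope scoring scope, see [robust_z()].
#' @param annotation optional reagent-to-gene table.
#' @return list with `gene` (data.frame `gene_id, n_reps,
#'   viability_z` -- mean robust Z across replicates), `scores` (the
#'   per-gene [gene_scores()]) and `wells` (the well-level
#'   `zscore_table`).
#' @export
score_viability <- function(measurements, layout,
                            scope = c("per_replicate", "per_plate"),
                            annotation = NULL) {
  stopifnot(inherits(measurements, "screen_measurements"))
  if (!all(measurements$channel == "viability_fluorescence"))
    stop("viability scoring expects channel viability_fluorescence",
         call. = FALSE)
  norm <- log2_normalize(measurements, layout,
                         reference_role = "nontargeting")
  z <- robust_z(norm, scope = match.arg(scope))
  scores <- aggregate_gene_scores(z, annotation = annotation)
  summ <- gene_summary(scores)
  names(summ)[names(summ) == "mean_z"] <- "viability_z"
  list(gene = summ, scores = scores, wells = z)
}

#' Stratify luminescence-decreasing hits by viability
#'
#' A reporter screen cannot distinguish decreased reporter activity
#' from loss of cell viability: both lower the luminescence signal.
#' Down-direction hits are therefore classified against the viability
#' counterscreen: `enhancer_candidate` when viability Z is above
#' `toxicity_z_cut` (the knockdown dims the reporter without killing
#' the cells), `toxicity_confounded` otherwise, and `unevaluable` when
#' no viability score exists. The three classes partition the input.
#'
#' @param down_hits data.frame of enhancer-direction hit calls (needs
#'   a `gene_id` column; typically the `selected & direction ==
#'   "enhancer"` rows of a hit table).
#' @param viability per-gene viability table (`gene` element of
#'   [score_viability()], or any data.frame `gene_id, viability_z`).
#' @param toxicity_z_cut viability robust-Z cut (default -2).
#' @return the `down_hits` rows plus `viability_z` and `class`.
#' @export
stratify_down_hits <- function(down_hits, viability, toxicity_z_cut = -2) {
  stopifnot(is.data.frame(down_hits), "gene_id" %in% names(down_hits))
  if (!all(c("gene_id", "viability_z") %in% names(viability)))
    stop("viability table requires columns gene_id, viability_z",
         call. = FALSE)
  out <- as.data.frame(down_hits)
  out$viability_z <-
    viability$viability_z[match(out$gene_id, viability$gene_id)]
  out$class <- ifelse(is.na(out$viability_z), "unevaluable",
                      ifelse(out$viability_z > toxicity_z_cut,
                             "enhancer_candidate", "toxicity_confounded"))
  out
}

#' Test a hit set for enrichment of toxicity
#'
#' Compares the viability scores of a hit set against a neutral
#' comparison set (reagents with reporter Z around zero) with a
#' two-sided Mann-Whitney test, reporting the direction of the shift.
#'
#' @param hit_values viability values (Z or normalized signal) for the
#'   hit set.
#' @param control_values values for the neutral set.
#' @param mode Mann-Whitney mode, see [mannwhitney_u()].
#' @return list `U, p_value, direction` (`"lower"`, `"higher"`, or
#'   `"none"`, hit set relative to controls), `n_hits, n_controls`.
#' @export
hitset_toxicity_test <- function(hit_values, control_values, mode = "auto") {
  if (length(hit_values) < 2L || length(control_values) < 2L)
    stop("both sets need at least 2 values", call. = FALSE)
  res <- mannwhitney_u(hit_values, control_values, mode = mode)
  shift <- median(hit_values) - median(control_values)
  list(U = res$U, p_value = res$p_value,
       direction = if (shift < 0) "lower" else if (shift > 0) "higher"
                   else "none",
       n_hits = length(hit_values), n_controls = length(control_values))
}

#' Select a neutral comparison set of nonmodulating genes
#'
#' Picks genes whose mean reporter Z lies in a band around zero, the
#' usual construction of an "irrelevant control" set for toxicity
#' comparisons.
#'
#' @param summary per-gene summary (data.frame `gene_id, mean_z`).
#' @param n number of genes to return.
#' @param band half-width of the |mean Z| band (default 0.5).
#' @return character vector of gene ids (the `n` closest to zero
#'   within the band).
#' @export
select_neutral_set <- function(summary, n = 299L, band = 0.5) {
  cand <- summary[abs(summary$mean_z) < band, ]
  if (nrow(cand) < n)
    stop("only ", nrow(cand), " genes inside |mean Z| < ", band,
         "; requested ", n, call. = FALSE)
  cand <- cand[order(abs(cand$mean_z)), ]
  head(cand$gene_id, n)
}
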