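# Internal: pivot gene_scores to a gene x replicate matrix of Z values.
scores_matrix <- function(scores) {
  stopifnot(inherits(scores, "gene_scores"))
  df <- as.data.frame(scores)
  genes <- sort(unique(df$gene_id))
  reps <- sort(unique(df$replicate_id))
  zmat <- matrix(NA_real_, length(genes), length(reps),
                 dimnames = list(genes, reps))
  zmat[cbind(match(df$gene_id, genes), match(df$replicate_id, reps))] <- df$z
  zmat
}

hit_table <- function(zmat, direction, selected, evaluable, rule) {
  data.frame(gene_id = rownames(zmat),
             n_reps = rowSums(is.finite(zmat)),
             mean_z = rowMeans(zmat, na.rm = TRUE),
             direction = direction,
             selected = selected,
             evaluable = evaluable,
             rule = rule,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fixed-threshold hit calling with all-replicate consistency
#'
#' A gene is called a p53-pathway *inhibitor* hit (reporter up) when
#' its Z-score strictly exceeds `z_min` in every replicate screen, and
#' an *enhancer* hit (reporter down) when Z is strictly below `-z_min`
#' in every replicate. The strict inequality mirrors the usual
#' "Z > 3" wording; genes with a missing replicate are flagged
#' unevaluable rather than silently dropped.
#'
#' @param scores a [gene_scores()] table.
#' @param z_min positive threshold (default 3).
#' @return data.frame with one row per gene: `gene_id, n_reps, mean_z,
#'   direction` (`"inhibitor"|"enhancer"|"none"`), `selected`,
#'   `evaluable`, `rule`.
#' @export
select_fixed_threshold <- function(scores, z_min = 3) {
  if (!is.numeric(z_min) || length(z_min) != 1L || z_min <= 0)
    stop("z_min must be a positive number", call. = FALSE)
  zmat <- scores_matrix(scores)
  evaluable <- rowSums(is.na(zmat)) == 0L
  up <- evaluable & apply(zmat, 1L, function(z) all(z > z_min))
  down <- evaluable & apply(zmat, 1L, function(z) all(z < -z_min))
  direction <- ifelse(up, "inhibitor", ifelse(down, "enhancer", "none"))
  hit_table(zmat, direction, selected = up | down, evaluable = evaluable,
            rule = "fixed_threshold_all_reps")
}

#' Control-anchored hit calling
#'
#' Selects genes at least as extreme as the positive controls. In
#' `mean` mode the gene's mean Z across replicates is compared with
#' the control anchors (inclusive: "at least as low/high as the
#' control"): enhancer iff `mean_z <= anchor_enhancer`, inhibitor iff
#' `mean_z >= anchor_inhibitor`. In `per_replicate` mode the
#' inequality must hold in every replicate against that replicate's
#' own control score, the comparison form of requiring a gene to be at
#' least as strong as the control in all screens.
#'
#' @param scores a [gene_scores()] table.
#' @param anchor_enhancer,anchor_inhibitor mean-mode anchors, normally
#'   from [control_anchors()]; must satisfy
#'   `anchor_enhancer < anchor_inhibitor`.
#' @param mode `"mean"` (default) or `"per_replicate"`.
#' @param rep_anchors per-replicate anchors for `per_replicate` mode:
#'   data.frame `replicate_id, anchor_enhancer, anchor_inhibitor`.
#' @return data.frame as in [select_fixed_threshold()], with
#'   `rule` `"mean_anchored"` or `"per_rep_anchored"`.
#' @export
select_control_anchored <- function(scores, anchor_enhancer,
                                    anchor_inhibitor,
                                    mode = c("mean", "per_replicate"),
                                    rep_anchors = NULL) {
  mode <- match.arg(mode)
  zmat <- scores_matrix(scores)
  if (mode == "mean") {
    if (!is.finite(anchor_enhancer) || !is.finite(anchor_inhibitor) ||
        anchor_enhancer >= anchor_inhibitor)
      stop("anchors must satisfy anchor_enhancer < anchor_inhibitor ",
           "(enhancer anchor negative, inhibitor anchor positive)",
           call. = FALSE)
    mean_z <- rowMeans(zmat, na.rm = TRUE)
    evaluable <- rowSums(is.finite(zmat)) > 0L
    down <- evaluable & mean_z <= anchor_enhancer
    up <- evaluable & mean_z >= anchor_inhibitor
    rule <- "mean_anchored"
  } else {
    if (is.null(rep_anchors))
      stop("per_replicate mode requires rep_anchors", call. = FALSE)
    required <- c("replicate_id", "anchor_enhancer", "anchor_inhibitor")
    if (!all(required %in% names(rep_anchors)))
      stop("rep_anchors requires columns ",
           paste(required, collapse = ", "), call. = FALSE)
    if (any(rep_anchors$anchor_enhancer >= rep_anchors$anchor_inhibitor))
      stop("anchors must satisfy anchor_enhancer < anchor_inhibitor ",
           "in every replicate", call. = FALSE)
    reps <- colnames(zmat)
    idx <- match(reps, rep_anchors$replicate_id)
    if (anyNA(idx))
      stop("rep_anchors missing replicate(s): ",
           paste(reps[is.na(idx)], collapse = ", "), call. = FALSE)
    enh <- rep_anchors$anchor_enhancer[idx]
    inh <- rep_anchors$anchor_inhibitor[idx]
    evaluable <- rowSums(is.na(zmat)) == 0L
    down <- evaluable &
      apply(sweep(zmat, 2L, enh, `<=`), 1L, all)
    up <- evaluable &
      apply(sweep(zmat, 2L, inh, `>=`), 1L, all)
    rule <- "per_rep_anchored"
  }
  direction <- ifelse(up, "inhibitor", ifelse(down, "enhancer", "none"))
  hit_table(zmat, direction, selected = up | down, evaluable = evaluable,
            rule = rule)
}
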