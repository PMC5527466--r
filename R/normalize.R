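#' Robust Z-scores of a numeric vector
#'
#' Core scoring primitive: deviation from the median of a reference
#' distribution in units of its scaled median absolute deviation,
#' `z = (x - median(ref)) / (c_mad * MAD(ref))`. With the default
#' `c_mad = 1.4826` the scaled MAD is a consistent estimator of the
#' standard deviation under normality.
#'
#' @param x values to score.
#' @param reference values defining location and scale (defaults to
#'   `x` itself; in screen scoring this is the library-well
#'   distribution). `NA`s are dropped from the reference.
#' @param c_mad MAD scaling constant.
#' @return numeric vector of Z-scores, same length as `x`.
#' @examples
#' robust_z_scores(4, reference = c(1, 2, 3, 4, 100))  # 1/1.4826
#' @export
robust_z_scores <- function(x, reference = x, c_mad = 1.4826) {
  ref <- reference[is.finite(reference)]
  if (length(ref) < 1L)
    stop("no finite reference values for robust Z", call. = FALSE)
  med <- median(ref)
  scale <- c_mad * median(abs(ref - med))
  if (scale == 0)
    stop("MAD of the reference distribution is zero (constant values); ",
         "inspect the plate/replicate before scoring", call. = FALSE)
  (x - med) / scale
}

#' Per-plate log2 normalization to reference wells
#'
#' Raw signals are log2-transformed and, per (screen, replicate,
#' plate), centred on the median log2 signal of the designated
#' reference wells: `m = log2(value) - median(log2(reference wells))`.
#' For reporter luminescence the reference role is `mock`
#' (transfection reagent only); the viability counterscreen uses
#' `nontargeting` wells instead.
#'
#' @param measurements a [screen_measurements()] table (one channel).
#' @param layout a [plate_layout()].
#' @param reference_role well role providing the per-plate reference;
#'   `"mock"` (default) or `"nontargeting"`.
#' @return data.frame of class `normalized_table` with columns
#'   `screen_id, replicate_id, plate_id, row, col, role, reagent_id,
#'   gene_id, m`. Missing raw values propagate as missing `m`.
#' @export
log2_normalize <- function(measurements, layout, reference_role = "mock") {
  stopifnot(inherits(measurements, "screen_measurements"),
            inherits(layout, "plate_layout"))
  reference_role <- match.arg(reference_role, WELL_ROLES)

  lay <- as.data.frame(layout)
  df <- merge(as.data.frame(measurements), lay,
              by = c("plate_id", "row", "col"), all.x = TRUE, sort = FALSE)
  df$log2_value <- log2(df$value)

  grp <- interaction(df$screen_id, df$replicate_id, df$plate_id, drop = TRUE)
  df$m <- NA_real_
  for (g in levels(grp)) {
    idx <- which(grp == g)
    ref <- df$log2_value[idx][df$role[idx] == reference_role]
    ref <- ref[is.finite(ref)]
    if (length(ref) < 1L)
      stop("no usable ", reference_role, " reference wells on plate ",
           df$plate_id[idx[1L]], " (screen ", df$screen_id[idx[1L]],
           ", replicate ", df$replicate_id[idx[1L]], ")", call. = FALSE)
    df$m[idx] <- df$log2_value[idx] - median(ref)
  }

  out <- df[c("screen_id", "replicate_id", "plate_id", "row", "col",
              "role", "reagent_id", "gene_id", "m")]
  structure(out, reference_role = reference_role,
            class = c("normalized_table", "data.frame"))
}

#' Robust Z-scoring of normalized screen values
#'
#' Scores every well against the library-well distribution: per scope
#' (replicate screen by default, single plate by flag),
#' `Z = (m - median_lib) / (c_mad * MAD_lib)` with median and MAD taken
#' over library wells only. Control wells are scored against that same
#' library distribution but never contribute to it, so a strong
#' control cannot shrink the scale it is measured on.
#'
#' @param normalized a `normalized_table` from [log2_normalize()].
#' @param scope `"per_replicate"` (default) or `"per_plate"`.
#' @param c_mad MAD scaling constant (1.4826).
#' @return data.frame of class `zscore_table`: the normalized table
#'   plus a `z` column.
#' @export
robust_z <- function(normalized, scope = c("per_replicate", "per_plate"),
                     c_mad = 1.4826) {
  stopifnot(inherits(normalized, "normalized_table"))
  scope <- match.arg(scope)
  df <- as.data.frame(normalized)

  grp <- if (scope == "per_replicate") {
    interaction(df$screen_id, df$replicate_id, drop = TRUE)
  } else {
    interaction(df$screen_id, df$replicate_id, df$plate_id, drop = TRUE)
  }
  df$z <- NA_real_
  for (g in levels(grp)) {
    idx <- which(grp == g)
    lib <- df$m[idx][df$role[idx] == "library"]
    lib <- lib[is.finite(lib)]
    if (length(lib) < 3L)
      stop("fewer than 3 scoreable library wells in scope ", g, call. = FALSE)
    scored <- is.finite(df$m[idx])
    df$z[idx][scored] <- tryCatch(
      robust_z_scores(df$m[idx][scored], reference = lib, c_mad = c_mad),
      error = function(e) stop("scope ", g, ": ", conditionMessage(e),
                               call. = FALSE))
  }
  structure(df, scope = scope, c_mad = c_mad,
            class = c("zscore_table", "data.frame"))
}

#' Aggregate well-level Z-scores to per-gene replicate scores
#'
#' Library wells are mapped to genes (from the layout's `gene_id`, or
#' an annotation table overriding it) and each gene receives one Z per
#' replicate screen (the mean, should a gene occupy several wells in
#' one replicate). Reagents without a gene mapping are dropped with a
#' warning and listed in the `excluded_reagents` attribute.
#'
#' @param zscores a `zscore_table` from [robust_z()].
#' @param annotation optional data.frame `reagent_id, gene_id` (see
#'   [read_annotation()]) overriding the layout's gene assignment.
#' @return data.frame of class `gene_scores` with columns
#'   `gene_id, replicate_id, z` (one row per gene x replicate;
#'   `replicate_id` is `screen_id/replicate_id`).
#' @export
aggregate_gene_scores <- function(zscores, annotation = NULL) {
  stopifnot(inherits(zscores, "zscore_table"))
  df <- as.data.frame(zscores)
  df <- df[df$role == "library" & is.finite(df$z), ]
  if (!is.null(annotation)) {
    map <- setNames(as.character(annotation$gene_id),
                    as.character(annotation$reagent_id))
    df$gene_id <- unname(map[df$reagent_id])
  }
  unmapped <- unique(df$reagent_id[is.na(df$gene_id)])
  if (length(unmapped) > 0L) {
    warning("excluding ", length(unmapped),
            " library reagent(s) without a gene mapping", call. = FALSE)
    df <- df[!is.na(df$gene_id), ]
  }
  df$rep <- paste(df$screen_id, df$replicate_id, sep = "/")
  agg <- aggregate(z ~ gene_id + rep, data = df, FUN = mean)
  names(agg)[names(agg) == "rep"] <- "replicate_id"
  agg <- agg[order(agg$gene_id, agg$replicate_id),
             c("gene_id", "replicate_id", "z")]
  rownames(agg) <- NULL
  gene_scores(agg, excluded_reagents = unmapped)
}

#' Construct a per-gene replicate score table
#'
#' @param df data.frame with columns `gene_id, replicate_id, z`.
#' @param excluded_reagents optional character vector carried as an
#'   attribute.
#' @return data.frame of class `gene_scores`.
#' @export
gene_scores <- function(df, excluded_reagents = character()) {
  required <- c("gene_id", "replicate_id", "z")
  if (!all(required %in% names(df)))
    stop("gene scores require columns gene_id, replicate_id, z",
         call. = FALSE)
  df <- as.data.frame(df)[required]
  df$gene_id <- as.character(df$gene_id)
  df$replicate_id <- as.character(df$replicate_id)
  df$z <- as.numeric(df$z)
  if (anyDuplicated(paste(df$gene_id, df$replicate_id)))
    stop("one score per gene and replicate expected", call. = FALSE)
  structure(df, excluded_reagents = excluded_reagents,
            class = c("gene_scores", "data.frame"))
}

#' Per-gene summary of replicate Z-scores
#'
#' @param scores a [gene_scores()] table.
#' @return data.frame `gene_id, n_reps, mean_z` (mean over the
#'   replicates in which the gene was scored).
#' @export
gene_summary <- function(scores) {
  stopifnot(inherits(scores, "gene_scores"))
  df <- as.data.frame(scores)
  n <- aggregate(z ~ gene_id, df, length)
  m <- aggregate(z ~ gene_id, df, mean)
  out <- merge(n, m, by = "gene_id", suffixes = c("_n", "_mean"))
  names(out) <- c("gene_id", "n_reps", "mean_z")
  out[order(out$gene_id), ]
}

#' Summarized positive-control scores and screen anchors
#'
#' Control wells replicated within a screen are summarized by their
#' median Z per replicate; the anchor for each control is the mean of
#' those per-replicate scores across replicates. Anchors are the
#' empirical effect sizes of the positive enhancer (for example
#' siTP53) and inhibitor (for example siSYVN1) controls and can be
#' passed to [select_control_anchored()].
#'
#' @param zscores a `zscore_table` from [robust_z()].
#' @return list with `per_replicate` (data.frame `role, replicate_id,
#'   z_ctrl`), `anchor_enhancer` and `anchor_inhibitor` (means across
#'   replicates).
#' @export
control_anchors <- function(zscores) {
  stopifnot(inherits(zscores, "zscore_table"))
  df <- as.data.frame(zscores)
  df <- df[df$role %in% c("pos_control_enhancer", "pos_control_inhibitor") &
             is.finite(df$z), ]
  if (nrow(df) == 0L)
    stop("no scored positive-control wells", call. = FALSE)
  df$rep <- paste(df$screen_id, df$replicate_id, sep = "/")
  per_rep <- aggregate(z ~ role + rep, df, median)
  names(per_rep) <- c("role", "replicate_id", "z_ctrl")
  mean_of <- function(r) {
    v <- per_rep$z_ctrl[per_rep$role == r]
    if (length(v) == 0L) NA_real_ else mean(v)
  }
  list(per_replicate = per_rep,
       anchor_enhancer = mean_of("pos_control_enhancer"),
       anchor_inhibitor = mean_of("pos_control_inhibitor"))
}
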