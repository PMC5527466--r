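#' Fold induction relative to mock
#'
#' Converts a mock-normalized log2 value `m` (or a raw signal plus the
#' mock median) to a fold change: `F = 2^m = raw / mock_median`.
#'
#' @param m mock-normalized log2 value(s); give either `m` or both
#'   `raw` and `mock`.
#' @param raw raw signal(s), strictly positive.
#' @param mock mock reference summary (median of mock wells), strictly
#'   positive.
#' @return fold induction (dimensionless, > 0).
#' @examples
#' fold_induction(m = 1)              # 2
#' fold_induction(raw = 300, mock = 100)  # 3
#' @export
fold_induction <- function(m = NULL, raw = NULL, mock = NULL) {
  if (!is.null(m)) {
    if (!is.null(raw) || !is.null(mock))
      stop("give either m or raw+mock, not both", call. = FALSE)
    return(2^m)
  }
  if (is.null(raw) || is.null(mock))
    stop("need raw and mock when m is not given", call. = FALSE)
  if (any(raw <= 0) || any(mock <= 0))
    stop("raw and mock signals must be positive", call. = FALSE)
  raw / mock
}

#' Confirm a pooled-siRNA phenotype across experiments
#'
#' A gene's pool is confirmed when its summarized fold induction
#' reaches `fold_cut`. "At least twofold" is inclusive, so a summary
#' fold of exactly 2.0 confirms.
#'
#' @param folds fold-induction values, one per independent experiment.
#' @param fold_cut confirmation threshold (default 2).
#' @param summary `"mean"` (default) or `"geometric"` mean across
#'   experiments.
#' @return list `confirmed` (logical), `fold` (the summary value),
#'   `n_experiments`.
#' @export
confirm_pool <- function(folds, fold_cut = 2,
                         summary = c("mean", "geometric")) {
  summary <- match.arg(summary)
  if (length(folds) < 1L) stop("no experiments supplied", call. = FALSE)
  if (any(!is.finite(folds)) || any(folds <= 0))
    stop("fold values must be finite and positive", call. = FALSE)
  f <- if (summary == "mean") mean(folds) else exp(mean(log(folds)))
  list(confirmed = f >= fold_cut, fold = f, n_experiments = length(folds))
}

#' Deconvolution confirmation: k-of-n consistent single siRNAs
#'
#' Deconvolution tests each of the (typically four) siRNA duplexes of
#' a pool individually across independent experiments. A siRNA is
#' *consistent* when its fold induction reaches `fold_cut` in every
#' experiment in which it was tested; siRNAs observed in fewer than
#' `min_experiments` experiments are unevaluable and never counted. A
#' gene is *confirmed* when at least `k_required` of its siRNAs are
#' consistent -- redundancy across independent sequences is the usual
#' guard against off-target effects.
#'
#' @param deconv data.frame with columns `gene_id, sirna_id,
#'   experiment_id, fold` (folds > 0).
#' @param fold_cut per-experiment threshold, inclusive (default 2).
#' @param k_required consistent siRNAs needed to confirm a gene
#'   (default 2; 0 confirms every gene).
#' @param min_experiments experiments needed for a siRNA to be
#'   evaluable (default 2).
#' @return list with `sirna` (per-siRNA: `gene_id, sirna_id, n_experiments,
#'   evaluable, consistent`) and `genes` (per-gene: `gene_id,
#'   n_consistent, confirmed`).
#' @export
confirm_deconvolution <- function(deconv, fold_cut = 2, k_required = 2L,
                                  min_experiments = 2L) {
  required <- c("gene_id", "sirna_id", "experiment_id", "fold")
  if (!all(required %in% names(deconv)))
    stop("deconvolution table requires columns ",
         paste(required, collapse = ", "), call. = FALSE)
  if (any(!is.finite(deconv$fold)) || any(deconv$fold <= 0))
    stop("fold values must be finite and positive", call. = FALSE)
  if (k_required < 0) stop("k_required must be >= 0", call. = FALSE)

  if (anyDuplicated(paste(deconv$gene_id, deconv$sirna_id,
                          deconv$experiment_id, sep = "\r")))
    stop("one fold per siRNA and experiment expected", call. = FALSE)

  deconv$pass <- deconv$fold >= fold_cut
  n_exp <- aggregate(fold ~ gene_id + sirna_id, deconv, length)
  all_pass <- aggregate(pass ~ gene_id + sirna_id, deconv, all)
  sirna <- merge(n_exp, all_pass, by = c("gene_id", "sirna_id"))
  names(sirna) <- c("gene_id", "sirna_id", "n_experiments", "all_pass")
  sirna$evaluable <- sirna$n_experiments >= min_experiments
  sirna$consistent <- sirna$evaluable & sirna$all_pass
  sirna$all_pass <- NULL
  sirna <- sirna[order(sirna$gene_id, sirna$sirna_id), ]
  rownames(sirna) <- NULL

  n_consistent <- tapply(sirna$consistent, sirna$gene_id, sum)
  genes <- data.frame(gene_id = names(n_consistent),
                      n_consistent = as.integer(n_consistent),
                      stringsAsFactors = FALSE)
  genes$confirmed <- genes$n_consistent >= k_required
  genes <- genes[order(genes$gene_id), ]
  rownames(genes) <- NULL
  list(sirna = sirna, genes = genes)
}

#' Read a deconvolution table from CSV
#'
#' @param path CSV with header `gene_id,sirna_id,experiment_id,fold`.
#' @param sep field delimiter.
#' @return validated data.frame.
#' @export
read_deconvolution <- function(path, sep = ",") {
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                 na.strings = c("NA", ""))
  required <- c("gene_id", "sirna_id", "experiment_id", "fold")
  if (!all(required %in% names(df)))
    stop("deconvolution table requires columns ",
         paste(required, collapse = ", "), call. = FALSE)
  df$fold <- as.numeric(df$fold)
  df
}
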