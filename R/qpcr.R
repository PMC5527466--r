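#' Relative expression by the delta-delta-Ct method
#'
#' Quantifies knockdown (or induction) of a target transcript relative
#' to a reference (household) gene, comparing a treated against a
#' control condition. Replicate Ct values are averaged per
#' (condition, transcript) before differencing:
#' `dCt = mean Ct(target) - mean Ct(reference)` per condition,
#' `ddCt = dCt(treated) - dCt(control)`, relative expression
#' `= 2^-ddCt`. A value of 0.25 means 75% knockdown.
#'
#' @param ct data.frame with columns `condition, target_id, ct`
#'   (additional columns such as `sample_id` are ignored).
#' @param target target transcript id.
#' @param reference reference gene id (for example GAPDH).
#' @param treated,control condition labels (defaults `"treated"`,
#'   `"control"`).
#' @return one-row data.frame `target_id, reference_id, dct_treated,
#'   dct_control, ddct, relative_expression`.
#' @export
ddct_relative_expression <- function(ct, target, reference,
                                     treated = "treated",
                                     control = "control") {
  if (!all(c("condition", "target_id", "ct") %in% names(ct)))
    stop("Ct table requires columns condition, target_id, ct",
         call. = FALSE)
  mean_ct <- function(cond, tgt) {
    v <- ct$ct[ct$condition == cond & ct$target_id == tgt]
    v <- v[is.finite(v)]
    if (length(v) == 0L)
      stop("no Ct values for target '", tgt, "' in condition '", cond,
           "'", call. = FALSE)
    mean(v)
  }
  dct_t <- mean_ct(treated, target) - mean_ct(treated, reference)
  dct_c <- mean_ct(control, target) - mean_ct(control, reference)
  ddct <- dct_t - dct_c
  data.frame(target_id = target, reference_id = reference,
             dct_treated = dct_t, dct_control = dct_c, ddct = ddct,
             relative_expression = 2^(-ddct), stringsAsFactors = FALSE)
}

#' Absolute expression proxy by 2^-dCt
#'
#' Expression of a transcript normalized to a reference gene within
#' one sample: `2^-(Ct_target - Ct_reference)`. Replicate Cts are
#' averaged. Used for comparing splice-variant abundances on a common
#' scale.
#'
#' @param ct data.frame with columns `target_id, ct`; optionally
#'   filter first on `sample_id`/`condition`.
#' @param target target transcript id.
#' @param reference reference gene id (for example beta-actin).
#' @return numeric scalar, `2^-dCt`.
#' @export
abs_expression <- function(ct, target, reference) {
  if (!all(c("target_id", "ct") %in% names(ct)))
    stop("Ct table requires columns target_id, ct", call. = FALSE)
  one <- function(tgt) {
    v <- ct$ct[ct$target_id == tgt]
    v <- v[is.finite(v)]
    if (length(v) == 0L)
      stop("no Ct values for target '", tgt, "'", call. = FALSE)
    mean(v)
  }
  2^-(one(target) - one(reference))
}

#' Two-sample comparison of expression values
#'
#' Classical two-sided Student's t-test (equal variances by default;
#' Welch by flag) on replicate expression values, for example
#' `2^-dCt` splice-variant levels in knockdown versus nontargeting
#' samples. Two identical constant groups return t = 0, p = 1 by
#' convention rather than an error.
#'
#' @param treated,control numeric vectors, each of length >= 2.
#' @param var_equal pool variances (default `TRUE`); `FALSE` gives
#'   Welch's test.
#' @return list `statistic, p_value, df, mean_treated, mean_control`.
#' @export
variant_comparison <- function(treated, control, var_equal = TRUE) {
  if (length(treated) < 2L || length(control) < 2L)
    stop("need >= 2 replicates per group", call. = FALSE)
  if (sd(treated) == 0 && sd(control) == 0) {
    if (mean(treated) == mean(control))
      return(list(statistic = 0, p_value = 1,
                  df = length(treated) + length(control) - 2L,
                  mean_treated = mean(treated),
                  mean_control = mean(control)))
    stop("both groups are constant with different means; ",
         "the t statistic is undefined", call. = FALSE)
  }
  tt <- t.test(treated, control, var.equal = var_equal)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter),
       mean_treated = mean(treated), mean_control = mean(control))
}

#' Knockdown-phenotype concordance classification
#'
#' Off-target guard for single-siRNA validation: each siRNA pairs a
#' residual target expression (fraction of control, from qPCR) with
#' its reporter phenotype (fold induction). A siRNA is *effective*
#' when residual expression is at most `kd_cut`; an effective siRNA is
#' *concordant* if its fold induction reaches `fold_cut`, otherwise
#' *discordant*; ineffective siRNAs are *uninformative*. The gene
#' verdict is `insufficient_data` with fewer than `min_effective`
#' effective siRNAs, `disqualified` when discordant siRNAs are at
#' least as many as concordant ones among the effective set (effective
#' knockdown without the phenotype indicates the phenotype was
#' off-target), and `qualified` otherwise.
#'
#' @param records data.frame with columns `gene_id, sirna_id,
#'   residual_expression, fold_induction`.
#' @param kd_cut residual-expression cut defining effective knockdown
#'   (default 0.4, i.e. >= 60% knockdown).
#' @param fold_cut phenotype-positive fold induction (default 2).
#' @param min_effective effective siRNAs needed for a verdict
#'   (default 2).
#' @return list with `sirna` (per-siRNA classes) and `genes`
#'   (`gene_id, n_effective, n_concordant, n_discordant, verdict`).
#' @export
concordance_classify <- function(records, kd_cut = 0.4, fold_cut = 2,
                                 min_effective = 2L) {
  required <- c("gene_id", "sirna_id", "residual_expression",
                "fold_induction")
  if (!all(required %in% names(records)))
    stop("records require columns ", paste(required, collapse = ", "),
         call. = FALSE)
  df <- as.data.frame(records)
  effective <- df$residual_expression <= kd_cut
  df$class <- ifelse(!effective, "uninformative",
                     ifelse(df$fold_induction >= fold_cut,
                            "concordant", "discordant"))
  per_gene <- function(cls) {
    n_eff <- sum(cls != "uninformative")
    n_con <- sum(cls == "concordant")
    n_dis <- sum(cls == "discordant")
    verdict <- if (n_eff < min_effective) "insufficient_data"
      else if (n_dis >= n_con) "disqualified" else "qualified"
    data.frame(n_effective = n_eff, n_concordant = n_con,
               n_discordant = n_dis, verdict = verdict,
               stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, lapply(split(df$class, df$gene_id), per_gene))
  genes <- cbind(data.frame(gene_id = rownames(genes),
                            stringsAsFactors = FALSE), genes)
  rownames(genes) <- NULL
  list(sirna = df, genes = genes[order(genes$gene_id), ])
}

#' Read a qPCR Ct table from CSV
#'
#' @param path CSV with header
#'   `sample_id,condition,target_id,reference_id,ct` (reference_id
#'   optional).
#' @param sep field delimiter.
#' @return validated data.frame; Ct values must be finite.
#' @export
read_ct_table <- function(path, sep = ",") {
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                 na.strings = c("NA", ""))
  if (!all(c("condition", "target_id", "ct") %in% names(df)))
    stop("Ct table requires columns condition, target_id, ct",
         call. = FALSE)
  df$ct <- suppressWarnings(as.numeric(df$ct))
  if (any(!is.finite(df$ct)))
    stop("Ct values must be finite", call. = FALSE)
  df
}
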