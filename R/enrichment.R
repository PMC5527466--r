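#' Mann-Whitney U test with exact enumeration or normal approximation
#'
#' The U statistic for group `a` counts pairs `(a_i, b_j)` with
#' `a_i > b_j`, ties counting one half (midranks). The exact two-sided
#' p-value enumerates every assignment of the pooled values to the two
#' group sizes and measures how often `|U - n_a n_b / 2|` is at least
#' as large as observed -- valid under ties, where the permutation
#' distribution need not be the classical tie-free one. The normal
#' approximation uses the tie-corrected variance and a continuity
#' correction of 1/2.
#'
#' @param a,b numeric vectors (both nonempty).
#' @param mode `"auto"` (exact when both groups are at most
#'   `exact_limit`), `"exact"`, or `"normal_approx"`.
#' @param exact_limit largest per-group size for automatic exact
#'   enumeration (default 10).
#' @return list `U` (for group `a`), `p_value`, `mode_used`,
#'   `n_a`, `n_b`.
#' @examples
#' mannwhitney_u(c(1, 2, 3), c(4, 5, 6))  # U = 0, p = 0.1
#' @export
mannwhitney_u <- function(a, b, mode = c("auto", "exact", "normal_approx"),
                          exact_limit = 10L) {
  mode <- match.arg(mode)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0L || length(b) == 0L)
    stop("both groups must be nonempty", call. = FALSE)
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop("values must be finite", call. = FALSE)
  n_a <- length(a); n_b <- length(b); n <- n_a + n_b
  pooled <- c(a, b)
  r <- rank(pooled)  # midranks
  u_obs <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  mu <- n_a * n_b / 2

  if (mode == "auto")
    mode <- if (n_a <= exact_limit && n_b <= exact_limit) "exact"
            else "normal_approx"

  if (mode == "exact") {
    # U for any subset of indices taken as group a, from the fixed
    # midranks of the pooled multiset.
    subsets <- combn(n, n_a)
    offset <- n_a * (n_a + 1) / 2
    u_all <- colSums(matrix(r[subsets], nrow = n_a)) - offset
    dev_obs <- abs(u_obs - mu)
    p <- mean(abs(u_all - mu) >= dev_obs - 1e-9)
  } else {
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties)
    sigma2 <- n_a * n_b / 12 * ((n + 1) - tie_term / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1  # all values tied
    } else {
      dev <- max(abs(u_obs - mu) - 0.5, 0)  # continuity correction
      p <- min(1, 2 * pnorm(-dev / sqrt(sigma2)))
    }
  }
  list(U = u_obs, p_value = p, mode_used = mode, n_a = n_a, n_b = n_b)
}

#' Rank-based shift scan over gene-set subgroups
#'
#' For each subgroup of each gene set, compares the screen scores of
#' its member genes against a background distribution with a
#' two-sided Mann-Whitney test: `"genome"` background compares
#' against all scored genes outside the subgroup; `"within_set"`
#' compares against the other members of the same set (for asking
#' whether a subgroup is further enriched relative to its parent
#' set). Raw p-values are adjusted per scan.
#'
#' @param summary per-gene scores: data.frame `gene_id, mean_z` (for
#'   example from [gene_summary()]).
#' @param genesets membership table `set_name, subgroup_name, gene_id`
#'   (see [read_genesets()]).
#' @param background `"genome"` (default) or `"within_set"`.
#' @param adjust_method multiplicity adjustment passed to
#'   [stats::p.adjust()] (default `"BH"`).
#' @param min_members subgroups with fewer scored members are skipped
#'   with a warning (default 2).
#' @param mode Mann-Whitney mode (see [mannwhitney_u()]).
#' @return data.frame `set_name, subgroup_name, n_members, direction,
#'   U, p_value, p_adjusted, test`.
#' @export
subgroup_shift_scan <- function(summary, genesets,
                                background = c("genome", "within_set"),
                                adjust_method = "BH", min_members = 2L,
                                mode = "auto") {
  background <- match.arg(background)
  if (!all(c("gene_id", "mean_z") %in% names(summary)))
    stop("summary requires columns gene_id, mean_z", call. = FALSE)
  scores <- setNames(summary$mean_z, summary$gene_id)
  scores <- scores[is.finite(scores)]

  rows <- list()
  for (set in unique(genesets$set_name)) {
    set_members <- genesets[genesets$set_name == set, ]
    set_genes <- unique(set_members$gene_id)
    for (sub in unique(set_members$subgroup_name)) {
      member_genes <-
        unique(set_members$gene_id[set_members$subgroup_name == sub])
      member_scores <- scores[names(scores) %in% member_genes]
      if (length(member_scores) < min_members) {
        warning("skipping subgroup '", sub, "' of set '", set,
                "': fewer than ", min_members, " scored members",
                call. = FALSE)
        next
      }
      bg_genes <- if (background == "genome") {
        setdiff(names(scores), member_genes)
      } else {
        setdiff(intersect(set_genes, names(scores)), member_genes)
      }
      bg_scores <- scores[bg_genes]
      if (length(bg_scores) < min_members) {
        warning("skipping subgroup '", sub, "': background too small",
                call. = FALSE)
        next
      }
      mw <- mannwhitney_u(member_scores, bg_scores, mode = mode)
      shift <- median(member_scores) - median(bg_scores)
      rows[[length(rows) + 1L]] <- data.frame(
        set_name = set, subgroup_name = sub,
        n_members = length(member_scores),
        direction = if (shift > 0) "up" else if (shift < 0) "down"
                    else "none",
        U = mw$U, p_value = mw$p_value,
        test = paste0("mannwhitney_", mw$mode_used),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    stop("no testable subgroups", call. = FALSE)
  out <- do.call(rbind, rows)
  out$p_adjusted <- p.adjust(out$p_value, method = adjust_method)
  out[c("set_name", "subgroup_name", "n_members", "direction", "U",
        "p_value", "p_adjusted", "test")]
}

#' Many-to-one comparisons with Monte-Carlo Dunnett adjustment
#'
#' Compares each treatment group against a shared control under the
#' pooled-variance (one-way ANOVA) model, adjusting for the family of
#' comparisons via the null distribution of the maximum absolute
#' Dunnett t statistic. That null is evaluated by Monte Carlo: group
#' and control means are drawn as independent normals with variances
#' `1/n_j`, the pooled variance as a scaled chi-square with the ANOVA
#' residual degrees of freedom, and the adjusted p-value of group `i`
#' is the fraction of draws whose max-|t| reaches `|t_i|`. Results
#' are deterministic given `seed`.
#'
#' @param groups list of numeric vectors (the treatment groups).
#' @param control numeric vector, the shared comparison group.
#' @param n_mc Monte-Carlo draws (default 1e5).
#' @param seed integer seed; the caller's RNG state is preserved.
#' @return data.frame `group, n, mean_diff, t, df, p_unadjusted,
#'   p_adjusted`, with attribute `pooled_sd`.
#' @export
dunnett_many_to_one <- function(groups, control, n_mc = 1e5L,
                                seed = NULL) {
  if (!is.list(groups) || length(groups) < 1L)
    stop("groups must be a nonempty list of numeric vectors",
         call. = FALSE)
  if (length(control) < 2L)
    stop("control group needs >= 2 values", call. = FALSE)
  k <- length(groups)
  ns <- vapply(groups, length, integer(1))
  if (any(ns < 2L)) stop("every group needs >= 2 values", call. = FALSE)
  n_c <- length(control)
  df <- sum(ns) + n_c - (k + 1L)
  ss <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1))) +
    sum((control - mean(control))^2)
  s2 <- ss / df
  if (s2 <= 0)
    stop("pooled variance is zero; groups are constant", call. = FALSE)

  se <- sqrt(s2 * (1 / ns + 1 / n_c))
  diffs <- vapply(groups, mean, numeric(1)) - mean(control)
  t_obs <- diffs / se

  max_t_null <- with_seed(seed, {
    zg <- matrix(rnorm(n_mc * k), n_mc, k)
    zg <- sweep(zg, 2L, sqrt(1 / ns), `*`)
    zc <- rnorm(n_mc, sd = sqrt(1 / n_c))
    s2_mc <- rchisq(n_mc, df) / df
    tmat <- abs(zg - zc) / sweep(matrix(sqrt(s2_mc), n_mc, k), 2L,
                                 sqrt(1 / ns + 1 / n_c), `*`)
    m <- tmat[, 1L]
    for (j in seq_len(k)[-1L]) m <- pmax(m, tmat[, j])
    m
  })
  p_adj <- vapply(abs(t_obs),
                  function(t) mean(max_t_null >= t), numeric(1))
  # a familywise-adjusted p can never undercut the single-comparison p;
  # clamp out Monte-Carlo noise so the coherence holds exactly
  p_adj <- pmax(p_adj, 2 * pt(-abs(t_obs), df))
  nm <- names(groups) %||% paste0("group", seq_len(k))
  nm[nm == ""] <- paste0("group", which(nm == ""))
  out <- data.frame(group = nm, n = ns, mean_diff = diffs, t = t_obs,
                    df = df, p_unadjusted = 2 * pt(-abs(t_obs), df),
                    p_adjusted = p_adj,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "pooled_sd") <- sqrt(s2)
  out
}
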