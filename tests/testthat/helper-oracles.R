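# Independent brute-force oracles, deliberately written without the
# package's rank/median machinery so equivalence tests have teeth.

# Median by explicit sorting.
brute_median <- function(x) {
  s <- sort(x)
  n <- length(s)
  if (n %% 2L == 1L) s[(n + 1L) / 2L] else (s[n / 2L] + s[n / 2L + 1L]) / 2
}

brute_mad <- function(x) brute_median(abs(x - brute_median(x)))

brute_robust_z <- function(x, reference = x, c_mad = 1.4826) {
  (x - brute_median(reference)) / (c_mad * brute_mad(reference))
}

# Mann-Whitney U by direct pair counting (ties count one half) and
# exact two-sided p by enumerating every split of the pooled values.
brute_u <- function(a, b) {
  sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
}

brute_mw_exact <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  n_a <- length(a)
  mu <- n_a * length(b) / 2
  u_obs <- brute_u(a, b)
  splits <- utils::combn(n, n_a)
  u_all <- apply(splits, 2L, function(idx)
    brute_u(pooled[idx], pooled[-idx]))
  p <- mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
  list(U = u_obs, p_value = p)
}

# Build a one-plate screen from raw values per role. Wells are laid
# out left to right across a 16x24 plate.
make_screen <- function(mock = NULL, library_vals = NULL,
                        nontargeting = NULL, pos_enh = NULL,
                        pos_inh = NULL, plate_id = "P1",
                        screen_id = "S1", replicate_id = "R1",
                        channel = "reporter_luminescence",
                        lib_genes = NULL) {
  roles <- c(rep("mock", length(mock)),
             rep("nontargeting", length(nontargeting)),
             rep("pos_control_enhancer", length(pos_enh)),
             rep("pos_control_inhibitor", length(pos_inh)),
             rep("library", length(library_vals)))
  values <- c(mock, nontargeting, pos_enh, pos_inh, library_vals)
  n <- length(values)
  stopifnot(n <= 16 * 24)
  pos <- expand.grid(col = 1:24, row = 1:16)[seq_len(n), ]
  n_lib <- length(library_vals)
  if (is.null(lib_genes)) lib_genes <- sprintf("g%03d", seq_len(n_lib))
  reagent <- rep(NA_character_, n)
  gene <- rep(NA_character_, n)
  reagent[roles == "nontargeting"] <- "NT"
  reagent[roles == "pos_control_enhancer"] <- "siTP53"
  reagent[roles == "pos_control_inhibitor"] <- "siSYVN1"
  reagent[roles == "library"] <- paste0("r_", lib_genes)
  gene[roles == "library"] <- lib_genes
  layout <- plate_layout(data.frame(
    plate_id = plate_id, row = pos$row, col = pos$col, role = roles,
    reagent_id = reagent, gene_id = gene, stringsAsFactors = FALSE))
  meas <- screen_measurements(data.frame(
    screen_id = screen_id, replicate_id = replicate_id,
    plate_id = plate_id, row = pos$row, col = pos$col,
    channel = channel, value = values, stringsAsFactors = FALSE), layout)
  list(layout = layout, measurements = meas)
}

# gene_scores table from a genes x replicates Z matrix.
scores_from_matrix <- function(zmat) {
  genes <- rownames(zmat) %||% sprintf("g%03d", seq_len(nrow(zmat)))
  reps <- colnames(zmat) %||% sprintf("R%d", seq_len(ncol(zmat)))
  df <- expand.grid(gene_id = genes, replicate_id = reps,
                    stringsAsFactors = FALSE)
  df$z <- as.vector(zmat)
  df <- df[!is.na(df$z), ]
  gene_scores(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
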