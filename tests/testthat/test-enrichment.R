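test_that("exact Mann-Whitney reproduces enumeration landmarks", {
  res <- mannwhitney_u(c(1, 2, 3), c(4, 5, 6), mode = "exact")
  expect_equal(res$U, 0)
  expect_equal(res$p_value, 0.1)  # 2 of the 20 splits are as extreme

  ties <- mannwhitney_u(c(1, 2), c(1, 2), mode = "exact")
  expect_equal(ties$U, 2)  # n_a * n_b / 2 under full ties
  expect_equal(ties$p_value, 1)

  expect_error(mannwhitney_u(numeric(0), 1), "nonempty")
})

test_that("U_a + U_b = n_a * n_b for arbitrary data", {
  set.seed(61)
  for (i in 1:20) {
    a <- sample(1:8, sample(2:6, 1), replace = TRUE)
    b <- sample(1:8, sample(2:6, 1), replace = TRUE)
    ua <- mannwhitney_u(a, b)$U
    ub <- mannwhitney_u(b, a)$U
    expect_equal(ua + ub, length(a) * length(b))
  }
})

test_that("exact p agrees with the brute-force enumeration oracle", {
  set.seed(62)
  for (i in 1:60) {
    n_a <- sample(1:6, 1); n_b <- sample(1:6, 1)
    # draws from a small integer alphabet so ties are common
    a <- sample(1:5, n_a, replace = TRUE)
    b <- sample(1:5, n_b, replace = TRUE)
    got <- mannwhitney_u(a, b, mode = "exact")
    want <- brute_mw_exact(a, b)
    expect_equal(got$U, want$U)
    expect_equal(got$p_value, want$p_value, tolerance = 1e-12)
  }
})

test_that("tie-free exact p matches wilcox.test", {
  set.seed(63)
  for (i in 1:20) {
    a <- rnorm(sample(3:6, 1)); b <- rnorm(sample(3:6, 1))
    got <- mannwhitney_u(a, b, mode = "exact")
    ref <- suppressWarnings(wilcox.test(a, b, exact = TRUE))
    expect_equal(got$U, unname(ref$statistic))
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("normal approximation converges to the exact p", {
  set.seed(64)
  for (i in 1:10) {
    a <- rnorm(15); b <- rnorm(15, mean = 0.4)
    p_exact <- suppressWarnings(wilcox.test(a, b, exact = TRUE))$p.value
    p_norm <- mannwhitney_u(a, b, mode = "normal_approx")$p_value
    expect_lt(abs(p_norm - p_exact), 0.01)
  }
})

test_that("subgroup scan: null p-values are roughly uniform", {
  set.seed(65)
  med_p <- median(replicate(200, {
    scores <- data.frame(gene_id = sprintf("g%03d", 1:220),
                         mean_z = rnorm(220))
    sets <- data.frame(set_name = "s", subgroup_name = "sub",
                       gene_id = sprintf("g%03d", 1:20))
    subgroup_shift_scan(scores, sets, mode = "normal_approx")$p_value
  }))
  expect_gt(med_p, 0.35)
  expect_lt(med_p, 0.65)
})

test_that("subgroup scan detects a shifted subgroup with power", {
  hits <- 0L
  for (seed in 1:20) {
    set.seed(seed + 100)
    n_bg <- 2000
    scores <- data.frame(gene_id = sprintf("g%04d", 1:(n_bg + 20)),
                         mean_z = c(rnorm(n_bg), rnorm(20, mean = 1)))
    sets <- data.frame(set_name = "s", subgroup_name = "shifted",
                       gene_id = sprintf("g%04d", (n_bg + 1):(n_bg + 20)))
    res <- subgroup_shift_scan(scores, sets, mode = "normal_approx")
    if (res$p_adjusted < 0.01 && res$direction == "up") hits <- hits + 1L
  }
  expect_gte(hits, 19L)  # >= 95% of seeds
})

test_that("subgroup scan adjusts p upward and skips tiny subgroups", {
  set.seed(66)
  scores <- data.frame(gene_id = sprintf("g%03d", 1:100),
                       mean_z = rnorm(100))
  sets <- rbind(
    data.frame(set_name = "s", subgroup_name = "a",
               gene_id = sprintf("g%03d", 1:10)),
    data.frame(set_name = "s", subgroup_name = "b",
               gene_id = sprintf("g%03d", 11:20)),
    data.frame(set_name = "s", subgroup_name = "tiny",
               gene_id = "g021"))
  expect_warning(res <- subgroup_shift_scan(scores, sets),
                 "fewer than")
  expect_equal(nrow(res), 2L)
  expect_true(all(res$p_adjusted >= res$p_value))
})

test_that("within-set background compares against the parent set", {
  scores <- data.frame(gene_id = sprintf("g%03d", 1:40),
                       mean_z = c(rep(3, 10), rep(0, 30)))
  sets <- data.frame(set_name = "s",
                     subgroup_name = rep(c("strong", "rest"), c(10, 30)),
                     gene_id = sprintf("g%03d", 1:40))
  res <- subgroup_shift_scan(scores, sets, background = "within_set",
                             mode = "normal_approx")
  strong <- res[res$subgroup_name == "strong", ]
  expect_equal(strong$direction, "up")
  expect_lt(strong$p_value, 0.001)
})

test_that("Dunnett with one group matches the unadjusted t-test", {
  set.seed(67)
  g <- rnorm(12, mean = 1); ctrl <- rnorm(12)
  res <- dunnett_many_to_one(list(g), ctrl, n_mc = 2e5, seed = 7)
  ref <- t.test(g, ctrl, var.equal = TRUE)$p.value
  expect_equal(res$p_adjusted, ref, tolerance = 0.02)
  expect_equal(res$p_unadjusted, ref, tolerance = 1e-12)
})

test_that("Dunnett adjusted p is coherent and monotone in |t|", {
  set.seed(68)
  groups <- list(a = rnorm(8, 0.2), b = rnorm(8, 1), c = rnorm(8, 2.5))
  res <- dunnett_many_to_one(groups, rnorm(8), n_mc = 5e4, seed = 11)
  expect_true(all(res$p_adjusted >= res$p_unadjusted))
  ord <- order(abs(res$t))
  expect_true(all(diff(res$p_adjusted[ord]) <= 0))
  expect_error(dunnett_many_to_one(list(rep(1, 5)), rep(1, 5)),
               "pooled variance")
})

test_that("Dunnett results are deterministic given a seed", {
  set.seed(69)
  groups <- list(rnorm(6), rnorm(6, 1))
  ctrl <- rnorm(6)
  r1 <- dunnett_many_to_one(groups, ctrl, n_mc = 1e4, seed = 42)
  r2 <- dunnett_many_to_one(groups, ctrl, n_mc = 1e4, seed = 42)
  expect_identical(r1, r2)
  # and the caller's RNG stream is untouched
  set.seed(5); before <- rnorm(1)
  set.seed(5); invisible(dunnett_many_to_one(groups, ctrl, n_mc = 1e3,
                                             seed = 1)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("Dunnett detects the shifted group and contains false flags", {
  shifted_found <- 0L
  sims_with_false_flag <- 0L
  for (seed in 1:20) {
    set.seed(seed + 300)
    groups <- c(lapply(1:4, function(i) rnorm(8)),
                list(shifted = rnorm(8, mean = 3)))
    res <- dunnett_many_to_one(groups, rnorm(8), n_mc = 2e4, seed = seed)
    sig <- res$group[res$p_adjusted < 0.05]
    if ("shifted" %in% sig) shifted_found <- shifted_found + 1L
    if (length(setdiff(sig, "shifted")) > 0L)
      sims_with_false_flag <- sims_with_false_flag + 1L
  }
  expect_gte(shifted_found, 19L)  # a 3-pooled-SD shift is near-certain
  # with familywise error held at 5%, sims flagging any null group are
  # Binomial(20, ~0.05); bound at its 99.9% envelope
  expect_lte(sims_with_false_flag, qbinom(0.999, 20, 0.05))
})

test_that("Monte-Carlo Dunnett agrees with the multivariate-t reference", {
  set.seed(70)
  dat <- data.frame(
    y = c(rnorm(8), rnorm(8, 1), rnorm(8, 2)),
    grp = factor(rep(c("ctrl", "g1", "g2"), each = 8),
                 levels = c("ctrl", "g1", "g2")))
  fit <- stats::aov(y ~ grp, data = dat)
  ref <- summary(multcomp::glht(fit, linfct = multcomp::mcp(grp = "Dunnett")))
  ref_p <- as.numeric(ref$test$pvalues)
  res <- dunnett_many_to_one(
    list(g1 = dat$y[dat$grp == "g1"], g2 = dat$y[dat$grp == "g2"]),
    dat$y[dat$grp == "ctrl"], n_mc = 2e5, seed = 99)
  expect_equal(res$p_adjusted, ref_p, tolerance = 0.02)
})
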