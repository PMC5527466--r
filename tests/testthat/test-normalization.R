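test_that("per-plate log2 normalization centres on the mock median", {
  scr <- make_screen(mock = c(100, 100, 100, 100),
                     library_vals = c(400, 100))
  norm <- log2_normalize(scr$measurements, scr$layout)
  lib <- norm$m[norm$role == "library"]
  expect_equal(lib, c(2, 0))
  expect_equal(median(norm$m[norm$role == "mock"]), 0)

  scr2 <- make_screen(mock = c(64, 128, 256), library_vals = 32)
  norm2 <- log2_normalize(scr2$measurements, scr2$layout)
  expect_equal(norm2$m[norm2$role == "library"], -2)
})

test_that("a plate without usable reference wells fails by name", {
  scr <- make_screen(nontargeting = c(100, 100),
                     library_vals = c(400, 50), plate_id = "P7")
  expect_error(log2_normalize(scr$measurements, scr$layout,
                              reference_role = "mock"),
               "mock reference wells on plate P7")
  # the same plate normalizes fine against its nontargeting wells
  expect_silent(log2_normalize(scr$measurements, scr$layout,
                               reference_role = "nontargeting"))
})

test_that("robust Z matches hand computation and is location invariant", {
  x <- c(1, 2, 3, 4, 100)  # median 3, raw MAD 1
  z <- robust_z_scores(x)
  expect_equal(z[4], 1 / 1.4826, tolerance = 1e-12)
  expect_equal(z[2], -1 / 1.4826, tolerance = 1e-12)
  expect_equal(robust_z_scores(x + 17), z, tolerance = 1e-12)
  expect_error(robust_z_scores(rep(5, 6)), "MAD.*zero")
})

test_that("library-well Z has median 0 and scaled MAD 1 per replicate", {
  set.seed(11)
  scr <- make_screen(mock = rep(100, 4) * 2^rnorm(4, sd = 0.1),
                     library_vals = 100 * 2^rnorm(60, sd = 0.6))
  z <- robust_z(log2_normalize(scr$measurements, scr$layout))
  lib_z <- z$z[z$role == "library"]
  expect_lt(abs(median(lib_z)), 1e-9)
  expect_lt(abs(1.4826 * median(abs(lib_z - median(lib_z))) - 1), 1e-9)
})

test_that("robust Z is invariant to rescaling all raw signals", {
  set.seed(12)
  vals <- 100 * 2^rnorm(40, sd = 0.5)
  scr1 <- make_screen(mock = rep(100, 4), library_vals = vals)
  scr2 <- make_screen(mock = rep(100, 4) * 7, library_vals = vals * 7)
  z1 <- robust_z(log2_normalize(scr1$measurements, scr1$layout))
  z2 <- robust_z(log2_normalize(scr2$measurements, scr2$layout))
  expect_equal(z1$z, z2$z, tolerance = 1e-12)
})

test_that("controls are scored against the library distribution", {
  set.seed(13)
  scr <- make_screen(mock = rep(100, 4),
                     pos_inh = rep(1600, 3),  # +4 log2 vs mock
                     library_vals = 100 * 2^rnorm(50, sd = 0.5))
  z <- robust_z(log2_normalize(scr$measurements, scr$layout))
  inh_z <- z$z[z$role == "pos_control_inhibitor"]
  expect_true(all(inh_z > 3))  # 4 log2 units / ~0.5 scale
  anchors <- control_anchors(z)
  expect_equal(anchors$anchor_inhibitor, median(inh_z))
})

test_that("gene aggregation averages replicate scores", {
  sc <- gene_scores(data.frame(
    gene_id = "g1", replicate_id = c("R1", "R2", "R3"),
    z = c(3.5, 3.2, 4.1)))
  expect_equal(gene_summary(sc)$mean_z, mean(c(3.5, 3.2, 4.1)))
  expect_equal(gene_summary(sc)$mean_z, 3.6, tolerance = 1e-12)

  single <- gene_scores(data.frame(gene_id = "g1", replicate_id = "R1",
                                   z = 2.2))
  expect_equal(gene_summary(single)$mean_z, 2.2)
})

test_that("unmapped library reagents are excluded with a warning", {
  scr <- make_screen(mock = rep(100, 4),
                     library_vals = c(90, 100, 110, 130, 70, 105))
  z <- robust_z(log2_normalize(scr$measurements, scr$layout))
  ann <- data.frame(reagent_id = unique(z$reagent_id[z$role == "library"])[-1],
                    gene_id = paste0("G", 1:5))
  expect_warning(sc <- aggregate_gene_scores(z, annotation = ann),
                 "without a gene mapping")
  expect_equal(length(attr(sc, "excluded_reagents")), 1L)
  expect_equal(nrow(sc), 5L)
})

test_that("module robust Z equals the brute-force median/MAD oracle", {
  set.seed(14)
  for (i in 1:50) {
    x <- round(rnorm(sample(4:20, 1), sd = 3), 2)
    if (brute_mad(x) == 0) next
    expect_equal(robust_z_scores(x), brute_robust_z(x), tolerance = 1e-12)
  }
})

test_that("per-plate scoring scope is available and differs", {
  set.seed(15)
  mk <- function(plate, rep_id, sd) {
    vals <- 100 * 2^rnorm(30, sd = sd)
    scr <- make_screen(mock = rep(100, 4), library_vals = vals,
                       plate_id = plate, replicate_id = rep_id)
    list(layout = as.data.frame(scr$layout),
         meas = as.data.frame(scr$measurements))
  }
  a <- mk("P1", "R1", 0.3)
  b <- mk("P2", "R1", 1.2)  # noisier plate
  layout <- plate_layout(rbind(a$layout, b$layout))
  meas <- screen_measurements(rbind(a$meas, b$meas), layout)
  norm <- log2_normalize(meas, layout)
  z_rep <- robust_z(norm, scope = "per_replicate")
  z_plate <- robust_z(norm, scope = "per_plate")
  expect_false(isTRUE(all.equal(z_rep$z, z_plate$z)))
  # per-plate scope restores unit scaled MAD on each plate separately
  for (p in c("P1", "P2")) {
    lib <- z_plate$z[z_plate$role == "library" & z_plate$plate_id == p]
    expect_lt(abs(1.4826 * median(abs(lib - median(lib))) - 1), 1e-9)
  }
})
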