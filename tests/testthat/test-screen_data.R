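test_that("layout files parse, validate roles, and round-trip", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("plate_id,row,col,role,reagent_id,gene_id",
               "P1,1,1,mock,,",
               "P1,1,2,library,pool_a,geneA"), path)
  lay <- read_layout(path)
  expect_s3_class(lay, "plate_layout")
  expect_equal(nrow(lay), 2L)
  expect_setequal(lay$role, c("mock", "library"))
  expect_equal(lay$reagent_id[lay$role == "library"], "pool_a")

  out <- withr::local_tempfile(fileext = ".csv")
  write_layout(lay, out)
  expect_equal(as.data.frame(read_layout(out)), as.data.frame(lay))

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("plate_id,row,col,role,reagent_id,gene_id",
               "P1,1,1,moock,,"), bad)
  expect_error(read_layout(bad), "allowed roles.*library.*mock")
})

test_that("letter-form row indices are normalized to integers", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("plate_id,row,col,role,reagent_id,gene_id",
               "P1,A,1,mock,,",
               "P1,B,3,library,pool_a,geneA"), path)
  lay <- read_layout(path)
  expect_identical(lay$row, c(1L, 2L))
})

test_that("duplicate and out-of-bounds wells are rejected by name", {
  base <- data.frame(plate_id = "P1", row = c(1, 1), col = c(2, 2),
                     role = "library",
                     reagent_id = c("a", "b"), gene_id = c("ga", "gb"))
  expect_error(plate_layout(base), "duplicate well.*P1.*\\(1,2\\)")
  oob <- data.frame(plate_id = "P1", row = 17, col = 1, role = "mock",
                    reagent_id = NA, gene_id = NA)
  expect_error(plate_layout(oob), "out of bounds")
  expect_silent(plate_layout(oob, n_rows = 32, n_cols = 48))
})

test_that("reagent rules per role are enforced", {
  no_reagent <- data.frame(plate_id = "P1", row = 1, col = 1,
                           role = "library", reagent_id = NA,
                           gene_id = "g")
  expect_error(plate_layout(no_reagent), "without reagent_id")
  mock_with <- data.frame(plate_id = "P1", row = 1, col = 1,
                          role = "mock", reagent_id = "x", gene_id = NA)
  expect_error(plate_layout(mock_with), "must not carry")
})

test_that("measurements validate positivity, wells, and round-trip", {
  scr <- make_screen(mock = c(100, 100), library_vals = c(400, 50))
  expect_s3_class(scr$measurements, "screen_measurements")
  expect_equal(scr$measurements$value[1], 100)

  df <- as.data.frame(scr$measurements)
  df$value[1] <- 0
  expect_error(screen_measurements(df, scr$layout), "values > 0")

  df2 <- as.data.frame(scr$measurements)
  df2$row[1] <- 15  # not defined in the layout
  expect_error(screen_measurements(df2, scr$layout),
               "absent from the layout")

  path <- withr::local_tempfile(fileext = ".csv")
  write_measurements(scr$measurements, path)
  back <- read_measurements(path, scr$layout)
  expect_equal(as.data.frame(back), as.data.frame(scr$measurements))
})

test_that("missing measurements stay missing, never zero", {
  scr <- make_screen(mock = c(100, 100), library_vals = c(400, 50))
  df <- as.data.frame(scr$measurements)
  df$value[4] <- NA
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE, na = "")
  back <- read_measurements(path, scr$layout)
  expect_true(is.na(back$value[4]))
  expect_false(any(back$value == 0, na.rm = TRUE))
})

test_that("annotation and gene-set readers validate their schemas", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("reagent_id,gene_id", "r1,g1", "r2,g1"), p)
  ann <- read_annotation(p)
  expect_equal(nrow(ann), 2L)  # many-to-one is fine
  writeLines(c("reagent_id,gene_id", "r1,g1", "r1,g2"), p)
  expect_error(read_annotation(p), "more than one gene")

  g <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("set_name,subgroup_name,gene_id", "s,sub,g1"), g)
  expect_equal(read_genesets(g)$gene_id, "g1")
  writeLines(c("set_name,gene_id", "s,g1"), g)
  expect_error(read_genesets(g), "subgroup_name")
})

test_that("random corruption triggers only documented error classes", {
  set.seed(42)
  for (i in 1:25) {
    df <- data.frame(plate_id = "P1", row = sample(1:16, 6),
                     col = sample(1:24, 6),
                     role = sample(c("library", "mock"), 6, TRUE),
                     reagent_id = NA_character_,
                     gene_id = NA_character_)
    df$reagent_id[df$role == "library"] <-
      paste0("r", seq_len(sum(df$role == "library")))
    corruption <- sample(c("none", "dup", "oob", "role"), 1)
    if (corruption == "dup") { df$row[2] <- df$row[1]; df$col[2] <- df$col[1] }
    if (corruption == "oob") df$col[1] <- 99L
    if (corruption == "role") df$role[1] <- "banana"
    if (corruption == "none") {
      expect_silent(plate_layout(df))
    } else {
      expect_error(plate_layout(df),
                   "duplicate well|out of bounds|unknown well role")
    }
  }
})
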