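#' Construct and validate a plate layout
#'
#' A plate layout maps wells of one or more microtitre plates to their
#' role in the screen (library, mock, nontargeting, positive control,
#' empty) and to the reagent and gene they carry. Row/column indices are
#' 1-based; the row field also accepts plate-reader letter notation
#' ("A".."P" for a 384-well plate), which is normalized to integers.
#'
#' @param wells data.frame with columns `plate_id`, `row`, `col`,
#'   `role`, `reagent_id`, `gene_id`. `reagent_id`/`gene_id` may be NA
#'   for wells that carry no reagent.
#' @param n_rows,n_cols plate geometry (defaults 16 x 24; 8 x 12 and
#'   other rectangular formats are supported).
#' @return data.frame of class `plate_layout` with integer `row`/`col`
#'   and attributes `n_rows`, `n_cols`.
#' @examples
#' lay <- plate_layout(data.frame(
#'   plate_id = "P1", row = c(1, 1), col = c(1, 2),
#'   role = c("mock", "library"),
#'   reagent_id = c(NA, "pool_A"), gene_id = c(NA, "geneA")))
#' @export
plate_layout <- function(wells, n_rows = 16L, n_cols = 24L) {
  required <- c("plate_id", "row", "col", "role", "reagent_id", "gene_id")
  missing_cols <- setdiff(required, names(wells))
  if (length(missing_cols) > 0L)
    stop("layout is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  wells <- as.data.frame(wells)[required]
  wells$plate_id <- as.character(wells$plate_id)
  wells$row <- normalize_row_index(wells$row)
  wells$col <- as.integer(wells$col)
  wells$role <- as.character(wells$role)
  wells$reagent_id <- as.character(wells$reagent_id)
  wells$gene_id <- as.character(wells$gene_id)

  bad_role <- setdiff(unique(wells$role), WELL_ROLES)
  if (length(bad_role) > 0L)
    stop("unknown well role(s): ", paste(bad_role, collapse = ", "),
         "; allowed roles are: ", paste(WELL_ROLES, collapse = ", "),
         call. = FALSE)

  oob <- is.na(wells$row) | is.na(wells$col) |
    wells$row < 1L | wells$row > n_rows |
    wells$col < 1L | wells$col > n_cols
  if (any(oob))
    stop("well index out of bounds for ", n_rows, "x", n_cols,
         " plate: ", well_label(wells[which(oob)[1L], ]), call. = FALSE)

  key <- paste(wells$plate_id, wells$row, wells$col)
  if (anyDuplicated(key))
    stop("duplicate well definition: ",
         well_label(wells[which(duplicated(key))[1L], ]), call. = FALSE)

  needs_reagent <- wells$role %in%
    c("library", "nontargeting", "pos_control_enhancer",
      "pos_control_inhibitor")
  if (any(needs_reagent & is.na(wells$reagent_id)))
    stop("library/control well without reagent_id: ",
         well_label(wells[which(needs_reagent & is.na(wells$reagent_id))[1L], ]),
         call. = FALSE)
  no_reagent <- wells$role %in% c("mock", "empty")
  if (any(no_reagent & !is.na(wells$reagent_id)))
    stop("mock/empty well must not carry a reagent_id: ",
         well_label(wells[which(no_reagent & !is.na(wells$reagent_id))[1L], ]),
         call. = FALSE)

  structure(wells, n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
            class = c("plate_layout", "data.frame"))
}

# "A" -> 1, "B" -> 2, ...; numeric strings pass through.
normalize_row_index <- function(x) {
  x <- as.character(x)
  out <- suppressWarnings(as.integer(x))
  letters_idx <- is.na(out) & grepl("^[A-Za-z]$", x)
  out[letters_idx] <- match(toupper(x[letters_idx]), LETTERS)
  if (any(is.na(out) & !is.na(x)))
    stop("unparseable row index: ", x[which(is.na(out) & !is.na(x))[1L]],
         call. = FALSE)
  out
}

well_label <- function(w) {
  sprintf("plate %s well (%s,%s)", w$plate_id, w$row, w$col)
}

#' Read a plate layout from a delimited text file
#'
#' Expects a header row with columns
#' `plate_id,row,col,role,reagent_id,gene_id`. Rows may be given as
#' integers or as plate letters ("A1" style split across `row`/`col`).
#'
#' @param path file path.
#' @param n_rows,n_cols plate geometry.
#' @param sep field delimiter; `","` (default) or `"\t"`.
#' @return a [plate_layout()].
#' @export
read_layout <- function(path, n_rows = 16L, n_cols = 24L, sep = ",") {
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                 na.strings = c("NA", ""))
  plate_layout(df, n_rows = n_rows, n_cols = n_cols)
}

#' Write a plate layout to CSV
#'
#' Column order is stable (`plate_id,row,col,role,reagent_id,gene_id`)
#' so that `read_layout(write_layout(x))` round-trips exactly.
#'
#' @param layout a [plate_layout()].
#' @param path output file path.
#' @param sep field delimiter.
#' @return `path`, invisibly.
#' @export
write_layout <- function(layout, path, sep = ",") {
  stopifnot(inherits(layout, "plate_layout"))
  write.table(as.data.frame(layout), path, sep = sep, row.names = FALSE,
              quote = FALSE, na = "NA")
  invisible(path)
}

#' @export
print.plate_layout <- function(x, ...) {
  cat(sprintf("<plate_layout> %d wells on %d plate(s), %dx%d format\n",
              nrow(x), length(unique(x$plate_id)),
              attr(x, "n_rows"), attr(x, "n_cols")))
  print(table(role = x$role))
  invisible(x)
}
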