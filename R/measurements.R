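#' Construct a validated table of raw well measurements
#'
#' Holds raw per-well signals (luminescence or fluorescence) for one
#' channel across screens, replicates and plates. Signals must be
#' strictly positive (log2 must be defined); a missing measurement is
#' recorded as `NA`, never as zero, and is excluded from downstream
#' medians and MADs.
#'
#' @param values data.frame with columns `screen_id`, `replicate_id`,
#'   `plate_id`, `row`, `col`, `channel`, `value`.
#' @param layout a [plate_layout()]; every measured well must exist in
#'   the layout.
#' @return data.frame of class `screen_measurements`.
#' @export
screen_measurements <- function(values, layout) {
  stopifnot(inherits(layout, "plate_layout"))
  required <- c("screen_id", "replicate_id", "plate_id", "row", "col",
                "channel", "value")
  missing_cols <- setdiff(required, names(values))
  if (length(missing_cols) > 0L)
    stop("measurement table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  values <- as.data.frame(values)[required]
  for (col in c("screen_id", "replicate_id", "plate_id", "channel"))
    values[[col]] <- as.character(values[[col]])
  values$row <- normalize_row_index(values$row)
  values$col <- as.integer(values$col)
  values$value <- as.numeric(values$value)

  bad_channel <- setdiff(unique(values$channel), CHANNELS)
  if (length(bad_channel) > 0L)
    stop("unknown channel(s): ", paste(bad_channel, collapse = ", "),
         "; allowed: ", paste(CHANNELS, collapse = ", "), call. = FALSE)

  nonpos <- !is.na(values$value) & values$value <= 0
  if (any(nonpos))
    stop("nonpositive measurement value (log2 requires values > 0) at ",
         well_label(values[which(nonpos)[1L], ]), call. = FALSE)

  layout_key <- paste(layout$plate_id, layout$row, layout$col)
  meas_key <- paste(values$plate_id, values$row, values$col)
  unknown <- !(meas_key %in% layout_key)
  if (any(unknown))
    stop("measurement refers to a well absent from the layout: ",
         well_label(values[which(unknown)[1L], ]), call. = FALSE)

  structure(values, class = c("screen_measurements", "data.frame"))
}

#' Read raw well measurements from a delimited text file
#'
#' @param path file path; header columns
#'   `screen_id,replicate_id,plate_id,row,col,channel,value`.
#' @param layout a [plate_layout()] used to validate well coordinates.
#' @param sep field delimiter.
#' @return a [screen_measurements()] table. Missing values (empty field
#'   or `NA`) stay missing.
#' @export
read_measurements <- function(path, layout, sep = ",") {
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                 na.strings = c("NA", ""))
  screen_measurements(df, layout)
}

#' Write measurements to CSV (stable column order, round-trip safe)
#'
#' @param measurements a [screen_measurements()] table.
#' @param path output file path.
#' @param sep field delimiter.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(measurements, path, sep = ",") {
  stopifnot(inherits(measurements, "screen_measurements"))
  write.table(as.data.frame(measurements), path, sep = sep,
              row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Read a reagent-to-gene annotation table
#'
#' @param path CSV with header `reagent_id,gene_id,gene_symbol`
#'   (symbol optional). The mapping must be many-to-one: a reagent maps
#'   to exactly one gene.
#' @param sep field delimiter.
#' @return data.frame with one row per reagent.
#' @export
read_annotation <- function(path, sep = ",") {
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                 na.strings = c("NA", ""))
  if (!all(c("reagent_id", "gene_id") %in% names(df)))
    stop("annotation requires columns reagent_id, gene_id", call. = FALSE)
  if (anyDuplicated(df$reagent_id))
    stop("annotation maps a reagent to more than one gene: ",
         df$reagent_id[which(duplicated(df$reagent_id))[1L]], call. = FALSE)
  df
}

#' Read a gene-set membership table
#'
#' Gene sets (for example KEGG pathway subgroups) are consumed from a
#' plain table; there is no live database access.
#'
#' @param path CSV with header `set_name,subgroup_name,gene_id`.
#' @param sep field delimiter.
#' @return data.frame of memberships.
#' @export
read_genesets <- function(path, sep = ",") {
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                 na.strings = c("NA", ""))
  if (!all(c("set_name", "subgroup_name", "gene_id") %in% names(df)))
    stop("gene-set table requires columns set_name, subgroup_name, gene_id",
         call. = FALSE)
  df$gene_id <- as.character(df$gene_id)
  df
}
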