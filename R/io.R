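#' Read a wide protein quantification table
#'
#' Parses a Proteome-Discoverer-style export: one row per protein, one
#' abundance column per LC-MS file x TMT channel. Abundance columns are
#' recognised by a trailing TMT channel token, e.g. `"Abundance F1 126"`,
#' `"plate1_S01: 127N"` or `"F3|133C"`; everything before the token is the
#' file identifier. Remaining columns are kept as protein annotations; a
#' `protein_id` column (or the `id_col` argument) is required. Blank, `NA`
#' and zero-coded abundances become missing, since an exported reporter s/n
#' of zero is indistinguishable from non-detection.
#'
#' @param path Path to the table.
#' @param dialect `"tab"` or `"comma"`.
#' @param id_col Name of the protein identifier column.
#' @return A list with `proteins` (annotation tibble), `raw_sn` (protein x
#'   column matrix, colnames `<file>|<channel>`) and `columns` (tibble mapping
#'   matrix columns to `file_id` and `channel`).
#' @export
read_protein_table <- function(path, dialect = c("tab", "comma"),
                               id_col = "protein_id") {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tab") "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  if (ncol(df) == 1 && grepl(if (dialect == "tab") "," else "\t", names(df)[1])) {
    abort(sprintf(
      "Delimiter mismatch: file does not look %s-separated (dialect = '%s').",
      if (dialect == "tab") "tab" else "comma", dialect))
  }
  if (!id_col %in% names(df)) {
    abort(paste0("Protein identifier column '", id_col, "' not found."))
  }
  ids <- as.character(df[[id_col]])
  if (anyDuplicated(ids)) {
    dups <- unique(ids[duplicated(ids)])
    abort(paste0("Duplicate protein identifiers: ",
                 paste(head(dups, 10), collapse = ", ")))
  }

  parsed <- .parse_abundance_columns(setdiff(names(df), id_col))
  ann_cols <- c(id_col, parsed$annotation)
  ab <- parsed$abundance

  mat <- as.matrix(df[ab$column])
  storage.mode(mat) <- "double"
  mat[mat == 0] <- NA_real_
  rownames(mat) <- ids
  colnames(mat) <- paste0(ab$file_id, "|", ab$channel)

  proteins <- as_tibble(df[ann_cols])
  names(proteins)[names(proteins) == id_col] <- "protein_id"
  proteins$protein_id <- ids
  list(proteins = proteins, raw_sn = mat,
       columns = tibble(column = colnames(mat),
                        file_id = ab$file_id, channel = ab$channel))
}

# Split column names into abundance columns (trailing TMT channel token) and
# annotation columns. A column that advertises itself as an abundance (name
# contains "Abundance") but does not parse is an error naming the column.
.parse_abundance_columns <- function(cols) {
  channel_re <- "(1[23][0-9][NC]?)"
  full_re <- paste0("^(?:Abundance[:. ]*)?(.+?)[:|_ .]+", channel_re, "$")
  m <- regmatches(cols, regexec(full_re, cols))
  ok <- lengths(m) == 3 & vapply(m, function(x) length(x) == 3 &&
                                   x[3] %in% TMTPRO16, logical(1))
  claims <- grepl("Abundance", cols, ignore.case = TRUE)
  bad <- claims & !ok
  if (any(bad)) {
    abort(paste0("Unparseable abundance column name(s): ",
                 paste(cols[bad], collapse = ", ")))
  }
  list(
    abundance = tibble(
      column = cols[ok],
      file_id = trimws(vapply(m[ok], `[`, character(1), 2)),
      channel = vapply(m[ok], `[`, character(1), 3)
    ),
    annotation = cols[!ok]
  )
}

#' Write a protein table in the dialect [read_protein_table()] reads
#'
#' @param proteins Annotation tibble with `protein_id`.
#' @param raw_sn Matrix with `<file>|<channel>` colnames.
#' @param path Output path.
#' @param dialect `"tab"` or `"comma"`.
#' @export
write_protein_table <- function(proteins, raw_sn, path,
                                dialect = c("tab", "comma")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tab") "\t" else ","
  ab <- as.data.frame(apply(raw_sn, 2, .fmt_num), check.names = FALSE)
  names(ab) <- sub("\\|", " ", colnames(raw_sn))
  df <- cbind(as.data.frame(proteins, check.names = FALSE), ab)
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Unit-normalize a FACS fluorescence vector
#'
#' Linearly rescales finite values so the minimum maps to 0 and the maximum
#' to 1; missing values stay missing. A constant vector maps to all zeros
#' (documented convention avoiding division by zero). Idempotent.
#'
#' @param values Numeric vector of fluorescence intensities.
#' @return Numeric vector in `[0, 1]` with `NA`s preserved.
#' @export
normalize_facs_unit <- function(values) {
  fin <- is.finite(values)
  if (!any(fin)) abort("Cannot unit-normalize an all-missing FACS vector.")
  lo <- min(values[fin])
  hi <- max(values[fin])
  out <- values
  if (hi == lo) {
    out[fin] <- 0
  } else {
    out[fin] <- (values[fin] - lo) / (hi - lo)
  }
  out
}

#' Assemble per-cell metadata from a layout and an index-FACS table
#'
#' Joins the sorted wells of a plate layout with a per-well FACS marker table
#' (CSV export of an index sort). Every single-cell well yields one record;
#' marker columns are carried both raw (`facs_<marker>`) and unit-normalized
#' across cells (`facs_norm_<marker>`). Wells missing from the FACS table get
#' missing marker values with a warning; FACS rows for unsorted wells are
#' ignored (their count is reported as an attribute).
#'
#' @param layout A `plate_layout` from [build_plate_layout()].
#' @param facs_table Data frame with a `well` column plus one numeric column
#'   per marker, or `NULL` for no FACS data.
#' @return A tibble of cell records: `cell_id`, `file_id`, `channel`,
#'   `plate_id`, `well`, `well_row`, `well_col`, `population`,
#'   `is_empty_well`, and FACS columns.
#' @export
assemble_cell_metadata <- function(layout, facs_table = NULL) {
  sorted <- dplyr::filter(as_tibble(layout), .data$sorted)
  cells <- tibble(
    cell_id = paste0(sorted$sample_id, "_", sorted$channel),
    file_id = sorted$sample_id,
    channel = sorted$channel,
    plate_id = sorted$plate_id,
    well = sorted$well,
    well_row = sorted$well_row,
    well_col = sorted$well_col,
    population = sorted$population,
    is_empty_well = FALSE
  )
  if (anyDuplicated(cells[c("file_id", "channel")])) {
    abort("Layout assigns the same (file, channel) pair to more than one well.")
  }
  n_ignored <- 0L
  if (!is.null(facs_table)) {
    facs_table <- as_tibble(facs_table)
    if (!"well" %in% names(facs_table)) abort("FACS table needs a `well` column.")
    if (anyDuplicated(facs_table$well)) {
      abort("FACS table lists some wells more than once.")
    }
    if (!all(grepl("^[A-Z][0-9]+$", facs_table$well))) {
      abort("FACS table well names do not follow the letter-row A1 convention.")
    }
    rows_seen <- match(sub("[0-9]+$", "", facs_table$well), LETTERS)
    cols_seen <- as.integer(sub("^[A-Z]", "", facs_table$well))
    if (max(rows_seen) > (attr(layout, "rows") %||% max(match(layout$well_row, LETTERS))) ||
        max(cols_seen) > (attr(layout, "cols") %||% max(layout$well_col))) {
      abort("FACS table and layout disagree on plate shape.")
    }
    n_ignored <- sum(!facs_table$well %in% cells$well)
    markers <- setdiff(names(facs_table), "well")
    idx <- match(cells$well, facs_table$well)
    for (mk in markers) {
      raw <- facs_table[[mk]][idx]
      cells[[paste0("facs_", mk)]] <- raw
      cells[[paste0("facs_norm_", mk)]] <- normalize_facs_unit(raw)
    }
    n_missing <- sum(is.na(idx))
    if (n_missing > 0) {
      warn(sprintf("%d sorted well(s) absent from the FACS table; markers set missing.",
                   n_missing))
    }
  }
  attr(cells, "n_facs_rows_ignored") <- n_ignored
  cells
}
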