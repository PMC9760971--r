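#' Read a segmented single-cell table
#'
#' Cell tables are comma-separated UTF-8 text with one row per segmented
#' cell: `cell_id`, `fov_id`, `x`, `y` (pixel centroids, 0-based,
#' FOV-local), an optional `phenotype` column, and per-marker intensity
#' columns named `<marker>_mean` / `<marker>_sd` on the 16-bit scale.
#' Logical `<marker>_pos` columns carry functional gate calls.
#'
#' Rows are validated against the coordinate and intensity invariants;
#' violations abort with row-indexed diagnostics. Phenotype strings outside
#' the scheme are mapped to `"UNASSIGNED"` so classification can be run
#' downstream.
#'
#' @param path path to a CSV file.
#' @param fov_width,fov_height FOV bounds in pixels used for validation
#'   (all coordinates must satisfy `0 <= x < fov_width` etc.).
#' @return a tibble, one row per cell, columns as above.
#' @seealso [write_cell_table()], [join_patient_metadata()]
#' @export
read_cell_table <- function(path, fov_width = 2040, fov_height = 2040) {
  # parse everything as text, then convert with strtod so that floats
  # written at full printed precision re-read to the identical double
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  required <- c("cell_id", "fov_id", "x", "y")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("cell table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  numeric_cols <- c("x", "y", grep("_(mean|sd)$", names(raw), value = TRUE))
  for (col in numeric_cols) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]))
    if (length(bad) > 0) {
      stop("non-numeric ", col, " at row(s): ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
    raw[[col]] <- v
  }
  for (col in grep("_pos$", names(raw), value = TRUE)) {
    raw[[col]] <- as.logical(raw[[col]])
  }
  cells <- tibble::as_tibble(raw)
  if ("phenotype" %in% names(cells)) {
    cells$phenotype <- normalize_phenotype(cells$phenotype)
  }
  validate_cell_table(cells, fov_width = fov_width, fov_height = fov_height)
  cells
}

#' Validate a cell table against its invariants
#'
#' Checks coordinates lie in `[0, fov_width) x [0, fov_height)`, marker
#' means in `[0, 65535]`, marker sds nonnegative, and cell ids unique.
#' Aborts with row numbers on the first violated invariant.
#'
#' @param cells a cell table tibble.
#' @inheritParams read_cell_table
#' @return `cells`, invisibly.
#' @export
validate_cell_table <- function(cells, fov_width = 2040, fov_height = 2040) {
  fail_rows <- function(bad, what) {
    if (any(bad, na.rm = TRUE)) {
      rows <- which(bad)
      stop(what, " at row(s): ", paste(utils::head(rows, 5), collapse = ", "),
           if (length(rows) > 5) sprintf(" (and %d more)", length(rows) - 5) else "",
           call. = FALSE)
    }
  }
  fail_rows(is.na(cells$x) | is.na(cells$y), "missing coordinate")
  fail_rows(cells$x < 0 | cells$x >= fov_width, "x outside FOV bounds")
  fail_rows(cells$y < 0 | cells$y >= fov_height, "y outside FOV bounds")
  if (anyDuplicated(cells$cell_id) > 0) {
    stop("duplicated cell_id at row(s): ",
         paste(utils::head(which(duplicated(cells$cell_id)), 5), collapse = ", "),
         call. = FALSE)
  }
  for (col in grep("_mean$", names(cells), value = TRUE)) {
    fail_rows(cells[[col]] < 0 | cells[[col]] > 65535,
              paste0(col, " outside [0, 65535]"))
  }
  for (col in grep("_sd$", names(cells), value = TRUE)) {
    fail_rows(cells[[col]] < 0, paste0(col, " negative"))
  }
  invisible(cells)
}

#' Write a cell table to CSV
#'
#' Columns are emitted in a deterministic order (identity columns, then
#' phenotype/grouping columns, then marker columns alphabetically) with
#' full-precision floats, so write-read-write round-trips are byte-stable.
#'
#' @param cells a cell table tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(cells, path) {
  lead <- intersect(
    c("cell_id", "fov_id", "patient_id", "specimen_id", "outcome",
      "x", "y", "phenotype"),
    names(cells)
  )
  rest <- sort(setdiff(names(cells), lead))
  readr::write_csv(cells[, c(lead, rest)], path, progress = FALSE)
  invisible(path)
}

#' Read and write patient metadata tables
#'
#' Patient tables are CSV with columns `patient_id`, `specimen_id` and
#' `outcome` (two levels, e.g. `"Recurrence"` / `"NoRecurrence"`).
#'
#' @param path path to a CSV file.
#' @return a tibble with one row per patient.
#' @export
read_patient_table <- function(path) {
  pts <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("patient_id", "outcome")
  missing <- setdiff(required, names(pts))
  if (length(missing) > 0) {
    stop("patient table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  pts$patient_id <- as.character(pts$patient_id)
  if (!"specimen_id" %in% names(pts)) pts$specimen_id <- pts$patient_id
  if (length(unique(pts$outcome)) > 2) {
    stop("outcome must have at most two levels", call. = FALSE)
  }
  tibble::as_tibble(pts)
}

#' @rdname read_patient_table
#' @param patients a patient table tibble.
#' @export
write_patient_table <- function(patients, path) {
  lead <- intersect(c("patient_id", "specimen_id", "outcome"), names(patients))
  rest <- sort(setdiff(names(patients), lead))
  readr::write_csv(patients[, c(lead, rest)], path, progress = FALSE)
  invisible(path)
}

#' Join patient metadata onto a cell table
#'
#' Attaches `specimen_id` and `outcome` to every cell via `patient_id`.
#' All statistics downstream are computed per patient, so the join must be
#' total: any cell whose `patient_id` is absent from `patients` is a
#' referential error.
#'
#' @param cells a cell table carrying a `patient_id` column.
#' @param patients a patient table (see [read_patient_table()]).
#' @return the cell table with `specimen_id` and `outcome` columns; row
#'   count unchanged.
#' @export
join_patient_metadata <- function(cells, patients) {
  if (!"patient_id" %in% names(cells)) {
    stop("cell table has no patient_id column", call. = FALSE)
  }
  orphans <- setdiff(unique(cells$patient_id), patients$patient_id)
  if (length(orphans) > 0) {
    stop("patient_id values missing from patient table: ",
         paste(orphans, collapse = ", "), call. = FALSE)
  }
  meta <- patients[, intersect(c("patient_id", "specimen_id", "outcome"),
                               names(patients))]
  out <- dplyr::left_join(
    dplyr::select(cells, -dplyr::any_of(c("specimen_id", "outcome"))),
    meta, by = "patient_id"
  )
  stopifnot(nrow(out) == nrow(cells))
  out
}

# Names of the marker intensity columns present in a cell table.
marker_names <- function(cells) {
  sub("_mean$", "", grep("_mean$", names(cells), value = TRUE))
}
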