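#' Build index-cell-centric cellular neighborhoods
#'
#' For every cell of `index_class`, counts the cells of each phenotype
#' class lying within a closed disc of the requested diameter (default
#' 57 px, i.e. radius 28.5 px, inclusive boundary) around the index
#' centroid, within the same FOV. The index cell itself is excluded from
#' its own counts. For every gated marker present (`<marker>_pos`
#' columns), per-class counts of functional-positive neighbors are
#' tallied as `<marker>pos_<class>` columns. Neighborhoods whose index
#' cell lies closer than one radius to an FOV edge are flagged `border`
#' (they are truncated, not edge-corrected).
#'
#' Tumor-centric neighborhoods (TCCN) use `index_class = "Tumor"`;
#' cytotoxic-T-centric (CTCN) use `index_class = "CytotoxicT"`.
#'
#' @param cells a classified cell table.
#' @param index_class phenotype of the index cells.
#' @param diameter neighborhood diameter in pixels.
#' @param fov_width,fov_height FOV bounds used for the border flag.
#' @return a `nbhd_matrix` tibble: one row per index cell with `cell_id`,
#'   `fov_id` (and `patient_id`/`outcome` if present), `x`, `y`,
#'   `n_<class>` neighbor counts, positive-neighbor counts, and `border`;
#'   attributes `index_class` and `diameter`.
#' @export
build_neighborhoods <- function(cells, index_class, diameter = 57,
                                fov_width = 2040, fov_height = 2040) {
  if (!index_class %in% phenotype_levels()) {
    stop("unknown index class: ", index_class, call. = FALSE)
  }
  if (diameter <= 0) stop("diameter must be positive", call. = FALSE)
  r <- diameter / 2
  levels_ <- phenotype_levels()
  pos_cols <- grep("_pos$", names(cells), value = TRUE)
  per_fov <- split(seq_len(nrow(cells)), cells$fov_id)
  rows <- lapply(per_fov, function(ridx) {
    fov <- cells[ridx, ]
    is_index <- fov$phenotype == index_class
    if (!any(is_index)) return(NULL)
    idx <- fov[is_index, ]
    codes <- match(fov$phenotype, levels_) - 1L
    counts <- cpp_radius_class_counts(idx$x, idx$y, fov$x, fov$y,
                                      codes, length(levels_), r, FALSE)
    colnames(counts) <- paste0("n_", levels_)
    # remove the index cell from its own class count (distance 0)
    counts[, paste0("n_", index_class)] <-
      counts[, paste0("n_", index_class)] - 1L
    out <- dplyr::bind_cols(
      idx[, intersect(c("cell_id", "fov_id", "patient_id", "outcome"),
                      names(idx))],
      tibble::tibble(x = idx$x, y = idx$y),
      tibble::as_tibble(counts)
    )
    for (pc in pos_cols) {
      marker <- sub("_pos$", "", pc)
      pcodes <- ifelse(fov[[pc]], codes, -1L)
      pcounts <- cpp_radius_class_counts(idx$x, idx$y, fov$x, fov$y,
                                         pcodes, length(levels_), r, FALSE)
      colnames(pcounts) <- paste0(marker, "pos_", levels_)
      # remove positive index cells from their own class count
      self_pos <- idx[[pc]]
      pcounts[, paste0(marker, "pos_", index_class)] <-
        pcounts[, paste0(marker, "pos_", index_class)] - as.integer(self_pos)
      out <- dplyr::bind_cols(out, tibble::as_tibble(pcounts))
    }
    out
  })
  res <- dplyr::bind_rows(rows)
  if (nrow(res) > 0) {
    res$border <- pmin(res$x, res$y, fov_width - res$x, fov_height - res$y) < r
  } else {
    res <- empty_nbhd_matrix(cells, levels_, pos_cols)
  }
  attr(res, "index_class") <- index_class
  attr(res, "diameter") <- diameter
  class(res) <- c("nbhd_matrix", class(res))
  res
}

empty_nbhd_matrix <- function(cells, levels_, pos_cols) {
  base <- cells[0, intersect(c("cell_id", "fov_id", "patient_id", "outcome"),
                             names(cells))]
  base$x <- numeric(0); base$y <- numeric(0)
  for (cl in paste0("n_", levels_)) base[[cl]] <- integer(0)
  for (pc in pos_cols) {
    marker <- sub("_pos$", "", pc)
    for (cl in paste0(marker, "pos_", levels_)) base[[cl]] <- integer(0)
  }
  base$border <- logical(0)
  base
}

#' Keep only populated neighborhoods
#'
#' Restricts a neighborhood matrix to rows containing at least one
#' neighbor of the required compartment: tumor-centric neighborhoods
#' (TCCN) keep rows with at least one immune neighbor; cytotoxic-T-centric
#' (CTCN) keep rows with at least one tumor neighbor. By default the
#' requirement is inferred from the matrix's index class.
#'
#' @param matrix a `nbhd_matrix`.
#' @param require `"Immune"` or `"Tumor"`; default `"Immune"` for tumor
#'   index cells, `"Tumor"` otherwise.
#' @return the filtered `nbhd_matrix` (attributes preserved).
#' @export
filter_populated <- function(matrix, require = NULL) {
  index_class <- attr(matrix, "index_class")
  if (is.null(require)) {
    require <- if (identical(index_class, "Tumor")) "Immune" else "Tumor"
  }
  require <- match.arg(require, c("Immune", "Tumor"))
  keep <- if (require == "Immune") {
    rowSums(as.matrix(matrix[, paste0("n_", immune_levels())])) >= 1
  } else {
    matrix$n_Tumor >= 1
  }
  out <- matrix[keep, ]
  attr(out, "index_class") <- index_class
  attr(out, "diameter") <- attr(matrix, "diameter")
  class(out) <- class(matrix)
  out
}

#' Per-patient neighborhood immune composition
#'
#' For each patient and each immune class, the fraction of the patient's
#' neighborhoods (rows of the, typically filtered, matrix) that contain
#' at least one neighbor of that class.
#'
#' @param matrix a `nbhd_matrix` carrying `patient_id` (build from a
#'   metadata-joined cell table).
#' @param classes phenotype classes to summarize; default the immune
#'   classes.
#' @return tibble: `patient_id`, (`outcome`,) `feature` (class),
#'   `events` (neighborhoods containing the class), `total` (patient's
#'   neighborhoods), `fraction`. Patients with zero neighborhoods are
#'   absent (a warning lists them if the matrix carries no row for them
#'   but other patients are present).
#' @export
neighborhood_composition_by_patient <- function(matrix,
                                                classes = immune_levels()) {
  if (!"patient_id" %in% names(matrix)) {
    stop("neighborhood matrix lacks patient_id: build it from a ",
         "metadata-joined cell table", call. = FALSE)
  }
  long <- purrr::map_dfr(classes, function(cl) {
    tibble::tibble(
      patient_id = matrix$patient_id,
      outcome = if ("outcome" %in% names(matrix)) matrix$outcome else NA,
      feature = cl,
      present = matrix[[paste0("n_", cl)]] >= 1
    )
  })
  out <- dplyr::summarise(
    dplyr::group_by(long, .data$patient_id, .data$outcome, .data$feature),
    events = sum(.data$present), total = dplyr::n(), .groups = "drop"
  )
  out$fraction <- out$events / out$total
  if (all(is.na(out$outcome))) out$outcome <- NULL
  out
}

#' Distribution of tumor-cell counts per neighborhood
#'
#' Histogram (over integer tumor counts) and mean of the number of tumor
#' neighbors per neighborhood, by outcome group.
#'
#' @param matrix a `nbhd_matrix` carrying `outcome`.
#' @return tibble: `outcome`, `tumor_count`, `n_neighborhoods`,
#'   `frequency` (within group); the per-group means are attached as
#'   attribute `"means"` (tibble `outcome`, `mean_tumor_count`).
#' @export
tumor_count_distribution <- function(matrix) {
  if (!"outcome" %in% names(matrix)) {
    stop("neighborhood matrix lacks outcome: build it from a ",
         "metadata-joined cell table", call. = FALSE)
  }
  df <- tibble::tibble(outcome = matrix$outcome,
                       tumor_count = matrix$n_Tumor)
  hist <- dplyr::count(df, .data$outcome, .data$tumor_count,
                       name = "n_neighborhoods")
  hist <- dplyr::mutate(
    dplyr::group_by(hist, .data$outcome),
    frequency = .data$n_neighborhoods / sum(.data$n_neighborhoods)
  )
  hist <- dplyr::ungroup(hist)
  means <- dplyr::summarise(dplyr::group_by(df, .data$outcome),
                            mean_tumor_count = mean(.data$tumor_count),
                            .groups = "drop")
  attr(hist, "means") <- means
  hist
}
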