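#' Categorize neighborhoods as tumor-only, homotypic or heterotypic
#'
#' Applies the interaction taxonomy to every row of an (unfiltered)
#' neighborhood matrix, based on the distinct immune classes present
#' among the neighbors (the index cell never counts, but neighbors of the
#' index cell's own class do):
#' \itemize{
#'   \item \strong{TumorOnly} — zero immune neighbors;
#'   \item \strong{Homotypic} — exactly one distinct immune class;
#'   \item \strong{Heterotypic} — two or more distinct immune classes.
#' }
#'
#' @param matrix a `nbhd_matrix` from [build_neighborhoods()].
#' @return tibble: `cell_id`, `fov_id` (and `patient_id`/`outcome` if
#'   present), `category`, `n_immune_classes`, `homotypic_class` (`NA`
#'   unless homotypic) and a list-column `immune_classes_present`;
#'   attribute `index_class` is carried over.
#' @export
categorize_neighborhoods <- function(matrix) {
  imm_cols <- paste0("n_", immune_levels())
  present <- as.matrix(matrix[, imm_cols]) >= 1
  colnames(present) <- immune_levels()
  m <- rowSums(present)
  category <- dplyr::case_when(
    m == 0 ~ "TumorOnly",
    m == 1 ~ "Homotypic",
    TRUE ~ "Heterotypic"
  )
  homotypic_class <- rep(NA_character_, nrow(matrix))
  if (any(m == 1)) {
    homotypic_class[m == 1] <-
      immune_levels()[max.col(present[m == 1, , drop = FALSE],
                              ties.method = "first")]
  }
  out <- dplyr::bind_cols(
    matrix[, intersect(c("cell_id", "fov_id", "patient_id", "outcome"),
                       names(matrix))],
    tibble::tibble(
      category = category,
      n_immune_classes = as.integer(m),
      homotypic_class = homotypic_class,
      immune_classes_present = lapply(seq_len(nrow(present)), function(i) {
        immune_levels()[present[i, ]]
      })
    )
  )
  attr(out, "index_class") <- attr(matrix, "index_class")
  out
}

#' Category and pairwise pairing frequencies per group
#'
#' Summarizes categorized neighborhoods per outcome group: the frequency
#' of tumor-only neighborhoods, of each homotypic class, of heterotypic
#' neighborhoods overall, and of each unordered immune-class pair among
#' heterotypic neighborhoods. A heterotypic neighborhood with m distinct
#' immune classes contributes to all choose(m, 2) pairs (presence-based,
#' not abundance-weighted). Category frequencies (tumor-only + homotypic
#' + heterotypic) sum to 1 within each group.
#'
#' @param categories output of [categorize_neighborhoods()] carrying
#'   `outcome`.
#' @param normalize denominator for pair frequencies: `"total"` (all
#'   neighborhoods of the index type in the group, default) or
#'   `"heterotypic"` (heterotypic neighborhoods only).
#' @return tibble: `outcome`, `type` (`"tumor_only"`, `"homotypic"`,
#'   `"heterotypic"`, `"pair"`), `class_a`, `class_b` (`NA` except for
#'   pairs; `class_a` holds the homotypic class), `count`, `frequency`.
#' @export
pairing_frequencies <- function(categories,
                                normalize = c("total", "heterotypic")) {
  normalize <- match.arg(normalize)
  if (!"outcome" %in% names(categories)) {
    stop("categories lack outcome: build neighborhoods from a ",
         "metadata-joined cell table", call. = FALSE)
  }
  purrr::map_dfr(split(categories, categories$outcome), function(grp) {
    n_total <- nrow(grp)
    het <- grp[grp$category == "Heterotypic", ]
    denom_pairs <- if (normalize == "total") n_total else max(nrow(het), 1L)
    base <- tibble::tibble(
      outcome = grp$outcome[1],
      type = c("tumor_only", "heterotypic"),
      class_a = NA_character_, class_b = NA_character_,
      count = c(sum(grp$category == "TumorOnly"), nrow(het))
    )
    base$frequency <- base$count / n_total
    homo <- dplyr::count(grp[grp$category == "Homotypic", ],
                         class_a = .data$homotypic_class, name = "count")
    if (nrow(homo) > 0) {
      homo <- tibble::tibble(outcome = grp$outcome[1], type = "homotypic",
                             class_a = homo$class_a,
                             class_b = NA_character_, count = homo$count,
                             frequency = homo$count / n_total)
    }
    pairs <- purrr::map_dfr(het$immune_classes_present, function(cls) {
      if (length(cls) < 2) return(NULL)
      cmb <- utils::combn(sort(cls), 2)
      tibble::tibble(class_a = cmb[1, ], class_b = cmb[2, ])
    })
    if (nrow(pairs) > 0) {
      pairs <- dplyr::count(pairs, .data$class_a, .data$class_b,
                            name = "count")
      pairs <- tibble::tibble(outcome = grp$outcome[1], type = "pair",
                              class_a = pairs$class_a,
                              class_b = pairs$class_b, count = pairs$count,
                              frequency = pairs$count / denom_pairs)
    }
    dplyr::bind_rows(base, homo, pairs)
  })
}

#' Per-patient pairing feature counts for cohort comparison
#'
#' Long per-patient event counts for the interaction features: tumor-only
#' neighborhoods, each homotypic class, and each unordered immune pair
#' (a neighborhood counts as an event for a pair if both classes are
#' present). `total` is the patient's neighborhood count, so features
#' feed directly into [compare_groups()].
#'
#' @param categories output of [categorize_neighborhoods()].
#' @param pairs optional 2-column matrix/data frame of class pairs to
#'   report; default all pairs observed in the data.
#' @return tibble: `patient_id`, (`outcome`,) `feature`, `events`, `total`.
#' @export
pairing_feature_counts <- function(categories, pairs = NULL) {
  if (!"patient_id" %in% names(categories)) {
    stop("categories lack patient_id", call. = FALSE)
  }
  pres <- matrix(FALSE, nrow(categories), length(immune_levels()),
                 dimnames = list(NULL, immune_levels()))
  for (i in seq_len(nrow(categories))) {
    pres[i, categories$immune_classes_present[[i]]] <- TRUE
  }
  if (is.null(pairs)) {
    seen <- colnames(pres)[colSums(pres) > 0]
    pairs <- if (length(seen) >= 2) t(utils::combn(sort(seen), 2)) else
      matrix(character(0), ncol = 2)
  } else {
    pairs <- as.matrix(pairs)
  }
  feats <- tibble::tibble(
    patient_id = categories$patient_id,
    tumor_only = categories$category == "TumorOnly"
  )
  for (cl in immune_levels()) {
    feats[[paste0("homotypic_", cl)]] <-
      categories$category == "Homotypic" & !is.na(categories$homotypic_class) &
      categories$homotypic_class == cl
  }
  if (nrow(pairs) > 0) {
    for (i in seq_len(nrow(pairs))) {
      feats[[paste0("pair_", pairs[i, 1], "_", pairs[i, 2])]] <-
        pres[, pairs[i, 1]] & pres[, pairs[i, 2]]
    }
  }
  long <- tidyr::pivot_longer(feats, -"patient_id", names_to = "feature",
                              values_to = "event")
  out <- dplyr::summarise(
    dplyr::group_by(long, .data$patient_id, .data$feature),
    events = sum(.data$event), total = dplyr::n(), .groups = "drop"
  )
  if ("outcome" %in% names(categories)) {
    out <- dplyr::left_join(
      out, dplyr::distinct(categories, .data$patient_id, .data$outcome),
      by = "patient_id"
    )
  }
  out
}

#' Per-patient frequencies of functional-positive neighbors
#'
#' For each patient and each tumor-infiltrating-lymphocyte class, the
#' fraction of neighborhoods containing at least one functional-positive
#' (e.g. PD1+) neighbor of that class. Rows of the matrix with a positive
#' neighbor of any TIL class are flagged for map export.
#'
#' @param matrix a `nbhd_matrix` built from gated cells (it must carry
#'   `<marker>pos_<class>` columns; run [gate_functional_marker()] before
#'   [build_neighborhoods()]).
#' @param marker gated marker name, default `"PD1"`.
#' @param classes TIL classes to report; default B cells, cytotoxic T,
#'   helper T and regulatory T cells.
#' @return tibble: `patient_id`, (`outcome`,) `feature`
#'   (`<marker>pos_<class>`), `events`, `total`, `fraction`. The logical
#'   per-neighborhood flag (any positive TIL neighbor) is attached as
#'   attribute `"flagged"` alongside `cell_id`.
#' @export
pd1_neighbor_frequencies <- function(matrix, marker = "PD1",
                                     classes = c("BCell", "CytotoxicT",
                                                 "HelperT", "Treg")) {
  cols <- paste0(marker, "pos_", classes)
  missing <- setdiff(cols, names(matrix))
  if (length(missing) > 0) {
    stop("matrix lacks ", paste(missing, collapse = ", "),
         ": gate the marker with gate_functional_marker() before building ",
         "neighborhoods", call. = FALSE)
  }
  if (!"patient_id" %in% names(matrix)) {
    stop("neighborhood matrix lacks patient_id", call. = FALSE)
  }
  long <- purrr::map_dfr(classes, function(cl) {
    tibble::tibble(
      patient_id = matrix$patient_id,
      outcome = if ("outcome" %in% names(matrix)) matrix$outcome else NA,
      feature = paste0(marker, "pos_", cl),
      present = matrix[[paste0(marker, "pos_", cl)]] >= 1
    )
  })
  out <- dplyr::summarise(
    dplyr::group_by(long, .data$patient_id, .data$outcome, .data$feature),
    events = sum(.data$present), total = dplyr::n(), .groups = "drop"
  )
  out$fraction <- out$events / out$total
  if (all(is.na(out$outcome))) out$outcome <- NULL
  attr(out, "flagged") <- tibble::tibble(
    cell_id = matrix$cell_id,
    flagged = rowSums(as.matrix(matrix[, cols])) >= 1
  )
  out
}
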