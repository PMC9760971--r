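#' Specify a synthetic tumor-core cohort
#'
#' Builds the parameter object consumed by [generate_cohort()]. The
#' generator emulates pathologist-annotated tumor-core fields of view
#' (FOVs): square tiles (default 2040 x 2040 px, about 1 mm^2) dominated
#' by tumor-cell nests laid down by a Thomas-style parent-offspring
#' cluster process, with stromal and immune cells scattered around them.
#' Cohorts have two outcome groups (default 9 recurrence / 16
#' no-recurrence patients, matching a typical anti-PD1 cohort) and
#' group-specific immune attraction can be planted so that downstream
#' neighborhood statistics have a known signal to recover.
#'
#' @section Spatial model:
#' Tumor cells: `tumor_nests$parents_per_fov` nest centers per FOV
#' (Poisson), each with Poisson(`mean_offspring`) cells displaced by an
#' isotropic Gaussian of sd `dispersion` pixels; offspring falling outside
#' the FOV are dropped. Non-tumor classes get Poisson counts proportional
#' to `class_proportions` (total FOV size calibrated so that tumor matches
#' its proportion). Each non-tumor class is placed by sampling from a
#' weighted uniform proposal: a candidate at position p has weight
#' `max(0, 1 + sum_e (m_e - 1) * n_e(p))` where the sum runs over
#' enrichment rows `e` whose `neighbor_class` is the class being placed,
#' `m_e` is the attraction multiplier, and `n_e(p)` counts already-placed
#' cells of `index_class` within `interaction_radius` of p. Multiplier 1
#' is exactly neutral (uniform placement), values above 1 attract, values
#' in `[0, 1)` repel. Classes are placed in scheme order (tumor, stroma,
#' then [immune_levels()]), so attraction only "sees" classes placed
#' earlier.
#'
#' @section Marker model:
#' Marker intensities are drawn on the arcsinh scale from a two-component
#' Gaussian (negative / positive component) and mapped back to the 16-bit
#' raw scale via `sinh`, clamped to `[0, 65535]`. Lineage markers are
#' positive deterministically for their `hi_classes`; gated markers (e.g.
#' PD1) are positive with probability `pos_fraction` among
#' `positive_classes` cells (optionally restricted to `positive_groups`).
#' A per-specimen location shift (sd `specimen_shift_sd`, arcsinh scale)
#' is added to every marker mean channel, emulating batch effects that
#' the gating procedure must remove. The per-cell sd channel is drawn
#' from the same component (location `0.6 * mean`, spread `0.8 * sd`),
#' so true positives sit high on both gate axes.
#'
#' @param n_patients_per_group named integer vector of patients per
#'   outcome group; names are the group labels.
#' @param fovs_per_patient FOVs generated per patient.
#' @param fov_size FOV side length in pixels.
#' @param class_proportions named numeric vector over
#'   [phenotype_levels()], summing to 1.
#' @param tumor_nests list with `parents_per_fov`, `mean_offspring`,
#'   `dispersion` (pixels).
#' @param enrichments tibble with columns `group`, `index_class`,
#'   `neighbor_class`, `multiplier` (all multipliers >= 0), or `NULL` for
#'   no planted structure.
#' @param marker_models named list of marker models as produced by
#'   [marker_model()]; defaults to [default_marker_models()].
#' @param interaction_radius radius (pixels) of the planted attraction;
#'   default 28.5 px so planted effects are directly visible to the
#'   57-px-diameter neighborhood analysis.
#' @param specimen_shift_sd sd of the per-specimen arcsinh-scale location
#'   shift on marker mean channels.
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @return an object of class `cohort_spec`.
#' @examples
#' spec <- cohort_spec(
#'   n_patients_per_group = c(GroupA = 2, GroupB = 2),
#'   fovs_per_patient = 1,
#'   tumor_nests = list(parents_per_fov = 4, mean_offspring = 40, dispersion = 50),
#'   seed = 1
#' )
#' cohort <- generate_cohort(spec)
#' dplyr::count(cohort$cells, phenotype)
#' @export
cohort_spec <- function(n_patients_per_group = c(Recurrence = 9, NoRecurrence = 16),
                        fovs_per_patient = 16,
                        fov_size = 2040,
                        class_proportions = default_class_proportions(),
                        tumor_nests = list(parents_per_fov = 12,
                                           mean_offspring = 180,
                                           dispersion = 60),
                        enrichments = default_enrichments(names(n_patients_per_group)),
                        marker_models = default_marker_models(),
                        interaction_radius = 28.5,
                        specimen_shift_sd = 0.15,
                        seed = 1L) {
  if (is.null(names(n_patients_per_group)) ||
      any(!nzchar(names(n_patients_per_group)))) {
    stop("n_patients_per_group must be a named vector of group sizes",
         call. = FALSE)
  }
  if (abs(sum(class_proportions) - 1) > 1e-9) {
    stop("class_proportions must sum to 1", call. = FALSE)
  }
  if (any(class_proportions < 0)) {
    stop("class_proportions must be nonnegative", call. = FALSE)
  }
  unknown <- setdiff(names(class_proportions), phenotype_levels())
  if (length(unknown) > 0) {
    stop("unknown phenotype(s) in class_proportions: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (!is.null(enrichments)) {
    enrichments <- tibble::as_tibble(enrichments)
    stopifnot(all(c("group", "index_class", "neighbor_class", "multiplier")
                  %in% names(enrichments)))
    if (any(enrichments$multiplier < 0)) {
      stop("attraction multipliers must be >= 0", call. = FALSE)
    }
  }
  for (mm in marker_models) {
    if (mm$pos_fraction < 0 || mm$pos_fraction > 1) {
      stop("marker pos_fraction must lie in [0, 1]", call. = FALSE)
    }
  }
  structure(
    list(
      n_patients_per_group = n_patients_per_group,
      fovs_per_patient = fovs_per_patient,
      fov_size = fov_size,
      class_proportions = class_proportions,
      tumor_nests = tumor_nests,
      enrichments = enrichments,
      marker_models = marker_models,
      interaction_radius = interaction_radius,
      specimen_shift_sd = specimen_shift_sd,
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

#' Default phenotype proportions of the tumor-core FOVs
#'
#' Tumor-dominant composition (62% tumor) with a stromal fraction and an
#' immune compartment split across the eight named immune classes plus
#' unclassified-immune, reflecting a tumor core rather than lymphoid
#' tissue.
#'
#' @return named numeric vector over [phenotype_levels()], summing to 1.
#' @export
default_class_proportions <- function() {
  c(Tumor = 0.62, Stroma = 0.10,
    BCell = 0.04, CytotoxicT = 0.05, HelperT = 0.05, Treg = 0.02,
    Neutrophil = 0.01, Monocyte = 0.02, Macrophage = 0.06,
    Dendritic = 0.02, UnclassifiedImmune = 0.01)
}

#' Default planted interaction enrichments
#'
#' Mirrors the qualitative structure reported for anti-PD1 outcome groups:
#' dendritic cells (and to a lesser degree cytotoxic T cells) attracted to
#' tumor cells in the no-recurrence group; macrophages and B cells
#' attracted to tumor cells in the recurrence group. With group labels
#' other than `Recurrence` / `NoRecurrence` no default is planted.
#'
#' @param groups character vector of group labels.
#' @return tibble of enrichment rows, or `NULL`.
#' @export
default_enrichments <- function(groups = c("Recurrence", "NoRecurrence")) {
  rows <- tibble::tribble(
    ~group,         ~index_class, ~neighbor_class, ~multiplier,
    "NoRecurrence", "Tumor",      "Dendritic",     3,
    "NoRecurrence", "Tumor",      "CytotoxicT",    2,
    "Recurrence",   "Tumor",      "Macrophage",    2,
    "Recurrence",   "Tumor",      "BCell",         1.5
  )
  rows <- rows[rows$group %in% groups, ]
  if (nrow(rows) == 0) NULL else rows
}

#' Construct a two-component marker intensity model
#'
#' @param neg,pos length-2 numeric `c(mean, sd)` of the negative and
#'   positive component on the arcsinh scale.
#' @param hi_classes phenotypes that always draw from the positive
#'   component (lineage markers).
#' @param pos_fraction probability that an eligible cell is functionally
#'   positive (gated markers); 0 for pure lineage markers.
#' @param positive_classes phenotypes eligible for random positivity
#'   (`NULL` = all).
#' @param positive_groups outcome groups eligible (`NULL` = all).
#' @param gated whether the marker is a functional, gated marker whose
#'   true positivity is recorded in the ground truth.
#' @return a `marker_model` list.
#' @export
marker_model <- function(neg = c(3, 0.35), pos = c(5.1, 0.35),
                         hi_classes = character(), pos_fraction = 0,
                         positive_classes = NULL, positive_groups = NULL,
                         gated = FALSE) {
  structure(
    list(neg = neg, pos = pos, hi_classes = hi_classes,
         pos_fraction = pos_fraction, positive_classes = positive_classes,
         positive_groups = positive_groups, gated = gated),
    class = "marker_model"
  )
}

#' Default marker panel
#'
#' One lineage marker per phenotype (gp100 for tumor, SMA for stroma,
#' CD20/CD8/CD4/FOXP3/CD66b/CD14/CD68/CD11c for the immune classes, CD45
#' pan-immune) plus gated PD1 on tumor-infiltrating lymphocytes. Component
#' means are separated by `separation` negative-component standard
#' deviations on the arcsinh scale.
#'
#' @param separation inter-component mean separation in units of the
#'   negative-component sd.
#' @param pd1_positive_fraction planted PD1-positive fraction among TIL
#'   cells (B, cytotoxic T, helper T, regulatory T).
#' @param pd1_positive_groups outcome groups whose TILs can be PD1
#'   positive (`NULL` = all).
#' @return named list of [marker_model()] objects.
#' @export
default_marker_models <- function(separation = 6,
                                  pd1_positive_fraction = 0.15,
                                  pd1_positive_groups = NULL) {
  lo <- 3; s <- 0.35; hi <- lo + separation * s
  lineage <- function(classes) {
    marker_model(neg = c(lo, s), pos = c(hi, s), hi_classes = classes)
  }
  list(
    gp100 = lineage("Tumor"),
    SMA = lineage("Stroma"),
    CD45 = lineage(immune_levels()),
    CD20 = lineage("BCell"),
    CD8 = lineage("CytotoxicT"),
    CD4 = lineage(c("HelperT", "Treg")),
    FOXP3 = lineage("Treg"),
    CD66b = lineage("Neutrophil"),
    CD14 = lineage("Monocyte"),
    CD68 = lineage("Macrophage"),
    CD11c = lineage("Dendritic"),
    PD1 = marker_model(
      neg = c(3, 0.4), pos = c(5.5, 0.5),
      pos_fraction = pd1_positive_fraction,
      positive_classes = c("BCell", "CytotoxicT", "HelperT", "Treg"),
      positive_groups = pd1_positive_groups,
      gated = TRUE
    )
  )
}

#' Generate a synthetic cohort
#'
#' Draws the full cohort described by a [cohort_spec()]: cell positions
#' and true phenotypes per FOV, marker intensities, patient metadata, and
#' a ground-truth sidecar. Fully reproducible from `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @return list with components
#'   \describe{
#'     \item{cells}{cell table (positions, `phenotype` set to the true
#'       class, `<marker>_mean` / `<marker>_sd` columns, `patient_id`,
#'       `specimen_id`, `outcome`).}
#'     \item{patients}{patient table (`patient_id`, `specimen_id`,
#'       `outcome`).}
#'     \item{truth}{ground truth keyed by `cell_id`: `true_class` and one
#'       logical `<marker>_pos` column per gated marker; the planted
#'       enrichment table is attached as attribute `"enrichments"`.}
#'   }
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  props <- spec$class_proportions
  p_tumor <- if ("Tumor" %in% names(props)) props[["Tumor"]] else 0
  exp_tumor <- spec$tumor_nests$parents_per_fov * spec$tumor_nests$mean_offspring
  exp_total <- if (p_tumor > 0) exp_tumor / p_tumor else {
    stop("class_proportions must include a positive Tumor fraction ",
         "(tumor nests calibrate the FOV cell count)", call. = FALSE)
  }
  if (exp_total < 10) {
    stop("degenerate spec: expected cells per FOV (", round(exp_total, 1),
         ") is below 10", call. = FALSE)
  }

  groups <- names(spec$n_patients_per_group)
  patients <- tibble::tibble(
    patient_id = sprintf("P%02d", seq_len(sum(spec$n_patients_per_group))),
    outcome = rep(groups, spec$n_patients_per_group)
  )
  patients$specimen_id <- sub("^P", "S", patients$patient_id)
  patients <- patients[, c("patient_id", "specimen_id", "outcome")]

  # classes placed after tumor, in scheme order
  later <- setdiff(phenotype_levels(), "Tumor")
  later <- later[later %in% names(props) & props[later] > 0]

  fov_list <- list()
  for (pi in seq_len(nrow(patients))) {
    g <- patients$outcome[pi]
    enr <- spec$enrichments
    if (!is.null(enr)) enr <- enr[enr$group == g, , drop = FALSE]
    for (fi in seq_len(spec$fovs_per_patient)) {
      fov_id <- sprintf("%s_f%02d", patients$patient_id[pi], fi)
      fov_list[[fov_id]] <- simulate_fov(
        fov_id = fov_id, fov_size = spec$fov_size, props = props,
        later = later, exp_total = exp_total, nests = spec$tumor_nests,
        enr = enr, radius = spec$interaction_radius
      )
    }
  }
  cells <- dplyr::bind_rows(fov_list)
  cells$patient_id <- sub("_f[0-9]+$", "", cells$fov_id)
  cells <- join_patient_metadata(cells, patients)

  mk <- simulate_markers(cells, spec)
  cells <- dplyr::bind_cols(cells, mk$intensities)
  truth <- dplyr::bind_cols(
    tibble::tibble(cell_id = cells$cell_id, true_class = cells$phenotype),
    mk$flags
  )
  attr(truth, "enrichments") <- spec$enrichments
  cells <- cells[, c("cell_id", "fov_id", "patient_id", "specimen_id",
                     "outcome", "x", "y", "phenotype",
                     names(mk$intensities))]
  list(cells = cells, patients = patients, truth = truth)
}

# One FOV: tumor nests first, then the remaining classes with planted
# attraction toward already-placed cells.
simulate_fov <- function(fov_id, fov_size, props, later, exp_total,
                         nests, enr, radius) {
  xs <- numeric(0); ys <- numeric(0); cls <- character(0)
  if ("Tumor" %in% names(props) && props[["Tumor"]] > 0) {
    n_par <- stats::rpois(1, nests$parents_per_fov)
    if (n_par > 0) {
      px <- stats::runif(n_par, 0, fov_size)
      py <- stats::runif(n_par, 0, fov_size)
      n_off <- stats::rpois(n_par, nests$mean_offspring)
      ox <- rep(px, n_off) + stats::rnorm(sum(n_off), 0, nests$dispersion)
      oy <- rep(py, n_off) + stats::rnorm(sum(n_off), 0, nests$dispersion)
      keep <- ox >= 0 & ox < fov_size & oy >= 0 & oy < fov_size
      xs <- ox[keep]; ys <- oy[keep]
      cls <- rep("Tumor", sum(keep))
    }
  }
  for (cl in later) {
    n_c <- stats::rpois(1, exp_total * props[[cl]])
    if (n_c == 0) next
    rows <- if (is.null(enr)) enr else
      enr[enr$neighbor_class == cl & enr$multiplier != 1, , drop = FALSE]
    if (is.null(rows) || nrow(rows) == 0) {
      nx <- stats::runif(n_c, 0, fov_size)
      ny <- stats::runif(n_c, 0, fov_size)
    } else {
      pool <- max(20L * n_c, 200L)
      cx <- stats::runif(pool, 0, fov_size)
      cy <- stats::runif(pool, 0, fov_size)
      w <- rep(1, pool)
      for (ri in seq_len(nrow(rows))) {
        sel <- cls == rows$index_class[ri]
        if (!any(sel)) next
        near <- cpp_radius_counts(cx, cy, xs[sel], ys[sel], radius)
        w <- w + (rows$multiplier[ri] - 1) * near
      }
      w <- pmax(w, 0)
      if (sum(w) <= 0) w <- rep(1, pool)
      take <- sample.int(pool, n_c, prob = w)
      nx <- cx[take]; ny <- cy[take]
    }
    xs <- c(xs, nx); ys <- c(ys, ny); cls <- c(cls, rep(cl, n_c))
  }
  tibble::tibble(
    cell_id = sprintf("%s_c%05d", fov_id, seq_along(xs)),
    fov_id = fov_id, x = xs, y = ys, phenotype = cls
  )
}

# Marker intensities for all cells at once. Returns the raw-scale
# intensity columns and the ground-truth positivity flags for gated
# markers.
simulate_markers <- function(cells, spec) {
  n <- nrow(cells)
  specimens <- sort(unique(cells$specimen_id))
  markers <- names(spec$marker_models)
  shifts <- matrix(
    stats::rnorm(length(specimens) * length(markers), 0, spec$specimen_shift_sd),
    nrow = length(specimens),
    dimnames = list(specimens, markers)
  )
  spec_idx <- match(cells$specimen_id, specimens)
  intensities <- list()
  flags <- list()
  for (m in markers) {
    mm <- spec$marker_models[[m]]
    pos <- cells$phenotype %in% mm$hi_classes
    if (mm$pos_fraction > 0) {
      eligible <- if (is.null(mm$positive_classes)) rep(TRUE, n) else
        cells$phenotype %in% mm$positive_classes
      if (!is.null(mm$positive_groups)) {
        eligible <- eligible & cells$outcome %in% mm$positive_groups
      }
      pos <- pos | (eligible & stats::runif(n) < mm$pos_fraction)
    }
    mu <- ifelse(pos, mm$pos[1], mm$neg[1])
    sd_ <- ifelse(pos, mm$pos[2], mm$neg[2])
    v_mean <- stats::rnorm(n, mu + shifts[cbind(spec_idx, match(m, markers))], sd_)
    v_sd <- stats::rnorm(n, 0.6 * mu, 0.8 * sd_)
    intensities[[paste0(m, "_mean")]] <- pmin(pmax(sinh(v_mean), 0), 65535)
    intensities[[paste0(m, "_sd")]] <- pmin(pmax(sinh(v_sd), 0), 65535)
    if (isTRUE(mm$gated)) flags[[paste0(m, "_pos")]] <- pos
  }
  list(intensities = tibble::as_tibble(intensities),
       flags = tibble::as_tibble(flags))
}

#' Sample an annotation subset from the ground truth
#'
#' Uniform random sample of cells without replacement, carrying the true
#' class label — the synthetic stand-in for an expert-annotated training
#' set used to fit the hierarchical classifier and calibrate gates.
#'
#' @param cells a generated cell table.
#' @param truth the matching ground-truth tibble.
#' @param n number of cells to sample (`n <= nrow(cells)`).
#' @param seed integer seed.
#' @return tibble: the sampled cells' rows joined with `true_class` (as
#'   column `label`) and the gated-marker truth flags.
#' @export
generate_annotation_subset <- function(cells, truth, n, seed = 1L) {
  if (n > nrow(cells)) {
    stop("annotation subset size n (", n, ") exceeds the number of cells (",
         nrow(cells), ")", call. = FALSE)
  }
  set.seed(as.integer(seed))
  take <- sample.int(nrow(cells), n)
  ann <- cells[sort(take), ]
  lab <- truth[match(ann$cell_id, truth$cell_id), ]
  ann$label <- lab$true_class
  for (col in grep("_pos$", names(lab), value = TRUE)) {
    ann[[col]] <- lab[[col]]
  }
  ann
}
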