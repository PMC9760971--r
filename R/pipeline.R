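#' Run the full tumor-immune microenvironment pipeline
#'
#' Orchestrates the stages end to end and writes every intermediate as
#' CSV plus a JSON run-metadata file, so a run is auditable and
#' reproducible: identical config and seed give byte-identical CSVs.
#'
#' @param config a list with elements
#'   \describe{
#'     \item{spec}{a [cohort_spec()] to simulate, \emph{or}}
#'     \item{cells_path, patients_path}{paths to existing CSV tables;}
#'     \item{out_dir}{output directory (created if needed);}
#'     \item{seed}{root integer seed for every random stage;}
#'     \item{stages}{subset of `c("phenotype", "gate", "communities",
#'       "neighborhoods", "interactions", "compare")`; default all but
#'       `"phenotype"` (generated/loaded tables already carry phenotype
#'       labels);}
#'     \item{k, c, label_threshold}{community parameters (75, 11, 0.10);}
#'     \item{diameter}{neighborhood diameter in pixels (57);}
#'     \item{marker, target_fpr}{gated marker and its calibration FPR
#'       (`"PD1"`, 0.01);}
#'     \item{n_annotations}{size of the annotation subset drawn from the
#'       ground truth for classifier/gate calibration (default
#'       `min(10000, cells/4)`);}
#'     \item{classifier}{optional list of overrides passed to
#'       [fit_hierarchical_classifier()] (e.g. `nrounds`).}
#'   }
#' @return (invisibly) a bundle list: the tables and fitted objects of
#'   every executed stage plus `paths` of all files written.
#' @export
run_pipeline <- function(config) {
  cfg <- utils::modifyList(
    list(stages = c("gate", "communities", "neighborhoods",
                    "interactions", "compare"),
         seed = 1L, k = 75, c = 11, label_threshold = 0.10, diameter = 57,
         marker = "PD1", target_fpr = 0.01, n_annotations = NULL,
         classifier = list()),
    config
  )
  if (is.null(cfg$out_dir)) stop("config$out_dir is required", call. = FALSE)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  bundle <- list()
  log_lines <- character(0)
  log <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
  }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  emit <- function(tbl, name) {
    p <- file.path(cfg$out_dir, paste0(name, ".csv"))
    readr::write_csv(tbl, p, progress = FALSE)
    paths[[name]] <<- p
    p
  }

  # data
  truth <- NULL
  if (!is.null(cfg$spec)) {
    spec <- cfg$spec
    spec$seed <- as.integer(cfg$seed)
    cohort <- run_stage("simulate", generate_cohort(spec))
    cells <- cohort$cells; patients <- cohort$patients; truth <- cohort$truth
    log("simulate: ", nrow(cells), " cells, ", nrow(patients), " patients")
  } else if (!is.null(cfg$cells_path) && !is.null(cfg$patients_path)) {
    cells <- run_stage("load", read_cell_table(cfg$cells_path))
    patients <- run_stage("load", read_patient_table(cfg$patients_path))
    cells <- run_stage("load", join_patient_metadata(cells, patients))
    log("load: ", nrow(cells), " cells, ", nrow(patients), " patients")
  } else {
    stop("config must provide either spec or cells_path + patients_path",
         call. = FALSE)
  }
  bundle$patients <- patients

  n_ann <- cfg$n_annotations
  if (is.null(n_ann)) n_ann <- min(10000L, floor(nrow(cells) / 4))
  annotations <- if (!is.null(truth)) {
    generate_annotation_subset(cells, truth, n_ann, seed = cfg$seed + 1L)
  } else cfg$annotations

  if ("phenotype" %in% cfg$stages) {
    if (is.null(annotations)) {
      stop("pipeline stage 'phenotype' failed: no annotations available",
           call. = FALSE)
    }
    args <- c(list(annotations = annotations, seed = cfg$seed + 2L),
              cfg$classifier)
    model <- run_stage("phenotype", do.call(fit_hierarchical_classifier, args))
    cells <- run_stage("phenotype", classify_cells(model, cells))
    cells$broad_class <- NULL
    bundle$tier_model <- model
    write_tier_model(model, file.path(cfg$out_dir, "tier_model.json"))
    paths$tier_model <- file.path(cfg$out_dir, "tier_model.json")
    log("phenotype: tier1 test accuracy ",
        round(model$accuracy$test_accuracy[1], 4))
  }

  if ("gate" %in% cfg$stages) {
    if (is.null(annotations)) {
      stop("pipeline stage 'gate' failed: no annotations available",
           call. = FALSE)
    }
    g <- run_stage("gate", gate_functional_marker(
      cells, cfg$marker, annotations, target_fpr = cfg$target_fpr))
    cells <- g$cells
    bundle$gate_model <- g$model
    write_gate_model(g$model, file.path(cfg$out_dir, "gate_model.json"))
    paths$gate_model <- file.path(cfg$out_dir, "gate_model.json")
    log("gate: ", cfg$marker, " positive fraction ",
        round(mean(cells[[paste0(cfg$marker, "_pos")]]), 4))
  }

  emit(cells, "cells")
  emit(patients, "patients")
  bundle$cells <- cells
  families <- list()

  if ("communities" %in% cfg$stages) {
    vectors <- run_stage("communities", knn_composition(cells, k = cfg$k))
    cm <- run_stage("communities",
                    fit_communities(vectors, c = cfg$c, seed = cfg$seed + 3L))
    cm <- label_communities(cm, threshold = cfg$label_threshold)
    bundle$community_model <- cm
    emit(cm$assignments, "community_assignments")
    emit(tidy(cm), "community_profiles")
    emit(community_frequencies(cm, cells), "community_frequencies")
    families$communities <- community_feature_counts(cm, cells)
    log("communities: c = ", cm$c, ", inertia ", round(cm$inertia, 4))
  }

  if ("neighborhoods" %in% cfg$stages ||
      "interactions" %in% cfg$stages) {
    fov_size <- if (!is.null(cfg$spec)) cfg$spec$fov_size else 2040
    tccn <- run_stage("neighborhoods", build_neighborhoods(
      cells, "Tumor", diameter = cfg$diameter,
      fov_width = fov_size, fov_height = fov_size))
    ctcn <- run_stage("neighborhoods", build_neighborhoods(
      cells, "CytotoxicT", diameter = cfg$diameter,
      fov_width = fov_size, fov_height = fov_size))
    bundle$tccn <- tccn; bundle$ctcn <- ctcn
    if ("neighborhoods" %in% cfg$stages) {
      emit(tccn, "tccn"); emit(ctcn, "ctcn")
      tccn_f <- filter_populated(tccn); ctcn_f <- filter_populated(ctcn)
      families$tccn_composition <-
        neighborhood_composition_by_patient(tccn_f)
      families$ctcn_composition <-
        neighborhood_composition_by_patient(ctcn_f)
      emit(families$tccn_composition, "tccn_composition")
      emit(families$ctcn_composition, "ctcn_composition")
      td <- tumor_count_distribution(tccn)
      emit(td, "tccn_tumor_count_distribution")
      emit(attr(td, "means"), "tccn_tumor_count_means")
      log("neighborhoods: ", nrow(tccn), " TCCN, ", nrow(ctcn), " CTCN")
    }
  }

  if ("interactions" %in% cfg$stages) {
    cat_t <- run_stage("interactions", categorize_neighborhoods(tccn))
    cat_c <- run_stage("interactions", categorize_neighborhoods(ctcn))
    bundle$tccn_categories <- cat_t; bundle$ctcn_categories <- cat_c
    emit(pairing_frequencies(cat_t), "tccn_pairing_frequencies")
    emit(pairing_frequencies(cat_c), "ctcn_pairing_frequencies")
    families$tccn_interactions <- pairing_feature_counts(cat_t)
    families$ctcn_interactions <- pairing_feature_counts(cat_c)
    if ("gate" %in% cfg$stages) {
      families$pd1 <- run_stage("interactions",
                                pd1_neighbor_frequencies(tccn, cfg$marker))
      emit(families$pd1, "pd1_neighbor_frequencies")
    }
    log("interactions: categorized TCCN and CTCN")
  }

  if ("compare" %in% cfg$stages) {
    comparisons <- purrr::imap_dfr(families, function(feat, fam) {
      res <- run_stage("compare", compare_groups(feat, patients))
      res$family <- fam
      res
    })
    bundle$comparisons <- comparisons
    emit(comparisons, "comparisons")
    log("compare: ", sum(comparisons$significant), " of ",
        nrow(comparisons), " features significant (BH < 0.05)")
  }

  meta <- list(
    package = "nichescape",
    version = as.character(utils::packageVersion("nichescape")),
    seed = cfg$seed,
    stages = cfg$stages,
    parameters = cfg[c("k", "c", "label_threshold", "diameter", "marker",
                       "target_fpr")],
    log = log_lines
  )
  jsonlite::write_json(meta, file.path(cfg$out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths$run_metadata <- file.path(cfg$out_dir, "run_metadata.json")
  bundle$paths <- paths
  invisible(bundle)
}
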