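# Classifier tests run on the default 6-sd-separated marker panel with a
# reduced number of boosting rounds; accuracy bounds hold with margin.

make_annotated_cohort <- function(seed, groups = c(GroupA = 3, GroupB = 3),
                                  n_ann = 2500) {
  co <- generate_cohort(small_spec(seed = seed, groups = groups, fovs = 1))
  ann <- generate_annotation_subset(co$cells, co$truth, n_ann, seed = seed + 1)
  list(cohort = co, ann = ann)
}

test_that("well-separated annotations give near-perfect tier-1 accuracy", {
  fx <- make_annotated_cohort(seed = 41)
  model <- fit_hierarchical_classifier(fx$ann, seed = 1, nrounds = 120)
  expect_gt(model$accuracy$test_accuracy[1], 0.95)
  expect_gt(model$accuracy$train_accuracy[1], 0.95)
  expect_identical(tidy(model), model$accuracy)
})

test_that("permuted labels collapse tier-1 accuracy to the majority rate", {
  fx <- make_annotated_cohort(seed = 42)
  perm <- fx$ann
  set.seed(99)
  perm$label <- sample(perm$label)
  model <- fit_hierarchical_classifier(perm, seed = 1, nrounds = 120)
  broad <- broad_class_of(perm$label)
  p0 <- max(table(broad)) / length(broad)
  n_test <- model$accuracy$n_test[1]
  expect_lt(model$accuracy$test_accuracy[1],
            p0 + 3 * sqrt(p0 * (1 - p0) / n_test))
})

test_that("classifier fitting is deterministic given the seed", {
  fx <- make_annotated_cohort(seed = 43, n_ann = 1200)
  m1 <- fit_hierarchical_classifier(fx$ann, seed = 7, nrounds = 60)
  m2 <- fit_hierarchical_classifier(fx$ann, seed = 7, nrounds = 60)
  expect_identical(m1$accuracy, m2$accuracy)
})

test_that("single-example classes are a stratification error", {
  fx <- make_annotated_cohort(seed = 44, n_ann = 600)
  ann <- fx$ann[fx$ann$label != "Neutrophil", ]
  one <- fx$ann[fx$ann$label == "Neutrophil", ][1, ]
  expect_error(fit_hierarchical_classifier(rbind(ann, one), seed = 1,
                                           nrounds = 10),
               "single annotated example")
})

test_that("classification is hierarchy-consistent and recovers true labels", {
  fx <- make_annotated_cohort(seed = 45)
  model <- fit_hierarchical_classifier(fx$ann, seed = 1, nrounds = 120)
  pred <- classify_cells(model, fx$cohort$cells)
  expect_equal(nrow(pred), nrow(fx$cohort$cells))
  expect_true(all(pred$phenotype %in% phenotype_levels()))
  # fine immune label only where tier 1 said Immune
  fine_imm <- pred$phenotype %in% immune_levels()
  expect_true(all(pred$broad_class[fine_imm] == "Immune"))
  expect_true(all(pred$broad_class[!fine_imm] == pred$phenotype[!fine_imm]))
  # planted-label recovery on the separable panel
  acc <- mean(pred$phenotype ==
                fx$cohort$truth$true_class[match(pred$cell_id,
                                                 fx$cohort$truth$cell_id)])
  expect_gt(acc, 0.9)

  empty <- classify_cells(model, fx$cohort$cells[0, ])
  expect_equal(nrow(empty), 0)
  expect_error(classify_cells(model, dplyr::select(fx$cohort$cells,
                                                   -"CD8_mean")),
               "feature column")
})

test_that("gate calibration hits the target false-positive rate", {
  co <- generate_cohort(cohort_spec(
    n_patients_per_group = c(GroupA = 4, GroupB = 4), fovs_per_patient = 1,
    fov_size = 2040, enrichments = NULL, seed = 51
  ))
  expect_gte(nrow(co$cells), 20000)
  ann <- generate_annotation_subset(co$cells, co$truth, 6000, seed = 52)
  g <- gate_functional_marker(co$cells, "PD1", ann, target_fpr = 0.01)
  calls <- g$cells$PD1_pos
  truth <- co$truth$PD1_pos[match(g$cells$cell_id, co$truth$cell_id)]
  heldout_neg <- !truth & !(g$cells$cell_id %in% ann$cell_id)
  expect_lte(mean(calls[heldout_neg]), 0.02)
  # planted positive fraction among TILs recovered within 0.02
  til <- co$cells$phenotype %in% c("BCell", "CytotoxicT", "HelperT", "Treg")
  expect_lt(abs(mean(calls[til]) - 0.15), 0.02)
})

test_that("gating is invariant to per-specimen location shifts", {
  co <- generate_cohort(small_spec(seed = 53, groups = c(GroupA = 2, GroupB = 2),
                                   specimen_shift_sd = 0))
  base <- co$cells[co$cells$specimen_id == co$cells$specimen_id[1], ]
  delta <- 0.8
  shifted <- base
  shifted$cell_id <- paste0(base$cell_id, "_sh")
  shifted$specimen_id <- "S_shifted"
  shifted$PD1_mean <- sinh(asinh(base$PD1_mean) + delta)
  both <- rbind(base, shifted)
  truth_base <- co$truth[match(base$cell_id, co$truth$cell_id), ]
  ann <- rbind(
    tibble::tibble(cell_id = base$cell_id, PD1_pos = truth_base$PD1_pos),
    tibble::tibble(cell_id = shifted$cell_id, PD1_pos = truth_base$PD1_pos)
  )
  g <- gate_functional_marker(both, "PD1", ann, target_fpr = 0.02)
  calls <- g$cells$PD1_pos
  # identical up to float round-trip noise in sinh(asinh(x) + delta),
  # which can flip only cells sitting exactly on a threshold
  agree <- calls[seq_len(nrow(base))] ==
    calls[nrow(base) + seq_len(nrow(base))]
  expect_gte(mean(agree), 0.995)
})

test_that("the gate is monotone in its thresholds", {
  co <- generate_cohort(small_spec(seed = 54, groups = c(GroupA = 2, GroupB = 2)))
  ann <- generate_annotation_subset(co$cells, co$truth, 1500, seed = 55)
  g <- gate_functional_marker(co$cells, "PD1", ann, target_fpr = 0.02)
  frac0 <- mean(g$cells$PD1_pos)
  for (bump in list(c(0.5, 0), c(0, 0.5), c(0.5, 0.5))) {
    stricter <- g$model
    stricter$mean_threshold <- stricter$mean_threshold + bump[1]
    stricter$sd_threshold <- stricter$sd_threshold + bump[2]
    expect_lte(mean(apply_gate(stricter, co$cells)$PD1_pos), frac0)
  }
})

test_that("gating error paths: no negatives, constant marker", {
  co <- generate_cohort(small_spec(seed = 56, groups = c(GroupA = 1, GroupB = 1)))
  ann <- generate_annotation_subset(co$cells, co$truth, 200, seed = 57)
  pos_only <- ann
  pos_only$PD1_pos <- TRUE
  expect_error(gate_functional_marker(co$cells, "PD1", pos_only, 0.01),
               "negative")
  flat <- co$cells
  flat$PD1_mean <- 100
  flat$PD1_sd <- 100
  expect_error(gate_functional_marker(flat, "PD1", ann, 0.01), "degenerate")
})

test_that("gate models round-trip through JSON", {
  co <- generate_cohort(small_spec(seed = 58, groups = c(GroupA = 2, GroupB = 1)))
  ann <- generate_annotation_subset(co$cells, co$truth, 1000, seed = 59)
  g <- gate_functional_marker(co$cells, "PD1", ann, target_fpr = 0.02)
  path <- withr::local_tempfile(fileext = ".json")
  write_gate_model(g$model, path)
  back <- read_gate_model(path)
  expect_equal(back$mean_threshold, g$model$mean_threshold)
  expect_identical(apply_gate(back, co$cells)$PD1_pos, g$cells$PD1_pos)
})
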