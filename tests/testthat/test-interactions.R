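nbhd_row <- function(counts, cell_id = "i1", patient_id = "P1",
                     outcome = "GroupA") {
  row <- tibble::tibble(cell_id = cell_id, fov_id = "f1",
                        patient_id = patient_id, outcome = outcome,
                        x = 0, y = 0)
  for (cl in phenotype_levels()) {
    row[[paste0("n_", cl)]] <- if (cl %in% names(counts)) counts[[cl]] else 0L
  }
  row$border <- FALSE
  row
}

as_nbhd <- function(rows, index_class = "Tumor") {
  mat <- dplyr::bind_rows(rows)
  attr(mat, "index_class") <- index_class
  attr(mat, "diameter") <- 57
  class(mat) <- c("nbhd_matrix", class(mat))
  mat
}

test_that("neighborhood categories follow the homo/heterotypic definitions", {
  mat <- as_nbhd(list(
    nbhd_row(c(Macrophage = 2), "a"),                       # homotypic MAC
    nbhd_row(c(Dendritic = 1, CytotoxicT = 1, Tumor = 3), "b"),  # heterotypic
    nbhd_row(c(Tumor = 4, Stroma = 1), "c")                 # tumor-only
  ))
  cats <- categorize_neighborhoods(mat)
  expect_identical(cats$category, c("Homotypic", "Heterotypic", "TumorOnly"))
  expect_identical(cats$homotypic_class, c("Macrophage", NA, NA))
  expect_setequal(cats$immune_classes_present[[2]],
                  c("Dendritic", "CytotoxicT"))
  expect_identical(cats$n_immune_classes, c(1L, 2L, 0L))
})

test_that("categories are exhaustive, exclusive, and sum to one per group", {
  co <- generate_cohort(small_spec(seed = 61, groups = c(GroupA = 2, GroupB = 2)))
  mat <- build_neighborhoods(co$cells, "Tumor", fov_width = 800,
                             fov_height = 800)
  cats <- categorize_neighborhoods(mat)
  expect_equal(nrow(cats), nrow(mat))
  pf <- pairing_frequencies(cats)
  for (g in unique(pf$outcome)) {
    cat_rows <- pf$type %in% c("tumor_only", "homotypic", "heterotypic") &
      pf$outcome == g
    expect_equal(sum(pf$frequency[cat_rows]), 1, tolerance = 1e-9)
  }
  # brute-force re-derivation from the raw counts
  imm <- as.matrix(mat[, paste0("n_", immune_levels())]) >= 1
  m <- rowSums(imm)
  expect_identical(cats$category[m == 0][1], "TumorOnly")
  expect_equal(sum(cats$category == "Heterotypic"), sum(m >= 2))
  expect_equal(sum(cats$category == "Homotypic"), sum(m == 1))
})

test_that("a heterotypic neighborhood contributes all class pairs", {
  mat <- as_nbhd(list(
    nbhd_row(c(Dendritic = 1, CytotoxicT = 2, Macrophage = 1), "a")
  ))
  cats <- categorize_neighborhoods(mat)
  pf <- pairing_frequencies(cats)
  pairs <- pf[pf$type == "pair", ]
  expect_equal(nrow(pairs), 3)  # C(3, 2)
  expect_equal(sum(pairs$count), choose(3, 2))

  # pair-incidence bookkeeping across mixed neighborhoods
  mat2 <- as_nbhd(list(
    nbhd_row(c(Dendritic = 1, CytotoxicT = 1, Macrophage = 1, BCell = 1), "a"),
    nbhd_row(c(Dendritic = 1, CytotoxicT = 1), "b"),
    nbhd_row(c(Macrophage = 3), "c")
  ))
  pf2 <- pairing_frequencies(categorize_neighborhoods(mat2))
  expect_equal(sum(pf2$count[pf2$type == "pair"]), choose(4, 2) + 1)
})

test_that("groups with no heterotypic neighborhoods have zero pair mass", {
  mat <- as_nbhd(list(nbhd_row(c(Macrophage = 1), "a"),
                      nbhd_row(c(Tumor = 2), "b")))
  pf <- pairing_frequencies(categorize_neighborhoods(mat))
  expect_equal(sum(pf$type == "pair"), 0)
  expect_equal(pf$frequency[pf$type == "heterotypic"], 0)
})

test_that("pair normalization denominators are switchable", {
  mat <- as_nbhd(list(
    nbhd_row(c(Dendritic = 1, CytotoxicT = 1), "a"),
    nbhd_row(c(Tumor = 1), "b"),
    nbhd_row(c(Tumor = 1), "c"),
    nbhd_row(c(Macrophage = 1), "d")
  ))
  cats <- categorize_neighborhoods(mat)
  by_total <- pairing_frequencies(cats, normalize = "total")
  by_het <- pairing_frequencies(cats, normalize = "heterotypic")
  expect_equal(by_total$frequency[by_total$type == "pair"], 1 / 4)
  expect_equal(by_het$frequency[by_het$type == "pair"], 1)
})

test_that("per-patient pairing features feed the cohort comparison", {
  co <- generate_cohort(small_spec(seed = 62, groups = c(GroupA = 2, GroupB = 2)))
  mat <- build_neighborhoods(co$cells, "Tumor", fov_width = 800,
                             fov_height = 800)
  feats <- pairing_feature_counts(categorize_neighborhoods(mat))
  expect_true(all(c("patient_id", "feature", "events", "total")
                  %in% names(feats)))
  expect_true(all(feats$events <= feats$total))
  per_pat <- unique(feats[, c("patient_id", "total")])
  expect_setequal(per_pat$total, as.vector(table(mat$patient_id)))
})

test_that("functional-positive neighbor frequencies behave at the extremes", {
  base <- make_cells(x = c(0, 10, 300, 310), y = c(0, 0, 0, 0),
                     phenotype = c("Tumor", "CytotoxicT", "Tumor",
                                   "CytotoxicT"),
                     patient_id = "P1")
  base$outcome <- "GroupA"

  # no positive cells anywhere
  none <- base
  none$PD1_pos <- FALSE
  mat <- build_neighborhoods(none, "Tumor", diameter = 57)
  freq <- pd1_neighbor_frequencies(mat)
  expect_true(all(freq$fraction == 0))
  expect_false(any(attr(freq, "flagged")$flagged))

  # every cytotoxic T positive and present in every neighborhood
  all_pos <- base
  all_pos$PD1_pos <- all_pos$phenotype == "CytotoxicT"
  mat2 <- build_neighborhoods(all_pos, "Tumor", diameter = 57)
  freq2 <- pd1_neighbor_frequencies(mat2)
  expect_equal(freq2$fraction[freq2$feature == "PD1pos_CytotoxicT"], 1)
  expect_true(all(attr(freq2, "flagged")$flagged))

  # ungated cells are a dependency error pointing at the gate
  mat3 <- build_neighborhoods(base, "Tumor", diameter = 57)
  expect_error(pd1_neighbor_frequencies(mat3), "gate_functional_marker")
})
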