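test_that("the 57 px diameter means an inclusive closed disc of radius 28.5", {
  cells <- make_cells(x = c(0, 28, 29, 28.5), y = c(0, 0, 0, 0),
                      phenotype = c("Tumor", "Dendritic", "Dendritic",
                                    "Macrophage"))
  mat <- build_neighborhoods(cells, "Tumor", diameter = 57)
  expect_equal(nrow(mat), 1)
  expect_equal(mat$n_Dendritic, 1)   # 28 in, 29 out
  expect_equal(mat$n_Macrophage, 1)  # exactly 28.5 counted
  expect_equal(mat$n_Tumor, 0)       # index cell excluded
  expect_true(mat$border)            # closer than one radius to the edge
})

test_that("neighborhood counts equal the all-pairs oracle", {
  cells <- random_cells(1000, fov_size = 400, n_fov = 2, seed = 23)
  for (cls in c("Tumor", "CytotoxicT")) {
    mat <- build_neighborhoods(cells, cls, diameter = 57, fov_width = 400,
                               fov_height = 400)
    oracle <- oracle_neighborhood_counts(cells, cls, diameter = 57)
    got <- as.matrix(mat[, paste0("n_", phenotype_levels())])
    expect_equal(unname(got[match(rownames(oracle), mat$cell_id), ]),
                 unname(oracle))
    # row sums: all cells in the disc minus the index cell
    expect_true(all(rowSums(got) >= 0))
  }
  expect_error(build_neighborhoods(cells, "NotAClass"), "unknown index class")
})

test_that("counts are monotone non-decreasing in the diameter", {
  cells <- random_cells(600, fov_size = 300, seed = 24)
  m1 <- build_neighborhoods(cells, "Tumor", diameter = 57, fov_width = 300,
                            fov_height = 300)
  m2 <- build_neighborhoods(cells, "Tumor", diameter = 90, fov_width = 300,
                            fov_height = 300)
  c1 <- as.matrix(m1[, paste0("n_", phenotype_levels())])
  c2 <- as.matrix(m2[, paste0("n_", phenotype_levels())])
  expect_true(all(c2 - c1 >= 0))
})

test_that("populated filters keep the right compartments", {
  cells <- make_cells(
    x = c(0, 10, 100, 110, 200, 210, 205),
    y = rep(0, 7),
    phenotype = c("Tumor", "Stroma",          # tumor-only neighborhood
                  "Tumor", "BCell",           # immune-populated
                  "CytotoxicT", "Tumor", "BCell")
  )
  tccn <- build_neighborhoods(cells, "Tumor", diameter = 57)
  kept <- filter_populated(tccn)
  expect_setequal(kept$cell_id, cells$cell_id[c(3, 6)])

  ctcn <- build_neighborhoods(cells, "CytotoxicT", diameter = 57)
  expect_equal(nrow(filter_populated(ctcn)), 1)  # has a tumor neighbor

  empty <- filter_populated(tccn[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("per-patient composition fractions are simple proportions", {
  # one patient, 4 tumor neighborhoods, 2 of them containing a dendritic cell
  cells <- make_cells(
    x = c(0, 300, 600, 900, 10, 310, 605, 905),
    y = rep(c(0, 20), each = 4),
    phenotype = c(rep("Tumor", 4), "Dendritic", "Dendritic",
                  "Macrophage", "Macrophage"),
    patient_id = "P1"
  )
  mat <- build_neighborhoods(cells, "Tumor", diameter = 57)
  comp <- neighborhood_composition_by_patient(mat)
  expect_equal(comp$fraction[comp$feature == "Dendritic"], 0.5)
  expect_equal(comp$fraction[comp$feature == "Macrophage"], 0.5)
  expect_equal(comp$fraction[comp$feature == "BCell"], 0)
  expect_true(all(comp$total == 4))
})

test_that("tumor count distributions report group means", {
  cells <- make_cells(
    x = c(0, 10, 20, 300, 600, 610, 620, 630),
    y = rep(0, 8), phenotype = "Tumor", patient_id = "P1"
  )
  cells$outcome <- "GroupA"
  mat <- build_neighborhoods(cells, "Tumor", diameter = 57)
  dist <- tumor_count_distribution(mat)
  means <- attr(dist, "means")
  # chain at 600..630: ends reach 2 cells, middles 3 (28.5 px radius)
  expect_equal(means$mean_tumor_count,
               mean(c(2, 2, 2, 0, 2, 3, 3, 2)))
  expect_equal(sum(dist$frequency), 1)
})

test_that("denser tumor nests raise the mean TCCN tumor count", {
  mean_count <- function(offspring, seed) {
    spec <- small_spec(seed = seed, groups = c(GroupA = 1, GroupB = 1),
                       nests = list(parents_per_fov = 5,
                                    mean_offspring = offspring,
                                    dispersion = 40))
    co <- generate_cohort(spec)
    mat <- build_neighborhoods(co$cells, "Tumor", fov_width = 800,
                               fov_height = 800)
    mean(mat$n_Tumor)
  }
  sparse <- vapply(1:20, function(s) mean_count(40, 100 + s), numeric(1))
  dense <- vapply(1:20, function(s) mean_count(110, 200 + s), numeric(1))
  expect_gt(mean(dense), mean(sparse))
})
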