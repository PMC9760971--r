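test_that("knn composition matches hand-computed neighbor fractions", {
  cells <- make_cells(x = c(0, 1, 2, 10), y = c(0, 0, 0, 0),
                      phenotype = c("Tumor", "BCell", "Tumor", "BCell"))
  comp <- knn_composition(cells, k = 2)
  q <- comp[comp$cell_id == cells$cell_id[1], ]
  expect_equal(q$Tumor, 0.5)
  expect_equal(q$BCell, 0.5)
  expect_equal(sum(as.matrix(comp[, phenotype_levels()])), nrow(comp))
})

test_that("single-class FOVs give one-hot composition vectors", {
  cells <- make_cells(x = runif(40, 0, 100), y = runif(40, 0, 100),
                      phenotype = "Macrophage")
  comp <- knn_composition(cells, k = 5)
  expect_true(all(comp$Macrophage == 1))
  expect_true(all(as.matrix(comp[, setdiff(phenotype_levels(),
                                           "Macrophage")]) == 0))
})

test_that("knn composition equals the exhaustive-distance oracle", {
  cells <- random_cells(500, n_fov = 2, seed = 13)
  comp <- knn_composition(cells, k = 75)
  oracle <- oracle_knn_composition(cells, k = 75)
  expect_equal(unname(as.matrix(comp[, phenotype_levels()])),
               unname(oracle))
})

test_that("knn composition guards: k bounds and small FOVs", {
  cells <- random_cells(50, seed = 14)
  expect_error(knn_composition(cells, k = 0), "positive")
  tiny <- random_cells(10, seed = 15)
  tiny$fov_id <- "tiny_fov"
  tiny$cell_id <- paste0("t", tiny$cell_id)
  expect_warning(knn_composition(rbind(cells, tiny), k = 20), "skipping")
  un <- cells
  un$phenotype[1] <- "UNASSIGNED"
  expect_error(knn_composition(un, k = 5), "UNASSIGNED")
})

test_that("planted one-hot blocks are recovered exactly", {
  skip_if_not_installed("mclust")
  cells <- make_cells(
    x = c(runif(150, 0, 40), runif(150, 400, 440)),
    y = runif(300, 0, 40),
    phenotype = rep(c("Tumor", "BCell"), each = 150)
  )
  comp <- knn_composition(cells, k = 10)
  fit <- fit_communities(comp, c = 2, seed = 3)
  truth <- rep(c(1, 2), each = 150)
  expect_equal(
    mclust::adjustedRandIndex(fit$assignments$cluster,
                              truth[match(fit$assignments$cell_id,
                                          cells$cell_id)]),
    1.0
  )
})

test_that("community fitting is deterministic and permutation-equivariant", {
  cells <- random_cells(400, seed = 16)
  comp <- knn_composition(cells, k = 15)
  f1 <- fit_communities(comp, c = 4, seed = 9)
  f2 <- fit_communities(comp, c = 4, seed = 9)
  expect_identical(f1$assignments, f2$assignments)

  shuffled <- cells[sample(nrow(cells)), ]
  f3 <- fit_communities(knn_composition(shuffled, k = 15), c = 4, seed = 9)
  expect_identical(f1$assignments, f3$assignments)
})

test_that("c = 1 collapses to the global mean composition", {
  cells <- random_cells(200, seed = 17)
  comp <- knn_composition(cells, k = 10)
  fit <- fit_communities(comp, c = 1, seed = 1)
  expect_true(all(fit$assignments$cluster == 1))
  expect_equal(as.numeric(fit$cluster_profiles),
               unname(colMeans(as.matrix(comp[, phenotype_levels()]))))
  expect_error(fit_communities(comp[1:3, ], c = 5, seed = 1), "exceeds")
})

test_that("cluster labels are the classes enriched above threshold", {
  fake <- function(profile) {
    prof <- matrix(0, 1, length(phenotype_levels()),
                   dimnames = list(NULL, phenotype_levels()))
    prof[1, names(profile)] <- profile
    structure(list(c = 1, cluster_profiles = prof), class = "community_model")
  }
  # tumor 59% + dendritic 26%, remainder spread below 10%
  m <- label_communities(fake(c(Tumor = 0.59, Dendritic = 0.26, Stroma = 0.08,
                                BCell = 0.07)))
  expect_identical(m$cluster_labels[[1]], c("Tumor", "Dendritic"))
  # 95% tumor dominates alone
  m <- label_communities(fake(c(Tumor = 0.95, Stroma = 0.05)))
  expect_identical(m$cluster_labels[[1]], "Tumor")
  # a uniform profile at exactly the threshold is unlabelled (strict >)
  u <- rep(1 / 10, 10)
  names(u) <- phenotype_levels()[1:10]
  m <- label_communities(fake(u), threshold = 0.10)
  expect_length(m$cluster_labels[[1]], 0)
})

test_that("community frequencies are per-patient fractions summing to one", {
  co <- generate_cohort(small_spec(seed = 18, groups = c(GroupA = 2, GroupB = 2)))
  comp <- knn_composition(co$cells, k = 20)
  fit <- fit_communities(comp, c = 4, seed = 2)
  freq <- community_frequencies(fit, co$cells)
  mat <- as.matrix(freq[, paste0("cluster_", 1:4)])
  expect_equal(unname(rowSums(mat)), rep(1, nrow(freq)))
  expect_setequal(freq$patient_id, co$patients$patient_id)

  # two patients with identical assignments get identical rows
  cells <- make_cells(x = rep(runif(60, 0, 100), 2), y = rep(runif(60, 0, 100), 2),
                      phenotype = rep(sample(c("Tumor", "BCell"), 60, TRUE), 2),
                      fov_id = rep(c("fA", "fB"), each = 60))
  cells$patient_id <- rep(c("P1", "P2"), each = 60)
  compd <- knn_composition(cells, k = 8)
  fitd <- fit_communities(compd, c = 2, seed = 4)
  fr <- community_frequencies(fitd, cells)
  expect_equal(unname(as.matrix(fr[1, -1])), unname(as.matrix(fr[2, -1])))
})

test_that("parameter sweeps cover the grid with sane diagnostics", {
  cells <- random_cells(300, seed = 19)
  sw <- sweep_parameters(cells, k_grid = c(5, 20), c_grid = c(2, 6), seed = 5)
  expect_equal(nrow(sw), 4)
  one <- sweep_parameters(cells, k_grid = 10, c_grid = 3, seed = 5)
  expect_equal(nrow(one), 1)
  # k-means objective: inertia non-increasing in c (1% mini-batch slack)
  sw2 <- sweep_parameters(cells, k_grid = 20, c_grid = c(2, 4, 8), seed = 5)
  ordered <- sw2$inertia[order(sw2$c)]
  expect_true(all(diff(ordered) <= 0.01 * ordered[-length(ordered)]))
})
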