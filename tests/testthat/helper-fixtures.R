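# Fixture builders and independent brute-force oracles shared across tests.

# Small cohort spec: defaults chosen so a whole cohort generates in well
# under a second.
small_spec <- function(seed = 1, groups = c(GroupA = 3, GroupB = 3),
                       fovs = 1, fov_size = 800,
                       nests = list(parents_per_fov = 5, mean_offspring = 60,
                                    dispersion = 40),
                       enrichments = NULL, ...) {
  cohort_spec(
    n_patients_per_group = groups, fovs_per_patient = fovs,
    fov_size = fov_size, tumor_nests = nests, enrichments = enrichments,
    seed = seed, ...
  )
}

# The replicate scale used for planted-enrichment recovery: 20 patients
# per group, 2 reduced-size FOVs per patient.
enrichment_spec <- function(seed, multiplier,
                            index_class = "Tumor",
                            neighbor_class = "Dendritic",
                            group = "GroupA") {
  cohort_spec(
    n_patients_per_group = c(GroupA = 20, GroupB = 20),
    fovs_per_patient = 2, fov_size = 1200,
    tumor_nests = list(parents_per_fov = 8, mean_offspring = 60,
                       dispersion = 40),
    enrichments = tibble::tibble(group = group, index_class = index_class,
                                 neighbor_class = neighbor_class,
                                 multiplier = multiplier),
    seed = seed
  )
}

# Hand-rolled cell table with explicit positions/phenotypes.
make_cells <- function(x, y, phenotype, fov_id = "f1", patient_id = NULL) {
  tb <- tibble::tibble(
    cell_id = sprintf("%s_c%03d", fov_id, seq_along(x)),
    fov_id = fov_id, x = x, y = y, phenotype = phenotype
  )
  if (!is.null(patient_id)) tb$patient_id <- patient_id
  tb
}

# Uniform random cell table over one or more FOVs.
random_cells <- function(n, fov_size = 500, n_fov = 1,
                         classes = phenotype_levels(), seed = 1) {
  set.seed(seed)
  tibble::tibble(
    cell_id = sprintf("r%05d", seq_len(n)),
    fov_id = sprintf("f%02d", sample.int(n_fov, n, replace = TRUE)),
    x = stats::runif(n, 0, fov_size),
    y = stats::runif(n, 0, fov_size),
    phenotype = sample(classes, n, replace = TRUE)
  )
}

# O(n^2) oracle for k-NN composition within one FOV: full pairwise
# distance sort per cell, ties broken by cell_id.
oracle_knn_composition <- function(cells, k) {
  levels_ <- phenotype_levels()
  out <- lapply(split(seq_len(nrow(cells)), cells$fov_id), function(rows) {
    fov <- cells[rows, ][order(cells$cell_id[rows]), ]
    n <- nrow(fov)
    t(vapply(seq_len(n), function(i) {
      d <- sqrt((fov$x - fov$x[i])^2 + (fov$y - fov$y[i])^2)
      ord <- order(d, fov$cell_id)
      ord <- ord[ord != i][seq_len(k)]
      tab <- table(factor(fov$phenotype[ord], levels = levels_))
      as.numeric(tab) / k
    }, numeric(length(levels_))))
  })
  res <- do.call(rbind, out)
  colnames(res) <- levels_
  res
}

# O(n^2) oracle for fixed-radius class counts around index cells.
oracle_neighborhood_counts <- function(cells, index_class, diameter) {
  r <- diameter / 2
  levels_ <- phenotype_levels()
  out <- lapply(split(seq_len(nrow(cells)), cells$fov_id), function(rows) {
    fov <- cells[rows, ]
    idx <- which(fov$phenotype == index_class)
    if (length(idx) == 0) return(NULL)
    counts <- t(vapply(idx, function(i) {
      d <- sqrt((fov$x - fov$x[i])^2 + (fov$y - fov$y[i])^2)
      nb <- which(d <= r & seq_len(nrow(fov)) != i)
      as.numeric(table(factor(fov$phenotype[nb], levels = levels_)))
    }, numeric(length(levels_))))
    rownames(counts) <- fov$cell_id[idx]
    counts
  })
  res <- do.call(rbind, out)
  colnames(res) <- levels_
  res
}

# Closed-form Pearson chi-squared for a 2x2 table of counts.
oracle_chisq_2x2 <- function(a, b, c, d) {
  n <- a + b + c + d
  e <- outer(c(a + b, c + d), c(a + c, b + d)) / n
  o <- matrix(c(a, c, b, d), 2)
  sum((o - e)^2 / e)
}

# Hand-applied BH step-up.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[ord] <- pmin(adj, 1)
  out
}

# Cells arranged as two macro-niches (disjoint FOVs with different
# compositions), for planted-community recovery.
make_two_niche_cells <- function(seed, n_fov_per_niche = 6, n_cells = 300,
                                 fov_size = 600) {
  set.seed(seed)
  props <- list(
    nicheA = c(Tumor = 0.8, Dendritic = 0.1, Stroma = 0.1),
    nicheB = c(Tumor = 0.2, BCell = 0.4, CytotoxicT = 0.2, Macrophage = 0.2)
  )
  out <- purrr::imap_dfr(props, function(p, niche) {
    purrr::map_dfr(seq_len(n_fov_per_niche), function(f) {
      tibble::tibble(
        fov_id = sprintf("%s_f%02d", niche, f),
        niche = niche,
        x = stats::runif(n_cells, 0, fov_size),
        y = stats::runif(n_cells, 0, fov_size),
        phenotype = sample(names(p), n_cells, replace = TRUE, prob = p)
      )
    })
  })
  out$cell_id <- sprintf("tn%05d", seq_len(nrow(out)))
  out
}
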