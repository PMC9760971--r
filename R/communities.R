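#' Per-cell k-nearest-neighbor composition vectors
#'
#' Each cell's community is summarized by the phenotype composition of
#' its k nearest neighbors (Euclidean distance on pixel centroids,
#' excluding the cell itself). Neighbor search never crosses FOV
#' boundaries: FOVs are non-contiguous tissue samples. FOVs with at most
#' `k` cells are skipped with a warning. Distance ties at the k-th
#' neighbor are broken toward the lowest `cell_id` for determinism.
#'
#' @param cells a classified cell table (no `UNASSIGNED` phenotypes).
#' @param k number of neighbors (default 75).
#' @return tibble with `cell_id`, `fov_id` and one fraction column per
#'   phenotype in [phenotype_levels()]; rows sum to 1. The neighbor count
#'   is attached as attribute `"k"`.
#' @export
knn_composition <- function(cells, k = 75) {
  if (k <= 0) stop("k must be positive", call. = FALSE)
  if (any(cells$phenotype == UNASSIGNED)) {
    stop("cells with UNASSIGNED phenotype: classify before computing ",
         "compositions", call. = FALSE)
  }
  levels_ <- phenotype_levels()
  per_fov <- split(seq_len(nrow(cells)), cells$fov_id)
  small <- names(per_fov)[lengths(per_fov) <= k]
  if (length(small) > 0) {
    warning("skipping ", length(small), " FOV(s) with <= k cells: ",
            paste(utils::head(small, 5), collapse = ", "), call. = FALSE)
    per_fov <- per_fov[lengths(per_fov) > k]
  }
  out <- lapply(per_fov, function(rows) {
    fov <- cells[rows, ]
    ord <- order(fov$cell_id)
    fov <- fov[ord, ]
    nb <- cpp_knn_indices(fov$x, fov$y, as.integer(k))
    codes <- match(fov$phenotype, levels_)
    nb_codes <- matrix(codes[nb], nrow = nrow(nb))
    frac <- vapply(seq_along(levels_), function(ci) {
      rowSums(nb_codes == ci) / k
    }, numeric(nrow(nb)))
    if (nrow(nb) == 1) frac <- matrix(frac, nrow = 1)
    colnames(frac) <- levels_
    dplyr::bind_cols(
      tibble::tibble(cell_id = fov$cell_id, fov_id = fov$fov_id),
      tibble::as_tibble(frac)
    )
  })
  res <- dplyr::bind_rows(out)
  attr(res, "k") <- as.integer(k)
  res
}

#' Cluster composition vectors into cellular communities
#'
#' Mini-batch k-means (k-means++ seeding, batch size 1024, at most 100
#' iterations by default) over the pooled composition vectors of the
#' whole cohort, following the regional macro-architecture analysis. The
#' default of 11 clusters follows the reported community structure; the
#' alternative of classes + 1 = 10 is a single argument away.
#'
#' @param vectors output of [knn_composition()].
#' @param c number of community clusters (default 11).
#' @param seed integer seed; results are deterministic given it.
#' @param batch_size,max_iter mini-batch parameters.
#' @return a `community_model`: assignments (`cell_id`, `cluster`,
#'   1-based), centroids, per-cluster mean composition profiles
#'   (`cluster_profiles`, rows summing to 1), inertia, and (after
#'   [label_communities()]) per-cluster enrichment labels.
#' @export
fit_communities <- function(vectors, c = 11, seed = 1L,
                            batch_size = 1024, max_iter = 100) {
  levels_ <- phenotype_levels()
  X <- as.matrix(vectors[, levels_])
  if (c > nrow(X)) {
    stop("c (", c, ") exceeds the number of composition vectors (",
         nrow(X), ")", call. = FALSE)
  }
  if (c <= 0) stop("c must be positive", call. = FALSE)
  km <- minibatch_kmeans(X, c = c, seed = seed, batch_size = batch_size,
                         max_iter = max_iter)
  profiles <- matrix(NA_real_, nrow = c, ncol = ncol(X),
                     dimnames = list(NULL, levels_))
  for (j in seq_len(c)) {
    rows <- km$assignment == j
    profiles[j, ] <- if (any(rows)) colMeans(X[rows, , drop = FALSE]) else
      km$centers[j, ] / sum(km$centers[j, ])
  }
  structure(
    list(
      c = c, k = attr(vectors, "k"),
      centroids = km$centers,
      assignments = tibble::tibble(cell_id = vectors$cell_id,
                                   cluster = km$assignment),
      cluster_profiles = profiles,
      cluster_sizes = tabulate(km$assignment, nbins = c),
      cluster_labels = NULL,
      inertia = km$inertia,
      seed = as.integer(seed)
    ),
    class = "community_model"
  )
}

# Mini-batch k-means with k-means++ seeding. Per-cluster learning rates
# 1/count, as in the standard mini-batch formulation; a final full pass
# assigns every point to its nearest centre and computes the inertia.
minibatch_kmeans <- function(X, c, seed, batch_size = 1024, max_iter = 100,
                             tol = 1e-7) {
  set.seed(as.integer(seed))
  n <- nrow(X)
  centers <- kmeanspp_init(X, c)
  counts <- rep(0, c)
  for (it in seq_len(max_iter)) {
    idx <- if (n <= batch_size) seq_len(n) else sample.int(n, batch_size)
    B <- X[idx, , drop = FALSE]
    a <- nearest_center(B, centers)
    old <- centers
    for (j in unique(a)) {
      pts <- B[a == j, , drop = FALSE]
      counts[j] <- counts[j] + nrow(pts)
      eta <- nrow(pts) / counts[j]
      centers[j, ] <- (1 - eta) * centers[j, ] + eta * colMeans(pts)
    }
    if (max(abs(centers - old)) < tol) break
  }
  assignment <- nearest_center(X, centers)
  inertia <- sum((X - centers[assignment, , drop = FALSE])^2)
  list(centers = centers, assignment = assignment, inertia = inertia)
}

# k-means++ seeding: first centre uniform, subsequent centres sampled
# with probability proportional to squared distance to the nearest
# already-chosen centre.
kmeanspp_init <- function(X, c) {
  n <- nrow(X)
  centers <- matrix(NA_real_, nrow = c, ncol = ncol(X))
  centers[1, ] <- X[sample.int(n, 1), ]
  if (c == 1) return(centers)
  d2 <- rowSums((X - matrix(centers[1, ], n, ncol(X), byrow = TRUE))^2)
  for (j in 2:c) {
    pick <- if (sum(d2) <= 0) sample.int(n, 1) else sample.int(n, 1, prob = d2)
    centers[j, ] <- X[pick, ]
    dj <- rowSums((X - matrix(centers[j, ], n, ncol(X), byrow = TRUE))^2)
    d2 <- pmin(d2, dj)
  }
  centers
}

nearest_center <- function(X, centers) {
  d2 <- outer(rowSums(X^2), rowSums(centers^2), "+") - 2 * X %*% t(centers)
  max.col(-d2, ties.method = "first")
}

#' Label community clusters by their enriched classes
#'
#' A cluster's label is the set of phenotype classes whose mean profile
#' fraction strictly exceeds `threshold` (default 10%), ordered by
#' decreasing fraction — e.g. a cluster with 59% tumor and 26% dendritic
#' cells is labelled Tumor+Dendritic.
#'
#' @param model a `community_model`.
#' @param threshold enrichment threshold on the profile fraction.
#' @return the model with `cluster_labels` filled (list of character
#'   vectors, one per cluster).
#' @export
label_communities <- function(model, threshold = 0.10) {
  stopifnot(inherits(model, "community_model"))
  model$cluster_labels <- lapply(seq_len(model$c), function(j) {
    p <- model$cluster_profiles[j, ]
    enriched <- p[p > threshold]
    names(enriched)[order(enriched, decreasing = TRUE)]
  })
  model$label_threshold <- threshold
  model
}

#' Per-patient community cluster frequencies
#'
#' @param model a fitted `community_model`.
#' @param cells the cell table the model was fitted on (for the
#'   `patient_id` of each cell).
#' @return wide tibble, one row per patient: `patient_id`, `outcome` (if
#'   present) and columns `cluster_1` ... `cluster_c` of fractions
#'   summing to 1 per row. Patients with zero assigned cells are dropped
#'   with a warning.
#' @export
community_frequencies <- function(model, cells) {
  long <- community_feature_counts(model, cells)
  wide <- tidyr::pivot_wider(
    dplyr::mutate(long, fraction = .data$events / .data$total,
                  feature = paste0("cluster_", .data$feature)),
    id_cols = dplyr::any_of(c("patient_id", "outcome")),
    names_from = "feature", values_from = "fraction", values_fill = 0
  )
  wide[, c(intersect(c("patient_id", "outcome"), names(wide)),
           paste0("cluster_", seq_len(model$c)))]
}

#' Per-patient community event counts for cohort comparison
#'
#' Long form of [community_frequencies()]: for each patient and cluster,
#' the number of that patient's cells assigned to the cluster (`events`)
#' and the patient's total assigned cells (`total`), ready for
#' [compare_groups()].
#'
#' @inheritParams community_frequencies
#' @return tibble: `patient_id`, (`outcome`,) `feature` (cluster index as
#'   character), `events`, `total`.
#' @export
community_feature_counts <- function(model, cells) {
  stopifnot(inherits(model, "community_model"))
  joined <- dplyr::inner_join(
    model$assignments,
    cells[, intersect(c("cell_id", "patient_id", "outcome"), names(cells))],
    by = "cell_id"
  )
  dropped <- setdiff(unique(cells$patient_id), unique(joined$patient_id))
  if (length(dropped) > 0) {
    warning("patient(s) with zero assigned cells excluded: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  grid <- tidyr::expand_grid(
    patient_id = unique(joined$patient_id),
    feature = as.character(seq_len(model$c))
  )
  counts <- dplyr::count(joined, .data$patient_id,
                         feature = as.character(.data$cluster), name = "events")
  out <- dplyr::left_join(grid, counts, by = c("patient_id", "feature"))
  out$events[is.na(out$events)] <- 0L
  totals <- dplyr::count(joined, .data$patient_id, name = "total")
  out <- dplyr::left_join(out, totals, by = "patient_id")
  if ("outcome" %in% names(joined)) {
    out <- dplyr::left_join(
      out, dplyr::distinct(joined, .data$patient_id, .data$outcome),
      by = "patient_id"
    )
  }
  out
}

#' Sweep community parameters
#'
#' Fits one community model per (k, c) grid point and reports the final
#' inertia and the entropy of the cluster-size distribution, supporting
#' manual parameter choice.
#'
#' @param cells a classified cell table.
#' @param k_grid,c_grid integer vectors of neighbor counts and cluster
#'   numbers.
#' @param seed integer seed (shared across grid points).
#' @return tibble with one row per (k, c): `k`, `c`, `inertia`,
#'   `size_entropy` (nats).
#' @export
sweep_parameters <- function(cells, k_grid = c(5, 25, 50, 75, 100),
                             c_grid = 10:11, seed = 1L) {
  stopifnot(length(k_grid) > 0, length(c_grid) > 0)
  purrr::map_dfr(k_grid, function(k) {
    vectors <- knn_composition(cells, k = k)
    purrr::map_dfr(c_grid, function(cc) {
      m <- fit_communities(vectors, c = cc, seed = seed)
      p <- m$cluster_sizes / sum(m$cluster_sizes)
      p <- p[p > 0]
      tibble::tibble(k = k, c = cc, inertia = m$inertia,
                     size_entropy = -sum(p * log(p)))
    })
  })
}

#' @export
print.community_model <- function(x, ...) {
  cat("Cellular community model: c =", x$c, "clusters over",
      nrow(x$assignments), "cells (k =", x$k, "neighbors)\n")
  cat("  inertia:", format(x$inertia, digits = 6), "| seed:", x$seed, "\n")
  if (!is.null(x$cluster_labels)) {
    for (j in seq_len(x$c)) {
      cat(sprintf("  cluster %2d (n=%d): %s\n", j, x$cluster_sizes[j],
                  paste(x$cluster_labels[[j]], collapse = "+")))
    }
  }
  invisible(x)
}

#' Tidy a community model
#'
#' `tidy()` returns one row per (cluster, phenotype) with the profile
#' fraction; `glance()` a one-row model summary.
#'
#' @param x a `community_model`.
#' @param ... unused.
#' @export
tidy.community_model <- function(x, ...) {
  prof <- tibble::as_tibble(x$cluster_profiles)
  prof$cluster <- seq_len(x$c)
  prof$size <- x$cluster_sizes
  out <- tidyr::pivot_longer(prof, -c("cluster", "size"),
                             names_to = "phenotype", values_to = "fraction")
  if (!is.null(x$cluster_labels)) {
    lab <- vapply(x$cluster_labels, paste, character(1), collapse = "+")
    out$label <- lab[out$cluster]
  }
  out
}

#' @rdname tidy.community_model
#' @export
glance.community_model <- function(x, ...) {
  tibble::tibble(c = x$c, k = x$k, n_cells = nrow(x$assignments),
                 inertia = x$inertia, seed = x$seed)
}
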