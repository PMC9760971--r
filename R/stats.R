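#' Pearson chi-squared test on a contingency table
#'
#' Pearson statistic `sum((O - E)^2 / E)` with expected counts from the
#' row/column margins, no continuity correction, and the p-value from the
#' chi-squared distribution with `(rows - 1) * (cols - 1)` degrees of
#' freedom.
#'
#' @param contingency numeric matrix of nonnegative counts, at least two
#'   nonzero rows and columns.
#' @return one-row tibble: `statistic`, `df`, `p_value`.
#' @export
chi_squared_test <- function(contingency) {
  contingency <- as.matrix(contingency)
  if (any(contingency < 0) || anyNA(contingency)) {
    stop("contingency counts must be nonnegative", call. = FALSE)
  }
  if (any(rowSums(contingency) == 0) || any(colSums(contingency) == 0)) {
    stop("degenerate table: zero row or column margin", call. = FALSE)
  }
  if (nrow(contingency) < 2 || ncol(contingency) < 2) {
    stop("contingency table must be at least 2 x 2", call. = FALSE)
  }
  res <- suppressWarnings(stats::chisq.test(contingency, correct = FALSE))
  tibble::tibble(statistic = unname(res$statistic),
                 df = unname(res$parameter),
                 p_value = unname(res$p.value))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values controlling the false discovery rate;
#' monotone in rank and clipped at 1.
#'
#' @param p numeric vector of raw p-values in `[0, 1]`.
#' @param method adjustment method (only `"BH"`).
#' @return numeric vector of adjusted p-values, elementwise `>= p`.
#' @export
adjust_pvalues <- function(p, method = "BH") {
  method <- match.arg(method)
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = method)
}

#' Compare per-patient features between outcome groups
#'
#' Patients are the independent sampling units, so every test is
#' performed on a per-patient basis: for each feature, the per-patient
#' event fraction (`events / total`) is dichotomized at the cohort
#' median and the resulting 2 x 2 table (outcome group x above/at-or-
#' below median) is tested with the Pearson chi-squared statistic, no
#' continuity correction — a nonparametric (Mood's median) chi-squared
#' comparison, robust to the unequal group sizes. p-values are
#' Benjamini-Hochberg adjusted across the feature family and flagged
#' significant at `p_adj < alpha`.
#'
#' Neighborhood-level events within a patient are spatially correlated
#' (neighborhood discs overlap), so a chi-squared test on counts pooled
#' over patients is anticonservative; the per-patient construction keeps
#' the nominal type-I level. The pooled per-group event fractions are
#' still reported (`frac_<group>` columns; `count_basis` names what the
#' events are) and a patient-level Wilcoxon rank-sum p-value (`p_rank`)
#' is included as a sensitivity check.
#'
#' @param features tibble with columns `patient_id`, `feature`, `events`,
#'   `total` (e.g. from [neighborhood_composition_by_patient()],
#'   [community_feature_counts()], [pairing_feature_counts()] or
#'   [pd1_neighbor_frequencies()]).
#' @param patients patient table supplying `outcome` per `patient_id`.
#' @param alpha significance level on the adjusted p-value.
#' @param count_basis label recorded in the output describing the event
#'   unit (`"neighborhoods"` or `"cells"`).
#' @return tibble, one row per feature: pooled per-group event fractions,
#'   `statistic`, `df`, `p_value`, `p_adj`, `direction` (group with the
#'   higher pooled event frequency), `p_rank`, `significant`,
#'   `count_basis`.
#' @export
compare_groups <- function(features, patients, alpha = 0.05,
                           count_basis = c("neighborhoods", "cells")) {
  count_basis <- match.arg(count_basis)
  required <- c("patient_id", "feature", "events", "total")
  missing <- setdiff(required, names(features))
  if (length(missing) > 0) {
    stop("features lack column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df <- dplyr::left_join(
    features[, required],
    patients[, c("patient_id", "outcome")],
    by = "patient_id"
  )
  if (anyNA(df$outcome)) {
    stop("patient(s) missing from the patient table: ",
         paste(unique(df$patient_id[is.na(df$outcome)]), collapse = ", "),
         call. = FALSE)
  }
  groups <- sort(unique(patients$outcome))
  if (length(groups) != 2) {
    stop("cohort comparison needs exactly two outcome groups, got ",
         length(groups), call. = FALSE)
  }
  if (!all(groups %in% df$outcome)) {
    stop("outcome group without any patients in the feature table",
         call. = FALSE)
  }
  out <- purrr::map_dfr(split(df, df$feature), function(fd) {
    frac <- fd$events / fd$total
    grp <- factor(fd$outcome, levels = groups)
    med <- stats::median(frac)
    above <- factor(frac > med, levels = c(FALSE, TRUE))
    tab <- table(grp, above)
    res <- if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      # all patients on one side of the median: no evidence of a shift
      tibble::tibble(statistic = 0, df = 1, p_value = 1)
    } else {
      chi_squared_test(tab)
    }
    pooled_frac <- vapply(groups, function(g) {
      sum(fd$events[fd$outcome == g]) / sum(fd$total[fd$outcome == g])
    }, numeric(1))
    ranks <- tryCatch(
      stats::wilcox.test(frac[fd$outcome == groups[1]],
                         frac[fd$outcome == groups[2]],
                         exact = FALSE)$p.value,
      error = function(e) NA_real_
    )
    tibble::tibble(
      feature = fd$feature[1],
      !!paste0("frac_", groups[1]) := pooled_frac[1],
      !!paste0("frac_", groups[2]) := pooled_frac[2],
      statistic = res$statistic, df = res$df, p_value = res$p_value,
      direction = dplyr::case_when(pooled_frac[1] > pooled_frac[2] ~ groups[1],
                                   pooled_frac[2] > pooled_frac[1] ~ groups[2],
                                   TRUE ~ NA_character_),
      p_rank = ranks
    )
  })
  out$p_adj <- adjust_pvalues(out$p_value)
  out$significant <- out$p_adj < alpha
  out$count_basis <- count_basis
  out[order(out$p_adj, out$p_value), ]
}
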