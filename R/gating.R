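#' Gate a functional marker at a fixed false-positive rate
#'
#' Binary positive/negative calling for a functional marker (e.g. PD1)
#' whose positives are a minority subpopulation. The procedure is, in
#' order:
#' \enumerate{
#'   \item arcsinh-transform the marker's per-cell mean and standard
#'     deviation quantifications (cofactor 1), compressing the 16-bit
#'     intensity range;
#'   \item per biospecimen, locate the peak (mode) of the transformed
#'     mean distribution with a Freedman-Diaconis histogram and shift it
#'     to zero, removing specimen-level batch shifts;
#'   \item standardize the pooled shifted means, and the pooled
#'     transformed sds, to zero mean and unit variance;
#'   \item choose the least-restrictive pair of thresholds (one per axis)
#'     such that the fraction of annotated negative cells exceeding BOTH
#'     thresholds is at most `target_fpr`, ties broken toward the lower
#'     mean threshold;
#'   \item call a cell positive iff its standardized mean AND
#'     standardized sd exceed their thresholds.
#' }
#' Since the positive call depends on the specimen-shifted values only,
#' the gate is invariant to per-specimen location shifts of the
#' transformed distribution.
#'
#' @param cells cell table with `<marker>_mean`, `<marker>_sd` and a
#'   `specimen_id` column.
#' @param marker marker name, e.g. `"PD1"`.
#' @param annotations tibble of annotated cells containing `cell_id` and
#'   a logical `<marker>_pos` column; cells with `FALSE` are the known
#'   negatives used for calibration.
#' @param target_fpr calibration false-positive rate in (0, 1).
#' @return list with `model` (a `gate_model`) and `cells` (`cells` with a
#'   logical `<marker>_pos` column appended).
#' @seealso [apply_gate()], [write_gate_model()]
#' @export
gate_functional_marker <- function(cells, marker, annotations,
                                   target_fpr = 0.01) {
  stopifnot(target_fpr > 0, target_fpr < 1)
  mcol <- paste0(marker, "_mean"); scol <- paste0(marker, "_sd")
  pcol <- paste0(marker, "_pos")
  for (col in c(mcol, scol)) {
    if (!col %in% names(cells)) {
      stop("cells lack marker column ", col, call. = FALSE)
    }
  }
  if (!"specimen_id" %in% names(cells)) {
    stop("cells lack a specimen_id column (join patient metadata first)",
         call. = FALSE)
  }
  if (!pcol %in% names(annotations)) {
    stop("annotations lack a ", pcol, " column", call. = FALSE)
  }
  neg_ids <- annotations$cell_id[!annotations[[pcol]]]
  if (length(neg_ids) == 0) {
    stop("calibration requires annotated negative cells for ", marker,
         call. = FALSE)
  }

  t_mean <- asinh(cells[[mcol]])
  t_sd <- asinh(cells[[scol]])
  if (stats::sd(t_mean) == 0 || stats::sd(t_sd) == 0) {
    stop("degenerate distribution: ", marker,
         " quantification is constant", call. = FALSE)
  }

  specimens <- sort(unique(cells$specimen_id))
  shifts <- vapply(specimens, function(s) {
    histogram_mode(t_mean[cells$specimen_id == s])
  }, numeric(1))
  names(shifts) <- specimens
  shifted <- t_mean - unname(shifts[cells$specimen_id])

  center_mean <- mean(shifted); scale_mean <- stats::sd(shifted)
  center_sd <- mean(t_sd); scale_sd <- stats::sd(t_sd)
  z_mean <- (shifted - center_mean) / scale_mean
  z_sd <- (t_sd - center_sd) / scale_sd

  neg_rows <- match(neg_ids, cells$cell_id)
  if (anyNA(neg_rows)) {
    stop("annotated negatives not found in the cell table", call. = FALSE)
  }
  thr <- search_dual_threshold(z_mean[neg_rows], z_sd[neg_rows], target_fpr)

  model <- structure(
    list(marker = marker, peak_shift_per_specimen = shifts,
         center_mean = center_mean, scale_mean = scale_mean,
         center_sd = center_sd, scale_sd = scale_sd,
         mean_threshold = thr$t_mean, sd_threshold = thr$t_sd,
         target_fpr = target_fpr, achieved_fpr = thr$fpr,
         n_negatives = length(neg_ids)),
    class = "gate_model"
  )
  out <- cells
  out[[pcol]] <- z_mean > thr$t_mean & z_sd > thr$t_sd
  list(model = model, cells = out)
}

# Histogram mode with Freedman-Diaconis bin widths; returns the midpoint
# of the fullest bin (first one on ties).
histogram_mode <- function(v) {
  v <- v[is.finite(v)]
  if (length(v) == 0) stop("no finite values for mode estimation", call. = FALSE)
  if (length(unique(v)) == 1) return(v[1])
  h <- 2 * stats::IQR(v) * length(v)^(-1 / 3)
  if (h <= 0) return(stats::median(v))
  breaks <- seq(min(v), max(v) + h, by = h)
  counts <- tabulate(findInterval(v, breaks, rightmost.closed = TRUE),
                     nbins = length(breaks) - 1)
  i <- which.max(counts)
  (breaks[i] + breaks[i + 1]) / 2
}

# Joint grid search over empirical quantiles of the annotated negatives.
# Feasible pairs keep the joint exceedance (both axes strictly above the
# thresholds) at or below target_fpr; among those, pick the pair with the
# largest achieved FPR (least restrictive), then the lowest mean
# threshold, then the lowest sd threshold.
search_dual_threshold <- function(neg_mean, neg_sd, target_fpr) {
  probs <- seq(0, 1, by = 0.0025)
  c1 <- sort(unique(stats::quantile(neg_mean, probs, names = FALSE)))
  c2 <- sort(unique(stats::quantile(neg_sd, probs, names = FALSE)))
  n <- length(neg_mean)
  best <- list(fpr = -1, t_mean = Inf, t_sd = Inf)
  for (t1 in c1) {
    sel <- neg_mean > t1
    if (!any(sel)) {
      exceed <- rep(0L, length(c2))
    } else {
      # for each t2: count of negatives above both thresholds
      vs <- neg_sd[sel]
      below <- findInterval(c2, sort(vs))      # vs <= t2 counts
      exceed <- length(vs) - below
    }
    fpr <- exceed / n
    ok <- which(fpr <= target_fpr)
    if (length(ok) == 0) next
    j <- ok[which.max(fpr[ok])]
    cand <- list(fpr = fpr[j], t_mean = t1, t_sd = c2[j])
    if (cand$fpr > best$fpr ||
        (cand$fpr == best$fpr && (cand$t_mean < best$t_mean ||
          (cand$t_mean == best$t_mean && cand$t_sd < best$t_sd)))) {
      best <- cand
    }
  }
  if (best$fpr < 0) {
    # fall back to the strictest corner (always feasible: FPR 0)
    best <- list(fpr = 0, t_mean = max(neg_mean), t_sd = max(neg_sd))
  }
  best
}

#' Apply a fitted gate to a cell table
#'
#' Uses the stored per-specimen shifts and pooled standardization, so the
#' gate must have seen every specimen present in `cells`.
#'
#' @param model a `gate_model` from [gate_functional_marker()].
#' @param cells a cell table with the marker columns and `specimen_id`.
#' @return `cells` with the logical `<marker>_pos` column appended.
#' @export
apply_gate <- function(model, cells) {
  stopifnot(inherits(model, "gate_model"))
  mcol <- paste0(model$marker, "_mean"); scol <- paste0(model$marker, "_sd")
  unseen <- setdiff(unique(cells$specimen_id),
                    names(model$peak_shift_per_specimen))
  if (length(unseen) > 0) {
    stop("gate was not calibrated for specimen(s): ",
         paste(unseen, collapse = ", "), call. = FALSE)
  }
  z_mean <- (asinh(cells[[mcol]]) -
               unname(model$peak_shift_per_specimen[cells$specimen_id]) -
               model$center_mean) / model$scale_mean
  z_sd <- (asinh(cells[[scol]]) - model$center_sd) / model$scale_sd
  out <- cells
  out[[paste0(model$marker, "_pos")]] <-
    z_mean > model$mean_threshold & z_sd > model$sd_threshold
  out
}

#' @export
print.gate_model <- function(x, ...) {
  cat("Fixed-FPR gate for", x$marker, "\n")
  cat(sprintf("  thresholds (standardized): mean > %.3f AND sd > %.3f\n",
              x$mean_threshold, x$sd_threshold))
  cat(sprintf("  target FPR %.4f, achieved %.4f on %d annotated negatives\n",
              x$target_fpr, x$achieved_fpr, x$n_negatives))
  cat("  specimens calibrated:", length(x$peak_shift_per_specimen), "\n")
  invisible(x)
}

#' @rdname tidy.tier_model
#' @export
glance.gate_model <- function(x, ...) {
  tibble::tibble(
    marker = x$marker, mean_threshold = x$mean_threshold,
    sd_threshold = x$sd_threshold, target_fpr = x$target_fpr,
    achieved_fpr = x$achieved_fpr, n_negatives = x$n_negatives,
    n_specimens = length(x$peak_shift_per_specimen)
  )
}

#' Serialize and restore a gate model as JSON
#'
#' The JSON schema holds the marker name, per-specimen peak shifts,
#' pooled standardization constants, both thresholds and the target FPR,
#' so a gate can be audited and re-applied without refitting.
#'
#' @param model a `gate_model`.
#' @param path file path.
#' @return `write_gate_model()` returns `path` invisibly;
#'   `read_gate_model()` returns the restored `gate_model`.
#' @export
write_gate_model <- function(model, path) {
  stopifnot(inherits(model, "gate_model"))
  obj <- unclass(model)
  obj$peak_shift_per_specimen <- as.list(obj$peak_shift_per_specimen)
  jsonlite::write_json(c(list(type = "gate_model"), obj), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_gate_model
#' @export
read_gate_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  stopifnot(identical(obj$type, "gate_model"))
  obj$type <- NULL
  obj$peak_shift_per_specimen <- unlist(obj$peak_shift_per_specimen)
  structure(obj, class = "gate_model")
}
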