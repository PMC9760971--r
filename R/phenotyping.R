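#' Fit the hierarchical two-tier phenotype classifier
#'
#' Tier 1 is a gradient-boosted tree ensemble (500 trees, depth 4,
#' learning rate 0.25 by default) predicting the broad classes Tumor /
#' Stroma / Immune from marker features. Tier 2 is a support-vector
#' machine refining cells the first tier calls Immune into the nine
#' immune classes; it is never applied to tumor or stromal calls.
#' Annotations are split into training and held-out test fractions
#' (default 2/3 : 1/3), stratified by class, and train/test accuracy is
#' reported per tier.
#'
#' @param annotations tibble of annotated cells: marker feature columns
#'   plus a `label` column with fine phenotype labels (see
#'   [generate_annotation_subset()]).
#' @param split_fraction training fraction of the annotations.
#' @param seed integer seed controlling the split and tree fitting.
#' @param features character vector of feature column names; default all
#'   `<marker>_mean` columns.
#' @param nrounds,max_depth,eta tier-1 boosting hyperparameters.
#' @param svm_cost tier-2 SVM cost parameter.
#' @return a `tier_model` object; its `accuracy` element (also via
#'   [generics::tidy()]) is a tibble with one row per tier giving train
#'   and test accuracy.
#' @export
fit_hierarchical_classifier <- function(annotations, split_fraction = 2 / 3,
                                        seed = 1L, features = NULL,
                                        nrounds = 500, max_depth = 4,
                                        eta = 0.25, svm_cost = 1) {
  if (is.null(features)) {
    features <- grep("_mean$", names(annotations), value = TRUE)
  }
  missing <- setdiff(features, names(annotations))
  if (length(missing) > 0) {
    stop("annotations lack feature column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!"label" %in% names(annotations)) {
    stop("annotations must carry a 'label' column", call. = FALSE)
  }
  counts <- table(annotations$label)
  if (any(counts < 2)) {
    stop("cannot stratify: class(es) with a single annotated example: ",
         paste(names(counts)[counts < 2], collapse = ", "), call. = FALSE)
  }

  set.seed(as.integer(seed))
  lab_fine <- annotations$label
  lab_broad <- broad_class_of(lab_fine)
  in_train <- stratified_split(lab_fine, split_fraction)
  X <- as.matrix(annotations[, features])

  tier1 <- fit_multiclass_gbm(X[in_train, , drop = FALSE], lab_broad[in_train],
                              nrounds = nrounds, max_depth = max_depth,
                              eta = eta, seed = seed)
  acc1 <- c(
    train = mean(predict_multiclass_gbm(tier1, X[in_train, , drop = FALSE]) ==
                   lab_broad[in_train]),
    test = mean(predict_multiclass_gbm(tier1, X[!in_train, , drop = FALSE]) ==
                  lab_broad[!in_train])
  )

  imm <- lab_broad == "Immune"
  tier2 <- NULL
  acc2 <- c(train = NA_real_, test = NA_real_)
  if (any(imm & in_train)) {
    y2 <- factor(lab_fine[imm], levels = immune_levels())
    y2 <- droplevels(y2)
    tr2 <- in_train[imm]
    if (nlevels(y2) >= 2) {
      tier2 <- e1071::svm(x = X[imm, , drop = FALSE][tr2, , drop = FALSE],
                          y = y2[tr2], kernel = "radial", cost = svm_cost,
                          scale = TRUE)
    }
    pred_tr <- predict_tier2(tier2, X[imm, , drop = FALSE][tr2, , drop = FALSE],
                             fallback = levels(y2)[1])
    acc2["train"] <- mean(pred_tr == as.character(y2[tr2]))
    if (any(!tr2)) {
      pred_te <- predict_tier2(tier2, X[imm, , drop = FALSE][!tr2, , drop = FALSE],
                               fallback = levels(y2)[1])
      acc2["test"] <- mean(pred_te == as.character(y2[!tr2]))
    }
  }

  accuracy <- tibble::tibble(
    tier = c("tier1_broad", "tier2_immune"),
    train_accuracy = c(acc1[["train"]], acc2[["train"]]),
    test_accuracy = c(acc1[["test"]], acc2[["test"]]),
    n_train = c(sum(in_train), sum(imm & in_train)),
    n_test = c(sum(!in_train), sum(imm & !in_train))
  )
  structure(
    list(tier1 = tier1, tier2 = tier2,
         tier2_fallback = if (any(imm)) names(sort(table(lab_fine[imm]),
                                                   decreasing = TRUE))[1]
              else "UnclassifiedImmune",
         features = features, split_fraction = split_fraction,
         seed = as.integer(seed), accuracy = accuracy),
    class = "tier_model"
  )
}

# Stratified train indicator: within each class, the first ceiling(f * n)
# of a random permutation go to training, so every class is represented.
stratified_split <- function(labels, fraction) {
  in_train <- logical(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    n_tr <- max(1L, min(length(idx) - 1L, ceiling(fraction * length(idx))))
    in_train[sample(idx)[seq_len(n_tr)]] <- TRUE
  }
  in_train
}

fit_multiclass_gbm <- function(X, labels, nrounds, max_depth, eta, seed) {
  classes <- sort(unique(labels))
  if (length(classes) == 1) {
    return(structure(list(constant = classes), class = "constant_gbm"))
  }
  y <- match(labels, classes) - 1L
  dtr <- xgboost::xgb.DMatrix(X, label = y)
  booster <- xgboost::xgb.train(
    params = list(objective = "multi:softprob", num_class = length(classes),
                  max_depth = max_depth, eta = eta, nthread = 1,
                  seed = as.integer(seed)),
    data = dtr, nrounds = nrounds, verbose = 0
  )
  list(booster = booster, classes = classes)
}

predict_multiclass_gbm <- function(model, X) {
  if (inherits(model, "constant_gbm")) return(rep(model$constant, nrow(X)))
  if (nrow(X) == 0) return(character(0))
  p <- predict(model$booster, xgboost::xgb.DMatrix(X))
  if (!is.matrix(p)) p <- matrix(p, ncol = length(model$classes), byrow = TRUE)
  model$classes[max.col(p, ties.method = "first")]
}

predict_tier2 <- function(tier2, X, fallback) {
  if (nrow(X) == 0) return(character(0))
  if (is.null(tier2)) return(rep(fallback, nrow(X)))
  as.character(predict(tier2, X))
}

#' Classify cells with a fitted tier model
#'
#' Applies tier 1 to every cell; cells called Immune are refined by
#' tier 2. Every cell receives exactly one fine phenotype and the
#' hierarchy is consistent by construction: a fine immune label implies a
#' tier-1 Immune call.
#'
#' @param model a `tier_model` from [fit_hierarchical_classifier()].
#' @param cells a cell table carrying all of `model$features`.
#' @return `cells` with its `phenotype` column replaced by predicted
#'   labels and a `broad_class` column with the tier-1 calls.
#' @export
classify_cells <- function(model, cells) {
  stopifnot(inherits(model, "tier_model"))
  missing <- setdiff(model$features, names(cells))
  if (length(missing) > 0) {
    stop("cells lack feature column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- cells
  if (nrow(cells) == 0) {
    out$broad_class <- character(0)
    out$phenotype <- character(0)
    return(out)
  }
  X <- as.matrix(cells[, model$features])
  broad <- predict_multiclass_gbm(model$tier1, X)
  fine <- broad
  imm <- broad == "Immune"
  if (any(imm)) {
    fine[imm] <- predict_tier2(model$tier2, X[imm, , drop = FALSE],
                               fallback = model$tier2_fallback)
  }
  out$broad_class <- broad
  out$phenotype <- fine
  out
}

#' @export
print.tier_model <- function(x, ...) {
  cat("Hierarchical phenotype classifier\n")
  cat("  features:", length(x$features), "| split:",
      format(x$split_fraction, digits = 3), "| seed:", x$seed, "\n")
  print(x$accuracy)
  invisible(x)
}

#' Tidy a fitted tier model
#'
#' @param x a `tier_model`.
#' @param ... unused.
#' @return the per-tier accuracy tibble (`tidy`) or a one-row model
#'   summary (`glance`).
#' @export
tidy.tier_model <- function(x, ...) x$accuracy

#' @rdname tidy.tier_model
#' @export
glance.tier_model <- function(x, ...) {
  tibble::tibble(
    n_features = length(x$features),
    split_fraction = x$split_fraction,
    tier1_test_accuracy = x$accuracy$test_accuracy[1],
    tier2_test_accuracy = x$accuracy$test_accuracy[2],
    seed = x$seed
  )
}

#' Serialize tier-model metadata to JSON
#'
#' Writes the audit metadata of a fitted tier model (feature list, split
#' fraction, seed, per-tier accuracies) as JSON. The tree/SVM weights are
#' not serialized; refit from the same annotations and seed reproduces
#' them.
#'
#' @param model a `tier_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tier_model <- function(model, path) {
  stopifnot(inherits(model, "tier_model"))
  jsonlite::write_json(
    list(type = "tier_model", features = model$features,
         split_fraction = model$split_fraction, seed = model$seed,
         accuracy = model$accuracy),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
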