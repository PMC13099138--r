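# Feature-table assembly, leakage-safe grouped partitioning, classifier
# training (gradient-boosted trees; logistic baseline), sequential backward
# selection, hyperparameter tuning, per-complex max-aggregation scoring,
# and ROC / threshold-table evaluation.

#' Assemble a feature table
#'
#' @param data data.frame with `complex_id`, `model_rank`, `label` and the
#'   manifest feature columns (order is enforced).
#' @param version manifest version tag.
#' @return a [FeatureTable-class].
#' @export
FeatureTable <- function(data, version = "v1") {
  feats <- featureNames(version)
  miss <- setdiff(feats, names(data))
  if (length(miss))
    .err("ppiDataError", "feature table missing manifest column(s): %s",
         paste(utils::head(miss, 5L), collapse = ", "))
  data <- data[, c("complex_id", "model_rank", "label", feats)]
  new("FeatureTable", data = data, manifestVersion = version)
}

#' Extract the full 57-feature vector of one model
#'
#' Computes the interface map and secondary structure, then concatenates
#' the confidence, counting and energy blocks in manifest order.
#'
#' @param model a [ComplexModel-class].
#' @param conf the paired [ConfidenceBundle-class].
#' @param cutoff interface cutoff in Angstrom (default 12).
#' @return named numeric vector of 57 features.
#' @export
extractFeatures <- function(model, conf, cutoff = 12) {
  iface <- findInterface(model, cutoff)
  ss <- assignSecondaryStructure(model)
  v <- c(confidenceFeatureBlock(model, conf, iface),
         countingFeatureBlock(model, iface, ss),
         energyFeatureBlock(model, iface))
  v[featureNames()]
}

#' Grouped train/validation/test split
#'
#' Random complex-level assignment at the stated fractions; all models of
#' one complex share the assignment (leakage guard).
#'
#' @param complexIds character vector of complex ids (>= 5 unique).
#' @param fractions named fractions for train/validation/test, summing
#'   to 1 (default 0.6/0.2/0.2).
#' @param seed integer seed.
#' @return a [SplitAssignment-class].
#' @export
assignSplits <- function(complexIds,
                         fractions = c(train = 0.6, validation = 0.2,
                                       test = 0.2),
                         seed = 42L) {
  ids <- unique(complexIds)
  if (length(ids) < 5L)
    .err("ppiConfigError",
         "need at least 5 complexes to realize a 60/20/20 split (got %d)",
         length(ids))
  if (abs(sum(fractions) - 1) > 1e-9 || any(fractions < 0))
    .err("ppiConfigError", "split fractions must be non-negative and sum to 1")
  stopifnot(identical(names(fractions), c("train", "validation", "test")))
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old))
  set.seed(seed)
  ids <- sample(ids)
  n <- length(ids)
  nTr <- max(1L, round(fractions[["train"]] * n))
  nVa <- max(1L, round(fractions[["validation"]] * n))
  if (nTr + nVa >= n) nTr <- n - nVa - 1L
  split <- c(rep("train", nTr), rep("validation", nVa),
             rep("test", n - nTr - nVa))
  new("SplitAssignment",
      assignment = data.frame(complex_id = ids, split = split,
                              stringsAsFactors = FALSE),
      fractions = fractions, seed = as.integer(seed))
}

.Random.seed.save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed.restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Split lookup
#'
#' @param splits a [SplitAssignment-class].
#' @param which one of train/validation/test.
#' @return character vector of complex ids in that partition.
#' @export
splitComplexes <- function(splits, which) {
  stopifnot(which %in% c("train", "validation", "test"))
  splits@assignment$complex_id[splits@assignment$split == which]
}

#' Filter mis-docked actives out of the training rows
#'
#' Active rows assigned to training whose model DockQ is below the
#' threshold are dropped; decoy rows and all validation/test rows are kept
#' untouched (the test set deliberately retains mis-docked actives).
#'
#' @param table a [FeatureTable-class].
#' @param splits a [SplitAssignment-class] covering the table's complexes.
#' @param dockqByRow numeric vector aligned with the table rows (NA allowed
#'   for decoy rows and non-training rows).
#' @param threshold DockQ acceptability threshold (default 0.23,
#'   inclusive).
#' @return filtered [FeatureTable-class].
#' @export
filterTrainingActives <- function(table, splits, dockqByRow,
                                  threshold = DOCKQ_ACCEPTABLE) {
  d <- featureData(table)
  stopifnot(length(dockqByRow) == nrow(d))
  sp <- stats::setNames(splits@assignment$split,
                        splits@assignment$complex_id)
  rowSplit <- sp[d$complex_id]
  affected <- rowSplit == "train" & d$label == "active"
  if (any(affected & is.na(dockqByRow)))
    .err("ppiDataError",
         "missing DockQ for %d active training row(s)",
         sum(affected & is.na(dockqByRow)))
  keep <- !affected | dockqByRow >= threshold
  FeatureTable(d[keep, , drop = FALSE], manifestVersion(table))
}

# ---- classifier backends ------------------------------------------------

# Feature subsampling (colsample_bytree) is on by default: with strongly
# redundant confidence features a single dominant split otherwise decides
# every tree, and held-out values falling into the training gap between
# class clusters land on an arbitrary side of it.
.defaultXgbParams <- list(max_depth = 4L, n_estimators = 100L,
                          learning_rate = 0.1, gamma = 0, lambda = 1,
                          min_child_weight = 1, colsample_bytree = 0.5)

.fitClassifier <- function(X, y, spec, seed = 42L) {
  if (spec$type == "logistic") {
    df <- as.data.frame(X)
    df$.y <- y
    fit <- suppressWarnings(stats::glm(.y ~ ., data = df,
                                       family = stats::binomial()))
    return(list(type = "logistic", fit = fit))
  }
  p <- utils::modifyList(.defaultXgbParams, spec$params %||% list())
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old))
  set.seed(seed)
  dtrain <- xgboost::xgb.DMatrix(as.matrix(X), label = y)
  xgbParams <- c(list(objective = "binary:logistic",
                      max_depth = as.integer(p$max_depth),
                      eta = p$learning_rate, gamma = p$gamma,
                      lambda = p$lambda,
                      min_child_weight = p$min_child_weight,
                      nthread = 1L),
                 p[setdiff(names(p), c("max_depth", "learning_rate",
                                       "gamma", "lambda",
                                       "min_child_weight",
                                       "n_estimators"))])
  booster <- xgboost::xgb.train(params = xgbParams, data = dtrain,
                                nrounds = as.integer(p$n_estimators),
                                verbose = 0)
  list(type = "xgboost", fit = booster, features = colnames(X))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.predictClassifier <- function(fit, X) {
  if (fit$type == "logistic")
    as.numeric(stats::predict(fit$fit, newdata = as.data.frame(X),
                              type = "response"))
  else
    as.numeric(stats::predict(fit$fit, xgboost::xgb.DMatrix(as.matrix(X))))
}

.featureMatrix <- function(table, features) {
  d <- featureData(table)
  as.matrix(d[, features, drop = FALSE])
}

.labels01 <- function(table) as.integer(featureData(table)$label == "active")

# Stratified complex-level fold assignment with group integrity: within
# each label, complexes are shuffled and dealt round-robin.
.foldAssign <- function(table, folds, seed) {
  d <- featureData(table)
  cx <- unique(d[, c("complex_id", "label")])
  if (anyDuplicated(cx$complex_id))
    .err("ppiDataError", "complex with mixed labels")
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old))
  set.seed(seed)
  fold <- integer(nrow(cx))
  for (lab in unique(cx$label)) {
    i <- which(cx$label == lab)
    i <- i[sample.int(length(i))]
    fold[i] <- rep_len(seq_len(folds), length(i))
  }
  assign <- stats::setNames(fold, cx$complex_id)
  for (f in seq_len(folds)) {
    held <- cx$label[assign[cx$complex_id] == f]
    if (length(unique(held)) < 2L || length(unique(cx$label[assign[cx$complex_id] != f])) < 2L)
      .err("ppiStratificationError",
           "fold %d does not contain both classes at complex level", f)
  }
  assign
}

#' Cross-validated training with grouped, stratified folds
#'
#' Folds are stratified by label at the complex level with group integrity
#' (all models of a complex share a fold). The combined cross-fold AUC is
#' computed on the pooled held-fold predictions.
#'
#' @param table a [FeatureTable-class] (training + validation rows only).
#' @param folds number of folds (default 5).
#' @param features feature subset to use (default: full manifest).
#' @param modelSpec list with `type` ("xgboost" or "logistic") and
#'   `params`.
#' @param seed integer seed.
#' @return list with `models`, `foldOfComplex`, `predictions` (data.frame
#'   of row predictions with fold ids), and `auc`.
#' @export
crossvalTrain <- function(table, folds = 5L, features = featureNames(),
                          modelSpec = list(type = "xgboost"),
                          seed = 42L) {
  d <- featureData(table)
  assign <- .foldAssign(table, folds, seed)
  rowFold <- unname(assign[d$complex_id])
  X <- .featureMatrix(table, features)
  y <- .labels01(table)
  preds <- numeric(nrow(d))
  models <- vector("list", folds)
  for (f in seq_len(folds)) {
    tr <- rowFold != f
    models[[f]] <- .fitClassifier(X[tr, , drop = FALSE], y[tr], modelSpec,
                                  seed = seed + f)
    preds[!tr] <- .predictClassifier(models[[f]], X[!tr, , drop = FALSE])
  }
  list(models = models, foldOfComplex = assign,
       predictions = data.frame(complex_id = d$complex_id,
                                model_rank = d$model_rank,
                                label = d$label, fold = rowFold,
                                score = preds,
                                stringsAsFactors = FALSE),
       auc = rocAuc(preds, y))
}

#' Sequential backward feature selection
#'
#' Iteratively removes the feature whose removal maximizes the combined
#' cross-fold AUC, until the target size is reached (or, when a tolerance
#' is given, until removal would drop the AUC more than `tolerance` below
#' the full-feature AUC).
#'
#' @param table a [FeatureTable-class] (training + validation rows only).
#' @param startFeatures initial feature set (default full manifest).
#' @param targetSize stop when this many features remain (default 7).
#' @param tolerance optional maximum allowed AUC drop from the full model.
#' @param folds,modelSpec,seed as in [crossvalTrain()].
#' @return list with `features` (final subset), `trace` (data.frame of
#'   removed features and the AUC after each removal), and `fullAuc`.
#' @export
backwardSelect <- function(table, startFeatures = featureNames(),
                           targetSize = 7L, tolerance = NULL,
                           folds = 5L, modelSpec = list(type = "xgboost"),
                           seed = 42L) {
  stopifnot(targetSize >= 1L)
  current <- startFeatures
  cvAuc <- function(feats)
    crossvalTrain(table, folds, feats, modelSpec, seed)$auc
  fullAuc <- cvAuc(current)
  trace <- data.frame(removed = character(0), auc = numeric(0),
                      stringsAsFactors = FALSE)
  while (length(current) > targetSize) {
    aucs <- vapply(seq_along(current), function(k)
      cvAuc(current[-k]), 0)
    best <- which.max(aucs)
    if (!is.null(tolerance) && aucs[best] < fullAuc - tolerance) break
    trace <- rbind(trace, data.frame(removed = current[best],
                                     auc = aucs[best],
                                     stringsAsFactors = FALSE))
    current <- current[-best]
  }
  list(features = current, trace = trace, fullAuc = fullAuc)
}

#' Hyperparameter grid search on the validation folds
#'
#' Evaluates each grid point by combined cross-fold AUC; the test partition
#' is never touched. The grid must cover the six tuned dimensions
#' (`max_depth`, `n_estimators`, `learning_rate`, `gamma`, `lambda`,
#' `min_child_weight`); extra columns are passed through.
#'
#' @param table a [FeatureTable-class] (training + validation rows only).
#' @param grid data.frame, one row per configuration.
#' @param features,folds,seed as in [crossvalTrain()].
#' @return list with `best` (named list), `results` (grid + auc column).
#' @export
tuneHyperparams <- function(table, grid, features = featureNames(),
                            folds = 5L, seed = 42L) {
  need <- c("max_depth", "n_estimators", "learning_rate", "gamma",
            "lambda", "min_child_weight")
  if (!nrow(grid))
    .err("ppiConfigError", "empty hyperparameter grid")
  miss <- setdiff(need, names(grid))
  if (length(miss))
    .err("ppiConfigError", "grid missing dimension(s): %s",
         paste(miss, collapse = ", "))
  aucs <- vapply(seq_len(nrow(grid)), function(i) {
    spec <- list(type = "xgboost", params = as.list(grid[i, , drop = FALSE]))
    crossvalTrain(table, folds, features, spec, seed)$auc
  }, 0)
  best <- which.max(aucs)
  list(best = as.list(grid[best, , drop = FALSE]),
       results = cbind(grid, auc = aucs))
}

#' Train the final interaction classifier
#'
#' Fits on all provided rows with the given feature subset and
#' hyperparameters; stores the ordered feature manifest subset, seed and
#' the cross-fold AUC, plus a threshold-performance table computed from
#' pooled cross-fold predictions.
#'
#' @param table a [FeatureTable-class] of training(+validation) rows.
#' @param features ordered feature subset.
#' @param hyperparams named list (xgboost dimensions) or NULL for defaults.
#' @param modelSpec classifier backend spec (default xgboost).
#' @param folds folds for the stored cross-fold AUC / threshold table.
#' @param seed integer seed.
#' @return a [TrainedModel-class].
#' @export
trainModel <- function(table, features = featureNames(),
                       hyperparams = NULL,
                       modelSpec = list(type = "xgboost"), folds = 5L,
                       seed = 42L) {
  if (!is.null(hyperparams)) modelSpec$params <- hyperparams
  cv <- crossvalTrain(table, folds, features, modelSpec, seed)
  fit <- .fitClassifier(.featureMatrix(table, features),
                        .labels01(table), modelSpec, seed)
  thr <- thresholdTable(cv$predictions$score,
                        cv$predictions$label == "active")
  new("TrainedModel", fit = fit, type = modelSpec$type,
      features = features,
      hyperparams = modelSpec$params %||% .defaultXgbParams,
      thresholds = thr,
      metadata = list(seed = seed, folds = folds, cv_auc = cv$auc,
                      manifest = manifestVersion(table)))
}

#' Score models and aggregate per complex
#'
#' Scores each feature row with the trained classifier; the complex-level
#' score is the maximum over its (up to five) model scores.
#'
#' @param trained a [TrainedModel-class].
#' @param rows data.frame or [FeatureTable-class] of rows sharing one
#'   `complex_id`.
#' @return list with `complex_score` and `per_model_scores`.
#' @export
scoreComplex <- function(trained, rows) {
  d <- if (is(rows, "FeatureTable")) featureData(rows) else rows
  if (length(unique(d$complex_id)) != 1L)
    .err("ppiGroupingError", "rows must share a single complex_id")
  s <- .predictClassifier(trained@fit,
                          as.matrix(d[, trained@features, drop = FALSE]))
  list(complex_score = max(s), per_model_scores = s)
}

#' Score a whole feature table per complex
#'
#' @param trained a [TrainedModel-class].
#' @param table a [FeatureTable-class].
#' @return data.frame with complex_id, label, score (max over models).
#' @export
scoreTable <- function(trained, table) {
  d <- featureData(table)
  s <- .predictClassifier(trained@fit,
                          as.matrix(d[, trained@features, drop = FALSE]))
  agg <- stats::aggregate(s, by = list(complex_id = d$complex_id), max)
  lab <- d$label[match(agg$complex_id, d$complex_id)]
  data.frame(complex_id = agg$complex_id, label = lab, score = agg$x,
             stringsAsFactors = FALSE)
}

#' Rank-based ROC AUC
#'
#' Mann-Whitney form with half credit for ties: equals U / (n+ * n-).
#'
#' @param scores numeric scores.
#' @param labels logical (or 0/1) positive-class indicator; both classes
#'   must be present.
#' @return AUC in \[0, 1\].
#' @export
rocAuc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L)
    .err("ppiMetricError", "ROC AUC undefined with a single class")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' @param scores,labels as in [rocAuc()].
#' @return data.frame of (threshold, fpr, tpr) sorted by decreasing
#'   threshold.
#' @export
rocCurve <- function(scores, labels) {
  labels <- as.logical(labels)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  pts <- t(vapply(thr, function(t) {
    pred <- scores >= t
    c(fpr = sum(pred & !labels) / sum(!labels),
      tpr = sum(pred & labels) / sum(labels))
  }, c(fpr = 0, tpr = 0)))
  data.frame(threshold = thr, fpr = pts[, "fpr"], tpr = pts[, "tpr"])
}

# Default operating thresholds for the performance table.
.DEFAULT_THRESHOLDS <- c(0.98, 0.95, 0.9, 0.85, 0.8, 0.75, 0.7, 0.64,
                         0.6, 0.56, 0.5, 0.47, 0.4, 0.38, 0.28, 0.21,
                         0.18, 0.08, 0.05, 0)

#' Threshold-performance table
#'
#' Confusion-matrix rates as a function of the score threshold used to
#' call a complex active (`prediction = score >= threshold`). Precision at
#' zero predicted positives is reported as 1 (with recall 0).
#'
#' @param scores numeric complex scores.
#' @param labels logical positive indicator.
#' @param thresholds thresholds to tabulate (default: the 20 standard
#'   operating points).
#' @return data.frame with threshold, FPR, TPR, FNR, TNR, precision,
#'   recall, F1.
#' @export
thresholdTable <- function(scores, labels,
                           thresholds = .DEFAULT_THRESHOLDS) {
  labels <- as.logical(labels)
  if (!any(labels) || all(labels))
    .err("ppiMetricError", "threshold table needs both classes")
  rows <- lapply(thresholds, function(t) {
    pred <- scores >= t
    tp <- sum(pred & labels); fp <- sum(pred & !labels)
    fn <- sum(!pred & labels); tn <- sum(!pred & !labels)
    prec <- if (tp + fp == 0L) 1 else tp / (tp + fp)
    rec <- tp / (tp + fn)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    data.frame(threshold = t, FPR = fp / (fp + tn), TPR = tp / (tp + fn),
               FNR = fn / (tp + fn), TNR = tn / (fp + tn),
               precision = prec, recall = rec, F1 = f1)
  })
  do.call(rbind, rows)
}

# pDockQ sigmoid constants, pinned from the published fit.
.PDOCKQ <- c(L = 0.724, x0 = 152.611, k = 0.052, b = 0.018)

#' Confidence-only baseline scores (iPTM and pDockQ)
#'
#' iPTM is read from the bundle. pDockQ = L / (1 + exp(-k (x - x0))) + b
#' with x = mean interface pLDDT times the natural log of the interface
#' contact-pair count (x = 0 when there are no contacts).
#'
#' @param conf a [ConfidenceBundle-class].
#' @param model the paired [ComplexModel-class].
#' @param iface an [InterfaceMap-class].
#' @return named numeric vector with `iptm` and `pdockq`.
#' @export
baselineScores <- function(conf, model, iface) {
  nContacts <- nrow(iface@pairs)
  ifaceAll <- c(iface@ifaceSet1, iface@ifaceSet2)
  x <- if (nContacts > 0)
    mean(conf@plddt[ifaceAll]) * log(nContacts) else 0
  p <- .PDOCKQ
  c(iptm = conf@iptm,
    pdockq = unname(p["L"] / (1 + exp(-p["k"] * (x - p["x0"]))) + p["b"]))
}

#' Leakage guard
#'
#' Asserts that no complex id crosses split boundaries for the given row
#' assignment.
#'
#' @param complexIds per-row complex ids.
#' @param groupLabels per-row partition labels (split or fold).
#' @return TRUE invisibly; errors on violation.
#' @export
assertGroupIntegrity <- function(complexIds, groupLabels) {
  tab <- table(complexIds, groupLabels)
  bad <- rownames(tab)[rowSums(tab > 0) > 1L]
  if (length(bad))
    .err("ppiDataError", "complex id(s) cross partition boundaries: %s",
         paste(utils::head(bad, 5L), collapse = ", "))
  invisible(TRUE)
}
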