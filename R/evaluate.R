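# A feature table is a wide data.frame with identifier columns subject_id,
# patient_id, group ("epilepsy"/"pnes") followed by numeric feature columns
# named "<band>_<family>_<index>" (e.g. "beta_coverage_1").

FEATURE_ID_COLS <- c("subject_id", "patient_id", "group")

feature_columns <- function(features) {
  setdiff(names(features), FEATURE_ID_COLS)
}

check_feature_table <- function(features) {
  missing <- setdiff(FEATURE_ID_COLS, names(features))
  if (length(missing))
    stopf("feature table lacks columns: %s", paste(missing, collapse = ", "))
  fc <- feature_columns(features)
  if (length(fc) == 0) stopf("feature table has no feature columns")
  for (col in fc) {
    bad <- !is.finite(features[[col]])
    if (any(bad))
      stopf("non-finite value in feature '%s' for subject %s", col,
            features$subject_id[which(bad)[1]])
  }
  invisible(features)
}

#' Enumerate the patient-wise paired cross-validation scheme
#'
#' Every (epilepsy patient, PNES patient) pair in turn forms the test set
#' (all of both patients' epochs); the remaining patients form the training
#' set. With 5 patients per group this gives the 25-fold paired protocol.
#' Enumeration is exhaustive and deterministic.
#'
#' @param patients data.frame with columns `patient_id` and `group`.
#' @return A `split_scheme`: list of folds, each with `test_epilepsy`,
#'   `test_pnes` and `train_patients`.
#' @export
build_split_scheme <- function(patients) {
  stopifnot(all(c("patient_id", "group") %in% names(patients)))
  patients <- unique(patients[, c("patient_id", "group")])
  epi <- patients$patient_id[patients$group == "epilepsy"]
  pnes <- patients$patient_id[patients$group == "pnes"]
  if (length(epi) == 0 || length(pnes) == 0)
    stopf("both groups must be non-empty")
  folds <- list()
  for (e in epi) for (p in pnes) {
    folds[[length(folds) + 1L]] <- list(
      test_epilepsy = e, test_pnes = p,
      train_patients = setdiff(patients$patient_id, c(e, p)))
  }
  structure(folds, class = "split_scheme")
}

#' Confusion-matrix classification metrics
#'
#' Precision, recall (sensitivity), accuracy and specificity with
#' `positive` as the positive class, plus the trapezoidal AUC when scores
#' are supplied. If no positive predictions exist, precision is recorded as
#' 0 with `precision_undefined = TRUE`.
#'
#' @param truth,predicted Character/factor vectors of equal length.
#' @param scores Optional numeric scores (higher = more positive) for AUC.
#' @param positive Positive class label (default `"epilepsy"`).
#' @return List of metrics.
#' @export
compute_metrics <- function(truth, predicted, scores = NULL,
                            positive = "epilepsy") {
  if (length(truth) != length(predicted)) stopf("length mismatch")
  truth_pos <- truth == positive
  pred_pos <- predicted == positive
  tp <- sum(truth_pos & pred_pos)
  fp <- sum(!truth_pos & pred_pos)
  fn <- sum(truth_pos & !pred_pos)
  tn <- sum(!truth_pos & !pred_pos)
  precision_undefined <- (tp + fp) == 0
  list(
    precision = if (precision_undefined) 0 else tp / (tp + fp),
    recall = if (tp + fn > 0) tp / (tp + fn) else 0,
    accuracy = (tp + tn) / length(truth),
    specificity = if (tn + fp > 0) tn / (tn + fp) else 0,
    auc = if (!is.null(scores)) roc_curve(scores, truth, positive)$auc
          else NA_real_,
    precision_undefined = precision_undefined
  )
}

#' ROC curve and trapezoidal AUC
#'
#' Standard threshold sweep over the score values; returns the false/true
#' positive rate pairs and the trapezoidal area under the curve.
#'
#' @param scores Numeric scores, higher meaning more `positive`.
#' @param truth Class labels.
#' @param positive Positive class label (default `"epilepsy"`).
#' @return List with `fpr`, `tpr`, `thresholds`, `auc`.
#' @export
roc_curve <- function(scores, truth, positive = "epilepsy") {
  truth_pos <- truth == positive
  n_pos <- sum(truth_pos)
  n_neg <- sum(!truth_pos)
  if (n_pos == 0 || n_neg == 0)
    stopf("ROC needs both classes present")
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(truth_pos[ord])
  fp <- cumsum(!truth_pos[ord])
  # collapse tied scores to the last index of each tie block
  keep <- c(diff(scores[ord]) != 0, TRUE)
  tpr <- c(0, tp[keep] / n_pos)
  fpr <- c(0, fp[keep] / n_neg)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  list(fpr = fpr, tpr = tpr,
       thresholds = c(Inf, scores[ord][keep]), auc = auc)
}

# ---- classifier wrappers -------------------------------------------------
# Each takes standardized train/test matrices and a factor y (levels
# c("pnes", "epilepsy")) and returns list(pred = character, score = numeric
# probability-like score for the positive class "epilepsy").

fit_predict <- function(classifier, xtr, ytr, xte, seed) {
  set.seed(seed)
  pos <- "epilepsy"
  ytr <- factor(ytr, levels = c("pnes", "epilepsy"))
  switch(classifier,
    knn = {
      pr <- class::knn(xtr, xte, ytr, k = 5, prob = TRUE)
      p <- attr(pr, "prob")
      score <- ifelse(pr == pos, p, 1 - p)
      list(pred = as.character(pr), score = score)
    },
    svm_linear = ,
    svm_rbf = {
      fit <- e1071::svm(xtr, ytr,
                        kernel = if (classifier == "svm_linear") "linear"
                                 else "radial",
                        probability = TRUE, scale = FALSE)
      pr <- predict(fit, xte, probability = TRUE)
      score <- attr(pr, "probabilities")[, pos]
      list(pred = as.character(pr), score = as.numeric(score))
    },
    decision_tree = {
      df_tr <- data.frame(xtr, y = ytr, check.names = FALSE)
      fit <- rpart::rpart(y ~ ., data = df_tr, method = "class")
      prob <- predict(fit, data.frame(xte, check.names = FALSE),
                      type = "prob")[, pos]
      list(pred = ifelse(prob >= 0.5, pos, "pnes"), score = as.numeric(prob))
    },
    random_forest = {
      fit <- randomForest::randomForest(xtr, ytr, ntree = 100)
      prob <- predict(fit, xte, type = "prob")[, pos]
      list(pred = ifelse(prob >= 0.5, pos, "pnes"), score = as.numeric(prob))
    },
    gradient_boosting = {
      fit <- xgboost::xgb.train(
        params = list(objective = "binary:logistic", max_depth = 3,
                      eta = 0.3, nthread = 1),
        data = xgboost::xgb.DMatrix(xtr, label = as.integer(ytr == pos)),
        nrounds = 50, verbose = 0)
      prob <- predict(fit, xgboost::xgb.DMatrix(xte))
      list(pred = ifelse(prob >= 0.5, pos, "pnes"), score = as.numeric(prob))
    },
    stopf("unknown classifier '%s'", classifier)
  )
}

#' Default classifier battery
#' @return Character vector of classifier names understood by
#'   [run_battery()].
#' @export
default_classifiers <- function() {
  c("knn", "svm_linear", "svm_rbf", "decision_tree", "random_forest",
    "gradient_boosting")
}

#' Run a classifier battery under the patient-wise split scheme
#'
#' For every fold: feature columns are z-scored using training-fold
#' statistics only, each classifier is fitted on the training subjects and
#' evaluated on the held-out patient pair, and confusion-matrix metrics plus
#' AUC are computed. Reported values are means over folds.
#'
#' @param features A feature table (see [check_feature_table()]).
#' @param scheme A `split_scheme` from [build_split_scheme()].
#' @param classifiers Character vector (default [default_classifiers()]).
#' @param seed Integer seed (fold x classifier fits are deterministic).
#' @return data.frame with one row per classifier (mean precision, recall,
#'   accuracy, specificity, auc) and attribute `per_fold` holding the
#'   fold-level values.
#' @export
run_battery <- function(features, scheme, classifiers = default_classifiers(),
                        seed = 1) {
  check_feature_table(features)
  stopifnot(inherits(scheme, "split_scheme"))
  fc <- feature_columns(features)
  per_fold <- list()
  for (clf in classifiers) {
    for (i in seq_along(scheme)) {
      fold <- scheme[[i]]
      te <- features$patient_id %in% c(fold$test_epilepsy, fold$test_pnes)
      tr <- features$patient_id %in% fold$train_patients
      xtr <- as.matrix(features[tr, fc, drop = FALSE])
      xte <- as.matrix(features[te, fc, drop = FALSE])
      mu <- colMeans(xtr)
      sdv <- apply(xtr, 2, sd)
      sdv[sdv == 0 | !is.finite(sdv)] <- 1
      xtr <- sweep(sweep(xtr, 2, mu), 2, sdv, "/")
      xte <- sweep(sweep(xte, 2, mu), 2, sdv, "/")
      res <- fit_predict(clf, xtr, features$group[tr], xte,
                         seed = derive_seed(seed, paste0(clf, "-", i)))
      m <- compute_metrics(features$group[te], res$pred, res$score)
      per_fold[[length(per_fold) + 1L]] <- data.frame(
        classifier = clf, fold = i,
        precision = m$precision, recall = m$recall, accuracy = m$accuracy,
        specificity = m$specificity, auc = m$auc,
        stringsAsFactors = FALSE)
    }
  }
  per_fold <- do.call(rbind, per_fold)
  summ <- aggregate(per_fold[, c("precision", "recall", "accuracy",
                                 "specificity", "auc")],
                    by = list(classifier = per_fold$classifier), FUN = mean)
  summ <- summ[match(classifiers, summ$classifier), ]
  rownames(summ) <- NULL
  attr(summ, "per_fold") <- per_fold
  summ
}

# Drop feature columns whose name matches any of the given regexes.
drop_features <- function(features, patterns) {
  fc <- feature_columns(features)
  drop <- unique(unlist(lapply(patterns, grep, x = fc, value = TRUE)))
  keep <- c(FEATURE_ID_COLS, setdiff(fc, drop))
  features[, keep, drop = FALSE]
}

#' Leave-one-band-out importance protocol
#'
#' Runs the battery on the full multi-band feature table, then once per
#' band with that band's feature columns removed. The band whose removal
#' degrades performance most carries the most discriminative information.
#'
#' @param features Feature table with band-prefixed column names
#'   (`"<band>_..."`).
#' @param scheme A `split_scheme`.
#' @param classifiers Classifier names.
#' @param seed Integer seed.
#' @return data.frame of battery summaries stacked over settings (`setting`
#'   column: `"All"`, `"All-<band>"`).
#' @export
leave_one_band_out <- function(features, scheme,
                               classifiers = default_classifiers(),
                               seed = 1) {
  fc <- feature_columns(features)
  bands <- unique(sub("_.*$", "", fc))
  out <- run_battery(features, scheme, classifiers, seed)
  out$setting <- "All"
  for (b in bands) {
    res <- run_battery(drop_features(features, paste0("^", b, "_")),
                       scheme, classifiers, seed)
    res$setting <- paste0("All-", b)
    out <- rbind(out, res)
  }
  out[, c("setting", setdiff(names(out), "setting"))]
}

#' Leave-one-feature-out importance protocol for microstate statistics
#'
#' Runs the battery on the full microstate feature table and once per
#' temporal feature family (occurrence, duration, coverage) with that
#' family's columns removed.
#'
#' @param features Microstate feature table with columns
#'   `"<band>_<family>_<class>"`.
#' @param scheme A `split_scheme`.
#' @param classifiers Classifier names.
#' @param seed Integer seed.
#' @param families Feature families to leave out (default the three
#'   microstate statistics).
#' @return data.frame of battery summaries stacked over settings.
#' @export
leave_one_feature_out <- function(features, scheme,
                                  classifiers = default_classifiers(),
                                  seed = 1,
                                  families = c("occurrence", "duration",
                                               "coverage")) {
  out <- run_battery(features, scheme, classifiers, seed)
  out$setting <- "All"
  for (f in families) {
    res <- run_battery(drop_features(features, paste0("_", f, "_")),
                       scheme, classifiers, seed)
    res$setting <- paste0("All-", f)
    out <- rbind(out, res)
  }
  out[, c("setting", setdiff(names(out), "setting"))]
}
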