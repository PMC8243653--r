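# Random-forest training, patient-wise cross-validation and metrics.

#' Random-forest configuration
#'
#' Defaults are the tuned values used by the pipeline: 500 trees,
#' minimum 10 samples to split, minimum 2 per leaf, maximum depth 20,
#' and no bootstrap resampling (every tree sees all training rows;
#' randomness enters through per-node feature subsampling only).
#'
#' @param n_trees number of trees.
#' @param min_split minimum node size to attempt a split.
#' @param min_leaf minimum samples per child.
#' @param max_depth maximum tree depth.
#' @param mtry features tried per node; `NULL` = floor(sqrt(p)).
#' @param seed integer seed (mandatory for reproducibility).
#' @return an `rf_config` list.
#' @export
rf_config <- function(n_trees = 500L, min_split = 10L, min_leaf = 2L,
                      max_depth = 20L, mtry = NULL, seed = 20210616L) {
  structure(list(n_trees = as.integer(n_trees),
                 min_split = as.integer(min_split),
                 min_leaf = as.integer(min_leaf),
                 max_depth = as.integer(max_depth),
                 mtry = if (is.null(mtry)) NULL else as.integer(mtry),
                 seed = as.integer(seed)),
            class = "rf_config")
}

#' Train a random forest on a feature matrix
#'
#' `mode = "binary"` relabels N and V to `Other` (S vs Other PAC
#' detection); `mode = "multiclass"` keeps N/S/V. Prediction returns
#' per-class vote fractions (average of leaf class proportions).
#'
#' @param x numeric feature matrix (rows = beats).
#' @param y character labels in {N,S,V}.
#' @param cfg an [rf_config].
#' @param mode `"multiclass"` or `"binary"`.
#' @return an `rf_model`.
#' @export
train_rf <- function(x, y, cfg = rf_config(), mode = c("multiclass", "binary")) {
  mode <- match.arg(mode)
  x <- as.matrix(x)
  y <- as.character(y)
  if (mode == "binary") y <- ifelse(y == "S", "S", "Other")
  classes <- sort(unique(y))
  if (length(classes) < 2L) {
    stop("train_rf: training labels are all one class")
  }
  mtry <- if (is.null(cfg$mtry)) max(1L, floor(sqrt(ncol(x)))) else cfg$mtry
  seeds <- vapply(seq_len(cfg$n_trees),
                  function(t) derive_seed(cfg$seed, paste0("tree", t)), 0L)
  fit <- .rf_train_cpp(x, match(y, classes) - 1L, length(classes),
                       cfg$n_trees, mtry, cfg$min_split, cfg$min_leaf,
                       cfg$max_depth, seeds)
  structure(list(trees = fit$trees,
                 importance = stats::setNames(as.numeric(fit$importance),
                                              colnames(x)),
                 classes = classes, mode = mode, features = colnames(x),
                 cfg = cfg),
            class = "rf_model")
}

#' Predict with a trained forest
#'
#' @param object an `rf_model`.
#' @param newdata feature matrix with the training columns.
#' @param type `"class"` (argmax, ties to first class in sorted order)
#'   or `"prob"` (vote-fraction matrix).
#' @param ... unused.
#' @export
predict.rf_model <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  x <- as.matrix(newdata)
  if (!is.null(object$features) && !is.null(colnames(x))) {
    x <- x[, object$features, drop = FALSE]
  }
  prob <- .rf_predict_cpp(object$trees, x, length(object$classes))
  colnames(prob) <- object$classes
  if (type == "prob") return(prob)
  object$classes[max.col(prob, ties.method = "first")]
}

#' Impurity-based feature importance
#'
#' Mean decrease in gini impurity, weighted by node sample fraction and
#' normalized to sum to 1 over features.
#'
#' @param model an `rf_model`.
#' @param top return only the `top` highest-ranked features (NULL =
#'   all).
#' @return data.frame `feature`, `importance`, sorted decreasing.
#' @export
feature_importance <- function(model, top = NULL) {
  imp <- sort(model$importance, decreasing = TRUE)
  df <- data.frame(feature = names(imp), importance = as.numeric(imp),
                   stringsAsFactors = FALSE)
  if (!is.null(top)) df <- head(df, top)
  df
}

#' Assign patients to folds balancing the S proportion
#'
#' Greedy longest-processing-time heuristic: patients sorted by S count
#' descending (ties shuffled with the seed), each assigned to the fold
#' with the lowest running S total; ties broken by fewest patients,
#' then lowest fold id. Every patient lands in exactly one fold.
#'
#' @param patients data.frame with columns `patient_id` and `s_count`.
#' @param k number of folds.
#' @param seed integer seed for tie shuffles.
#' @return a `fold_plan`: data.frame `patient_id`, `fold`, plus
#'   attribute `s_per_fold`.
#' @export
make_folds <- function(patients, k = 10L, seed = 20210616L) {
  stopifnot(all(c("patient_id", "s_count") %in% names(patients)))
  if (nrow(patients) < k) stop("fewer patients than folds")
  ord <- with_seed(derive_seed(seed, "fold"),
                   sample.int(nrow(patients)))
  p <- patients[ord, , drop = FALSE]
  p <- p[order(-p$s_count), , drop = FALSE]  # stable: keeps shuffled ties
  fold_s <- numeric(k)
  fold_n <- integer(k)
  fold <- integer(nrow(p))
  for (r in seq_len(nrow(p))) {
    cand <- which(fold_s == min(fold_s))
    if (length(cand) > 1L) cand <- cand[fold_n[cand] == min(fold_n[cand])]
    f <- cand[1L]
    fold[r] <- f
    fold_s[f] <- fold_s[f] + p$s_count[r]
    fold_n[f] <- fold_n[f] + 1L
  }
  plan <- data.frame(patient_id = p$patient_id, fold = fold,
                     stringsAsFactors = FALSE)
  plan <- plan[order(plan$patient_id), , drop = FALSE]
  rownames(plan) <- NULL
  attr(plan, "s_per_fold") <- fold_s
  attr(plan, "k") <- k
  class(plan) <- c("fold_plan", "data.frame")
  plan
}

#' Cap the per-class training beat count
#'
#' Classes with more than `cap` beats are subsampled uniformly without
#' replacement (seeded); smaller classes are kept whole. Row order of
#' the kept beats is preserved.
#'
#' @param df training feature data.frame with a `label` column.
#' @param cap per-class maximum (default 10000).
#' @param seed integer seed.
#' @export
cap_training <- function(df, cap = 10000L, seed = 20210616L) {
  keep <- logical(nrow(df))
  for (cl in unique(df$label)) {
    rows <- which(df$label == cl)
    if (length(rows) > cap) {
      rows <- with_seed(derive_seed(seed, paste0("cap_", cl)),
                        sort(sample(rows, cap)))
    }
    keep[rows] <- TRUE
  }
  df[keep, , drop = FALSE]
}

#' One-vs-rest classification metrics from labels
#'
#' @param truth,pred character vectors over the same class set.
#' @param classes class order for the confusion matrix.
#' @return list: `confusion` (counts), `confusion_pct` (row-normalized
#'   percent), `per_class` data.frame with accuracy, sensitivity,
#'   specificity, PPV, NPV (percent).
#' @export
evaluate_metrics <- function(truth, pred, classes = sort(unique(truth))) {
  truth <- factor(truth, levels = classes)
  pred <- factor(pred, levels = classes)
  cm <- table(truth = truth, pred = pred)
  pct <- sweep(cm, 1L, pmax(rowSums(cm), 1L), "/") * 100
  per <- do.call(rbind, lapply(classes, function(cl) {
    tp <- cm[cl, cl]
    fn <- sum(cm[cl, ]) - tp
    fp <- sum(cm[, cl]) - tp
    tn <- sum(cm) - tp - fn - fp
    data.frame(class = cl,
               n = tp + fn,
               accuracy = 100 * (tp + tn) / sum(cm),
               sensitivity = 100 * tp / (tp + fn),
               specificity = 100 * tn / (tn + fp),
               ppv = 100 * tp / (tp + fp),
               npv = 100 * tn / (tn + fn),
               stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  list(confusion = unclass(cm), confusion_pct = unclass(pct),
       per_class = per)
}

#' Patient-wise metric summary (median and IQR across patients)
#'
#' Metrics are computed per patient and summarized per class; a patient
#' with no true beats of a class is excluded from that class's summary.
#' Undefined ratios within a patient (e.g. PPV with no predicted
#' positives) are dropped from that statistic's summary.
#'
#' @param df data.frame with columns `patient_id`, `truth`, `pred`.
#' @param classes class set.
#' @return data.frame: class, metric, n_patients, median, q25, q75.
#' @export
patient_metrics <- function(df, classes = sort(unique(df$truth))) {
  out <- list()
  for (cl in classes) {
    vals <- lapply(split(df, df$patient_id), function(d) {
      if (!any(d$truth == cl)) return(NULL)
      tp <- sum(d$truth == cl & d$pred == cl)
      fn <- sum(d$truth == cl & d$pred != cl)
      fp <- sum(d$truth != cl & d$pred == cl)
      tn <- sum(d$truth != cl & d$pred != cl)
      c(accuracy = 100 * (tp + tn) / nrow(d),
        sensitivity = 100 * tp / (tp + fn),
        specificity = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_,
        ppv = if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_,
        npv = if (tn + fn > 0) 100 * tn / (tn + fn) else NA_real_)
    })
    vals <- do.call(rbind, vals[!vapply(vals, is.null, TRUE)])
    if (is.null(vals)) next
    for (m in colnames(vals)) {
      v <- vals[, m]
      out[[length(out) + 1L]] <- data.frame(
        class = cl, metric = m, n_patients = sum(!is.na(v)),
        median = median(v, na.rm = TRUE),
        q25 = unname(quantile(v, 0.25, na.rm = TRUE)),
        q75 = unname(quantile(v, 0.75, na.rm = TRUE)),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Patient-wise k-fold cross-validation
#'
#' For each fold: the feature transform and the per-class cap are
#' fitted on the training folds only, applied to the held-out fold,
#' a forest is trained and the fold predicted. Predictions are pooled
#' for beat-wise metrics; patient-wise metrics are summarized as
#' median/IQR. Train/test patient disjointness is recorded in the
#' audit log.
#'
#' @param features feature data.frame (from [assemble_features()] /
#'   [read_features_csv()]).
#' @param k number of folds.
#' @param cfg an [rf_config] (its seed is the master seed for folds,
#'   caps and trees).
#' @param mode `"multiclass"` or `"binary"`.
#' @param cap per-class training cap.
#' @param corr_max,var_min pruning thresholds.
#' @return a `cv_result` list: `predictions`, `beat_metrics`,
#'   `patient_metrics`, `importances` (top-10 per fold), `fold_plan`,
#'   `audit`.
#' @export
cross_validate <- function(features, k = 10L, cfg = rf_config(),
                           mode = c("multiclass", "binary"),
                           cap = 10000L, corr_max = 0.95, var_min = 0.05) {
  mode <- match.arg(mode)
  stopifnot(all(c("patient_id", "label") %in% names(features)))
  s_counts <- tapply(features$label == "S", features$patient_id, sum)
  patients <- data.frame(patient_id = names(s_counts),
                         s_count = as.integer(s_counts),
                         stringsAsFactors = FALSE)
  plan <- make_folds(patients, k = k, seed = cfg$seed)
  fmap <- stats::setNames(plan$fold, plan$patient_id)
  fold_of_beat <- fmap[features$patient_id]

  preds <- vector("list", k)
  imps <- vector("list", k)
  audit <- vector("list", k)
  for (f in seq_len(k)) {
    train_df <- features[fold_of_beat != f, , drop = FALSE]
    test_df <- features[fold_of_beat == f, , drop = FALSE]
    if (nrow(test_df) == 0L) next
    train_df <- cap_training(train_df, cap = cap,
                             seed = derive_seed(cfg$seed, paste0("capf", f)))
    tr <- fit_feature_transform(train_df, corr_max = corr_max,
                                var_min = var_min)
    xtr <- apply_feature_transform(tr, train_df)
    xte <- apply_feature_transform(tr, test_df)
    fold_cfg <- cfg
    fold_cfg$seed <- derive_seed(cfg$seed, paste0("rf", f))
    model <- train_rf(xtr, train_df$label, fold_cfg, mode = mode)
    truth <- if (mode == "binary") {
      ifelse(test_df$label == "S", "S", "Other")
    } else test_df$label
    preds[[f]] <- data.frame(patient_id = test_df$patient_id,
                             beat_sample = test_df$beat_sample,
                             fold = f, truth = truth,
                             pred = predict(model, xte),
                             stringsAsFactors = FALSE)
    imps[[f]] <- cbind(fold = f, feature_importance(model, top = 10L))
    audit[[f]] <- list(
      fold = f,
      train_patients = sort(unique(train_df$patient_id)),
      test_patients = sort(unique(test_df$patient_id)),
      disjoint = length(intersect(train_df$patient_id,
                                  test_df$patient_id)) == 0L,
      n_train = nrow(train_df), n_test = nrow(test_df),
      dropped_var = tr$dropped_var, dropped_corr = tr$dropped_corr,
      n_features = length(tr$keep))
  }
  predictions <- do.call(rbind, preds)
  classes <- if (mode == "binary") c("Other", "S") else PAC_CLASSES
  structure(list(
    predictions = predictions,
    beat_metrics = evaluate_metrics(predictions$truth, predictions$pred,
                                    classes),
    patient_metrics = patient_metrics(predictions, classes),
    importances = do.call(rbind, imps),
    fold_plan = plan, audit = audit, mode = mode, k = k),
    class = "cv_result")
}
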